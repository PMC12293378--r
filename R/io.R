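#' Write a simulated cohort to plain-text tables
#'
#' Emits `patients.tsv` (patient_id, arm, tmb, os_months, event),
#' `marker_calls.tsv` in long format (patient_id, marker_id, dilution,
#' present), `expression.tsv` (genes x patients, tab-separated, header row of
#' patient ids), and a sidecar `bundle.json` recording the seed and a hash of
#' the generating configuration. All writers are locale-independent (C
#' locale decimal points, no grouping).
#'
#' @param cohort A `ccm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ccm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.tsv"),
             marker_calls = file.path(dir, "marker_calls.tsv"),
             expression = file.path(dir, "expression.tsv"),
             sidecar = file.path(dir, "bundle.json"))

  write_tsv(cohort$patients, paths["patients"])

  dn <- dimnames(cohort$marker_calls)
  long <- expand.grid(patient_id = dn[[1]], marker_id = dn[[2]],
                      dilution = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$present <- as.integer(cohort$marker_calls)
  long <- long[order(long$marker_id, long$dilution, long$patient_id), ]
  write_tsv(long, paths["marker_calls"])

  expr <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, paths["expression"])

  sidecar <- list(seed = cohort$seed,
                  config_hash = config_hash(cohort$config),
                  n_patients = nrow(cohort$patients),
                  files = basename(unname(paths[1:3])))
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

write_tsv <- function(df, path) {
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

schema_error <- function(file, line, field, msg) {
  stop(sprintf("%s: line %s: field '%s': %s", file, line, field, msg),
       call. = FALSE)
}

#' Load and validate a cohort bundle written by [write_cohort()]
#'
#' Reads the patients, marker-call, and (optionally) expression tables,
#' enforcing the schema: known arm labels, strictly binary marker calls,
#' positive survival times, unique patient ids, and cross-file patient-id
#' consistency. Violations raise errors naming the file, line, and field.
#'
#' @param dir Directory containing `patients.tsv`, `marker_calls.tsv`, and
#'   optionally `expression.tsv`, or a named list/vector of explicit paths
#'   (`patients`, `marker_calls`, `expression`).
#' @return A `ccm_cohort`-like list with `patients`, `marker_calls` (array),
#'   `expression` (matrix or NULL), and a `load_report` summarizing counts.
#' @export
load_bundle <- function(dir) {
  if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    paths <- list(patients = file.path(dir, "patients.tsv"),
                  marker_calls = file.path(dir, "marker_calls.tsv"),
                  expression = file.path(dir, "expression.tsv"))
  } else paths <- as.list(dir)
  for (nm in c("patients", "marker_calls")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop("bundle file missing: ", nm)
  }

  pf <- paths$patients
  patients <- utils::read.delim(pf, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "tmb", "os_months", "event")
  miss <- setdiff(need, names(patients))
  if (length(miss)) schema_error(pf, 1, miss[1], "required column missing")
  dup <- which(duplicated(patients$patient_id))
  if (length(dup)) schema_error(pf, dup[1] + 1L, "patient_id", "duplicate patient id")
  bad_arm <- which(!patients$arm %in% c("avelumab_bsc", "bsc"))
  if (length(bad_arm))
    schema_error(pf, bad_arm[1] + 1L, "arm",
                 paste0("unknown arm label '", patients$arm[bad_arm[1]], "'"))
  bad_t <- which(!is.finite(patients$os_months) | patients$os_months <= 0)
  if (length(bad_t)) schema_error(pf, bad_t[1] + 1L, "os_months", "must be > 0")
  bad_e <- which(!patients$event %in% c(0L, 1L))
  if (length(bad_e)) schema_error(pf, bad_e[1] + 1L, "event", "must be 0 or 1")
  bad_m <- which(!is.finite(patients$tmb))
  if (length(bad_m)) schema_error(pf, bad_m[1] + 1L, "tmb", "missing TMB")
  patients$arm <- factor(patients$arm, levels = c("bsc", "avelumab_bsc"))

  mf <- paths$marker_calls
  calls <- utils::read.delim(mf, stringsAsFactors = FALSE)
  needm <- c("patient_id", "marker_id", "dilution", "present")
  missm <- setdiff(needm, names(calls))
  if (length(missm)) schema_error(mf, 1, missm[1], "required column missing")
  bad_p <- which(!calls$present %in% c(0L, 1L))
  if (length(bad_p)) schema_error(mf, bad_p[1] + 1L, "present", "non-binary marker call")
  bad_id <- which(!calls$patient_id %in% patients$patient_id)
  if (length(bad_id))
    schema_error(mf, bad_id[1] + 1L, "patient_id",
                 "patient absent from patients table")

  pid <- patients$patient_id
  mid <- sort(unique(calls$marker_id))
  dil <- unique(calls$dilution)
  arr <- array(NA_integer_, dim = c(length(pid), length(mid), length(dil)),
               dimnames = list(pid, mid, dil))
  arr[cbind(match(calls$patient_id, pid), match(calls$marker_id, mid),
            match(calls$dilution, dil))] <- calls$present
  if (anyNA(arr))
    schema_error(mf, NA, "present", "incomplete patient x marker x dilution grid")

  expression <- NULL
  ef <- paths$expression
  if (!is.null(ef) && file.exists(ef)) {
    ex <- utils::read.delim(ef, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(ex)[1] != "gene") schema_error(ef, 1, "gene", "first column must be 'gene'")
    unknown <- setdiff(names(ex)[-1], pid)
    if (length(unknown))
      schema_error(ef, 1, unknown[1], "patient absent from patients table")
    expression <- as.matrix(ex[, -1, drop = FALSE])
    rownames(expression) <- ex$gene
  }

  out <- list(patients = patients, marker_calls = arr, expression = expression,
              latent_immune = NULL, config = NULL, seed = NA_integer_,
              load_report = list(
                n_patients = nrow(patients), n_markers = length(mid),
                n_dilutions = length(dil),
                n_genes = if (is.null(expression)) 0L else nrow(expression)))
  class(out) <- "ccm_cohort"
  out
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write stage results with a reproducibility manifest
#'
#' Writes each element of `results` to `outdir`: data frames as TSV, other
#' objects as JSON. A `manifest.json` lists every emitted file exactly once
#' together with the seed, a configuration hash, and package/R versions.
#' Re-running with identical inputs reproduces identical files.
#'
#' @param results Named list of stage outputs.
#' @param outdir Output directory (created if needed).
#' @param config Configuration object to hash into the manifest (optional).
#' @param seed Seed recorded in the manifest (optional).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, outdir, config = NULL, seed = NA_integer_) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- paste0(nm, ".tsv")
      write_tsv(format_ne(x), file.path(outdir, f))
    } else {
      f <- paste0(nm, ".json")
      jsonlite::write_json(strip_unserializable(x), file.path(outdir, f),
                           auto_unbox = TRUE, digits = NA, force = TRUE,
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    files = files,
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    package = "ccmsurv",
    package_version = as.character(utils::packageVersion("ccmsurv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Non-estimable medians and bounds are written as "NE"; other missing values
# as empty fields.
format_ne <- function(df) {
  ne_cols <- intersect(c("os_median", "os_median_lower", "os_median_upper"),
                       names(df))
  for (cl in ne_cols) {
    v <- df[[cl]]
    df[[cl]] <- ifelse(is.na(v), "NE", format(v, trim = TRUE))
  }
  df
}

strip_unserializable <- function(x) {
  if (inherits(x, "elastic_net_report"))
    return(x[c("pair_frequency", "chosen_alpha", "chosen_lambda",
               "coefficients", "selected", "cv_cindex")])
  if (is.list(x)) {
    drop <- vapply(x, function(e) inherits(e, c("survfit", "coxph")), TRUE)
    x <- x[!drop]
  }
  x
}
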