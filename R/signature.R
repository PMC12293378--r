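#' The packaged 26-gene tumor immune signature
#'
#' Returns the 26 gene symbols of the tumor immune expression signature used
#' throughout the package (T/NK-cell dominated; per-unit scores are the mean
#' of normalized expression over these genes).
#'
#' @return Character vector of 26 unique gene symbols.
#' @export
jav_immuno_genes <- function() {
  path <- system.file("extdata", "jav_immuno.txt", package = "ccmsurv")
  if (nzchar(path)) read_signature(path) else .jav_immuno_fallback
}

.jav_immuno_fallback <- c(
  "CCL5", "CD2", "CD244", "CD247", "CD3E", "CD3G", "CD6", "CD8B", "CD96",
  "CST7", "EOMES", "GFI1", "GPR18", "GRAP2", "IL7R", "ITK", "KCNA3", "KLRD1",
  "NLRC3", "PRF1", "PSTPIP1", "SH2D1A", "SIT1", "THEMIS", "TRAT1", "XCL2"
)

#' Read a gene signature from a one-symbol-per-line text file or JSON
#'
#' @param path File path. Plain text: one symbol per line, `#` comments
#'   allowed. JSON: either an array of symbols or an object with a `genes`
#'   field.
#' @return Character vector of unique, non-empty gene symbols.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    genes <- if (is.list(x) && !is.null(x$genes)) x$genes else x
  } else {
    genes <- readLines(path, warn = FALSE)
    genes <- sub("#.*$", "", genes)
  }
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature file contains no gene symbols: ", path)
  if (anyDuplicated(genes)) stop("signature contains duplicated symbols: ", path)
  genes
}

#' Score units against a gene signature
#'
#' The score of a unit (patient or spatial spot) is the mean over signature
#' genes of the per-gene normalized expression. Under `normalization =
#' "zscore"` each gene row is centered and scaled across units before
#' averaging, so the score is invariant to affine rescaling of any gene row.
#'
#' @param expression Numeric matrix, genes x units, with gene symbols as row
#'   names and unit ids as column names.
#' @param signature Character vector of gene symbols (or the result of
#'   [read_signature()]).
#' @param normalization `"zscore"` (default) or `"none"`.
#' @return Data frame of class `signature_scores` with columns `unit_id`,
#'   `score`, `class_label` (NA until [median_split()] is applied). Attributes
#'   `genes_used`, `genes_missing`, `genes_constant` record the gene
#'   accounting.
#' @export
score_signature <- function(expression, signature,
                            normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  signature <- unique(as.character(signature))
  present <- intersect(signature, rownames(expression))
  missing <- setdiff(signature, present)
  if (!length(present))
    stop("empty overlap: no signature gene present in the expression matrix")
  if (normalization == "zscore" && ncol(expression) < 2L)
    stop("zscore normalization requires >= 2 units")

  sub <- expression[present, , drop = FALSE]
  constant <- character(0)
  if (normalization == "zscore") {
    sds <- apply(sub, 1L, stats::sd)
    constant <- rownames(sub)[sds == 0 | !is.finite(sds)]
    if (length(constant)) {
      warning("skipping zero-variance signature gene(s): ",
              paste(constant, collapse = ", "))
      sub <- sub[setdiff(rownames(sub), constant), , drop = FALSE]
      if (!nrow(sub)) stop("all overlapping signature genes have zero variance")
    }
    sub <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  }
  score <- colMeans(sub)
  out <- data.frame(unit_id = colnames(expression), score = as.numeric(score),
                    class_label = NA_character_, stringsAsFactors = FALSE)
  attr(out, "genes_used") <- rownames(sub)
  attr(out, "genes_missing") <- missing
  attr(out, "genes_constant") <- constant
  attr(out, "normalization") <- normalization
  class(out) <- c("signature_scores", "data.frame")
  out
}

#' Split signature scores at the sample median into hi/lo classes
#'
#' A unit is `hi` when its score is strictly greater than the sample median
#' and `lo` when it is less than or equal to the median (a score exactly at
#' the median is `lo`; set `ties = "hi"` for the opposite convention). The
#' median is computed over finite scores only.
#'
#' @param scores A `signature_scores` data frame (or any data frame with a
#'   `score` column).
#' @param ties Class assigned to scores exactly equal to the median.
#' @return The input with `class_label` filled in (`"hi"`/`"lo"`, NA for
#'   non-finite scores) and attribute `median`.
#' @export
median_split <- function(scores, ties = c("lo", "hi")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  finite <- is.finite(scores$score)
  if (sum(finite) < 2L) stop("median split requires >= 2 finite scores")
  med <- stats::median(scores$score[finite])
  lab <- rep(NA_character_, nrow(scores))
  if (ties == "lo") {
    lab[finite] <- ifelse(scores$score[finite] > med, "hi", "lo")
  } else {
    lab[finite] <- ifelse(scores$score[finite] >= med, "hi", "lo")
  }
  if (length(unique(scores$score[finite])) == 1L)
    warning("all scores identical: every unit assigned the tie class")
  scores$class_label <- lab
  attr(scores, "median") <- med
  scores
}

#' Per-gene Pearson correlation with a signature score
#'
#' Computes, for every gene row, the Pearson correlation with the per-unit
#' score, a two-sided p-value from the t transform
#' `t = r * sqrt(n-2) / sqrt(1-r^2)`, and Benjamini-Hochberg q-values over the
#' tested genes. Constant genes are excluded from testing and reported.
#'
#' @param expression Genes x units numeric matrix.
#' @param scores `signature_scores` data frame aligned to the matrix columns
#'   (matched by `unit_id` when column names are present), or a numeric
#'   vector.
#' @return Data frame with columns `gene`, `r`, `p`, `q`, `tested`, sorted by
#'   `p` with untested (constant) genes last.
#' @export
correlate_genes <- function(expression, scores) {
  stopifnot(is.matrix(expression))
  s <- if (is.data.frame(scores)) {
    if (!is.null(colnames(expression)) && "unit_id" %in% names(scores)) {
      idx <- match(colnames(expression), scores$unit_id)
      if (anyNA(idx)) stop("scores missing for some expression columns")
      scores$score[idx]
    } else scores$score
  } else as.numeric(scores)
  n <- ncol(expression)
  if (length(s) != n) stop("scores length does not match number of units")
  if (n < 3L) stop("insufficient data: need >= 3 units for correlation tests")

  sds <- apply(expression, 1L, stats::sd)
  tested <- sds > 0 & is.finite(sds)
  r <- rep(NA_real_, nrow(expression))
  r[tested] <- as.numeric(stats::cor(t(expression[tested, , drop = FALSE]), s))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[tested & !is.finite(tt)] <- 0  # |r| == 1
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(gene = rownames(expression), r = r, p = p, q = q,
                    tested = tested, stringsAsFactors = FALSE)
  out[order(!out$tested, out$p), , drop = FALSE]
}

#' Aggregate spot-level expression over annotated regions
#'
#' Averages each gene (row) over the spots of each region, then z-scores each
#' gene across the region means (the heat-map normalization used for
#' region-level signature displays). With a single region the means are
#' returned and the z-scores are flagged undefined.
#'
#' @param expression Genes x spots numeric matrix (a single signature row is
#'   allowed).
#' @param region_labels Region label per spot (length `ncol(expression)`).
#' @return List with `region_means` (genes x regions), `region_z` (same shape;
#'   all NA when fewer than 2 regions), and `z_defined` flag.
#' @export
aggregate_regions <- function(expression, region_labels) {
  if (is.vector(expression)) expression <- matrix(expression, nrow = 1)
  stopifnot(is.matrix(expression))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(expression))
    stop("every spot needs a region label")
  if (anyNA(region_labels)) stop("every spot needs a region label")
  regions <- sort(unique(region_labels))
  means <- vapply(regions,
                  function(rg) rowMeans(expression[, region_labels == rg, drop = FALSE]),
                  numeric(nrow(expression)))
  means <- matrix(means, nrow = nrow(expression),
                  dimnames = list(rownames(expression), regions))
  z_defined <- length(regions) >= 2L
  if (z_defined) {
    mu <- rowMeans(means)
    sdv <- apply(means, 1L, stats::sd)
    z <- (means - mu) / sdv
    z[sdv == 0, ] <- 0
  } else {
    warning("single region: z-scores across regions are undefined")
    z <- means * NA_real_
  }
  list(region_means = means, region_z = z, z_defined = z_defined)
}
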