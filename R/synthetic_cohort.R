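#' Simulation configuration for a two-arm CCM trial cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator emulates a maintenance-therapy trial population: two arms
#' (active + best supportive care vs BSC alone), a lognormal tumor mutation
#' burden (TMB), binary chromatin conformation marker (CCM) calls measured at
#' several template dilutions, a latent tumor immune score with a correlated
#' gene-expression matrix, and overall survival generated under a
#' proportional-hazards model whose linear predictor may contain per-marker
#' main effects, marker-by-treatment interactions, and
#' marker-by-treatment-by-TMB three-way interactions.
#'
#' Marker calls arise by thinning a latent per-patient marker state with a
#' per-dilution detection probability, so calls at different dilutions are
#' correlated but not nested. Marker effects on survival act through the
#' observed call at `effect_dilution`, so that the causal feature is one the
#' downstream screen can actually see.
#'
#' @param n_patients Number of patients (default 496).
#' @param n_markers Number of CCMs (default 25).
#' @param n_dilutions Number of template dilutions per marker (default 3).
#' @param dilution_labels Labels for the dilutions (default `"1x","2x","4x"`).
#' @param prevalence_range Range from which per-marker latent prevalences are
#'   drawn uniformly when `prevalence` is not given (default 0.15--0.75,
#'   spanning the "<20% to >70%" detection rates seen on real panels).
#' @param prevalence Optional vector of per-marker latent-state probabilities
#'   (recycled to `n_markers`); overrides `prevalence_range`.
#' @param dilution_detection Per-dilution detection probability applied to the
#'   latent marker state; need not be monotone in concentration.
#' @param arm_fraction Fraction randomized to the active arm (default 0.5).
#' @param tmb_log_mean,tmb_log_sd Lognormal TMB parameters; the default
#'   `log(7.66)` anchors the median at 7.66 mutations/Mb.
#' @param beta_trt Log-hazard ratio for treatment (default `log(0.7)`).
#' @param beta_tmb Log-hazard coefficient for standardized log TMB.
#' @param beta_marker,beta_marker_trt,beta_marker_trt_tmb Per-marker log-hazard
#'   coefficients (recycled to `n_markers`) for the marker main effect, the
#'   marker x treatment interaction, and the marker x treatment x TMB
#'   three-way interaction.
#' @param beta_signature Per-marker shift of the latent immune score when the
#'   latent marker state is present (recycled).
#' @param effect_dilution Dilution index at which each marker's survival
#'   effect acts (recycled).
#' @param baseline_rate Baseline hazard rate per month; the default gives a
#'   median untreated survival of 18 months under an exponential baseline.
#' @param weibull_shape Weibull shape of the baseline hazard (1 = exponential).
#' @param censor_admin_time Administrative censoring time in months
#'   (`Inf` disables it).
#' @param censor_dropout_rate Exponential dropout rate per month (0 disables).
#' @param n_genes Number of genes in the simulated expression matrix.
#' @param gene_signature_corr Per-gene target correlation with the latent
#'   immune score. By default the packaged 26-gene immune signature genes get
#'   0.6 and all remaining genes 0.
#' @param gene_names Gene symbols for expression rows. Defaults to the
#'   packaged immune signature symbols followed by `GENE027`, ...
#' @param seed Default seed used by [generate_cohort()] when none is given.
#'
#' @return An object of class `ccm_sim_config` (a validated list).
#' @seealso [generate_cohort()], [true_features()]
#' @export
sim_config <- function(n_patients = 496L,
                       n_markers = 25L,
                       n_dilutions = 3L,
                       dilution_labels = NULL,
                       prevalence_range = c(0.15, 0.75),
                       prevalence = NULL,
                       dilution_detection = NULL,
                       arm_fraction = 0.5,
                       tmb_log_mean = log(7.66),
                       tmb_log_sd = 0.6,
                       beta_trt = log(0.7),
                       beta_tmb = 0,
                       beta_marker = 0,
                       beta_marker_trt = 0,
                       beta_marker_trt_tmb = 0,
                       beta_signature = 0,
                       effect_dilution = 1L,
                       baseline_rate = log(2) / 18,
                       weibull_shape = 1,
                       censor_admin_time = 48,
                       censor_dropout_rate = 0.01,
                       n_genes = 60L,
                       gene_signature_corr = NULL,
                       gene_names = NULL,
                       seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_markers <- as.integer(n_markers)
  n_dilutions <- as.integer(n_dilutions)
  if (n_patients < 1L) stop("config error: n_patients must be >= 1")
  if (n_markers < 1L) stop("config error: n_markers must be >= 1")
  if (n_dilutions < 1L) stop("config error: n_dilutions must be >= 1")

  if (is.null(dilution_labels)) {
    dilution_labels <- paste0(c(1L, 2L, 4L, 8L, 16L)[seq_len(min(n_dilutions, 5L))], "x")
    if (n_dilutions > 5L) dilution_labels <- c(dilution_labels, paste0("d", 6:n_dilutions))
  }
  if (length(dilution_labels) != n_dilutions)
    stop("config error: dilution_labels must have length n_dilutions")

  if (length(prevalence_range) != 2L || any(!is.finite(prevalence_range)) ||
      any(prevalence_range <= 0) || any(prevalence_range >= 1) ||
      prevalence_range[1] > prevalence_range[2])
    stop("config error: prevalence_range must be an increasing pair within (0,1)")
  if (!is.null(prevalence)) {
    prevalence <- rep_len(prevalence, n_markers)
    if (any(prevalence < 0 | prevalence > 1))
      stop("config error: prevalence must lie in [0,1]")
  }

  if (is.null(dilution_detection))
    dilution_detection <- c(1, 0.85, 0.7, 0.6, 0.5)[seq_len(min(n_dilutions, 5L))]
  dilution_detection <- rep_len(dilution_detection, n_dilutions)
  if (any(dilution_detection < 0 | dilution_detection > 1))
    stop("config error: dilution_detection must lie in [0,1]")

  if (arm_fraction <= 0 || arm_fraction >= 1)
    stop("config error: arm_fraction must lie in (0,1)")
  if (tmb_log_sd <= 0) stop("config error: tmb_log_sd must be > 0")
  if (baseline_rate <= 0 || weibull_shape <= 0)
    stop("config error: baseline hazard parameters must be > 0")
  if (censor_admin_time <= 0) stop("config error: censor_admin_time must be > 0")
  if (censor_dropout_rate < 0) stop("config error: censor_dropout_rate must be >= 0")

  effect_dilution <- rep_len(as.integer(effect_dilution), n_markers)
  if (any(effect_dilution < 1L | effect_dilution > n_dilutions))
    stop("config error: effect_dilution indices out of range")

  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("config error: n_genes must be >= 1")
  if (is.null(gene_names)) {
    sig <- jav_immuno_genes()
    gene_names <- c(sig[seq_len(min(n_genes, length(sig)))],
                    sprintf("GENE%03d", seq_len(max(0L, n_genes - length(sig))) + length(sig)))
  }
  gene_names <- rep_len(as.character(gene_names), n_genes)
  if (anyDuplicated(gene_names)) stop("config error: gene_names must be unique")
  if (is.null(gene_signature_corr)) {
    gene_signature_corr <- ifelse(gene_names %in% jav_immuno_genes(), 0.6, 0)
  }
  gene_signature_corr <- rep_len(gene_signature_corr, n_genes)
  if (any(abs(gene_signature_corr) > 1))
    stop("config error: gene_signature_corr must lie in [-1,1]")

  cfg <- list(
    n_patients = n_patients, n_markers = n_markers, n_dilutions = n_dilutions,
    dilution_labels = dilution_labels,
    prevalence_range = prevalence_range, prevalence = prevalence,
    dilution_detection = dilution_detection,
    arm_fraction = arm_fraction,
    tmb_log_mean = tmb_log_mean, tmb_log_sd = tmb_log_sd,
    beta_trt = beta_trt, beta_tmb = beta_tmb,
    beta_marker = rep_len(beta_marker, n_markers),
    beta_marker_trt = rep_len(beta_marker_trt, n_markers),
    beta_marker_trt_tmb = rep_len(beta_marker_trt_tmb, n_markers),
    beta_signature = rep_len(beta_signature, n_markers),
    effect_dilution = effect_dilution,
    baseline_rate = baseline_rate, weibull_shape = weibull_shape,
    censor_admin_time = censor_admin_time, censor_dropout_rate = censor_dropout_rate,
    n_genes = n_genes, gene_signature_corr = gene_signature_corr,
    gene_names = gene_names,
    seed = as.integer(seed)
  )
  class(cfg) <- "ccm_sim_config"
  cfg
}

#' @export
print.ccm_sim_config <- function(x, ...) {
  cat("ccm_sim_config:", x$n_patients, "patients,", x$n_markers, "markers x",
      x$n_dilutions, "dilutions,", x$n_genes, "genes\n")
  tf <- true_features(x)
  cat("  nonzero survival effects:", nrow(tf), "\n")
  invisible(x)
}

marker_ids <- function(config) sprintf("CCM%03d", seq_len(config$n_markers))

# Independent RNG substream per data domain so e.g. adding genes does not
# perturb the survival draws. Seeds are a deterministic function of
# (seed, stream name), kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars)) %% 100003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

#' Generate a synthetic trial cohort
#'
#' Draws a cohort under the generative model described in [sim_config()]:
#' latent marker states thinned by per-dilution detection probabilities,
#' lognormal TMB, exponential/Weibull proportional-hazards survival with the
#' configured main, two-way, and three-way effects, independent dropout plus
#' administrative censoring, and an expression matrix whose genes track a
#' latent immune score at the configured correlations.
#'
#' Survival effects use the observed call at each marker's `effect_dilution`.
#' The linear predictor is
#' `beta_trt*trt + beta_tmb*z + sum_m x_m*(beta_marker + beta_marker_trt*trt +
#' beta_marker_trt_tmb*trt*z)` where `z` is the standardized log TMB.
#'
#' @param config A `ccm_sim_config` object.
#' @param seed Integer seed; defaults to `config$seed`. The seed fully
#'   determines the output.
#' @return An object of class `ccm_cohort`: a list with `patients` (data frame
#'   with `patient_id`, `arm`, `tmb`, `os_months`, `event`), `marker_calls`
#'   (patients x markers x dilutions binary array), `expression` (genes x
#'   patients matrix), `latent_immune` (ground-truth immune score), and the
#'   generating `config` and `seed`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ccm_sim_config"))
  seed <- as.integer(seed)
  n <- config$n_patients
  m <- config$n_markers
  d <- config$n_dilutions
  pid <- sprintf("P%04d", seq_len(n))
  mid <- marker_ids(config)

  # --- marker domain -------------------------------------------------------
  set.seed(stream_seed(seed, "markers"))
  prev <- config$prevalence
  if (is.null(prev))
    prev <- stats::runif(m, config$prevalence_range[1], config$prevalence_range[2])
  latent <- matrix(stats::rbinom(n * m, 1L, rep(prev, each = n)), n, m,
                   dimnames = list(pid, mid))
  calls <- array(0L, dim = c(n, m, d),
                 dimnames = list(pid, mid, config$dilution_labels))
  for (k in seq_len(d)) {
    det <- matrix(stats::rbinom(n * m, 1L, config$dilution_detection[k]), n, m)
    calls[, , k] <- latent * det
  }

  # --- survival domain -----------------------------------------------------
  set.seed(stream_seed(seed, "survival"))
  n_trt <- round(n * config$arm_fraction)
  trt <- integer(n)
  trt[sample.int(n, n_trt)] <- 1L
  tmb <- stats::rlnorm(n, config$tmb_log_mean, config$tmb_log_sd)
  z <- (log(tmb) - config$tmb_log_mean) / config$tmb_log_sd

  xeff <- matrix(0L, n, m)
  for (j in seq_len(m)) xeff[, j] <- calls[, j, config$effect_dilution[j]]
  lp <- config$beta_trt * trt + config$beta_tmb * z +
    xeff %*% config$beta_marker +
    (xeff * trt) %*% config$beta_marker_trt +
    (xeff * (trt * z)) %*% config$beta_marker_trt_tmb
  lp <- as.numeric(lp)

  u <- stats::runif(n)
  t_event <- (-log(u) / (config$baseline_rate * exp(lp)))^(1 / config$weibull_shape)
  t_drop <- if (config$censor_dropout_rate > 0)
    stats::rexp(n, config$censor_dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, config$censor_admin_time)
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # --- expression domain ---------------------------------------------------
  set.seed(stream_seed(seed, "expression"))
  shift <- as.numeric(latent %*% config$beta_signature)
  immune <- stats::rnorm(n) + shift
  iz <- if (stats::sd(immune) > 0) (immune - mean(immune)) / stats::sd(immune)
        else immune * 0
  g <- config$n_genes
  gene_mean <- stats::rnorm(g, 5, 1.5)
  noise <- matrix(stats::rnorm(g * n), g, n)
  r <- config$gene_signature_corr
  expr <- matrix(gene_mean, g, n) +
    r * matrix(iz, g, n, byrow = TRUE) +
    sqrt(1 - r^2) * noise
  dimnames(expr) <- list(config$gene_names, pid)

  patients <- data.frame(
    patient_id = pid,
    arm = factor(ifelse(trt == 1L, "avelumab_bsc", "bsc"),
                 levels = c("bsc", "avelumab_bsc")),
    tmb = tmb,
    os_months = os,
    event = event,
    stringsAsFactors = FALSE
  )

  out <- list(patients = patients, marker_calls = calls, expression = expr,
              latent_immune = immune, config = config, seed = seed)
  class(out) <- "ccm_cohort"
  out
}

#' @export
print.ccm_cohort <- function(x, ...) {
  cat("ccm_cohort:", nrow(x$patients), "patients,",
      dim(x$marker_calls)[2], "markers x", dim(x$marker_calls)[3], "dilutions,",
      nrow(x$expression), "genes;",
      sum(x$patients$event), "events\n")
  invisible(x)
}

#' Ground-truth survival-effect features of a simulation configuration
#'
#' Lists the (marker, dilution) features given any nonzero generative
#' log-hazard coefficient, labeled by the highest-order nonzero term
#' (`three_way` > `two_way` > `main`).
#'
#' @param config A `ccm_sim_config` object.
#' @return Data frame with columns `marker_id`, `dilution` (index),
#'   `dilution_label`, `tier`.
#' @export
true_features <- function(config) {
  stopifnot(inherits(config, "ccm_sim_config"))
  tier <- rep(NA_character_, config$n_markers)
  tier[config$beta_marker != 0] <- "main"
  tier[config$beta_marker_trt != 0] <- "two_way"
  tier[config$beta_marker_trt_tmb != 0] <- "three_way"
  keep <- !is.na(tier)
  data.frame(
    marker_id = marker_ids(config)[keep],
    dilution = config$effect_dilution[keep],
    dilution_label = config$dilution_labels[config$effect_dilution[keep]],
    tier = tier[keep],
    stringsAsFactors = FALSE
  )
}

#' Flatten marker calls into a patients x features binary matrix
#'
#' @param cohort A `ccm_cohort`, or a marker-call array shaped like
#'   `cohort$marker_calls`.
#' @return Binary matrix with one column per (marker, dilution) feature named
#'   `"<marker>@<dilution label>"`.
#' @export
feature_matrix <- function(cohort) {
  calls <- if (inherits(cohort, "ccm_cohort")) cohort$marker_calls else cohort
  stopifnot(length(dim(calls)) == 3L)
  dn <- dimnames(calls)
  m <- dim(calls)[2]; d <- dim(calls)[3]
  out <- matrix(calls, nrow = dim(calls)[1], ncol = m * d)
  colnames(out) <- as.vector(outer(dn[[2]], dn[[3]], function(a, b) paste0(a, "@", b)))
  rownames(out) <- dn[[1]]
  out[, order(rep(seq_len(m), d) * 10L + rep(seq_len(d), each = m)), drop = FALSE]
}

split_feature_id <- function(feature) {
  parts <- strsplit(feature, "@", fixed = TRUE)
  data.frame(marker_id = vapply(parts, `[`, "", 1L),
             dilution_label = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}
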