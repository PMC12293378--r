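#' Fit a Cox proportional hazards model and tidy the result
#'
#' Thin wrapper around [survival::coxph()] returning a per-term table of
#' log-hazard coefficients, hazard ratios, standard errors, Wald z statistics
#' and two-sided p-values, plus the partial log-likelihood and a convergence
#' flag. Monotone likelihoods (perfect separation, flagged by an infinite or
#' huge coefficient standard error) are reported as non-converged rather than
#' silently returned.
#'
#' @param data Data frame containing `time`, `event` (or the columns named in
#'   `time_col`/`event_col`) and the covariates.
#' @param terms Right-hand-side model formula as a string or formula, e.g.
#'   `"x * trt * tmb"`.
#' @param ties Ties method, `"efron"` (default) or `"breslow"`.
#' @param time_col,event_col Column names for the survival outcome.
#' @return Object of class `cox_fit`: list with `table` (term, coef, hr, se,
#'   z, p), `loglik` (null and fitted), `n`, `n_event`, `converged`, and the
#'   underlying `fit`.
#' @export
fit_cox <- function(data, terms, ties = c("efron", "breslow"),
                    time_col = "os_months", event_col = "event") {
  ties <- match.arg(ties)
  if (!all(c(time_col, event_col) %in% names(data)))
    stop("data must contain columns '", time_col, "' and '", event_col, "'")
  if (any(data[[time_col]] <= 0)) stop("survival times must be positive")
  if (sum(data[[event_col]]) < 1L) stop("at least one event is required")
  rhs <- if (inherits(terms, "formula")) paste(deparse(terms[[2]]), collapse = "")
         else as.character(terms)
  fml <- stats::as.formula(
    paste0("survival::Surv(", time_col, ", ", event_col, ") ~ ", rhs))

  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-8, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik converged", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("model matrix is rank deficient")
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  converged <- !warned && all(is.finite(se)) && all(abs(cf) < 15)
  out <- list(
    table = data.frame(term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
                       se = unname(se), z = unname(z),
                       p = 2 * stats::pnorm(-abs(unname(z))),
                       stringsAsFactors = FALSE),
    loglik = fit$loglik, n = fit$n, n_event = fit$nevent,
    converged = converged, ties = ties, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (", x$ties, " ties): n = ", x$n, ", events = ", x$n_event,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Kaplan-Meier curve with median survival and log-log confidence interval
#'
#' Product-limit estimate of the survival function; the median is the
#' smallest observed time at which the estimated survival falls to 0.5 or
#' below, with a Brookmeyer-Crowley style confidence interval from the
#' log-log transformed curve. A median (or bound) the curve never reaches is
#' returned as `NA` and rendered as `"NE"` (not estimable) by the table
#' writers.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = observed, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `median`, `lower`, `upper`, `n`, `n_event`, and the
#'   underlying `survfit` object.
#' @export
km_median <- function(times, events, conf_level = 0.95) {
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  q <- stats::quantile(fit, probs = 0.5)
  list(median = unname(q$quantile), lower = unname(q$lower),
       upper = unname(q$upper), n = sum(fit$n), n_event = sum(fit$n.event),
       fit = fit)
}

#' Arm x TMB-stratum x marker-status survival table
#'
#' Builds the eight-row subgroup table for one (marker, dilution) feature:
#' within each arm x TMB stratum, patient and event counts and KM medians per
#' marker status, plus an unadjusted Cox hazard ratio comparing marker-absent
#' vs marker-present patients with its Wald confidence interval and p-value.
#' TMB strata split at the cohort median: `lo` is TMB <= median, `hi` is TMB
#' > median by default (`boundary = "lt_lo"` puts the median itself in the hi
#' stratum). Empty or single-status cells yield `NA` (not estimable) entries
#' rather than errors.
#'
#' @param cohort A `ccm_cohort`.
#' @param marker_id Marker identifier (e.g. `"CCM007"`).
#' @param dilution Dilution label or index for the feature.
#' @param tmb_threshold Stratum boundary; defaults to the cohort TMB median.
#' @param boundary `"le_lo"` (default; lo stratum is TMB <= threshold) or
#'   `"lt_lo"` (lo stratum is TMB < threshold).
#' @param conf_level Confidence level for the HR interval.
#' @return Data frame of class `subgroup_survival_table` with columns `arm`,
#'   `tmb_stratum`, `marker_status`, `n`, `events`, `os_median`,
#'   `os_median_lower`, `os_median_upper`, `hr_absent_vs_present`,
#'   `hr_lower`, `hr_upper`, `p_value` (HR columns populated on the `absent`
#'   row of each pair).
#' @export
subgroup_table <- function(cohort, marker_id, dilution = 1L,
                           tmb_threshold = NULL,
                           boundary = c("le_lo", "lt_lo"),
                           conf_level = 0.95) {
  stopifnot(inherits(cohort, "ccm_cohort"))
  boundary <- match.arg(boundary)
  pts <- cohort$patients
  dn <- dimnames(cohort$marker_calls)
  if (!marker_id %in% dn[[2]]) stop("unknown marker: ", marker_id)
  dl <- if (is.numeric(dilution)) dn[[3]][dilution] else as.character(dilution)
  if (!dl %in% dn[[3]]) stop("unknown dilution: ", dilution)
  x <- cohort$marker_calls[, marker_id, dl]
  if (is.null(tmb_threshold)) tmb_threshold <- stats::median(pts$tmb)
  stratum <- if (boundary == "le_lo") ifelse(pts$tmb > tmb_threshold, "hi", "lo")
             else ifelse(pts$tmb >= tmb_threshold, "hi", "lo")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  rows <- list()
  for (arm in levels(pts$arm)[c(2, 1)]) {
    for (st in c("lo", "hi")) {
      sel <- pts$arm == arm & stratum == st
      hr <- c(NA_real_, NA_real_, NA_real_); pv <- NA_real_
      both <- sum(sel & x == 1L) > 0L && sum(sel & x == 0L) > 0L
      if (both && sum(pts$event[sel]) > 0L) {
        d <- data.frame(os_months = pts$os_months[sel], event = pts$event[sel],
                        absent = 1L - x[sel])
        f <- tryCatch(fit_cox(d, "absent"), error = function(e) NULL)
        if (!is.null(f) && f$converged) {
          b <- f$table$coef[1]; s <- f$table$se[1]
          hr <- exp(c(b, b - zq * s, b + zq * s)); pv <- f$table$p[1]
        }
      }
      for (ms in c("absent", "present")) {
        sel2 <- sel & x == (if (ms == "absent") 0L else 1L)
        if (sum(sel2)) {
          km <- km_median(pts$os_months[sel2], pts$event[sel2], conf_level)
          med <- c(km$median, km$lower, km$upper)
        } else med <- c(NA_real_, NA_real_, NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, tmb_stratum = st, marker_status = ms,
          n = sum(sel2), events = sum(pts$event[sel2]),
          os_median = med[1], os_median_lower = med[2], os_median_upper = med[3],
          hr_absent_vs_present = if (ms == "absent") hr[1] else NA_real_,
          hr_lower = if (ms == "absent") hr[2] else NA_real_,
          hr_upper = if (ms == "absent") hr[3] else NA_real_,
          p_value = if (ms == "absent") pv else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "marker_id") <- marker_id
  attr(out, "dilution") <- dl
  attr(out, "tmb_threshold") <- tmb_threshold
  attr(out, "boundary") <- boundary
  class(out) <- c("subgroup_survival_table", "data.frame")
  out
}

#' Per-gene three-way interaction scan
#'
#' For every gene passing the expression filters, fits an unadjusted Cox
#' model containing the gene x treatment x TMB interaction and all
#' lower-order terms (gene expression and TMB continuous), and reports the
#' three-way coefficient with its two-sided Wald p-value. Genes expressed
#' (value > `expressed_cutoff`) in at most half of the samples, or with a
#' coefficient of variation (SD/mean x 100 on the supplied scale) of at most
#' `cv_min` percent, are excluded with a recorded reason; non-convergent fits
#' are flagged, not dropped.
#'
#' @param cohort A `ccm_cohort` (or data frame with `os_months`, `event`,
#'   `arm`/`trt`, `tmb`).
#' @param expression Genes x patients matrix aligned to the cohort (defaults
#'   to `cohort$expression`).
#' @param expressed_cutoff Expression value above which a gene counts as
#'   expressed in a sample (default 0).
#' @param expressed_min Minimum expressed fraction, exclusive (default 0.5).
#' @param cv_min Minimum coefficient of variation in percent, exclusive
#'   (default 5).
#' @return Data frame of class `gene_scan_result`: `gene`, `included`,
#'   `reason`, `coef_three_way`, `se`, `p`, sorted by `p` among included
#'   genes.
#' @export
gene_interaction_scan <- function(cohort, expression = NULL,
                                  expressed_cutoff = 0, expressed_min = 0.5,
                                  cv_min = 5) {
  if (inherits(cohort, "ccm_cohort")) {
    if (is.null(expression)) expression <- cohort$expression
    pts <- cohort$patients
  } else pts <- cohort
  stopifnot(is.matrix(expression))
  if (ncol(expression) != nrow(pts)) stop("expression must align to cohort patients")
  trt <- if ("trt" %in% names(pts)) pts$trt else as.integer(pts$arm == "avelumab_bsc")

  genes <- rownames(expression)
  out <- data.frame(gene = genes, included = FALSE, reason = "",
                    coef_three_way = NA_real_, se = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- expression[i, ]
    fr <- mean(g > expressed_cutoff)
    mu <- mean(g); sdv <- stats::sd(g)
    cv <- if (mu != 0) sdv / mu * 100 else Inf
    if (fr <= expressed_min) { out$reason[i] <- "expressed_fraction_le_0.5"; next }
    if (cv <= cv_min) { out$reason[i] <- "cv_le_5"; next }
    d <- data.frame(os_months = pts$os_months, event = pts$event,
                    gene = g, trt = trt, tmb = pts$tmb)
    f <- tryCatch(fit_cox(d, "gene * trt * tmb"), error = function(e) NULL)
    if (is.null(f)) { out$reason[i] <- "fit_error"; next }
    out$included[i] <- TRUE
    if (!f$converged) out$reason[i] <- "not_converged"
    row <- f$table[f$table$term == "gene:trt:tmb", ]
    out$coef_three_way[i] <- row$coef
    out$se[i] <- row$se
    out$p[i] <- row$p
  }
  out <- out[order(!out$included, out$p), , drop = FALSE]
  class(out) <- c("gene_scan_result", "data.frame")
  out
}
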