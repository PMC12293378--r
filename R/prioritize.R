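#' Configuration for the three-step marker prioritization
#'
#' Step 1 drops features with fewer than `min_group` patients in either the
#' present or absent category, or fewer than `min_subgroup` patients in any of
#' the four arm x presence subgroups. Step 2 runs the nested-Cox dilution
#' cascade at threshold `cascade_alpha`. Step 3 tunes an elastic-net Cox
#' model by repeated stratified `cv_folds`-fold cross-validation on the
#' concordance index, choosing the modal optimal (alpha, lambda) pair across
#' `n_repeats` random partitions.
#'
#' @param min_group Minimum patients in each of present/absent (default 40).
#' @param min_subgroup Minimum patients in each arm x presence subgroup
#'   (default 15).
#' @param cascade_alpha Cascade p-value threshold (default 0.1).
#' @param alpha_grid Elastic-net mixing values in (0, 1].
#' @param n_lambda,lambda_min_ratio Penalty path shape: `n_lambda` log-spaced
#'   values down to `lambda_min_ratio` times the per-alpha maximal penalty.
#' @param cv_folds Cross-validation folds (default 5).
#' @param n_repeats Number of repeated CV partitions. The default (50) is a
#'   desk-scale working value; increase (e.g. to 1000) for production runs.
#' @param tmb_as `"continuous"` (default) or `"median_split"`: how TMB enters
#'   the cascade and interaction models.
#' @param selection_rule Per-repeat hyperparameter rule: `"1se"` (default)
#'   picks, among pairs whose mean CV concordance is within one standard
#'   error of the best, the sparsest model (fewest nonzero coefficients on
#'   the full-data path, ties toward the larger penalty); `"max"` is the
#'   strict argmax of mean CV concordance.
#' @param seed Integer seed for fold generation.
#' @return Object of class `ccm_prioritization_config`.
#' @export
prioritization_config <- function(min_group = 40L, min_subgroup = 15L,
                                  cascade_alpha = 0.1,
                                  alpha_grid = seq(0.1, 1, by = 0.1),
                                  n_lambda = 50L, lambda_min_ratio = 1e-3,
                                  cv_folds = 5L, n_repeats = 50L,
                                  tmb_as = c("continuous", "median_split"),
                                  selection_rule = c("1se", "max"),
                                  seed = 1L) {
  tmb_as <- match.arg(tmb_as)
  selection_rule <- match.arg(selection_rule)
  if (min_group < 1L || min_subgroup < 1L) stop("config error: thresholds must be positive")
  if (cascade_alpha <= 0 || cascade_alpha >= 1)
    stop("config error: cascade_alpha must lie in (0,1)")
  if (!length(alpha_grid) || any(alpha_grid <= 0 | alpha_grid > 1))
    stop("config error: alpha_grid values must lie in (0,1]")
  if (n_lambda < 2L) stop("config error: n_lambda must be >= 2")
  if (cv_folds < 2L) stop("config error: cv_folds must be >= 2")
  if (n_repeats < 1L) stop("config error: n_repeats must be >= 1")
  structure(list(min_group = as.integer(min_group),
                 min_subgroup = as.integer(min_subgroup),
                 cascade_alpha = cascade_alpha,
                 alpha_grid = sort(alpha_grid),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 cv_folds = as.integer(cv_folds),
                 n_repeats = as.integer(n_repeats),
                 tmb_as = tmb_as, selection_rule = selection_rule,
                 seed = as.integer(seed)),
            class = "ccm_prioritization_config")
}

#' Step 1: subgroup count filter
#'
#' Tags every (marker, dilution) feature as kept or dropped. A feature is
#' kept iff both the present and absent categories contain at least
#' `min_group` patients and each of the four arm x presence subgroups
#' (active arm present/absent, BSC present/absent) contains at least
#' `min_subgroup` patients.
#'
#' @param cohort A `ccm_cohort` or a patients x features binary matrix (in
#'   which case `arm` must be supplied).
#' @param features Optional subset of feature ids to assess.
#' @param min_group,min_subgroup Count thresholds (defaults 40 / 15).
#' @param arm Arm factor when `cohort` is a bare matrix.
#' @return Data frame of class `filter_report`: per-feature counts, the four
#'   subgroup counts, `kept`, `reason`.
#' @export
filter_features <- function(cohort, features = NULL, min_group = 40L,
                            min_subgroup = 15L, arm = NULL) {
  if (inherits(cohort, "ccm_cohort")) {
    X <- feature_matrix(cohort)
    arm <- cohort$patients$arm
  } else X <- cohort
  stopifnot(is.matrix(X), !is.null(arm), length(arm) == nrow(X))
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  trt <- arm == "avelumab_bsc"

  ids <- split_feature_id(colnames(X))
  n_present <- colSums(X)
  n_absent <- nrow(X) - n_present
  trt_present <- colSums(X[trt, , drop = FALSE])
  bsc_present <- n_present - trt_present
  trt_absent <- sum(trt) - trt_present
  bsc_absent <- sum(!trt) - bsc_present

  group_ok <- pmin(n_present, n_absent) >= min_group
  sub_ok <- pmin(trt_present, trt_absent, bsc_present, bsc_absent) >= min_subgroup
  kept <- group_ok & sub_ok
  reason <- ifelse(kept, "",
                   ifelse(!group_ok, "present/absent group below minimum",
                          "arm x presence subgroup below minimum"))
  out <- data.frame(feature = colnames(X), marker_id = ids$marker_id,
                    dilution_label = ids$dilution_label,
                    n_present = as.integer(n_present),
                    n_absent = as.integer(n_absent),
                    n_trt_present = as.integer(trt_present),
                    n_trt_absent = as.integer(trt_absent),
                    n_bsc_present = as.integer(bsc_present),
                    n_bsc_absent = as.integer(bsc_absent),
                    kept = kept, reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' Dilution-selection rule applied to a grid of p-values
#'
#' Pure decision rule of the cascade, exposed for testing: given the
#' dilutions x tier p-value grid of one marker, selects the dilution with
#' the smallest three-way interaction p-value if that p-value is below
#' `alpha`; otherwise falls through to the two-way interaction, then the
#' main effect; otherwise the marker is eliminated. Missing (`NA`) p-values
#' (unfitted or non-convergent dilutions) are skipped.
#'
#' @param p_grid Numeric matrix, one row per dilution, with columns
#'   `three_way`, `two_way`, `main`.
#' @param alpha Selection threshold (default 0.1).
#' @return List with `tier` (`"three_way"`, `"two_way"`, `"main"`, or
#'   `"eliminated"`), `dilution` (row index or NA), `p` (selected p or NA).
#' @export
cascade_decision <- function(p_grid, alpha = 0.1) {
  p_grid <- as.matrix(p_grid)
  stopifnot(all(c("three_way", "two_way", "main") %in% colnames(p_grid)))
  for (tier in c("three_way", "two_way", "main")) {
    p <- p_grid[, tier]
    p[!is.finite(p)] <- Inf
    if (any(p < alpha)) {
      k <- which.min(p)
      return(list(tier = tier, dilution = unname(k), p = unname(p_grid[k, tier])))
    }
  }
  list(tier = "eliminated", dilution = NA_integer_, p = NA_real_)
}

# Fit the three nested models for one (marker, dilution) and return the Wald
# p of the highest-order new term in each: M1 marker only; M2 adds treatment
# and marker:treatment; M3 adds TMB and all interactions up to
# marker:treatment:TMB.
cascade_fit_one <- function(d) {
  p_of <- function(rhs, term) {
    f <- tryCatch(fit_cox(d, rhs), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    f$table$p[f$table$term == term]
  }
  c(three_way = p_of("x * trt * tmb", "x:trt:tmb"),
    two_way = p_of("x * trt", "x:trt"),
    main = p_of("x", "x"))
}

#' Step 2: nested-Cox dilution cascade
#'
#' For every marker with at least one surviving feature, fits at each
#' surviving dilution three nested Cox models (marker main effect; + treatment
#' and marker x treatment; + TMB and all two-way terms and the marker x
#' treatment x TMB three-way interaction), extracts the Wald p of the
#' highest-order new term from each model, and applies [cascade_decision()]
#' to pick one dilution per marker or eliminate it.
#'
#' @param cohort A `ccm_cohort`.
#' @param features Feature ids that passed [filter_features()]; dilutions not
#'   listed are not fitted (their p-values are `NA`).
#' @param config A `ccm_prioritization_config`.
#' @return Data frame of class `cascade_report`: per marker, the nine
#'   p-values (`p_<tier>_<dilution>`), `selected_dilution`, `tier`,
#'   `selected_feature`, `selected_p`.
#' @export
dilution_cascade <- function(cohort, features, config = prioritization_config()) {
  stopifnot(inherits(cohort, "ccm_cohort"))
  pts <- cohort$patients
  dn <- dimnames(cohort$marker_calls)
  dlabs <- dn[[3]]
  ids <- split_feature_id(features)
  markers <- unique(ids$marker_id)
  tmb <- if (config$tmb_as == "continuous") pts$tmb
         else as.integer(pts$tmb > stats::median(pts$tmb))
  trt <- as.integer(pts$arm == "avelumab_bsc")

  rows <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    p_grid <- matrix(NA_real_, length(dlabs), 3,
                     dimnames = list(dlabs, c("three_way", "two_way", "main")))
    for (dl in ids$dilution_label[ids$marker_id == mk]) {
      d <- data.frame(os_months = pts$os_months, event = pts$event,
                      x = cohort$marker_calls[, mk, dl], trt = trt, tmb = tmb)
      p_grid[dl, ] <- cascade_fit_one(d)
    }
    dec <- cascade_decision(p_grid, config$cascade_alpha)
    row <- data.frame(marker_id = mk, stringsAsFactors = FALSE)
    for (tier in colnames(p_grid))
      for (k in seq_along(dlabs))
        row[[paste0("p_", tier, "_", dlabs[k])]] <- p_grid[k, tier]
    row$tier <- dec$tier
    row$selected_dilution <- if (is.na(dec$dilution)) NA_character_ else dlabs[dec$dilution]
    row$selected_feature <- if (is.na(dec$dilution)) NA_character_
                            else paste0(mk, "@", dlabs[dec$dilution])
    row$selected_p <- dec$p
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cascade_report", "data.frame")
  out
}

# Harrell's concordance of each linear-predictor column against the outcome,
# computed over precomputed comparable pairs (event i before j). Ties in the
# predictor count 1/2.
comparable_pairs <- function(time, status) {
  ev <- which(status == 1L)
  i <- rep(ev, times = length(time))
  j <- rep(seq_along(time), each = length(ev))
  keep <- time[j] > time[i]
  list(i = i[keep], j = j[keep])
}

# One repeat's hyperparameter choice from the per-(alpha, lambda) mean CV
# concordance. "max": strict argmax (within an alpha, ties fall to the
# larger lambda because paths are stored in descending order). "1se": among
# pairs within one standard error of the best mean concordance, minimize the
# full-data path sparsity, then prefer larger lambda, then larger alpha.
pick_pair <- function(alphas, lam, dfs, cmeans, csds, rule) {
  grid <- do.call(rbind, lapply(seq_along(alphas), function(ai) {
    if (is.null(cmeans[[ai]])) return(NULL)
    data.frame(alpha = alphas[ai], lambda = lam[[ai]], df = dfs[[ai]],
               cindex = cmeans[[ai]], se = csds[[ai]])
  }))
  if (is.null(grid) || !nrow(grid)) stop("no hyperparameter pair evaluable")
  best <- which.max(grid$cindex)
  if (rule == "max") {
    sel <- best
  } else {
    thr <- grid$cindex[best] - grid$se[best]
    cand <- which(grid$cindex >= thr)
    ord <- order(grid$df[cand], -grid$lambda[cand], -grid$alpha[cand])
    sel <- cand[ord[1]]
  }
  data.frame(alpha = grid$alpha[sel], lambda = grid$lambda[sel],
             df = grid$df[sel], cindex = grid$cindex[sel])
}

cindex_cols <- function(lp, pairs) {
  if (!length(pairs$i)) return(rep(NA_real_, ncol(lp)))
  vapply(seq_len(ncol(lp)), function(k) {
    v <- lp[, k]
    if (v[1] == v[length(v)] && all(v == v[1])) return(0.5)  # constant predictor
    d <- v[pairs$i] - v[pairs$j]
    mean(d > 0) + 0.5 * mean(d == 0)
  }, numeric(1))
}

#' Step 3: elastic-net Cox selection with CV-frequency hyperparameter choice
#'
#' Fits penalized Cox models over a grid of elastic-net mixing values `alpha`
#' and per-alpha penalty paths `lambda`. On each of `n_repeats` random
#' event-stratified `cv_folds`-fold partitions, the held-out concordance
#' index is averaged over folds for every (alpha, lambda) and one optimal
#' pair is recorded according to `config$selection_rule`: the default `"1se"`
#' rule takes, among pairs within one standard error of the best mean
#' concordance, the one whose full-data path model is sparsest (ties toward
#' the larger penalty, then the larger mixing value); `"max"` is the strict
#' argmax. The modal pair across repeats (ties resolved toward the larger
#' penalty, then the larger alpha) is refitted on the full data; the features
#' with nonzero coefficients form the selection. Binary features are
#' deliberately not standardized, so presence/absence indicators share one
#' scale.
#'
#' @param cohort A `ccm_cohort`, or a patients x features binary matrix (then
#'   supply `time` and `event`).
#' @param features Feature ids (columns) to offer to the model; at least 2.
#' @param config A `ccm_prioritization_config`.
#' @param time,event Outcome vectors when `cohort` is a bare matrix.
#' @return Object of class `elastic_net_report`: list with `pair_frequency`
#'   (data frame of per-repeat optimal pairs), `chosen_alpha`,
#'   `chosen_lambda`, `coefficients` (named vector at the chosen pair),
#'   `selected` (nonzero features), `cv_cindex` (mean CV concordance at the
#'   chosen pair), `cv_surface` (per-alpha mean concordance matrices).
#' @export
elastic_net_select <- function(cohort, features, config = prioritization_config(),
                               time = NULL, event = NULL) {
  if (inherits(cohort, "ccm_cohort")) {
    X <- feature_matrix(cohort)[, features, drop = FALSE]
    time <- cohort$patients$os_months
    event <- cohort$patients$event
  } else X <- cohort[, features, drop = FALSE]
  if (ncol(X) < 2L) stop("elastic net needs >= 2 features")
  if (sum(event) < config$cv_folds) stop("too few events for stratified folding")
  y <- survival::Surv(time, event)
  alphas <- config$alpha_grid

  # shared per-alpha lambda path (and path sparsity) from the full data
  full_paths <- lapply(alphas, function(a)
    glmnet::glmnet(X, y, family = "cox", alpha = a, nlambda = config$n_lambda,
                   lambda.min.ratio = config$lambda_min_ratio,
                   standardize = FALSE))
  lam <- lapply(full_paths, function(f) f$lambda)
  dfs <- lapply(full_paths, function(f) f$df)
  names(lam) <- names(dfs) <- as.character(alphas)

  set.seed(config$seed)
  picks <- vector("list", config$n_repeats)
  csum <- lapply(lam, function(l) numeric(length(l)))
  for (r in seq_len(config$n_repeats)) {
    foldid <- stratified_folds(event, config$cv_folds)
    cmeans <- csds <- vector("list", length(alphas))
    for (ai in seq_along(alphas)) {
      a <- alphas[ai]
      cmat <- matrix(NA_real_, config$cv_folds, length(lam[[ai]]))
      for (k in seq_len(config$cv_folds)) {
        tr <- foldid != k
        fit <- tryCatch(
          glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "cox",
                         alpha = a, lambda = lam[[ai]], standardize = FALSE),
          error = function(e) NULL)
        if (is.null(fit)) next
        lp <- stats::predict(fit, X[!tr, , drop = FALSE], s = lam[[ai]])
        pr <- comparable_pairs(time[!tr], event[!tr])
        cmat[k, ] <- cindex_cols(lp, pr)
      }
      ok <- stats::complete.cases(cmat)
      if (!any(ok)) next
      cmeans[[ai]] <- colMeans(cmat[ok, , drop = FALSE])
      csds[[ai]] <- apply(cmat[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
      csum[[ai]] <- csum[[ai]] + cmeans[[ai]]
    }
    picks[[r]] <- pick_pair(alphas, lam, dfs, cmeans, csds, config$selection_rule)
  }
  picks <- do.call(rbind, picks)

  key <- paste(picks$alpha, signif(picks$lambda, 10))
  tab <- table(key)
  cand <- names(tab)[tab == max(tab)]
  info <- unique(picks[key %in% cand, c("alpha", "lambda")])
  info <- info[order(-info$lambda, -info$alpha), , drop = FALSE]
  chosen_alpha <- info$alpha[1]
  chosen_lambda <- info$lambda[1]

  ai <- match(chosen_alpha, alphas)
  final <- glmnet::glmnet(X, y, family = "cox", alpha = chosen_alpha,
                          lambda = lam[[ai]], standardize = FALSE)
  cf <- as.numeric(stats::coef(final, s = chosen_lambda))
  names(cf) <- colnames(X)

  surface <- Map(function(l, cs) data.frame(lambda = l, cindex = cs / config$n_repeats),
                 lam, csum)
  out <- list(
    pair_frequency = stats::setNames(
      stats::aggregate(rep(1L, nrow(picks)),
                       by = list(picks$alpha, picks$lambda), FUN = sum),
      c("alpha", "lambda", "n")),
    picks = picks,
    chosen_alpha = chosen_alpha, chosen_lambda = chosen_lambda,
    coefficients = cf,
    selected = names(cf)[cf != 0],
    cv_cindex = {
      s <- surface[[as.character(chosen_alpha)]]
      s$cindex[which.min(abs(s$lambda - chosen_lambda))]
    },
    cv_surface = surface,
    paths = Map(function(l, d) data.frame(lambda = l, df = d), lam, dfs))
  class(out) <- "elastic_net_report"
  out
}

#' @export
print.elastic_net_report <- function(x, ...) {
  cat("elastic-net Cox selection: chose alpha =", x$chosen_alpha,
      "lambda =", signif(x$chosen_lambda, 4),
      "(CV C-index", round(x$cv_cindex, 3), ")\n")
  cat("  selected", length(x$selected), "of", length(x$coefficients),
      "features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full three-step prioritization
#'
#' Applies the count filter, the dilution cascade, and the elastic-net
#' selection in sequence, each stage consuming the previous stage's
#' survivors. An empty survivor set at any stage terminates with a structured
#' report (status `"empty_after_filter"` / `"empty_after_cascade"` /
#' `"too_few_for_elastic_net"`) rather than an error.
#'
#' @param cohort A `ccm_cohort`.
#' @param features Optional feature-id subset to start from (default: all).
#' @param config A `ccm_prioritization_config`.
#' @return Object of class `ccm_prioritization`: list with `filter`,
#'   `cascade`, `elastic_net` (possibly `NULL`), `selected` (final feature
#'   ids), `status`, and `provenance` (seed, thresholds, per-stage counts).
#' @export
run_prioritization <- function(cohort, features = NULL,
                               config = prioritization_config()) {
  stopifnot(inherits(cohort, "ccm_cohort"))
  filt <- filter_features(cohort, features,
                          min_group = config$min_group,
                          min_subgroup = config$min_subgroup)
  survivors1 <- filt$feature[filt$kept]
  res <- list(filter = filt, cascade = NULL, elastic_net = NULL,
              selected = character(0), status = "ok",
              provenance = list(seed = config$seed, config = unclass(config),
                                n_features_in = nrow(filt),
                                n_after_filter = length(survivors1)))
  class(res) <- "ccm_prioritization"
  if (!length(survivors1)) {
    res$status <- "empty_after_filter"
    return(res)
  }
  casc <- dilution_cascade(cohort, survivors1, config)
  res$cascade <- casc
  survivors2 <- casc$selected_feature[casc$tier != "eliminated"]
  res$provenance$n_after_cascade <- length(survivors2)
  if (!length(survivors2)) {
    res$status <- "empty_after_cascade"
    return(res)
  }
  if (length(survivors2) < 2L) {
    res$status <- "too_few_for_elastic_net"
    res$selected <- survivors2
    return(res)
  }
  enet <- elastic_net_select(cohort, survivors2, config)
  res$elastic_net <- enet
  res$selected <- enet$selected
  res$provenance$n_selected <- length(enet$selected)
  res
}

#' @export
print.ccm_prioritization <- function(x, ...) {
  pv <- x$provenance
  cat("ccm_prioritization (status:", x$status, ")\n")
  cat("  step 1 count filter:  ", pv$n_after_filter, "/", pv$n_features_in,
      "features kept\n")
  if (!is.null(x$cascade))
    cat("  step 2 dilution cascade:", pv$n_after_cascade, "markers retained\n")
  if (!is.null(x$elastic_net))
    cat("  step 3 elastic net:   ", length(x$selected), "features selected\n")
  if (length(x$selected))
    cat("  final:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
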