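#' Univariate marker-vs-signature screen (Wilcoxon rank-sum)
#'
#' For every (marker, dilution) feature, compares the signature score between
#' patients in whom the marker is present vs absent: group sizes, the mean
#' difference `delta = mean(present) - mean(absent)` (the volcano x-axis), a
#' two-sided Wilcoxon rank-sum p-value, and a Benjamini-Hochberg q-value
#' computed jointly over all testable features. The exact Wilcoxon null
#' distribution is used when the smaller group has at most 25 patients and
#' there are no tied scores; otherwise the normal approximation with
#' continuity correction is used. Features with an empty group are flagged
#' and excluded from the FDR adjustment.
#'
#' @param cohort A `ccm_cohort`, or a patients x features binary matrix as
#'   returned by [feature_matrix()].
#' @param scores `signature_scores` data frame (or numeric vector) aligned to
#'   the patients.
#' @return Data frame of class `screen_result`: one row per feature with
#'   columns `feature`, `marker_id`, `dilution_label`, `n_present`,
#'   `n_absent`, `delta`, `direction`, `p_wilcoxon`, `q`, `flag`.
#' @export
univariate_screen <- function(cohort, scores) {
  X <- if (inherits(cohort, "ccm_cohort")) feature_matrix(cohort) else cohort
  stopifnot(is.matrix(X))
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) != nrow(X)) stop("scores must align to cohort patients")

  feats <- colnames(X)
  ids <- split_feature_id(feats)
  out <- data.frame(feature = feats, marker_id = ids$marker_id,
                    dilution_label = ids$dilution_label,
                    n_present = NA_integer_, n_absent = NA_integer_,
                    delta = NA_real_, direction = NA_integer_,
                    p_wilcoxon = NA_real_, q = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (j in seq_along(feats)) {
    x <- X[, j]
    sp <- s[x == 1L]; sa <- s[x == 0L]
    out$n_present[j] <- length(sp); out$n_absent[j] <- length(sa)
    if (!length(sp) || !length(sa)) {
      out$flag[j] <- "empty_group"
      next
    }
    out$delta[j] <- mean(sp) - mean(sa)
    out$direction[j] <- sign(out$delta[j])
    ties <- anyDuplicated(c(sp, sa)) > 0L
    exact <- min(length(sp), length(sa)) <= 25L && !ties
    out$p_wilcoxon[j] <- suppressWarnings(
      stats::wilcox.test(sp, sa, exact = exact, correct = TRUE)$p.value)
  }
  ok <- out$flag == ""
  out$q[ok] <- stats::p.adjust(out$p_wilcoxon[ok], method = "BH")
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Fisher exact contingency screen of features against hi/lo classes
#'
#' Tests each (marker, dilution) feature's 2x2 table of presence against the
#' hi/lo signature class with the two-sided Fisher exact test (summing
#' hypergeometric probabilities no larger than the observed table's).
#' Degenerate margins (all present, all absent, or a single class) are
#' flagged and left untested.
#'
#' @inheritParams univariate_screen
#' @param class_labels Character vector of `"hi"`/`"lo"` per patient, or a
#'   `signature_scores` data frame after [median_split()].
#' @return Data frame: `feature`, `marker_id`, `dilution_label`, the four
#'   cell counts, `p_fisher`, `q`, `flag`.
#' @export
contingency_screen <- function(cohort, class_labels) {
  X <- if (inherits(cohort, "ccm_cohort")) feature_matrix(cohort) else cohort
  stopifnot(is.matrix(X))
  cls <- if (is.data.frame(class_labels)) class_labels$class_label
         else as.character(class_labels)
  if (length(cls) != nrow(X)) stop("class labels must align to cohort patients")
  if (!all(cls %in% c("hi", "lo", NA)))
    stop("class labels must be 'hi'/'lo' (run median_split first)")

  feats <- colnames(X)
  ids <- split_feature_id(feats)
  keep <- !is.na(cls)
  out <- data.frame(feature = feats, marker_id = ids$marker_id,
                    dilution_label = ids$dilution_label,
                    n_present_hi = NA_integer_, n_present_lo = NA_integer_,
                    n_absent_hi = NA_integer_, n_absent_lo = NA_integer_,
                    p_fisher = NA_real_, q = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  for (j in seq_along(feats)) {
    x <- X[keep, j]
    c2 <- cls[keep]
    tab <- table(factor(x, levels = c(1, 0)), factor(c2, levels = c("hi", "lo")))
    out$n_present_hi[j] <- tab[1, 1]; out$n_present_lo[j] <- tab[1, 2]
    out$n_absent_hi[j] <- tab[2, 1]; out$n_absent_lo[j] <- tab[2, 2]
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      out$flag[j] <- "degenerate_margin"
      next
    }
    out$p_fisher[j] <- stats::fisher.test(tab)$p.value
  }
  ok <- out$flag == ""
  out$q[ok] <- stats::p.adjust(out$p_fisher[ok], method = "BH")
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Rank screened features and keep the top k
#'
#' Ranks testable features by BH q-value ascending, breaking ties by absolute
#' mean-difference `|delta|` descending and then by feature id
#' lexicographically, and returns the first `min(k, available)`.
#'
#' @param results A `screen_result` from [univariate_screen()].
#' @param k Number of features to keep (default 150).
#' @return The ranked subset of `results` with a `rank` column prepended.
#' @export
select_top_markers <- function(results, k = 150L) {
  stopifnot(is.data.frame(results), all(c("feature", "q") %in% names(results)))
  cand <- results[!is.na(results$q), , drop = FALSE]
  ad <- if ("delta" %in% names(cand)) -abs(cand$delta) else rep(0, nrow(cand))
  ord <- order(cand$q, ad, cand$feature)
  cand <- cand[ord, , drop = FALSE]
  cand <- utils::head(cand, k)
  cbind(rank = seq_len(nrow(cand)), cand)
}

#' Reduce a candidate panel by stability selection
#'
#' A single documented stand-in for ensemble feature-selection pipelines:
#' repeated cross-validated sparse (elastic-net) logistic classification of
#' the hi/lo class from the binary feature matrix. On each repeat the data
#' are split into stratified folds; a penalized path is fitted on each
#' training set and the penalty with the best held-out accuracy is chosen;
#' features with nonzero coefficients at that penalty are counted as
#' selected. Features are ranked by selection frequency across all
#' repeat-folds and the top `target` are returned together with the mean
#' held-out accuracy. Raw presence/absence indicators are used without
#' standardization ("binary weighting").
#'
#' @param features Patients x features binary matrix (typically the columns
#'   picked by [select_top_markers()]).
#' @param class_labels `"hi"`/`"lo"` per patient (or a data frame from
#'   [median_split()]).
#' @param target Panel size to return (default 25).
#' @param alpha Elastic-net mixing parameter for the classifier (default 0.9,
#'   mostly-lasso).
#' @param cv_folds,n_repeats Cross-validation shape (defaults 5 x 20).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return List with `panel` (character vector, ranked), `frequency` (named
#'   selection frequencies for all features), `accuracy` (mean held-out
#'   accuracy at the chosen penalties).
#' @export
reduce_panel <- function(features, class_labels, target = 25L, alpha = 0.9,
                         cv_folds = 5L, n_repeats = 20L, seed = 1L) {
  stopifnot(is.matrix(features))
  cls <- if (is.data.frame(class_labels)) class_labels$class_label
         else as.character(class_labels)
  keep <- !is.na(cls)
  X <- features[keep, , drop = FALSE]
  y <- as.integer(cls[keep] == "hi")
  if (length(unique(y)) < 2L) stop("degenerate classes: need both hi and lo")
  if (ncol(X) <= target) {
    return(list(panel = colnames(X),
                frequency = stats::setNames(rep(1, ncol(X)), colnames(X)),
                accuracy = NA_real_))
  }
  set.seed(as.integer(seed))
  freq <- stats::setNames(numeric(ncol(X)), colnames(X))
  accs <- c(); n_sel <- 0L
  for (r in seq_len(n_repeats)) {
    foldid <- stratified_folds(y, cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- foldid != k
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = alpha, nlambda = 30,
                            lambda.min.ratio = 1e-2, standardize = FALSE)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
      acc <- colMeans((pr > 0.5) == y[!tr])
      best <- which.max(acc)  # first (largest lambda) on ties
      cf <- as.matrix(stats::coef(fit))[-1L, best]
      freq[cf != 0] <- freq[cf != 0] + 1
      accs <- c(accs, acc[best]); n_sel <- n_sel + 1L
    }
  }
  freq <- freq / n_sel
  ord <- order(-freq, names(freq))
  list(panel = names(freq)[ord][seq_len(target)],
       frequency = freq[ord],
       accuracy = mean(accs))
}

# Event/class-stratified fold assignment: each stratum is spread as evenly as
# possible across folds.
stratified_folds <- function(strata, k) {
  foldid <- integer(length(strata))
  for (g in unique(strata)) {
    idx <- which(strata == g)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}
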