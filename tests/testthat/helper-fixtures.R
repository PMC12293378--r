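# Shared fixtures: all data are built in code at test time.

small_cohort <- function(seed = 1, n = 300, n_markers = 6, n_genes = 30, ...) {
  generate_cohort(sim_config(n_patients = n, n_markers = n_markers,
                             n_genes = n_genes, seed = seed, ...))
}

# Tiny prioritization config for desk-scale module tests.
tiny_pc <- function(seed = 1, ...) {
  prioritization_config(alpha_grid = c(0.5, 1), n_lambda = 20, n_repeats = 5,
                        seed = seed, ...)
}

# Binary feature matrix with given per-feature prevalence, named like the
# simulator's features.
random_features <- function(n, p, prev = 0.5, seed = 1, dilutions = c("1x")) {
  set.seed(seed)
  prev <- rep_len(prev, p)
  X <- sapply(prev, function(pr) rbinom(n, 1L, pr))
  nm <- as.vector(outer(sprintf("CCM%03d", seq_len(ceiling(p / length(dilutions)))),
                        dilutions, paste, sep = "@"))
  colnames(X) <- nm[seq_len(p)]
  rownames(X) <- sprintf("P%04d", seq_len(n))
  X
}

# Exponential PH survival for hand-built designs.
sim_surv <- function(lp, rate = log(2) / 18, admin = Inf, dropout = 0) {
  n <- length(lp)
  t_ev <- rexp(n, rate * exp(lp))
  t_c <- pmin(if (dropout > 0) rexp(n, dropout) else Inf, admin)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}
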