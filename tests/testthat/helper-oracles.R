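# Independent oracles shared by module and acceptance tests:
# exhaustive enumeration, brute-force scans, and recounts that
# re-derive each rule without touching the implementation path.

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# group-label splits (independent oracle).
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  ranks <- rank(pooled)
  splits <- utils::combn(length(pooled), nx)
  W <- apply(splits, 2, function(idx) sum(ranks[idx])) - nx * (nx + 1) / 2
  wobs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  p_le <- mean(W <= wobs)
  p_ge <- mean(W >= wobs)
  min(1, 2 * min(p_le, p_ge))
}

screen_one <- function(x, scores) {
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "CCM001@1x"))
  univariate_screen(X, scores)
}

# Brute-force Cox partial likelihood for one covariate, untied data
# (independent oracle; Efron and Breslow coincide without ties).
grid_cox_coef <- function(time, event, x, grid = seq(-4, 4, by = 1e-3)) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  logpl <- vapply(grid, function(b) {
    eta <- b * x
    sum(vapply(which(event == 1), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(logpl)]
}

# Independent recount oracle for the step-1 filter.
recount_kept <- function(X, arm, min_group = 40, min_subgroup = 15) {
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    trt <- arm == "avelumab_bsc"
    counts <- c(sum(x == 1), sum(x == 0),
                sum(x == 1 & trt), sum(x == 0 & trt),
                sum(x == 1 & !trt), sum(x == 0 & !trt))
    counts[1] >= min_group && counts[2] >= min_group && all(counts[3:6] >= min_subgroup)
  }, logical(1))
}

# Independent case-analysis oracle for the cascade rule, vectorized over a
# matrix of grids (columns: three_way d1..d3, two_way d1..d3, main d1..d3).
oracle_cascade_matrix <- function(G, alpha = 0.1) {
  n <- nrow(G)
  tier <- rep("eliminated", n)
  dil <- rep(NA_integer_, n)
  for (ti in 1:3) {
    block <- G[, (ti - 1) * 3 + 1:3, drop = FALSE]
    block[is.na(block)] <- Inf
    hit <- tier == "eliminated" & apply(block, 1, min) < alpha
    if (any(hit)) {
      dil[hit] <- apply(block[hit, , drop = FALSE], 1, which.min)
      tier[hit] <- c("three_way", "two_way", "main")[ti]
    }
  }
  list(tier = tier, dilution = dil)
}

# Exhaustive per-gene scan oracle for closest_genes.
scan_closest <- function(ccm, genes) {
  res <- list(within = character(0), up = NULL, down = NULL,
              up_d = Inf, down_d = Inf)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$biotype != "protein_coding" || g$chrom != ccm$chrom) next
    if (g$end >= ccm$start && g$start <= ccm$end) {
      res$within <- c(res$within, g$symbol)
    } else if (g$end < ccm$start) {
      d <- ccm$start - g$end - 1
      if (d < res$up_d || (d == res$up_d && g$symbol < res$up)) {
        res$up <- g$symbol; res$up_d <- d
      }
    } else {
      d <- g$start - ccm$end - 1
      if (d < res$down_d || (d == res$down_d && g$symbol < res$down)) {
        res$down <- g$symbol; res$down_d <- d
      }
    }
  }
  res$within <- sort(res$within)
  res
}

random_genes <- function(n, seed, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  start <- sample.int(5e5, n)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(5e4, n),
             symbol = sprintf("G%04d", seq_len(n)),
             biotype = sample(c("protein_coding", "lncRNA"), n,
                              replace = TRUE, prob = c(0.8, 0.2)),
             stringsAsFactors = FALSE)
}
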