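test_that("identical event-time multisets in both groups give a null coefficient", {
  d <- data.frame(os_months = rep(c(3, 7, 12, 20), 2),
                  event = rep(1L, 8),
                  x = rep(c(0, 1), each = 4))
  f <- fit_cox(d, "x")
  expect_lt(abs(f$table$coef), 1e-6)
  expect_equal(f$table$hr, exp(f$table$coef))
})

test_that("coefficient on an n = 6 toy matches brute-force partial likelihood", {
  d <- data.frame(os_months = c(2, 5, 8, 11, 14, 20),
                  event = c(1L, 1L, 1L, 1L, 1L, 0L),
                  x = c(1, 0, 1, 0, 1, 0))
  f <- fit_cox(d, "x")
  b_grid <- grid_cox_coef(d$os_months, d$event, d$x)
  expect_lt(abs(f$table$coef - b_grid), 1e-3)
})

test_that("Cox coefficients are invariant under monotone time transforms", {
  set.seed(20)
  d <- data.frame(x = rbinom(100, 1, 0.5))
  sv <- sim_surv(0.6 * d$x)
  d$os_months <- sv$time; d$event <- sv$event
  f1 <- fit_cox(d, "x")
  d2 <- d; d2$os_months <- d$os_months^1.7 + 0.5 * log1p(d$os_months)
  f2 <- fit_cox(d2, "x")
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-7)
})

test_that("Wald CI covers a true log-HR of 0.7 in at least 93% of replicates", {
  set.seed(21)
  hits <- 0L
  for (r in 1:200) {
    x <- rbinom(5000, 1, 0.5)
    sv <- sim_surv(0.7 * x, admin = 60)
    f <- fit_cox(data.frame(os_months = sv$time, event = sv$event, x = x), "x")
    ci <- f$table$coef + c(-1.96, 1.96) * f$table$se
    if (ci[1] <= 0.7 && 0.7 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})

test_that("perfect separation is flagged rather than silently reported", {
  d <- data.frame(os_months = c(1, 2, 3, 10, 11, 12),
                  event = rep(1L, 6),
                  x = c(1, 1, 1, 0, 0, 0))
  f <- fit_cox(d, "x")
  expect_false(f$converged)
})

test_that("input contracts are enforced", {
  d <- data.frame(os_months = c(1, 2), event = c(1L, 0L), x = c(0, 1))
  expect_error(fit_cox(data.frame(os_months = c(-1, 2), event = c(1L, 1L),
                                  x = c(0, 1)), "x"), "positive")
  expect_error(fit_cox(data.frame(os_months = c(1, 2), event = c(0L, 0L),
                                  x = c(0, 1)), "x"), "event")
  d2 <- data.frame(os_months = 1:4, event = rep(1L, 4), x = c(0, 1, 0, 1))
  d2$x2 <- d2$x
  expect_error(fit_cox(d2, "x + x2"), "rank deficient")
})

test_that("KM median follows the S(t) <= 0.5 convention", {
  km <- km_median(1:9, rep(1L, 9))
  expect_equal(km$median, 5)
  km2 <- km_median(c(2, 4, 9, 12), rep(0L, 4))
  expect_true(is.na(km2$median))  # all censored: not estimable
  expect_error(km_median(numeric(0), integer(0)), "empty")
})

test_that("KM median matches the exponential closed form within 2%", {
  set.seed(22)
  lambda <- log(2) / 18
  t <- rexp(10000, lambda)
  cens <- runif(10000, 60, 120)  # light censoring
  km <- km_median(pmin(t, cens), as.integer(t <= cens))
  expect_lt(abs(km$median - 18) / 18, 0.02)
})

test_that("subgroup table has 8 rows, conserves n, and handles empty cells", {
  co <- small_cohort(seed = 23, n = 400, n_markers = 4)
  tab <- subgroup_table(co, "CCM002", dilution = "2x")
  expect_equal(nrow(tab), 8L)
  expect_equal(sum(tab$n), 400L)
  expect_equal(sum(tab$events), sum(co$patients$event))
  expect_setequal(unique(tab$tmb_stratum), c("lo", "hi"))

  # empty cell: a marker present in nobody still yields NE rows, no crash
  co2 <- co
  co2$marker_calls[, "CCM001", ] <- 0L
  tab2 <- subgroup_table(co2, "CCM001", dilution = "1x")
  expect_equal(nrow(tab2), 8L)
  expect_true(all(is.na(tab2$hr_absent_vs_present)))
  expect_true(all(is.na(tab2$os_median[tab2$marker_status == "present"])))
})

test_that("flipping the comparison direction inverts the hazard ratio exactly", {
  set.seed(24)
  x <- rbinom(300, 1, 0.4)
  sv <- sim_surv(-0.5 * x, admin = 48)
  d <- data.frame(os_months = sv$time, event = sv$event, absent = 1 - x,
                  present = x)
  hr_ab <- exp(fit_cox(d, "absent")$table$coef)
  hr_pr <- exp(fit_cox(d, "present")$table$coef)
  expect_equal(hr_ab, 1 / hr_pr, tolerance = 1e-9)
})

test_that("subgroup HR estimates cover a planted absent-vs-present effect", {
  # one arm x stratum cell with log-HR(absent vs present) = -0.7
  set.seed(25)
  reps <- 500L
  hits <- 0L
  for (r in seq_len(reps)) {
    n <- 1000
    x <- rbinom(n, 1, 0.5)           # marker presence
    sv <- sim_surv(0.7 * x)          # presence is harmful in this cell
    d <- data.frame(os_months = sv$time, event = sv$event, absent = 1 - x)
    f <- fit_cox(d, "absent")
    ci <- f$table$coef + c(-1.96, 1.96) * f$table$se
    if (ci[1] <= -0.7 && -0.7 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.93)
})

test_that("gene scan applies the expression-fraction and CV exclusion rules", {
  set.seed(26)
  n <- 200
  pts <- data.frame(os_months = rexp(n, 0.05), event = rbinom(n, 1, 0.8),
                    trt = rbinom(n, 1, 0.5), tmb = rlnorm(n, log(7.66), 0.6))
  half <- c(rep(0, n / 2), rexp(n / 2, 1) + 1)     # expressed in exactly 50%
  z <- rnorm(n)
  cv5 <- 100 + 5 * (z - mean(z)) / sd(z)           # CV exactly 5%
  good <- rnorm(n, 5, 2)
  expr <- rbind(HALF = half, CV5 = cv5, GOOD = good)
  colnames(expr) <- seq_len(n)
  res <- gene_interaction_scan(pts, expr)
  expect_false(res$included[res$gene == "HALF"])
  expect_equal(res$reason[res$gene == "HALF"], "expressed_fraction_le_0.5")
  expect_false(res$included[res$gene == "CV5"])
  expect_equal(res$reason[res$gene == "CV5"], "cv_le_5")
  expect_true(res$included[res$gene == "GOOD"])
  expect_true(is.finite(res$p[res$gene == "GOOD"]))
})

test_that("a planted three-way gene interaction is recovered with the right sign", {
  set.seed(27)
  n <- 5000
  g <- rnorm(n); trt <- rbinom(n, 1, 0.5); tz <- rnorm(n)
  sv <- sim_surv(0.8 * g * trt * tz, admin = 60)
  pts <- data.frame(os_months = sv$time, event = sv$event, trt = trt, tmb = tz + 10)
  expr <- matrix(g + 6, 1, n, dimnames = list("TARGET", seq_len(n)))
  res <- gene_interaction_scan(pts, expr)
  expect_true(res$included[1])
  expect_gt(res$coef_three_way[1], 0)
  expect_lt(res$p[1], 0.05)
})
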