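test_that("count filter applies the 40/15 boundaries exactly", {
  arm <- rep(c("avelumab_bsc", "bsc"), c(248, 248))
  # 39 carriers: below the present/absent minimum
  x1 <- c(rep(1, 39), rep(0, 457))
  # 200 carriers but only 14 in the treated arm
  x2 <- c(rep(1, 14), rep(0, 234), rep(1, 186), rep(0, 62))
  # comfortable feature
  x3 <- rep(c(1, 0), 248)
  X <- cbind("CCM001@1x" = x1, "CCM002@1x" = x2, "CCM003@1x" = x3)
  rep_ <- filter_features(X, arm = arm)
  expect_equal(rep_$kept, c(FALSE, FALSE, TRUE))
  expect_equal(rep_$n_present[1], 39L)
  expect_equal(rep_$n_trt_present[2], 14L)
  expect_match(rep_$reason[1], "group")
  expect_match(rep_$reason[2], "subgroup")
  # boundary: exactly 40 and exactly 15 are kept
  x4 <- c(rep(1, 15), rep(0, 233), rep(1, 25), rep(0, 223))
  rep4 <- filter_features(cbind("CCM004@1x" = x4), arm = arm)
  expect_true(rep4$kept)
})

test_that("filter equals a brute-force recount on random cohorts", {
  set.seed(30)
  for (r in 1:10) {
    n <- sample(150:400, 1)
    X <- random_features(n, 12, prev = runif(12, 0.02, 0.95), seed = 30 + r,
                         dilutions = c("1x", "2x", "4x"))
    arm <- sample(c("avelumab_bsc", "bsc"), n, replace = TRUE)
    got <- filter_features(X, arm = arm)$kept
    expect_identical(got, recount_kept(X, arm))
  }
})

test_that("filter is invariant to feature order", {
  co <- small_cohort(seed = 31, n = 200, n_markers = 5)
  rep1 <- filter_features(co)
  X <- feature_matrix(co)
  perm <- sample(ncol(X))
  rep2 <- filter_features(X[, perm], arm = co$patients$arm)
  expect_equal(rep2$kept[match(rep1$feature, rep2$feature)], rep1$kept)
})

test_that("cascade decision follows the sequential three-way/two-way/main rule", {
  pg <- matrix(1, 3, 3, dimnames = list(NULL, c("three_way", "two_way", "main")))
  expect_equal(cascade_decision(pg)$tier, "eliminated")

  pg2 <- pg; pg2[, "three_way"] <- c(0.05, 0.2, 0.5)
  dec <- cascade_decision(pg2)
  expect_equal(dec$tier, "three_way")
  expect_equal(dec$dilution, 1L)
  expect_equal(dec$p, 0.05)

  pg3 <- pg; pg3[, "two_way"] <- c(0.5, 0.09, 0.15)
  dec3 <- cascade_decision(pg3)
  expect_equal(dec3$tier, "two_way")
  expect_equal(dec3$dilution, 2L)

  # a sub-threshold lower tier never preempts a qualifying higher tier
  pg4 <- pg; pg4[, "main"] <- 0.001; pg4[2, "three_way"] <- 0.09
  expect_equal(cascade_decision(pg4)$tier, "three_way")

  # NA p-values are skipped, not selected
  pg5 <- pg; pg5[, "three_way"] <- c(NA, 0.08, NA)
  expect_equal(cascade_decision(pg5)$dilution, 2L)
  pg6 <- pg * NA
  expect_equal(cascade_decision(pg6)$tier, "eliminated")
})

test_that("cascade decision equals the case-analysis oracle on random grids", {
  set.seed(32)
  vals <- c(0.05, 0.09, 0.15, 0.5, NA)
  G <- matrix(sample(vals, 9 * 2000, replace = TRUE), ncol = 9)
  oracle <- oracle_cascade_matrix(G)
  for (i in seq_len(nrow(G))) {
    pg <- matrix(G[i, ], 3, 3,
                 dimnames = list(NULL, c("three_way", "two_way", "main")))
    dec <- cascade_decision(pg)
    expect_identical(dec$tier, oracle$tier[i])
    if (!is.na(oracle$dilution[i]))
      expect_identical(dec$dilution, as.integer(oracle$dilution[i]))
  }
})

test_that("cascade p-values agree with directly fitted nested Cox models", {
  co <- small_cohort(seed = 33, n = 250, n_markers = 3,
                     beta_marker = c(0.6, 0, 0))
  filt <- filter_features(co)
  casc <- dilution_cascade(co, filt$feature[filt$kept])
  pts <- co$patients
  d <- data.frame(os_months = pts$os_months, event = pts$event,
                  x = co$marker_calls[, "CCM001", "2x"],
                  trt = as.integer(pts$arm == "avelumab_bsc"), tmb = pts$tmb)
  f1 <- survival::coxph(survival::Surv(os_months, event) ~ x, data = d)
  f3 <- survival::coxph(survival::Surv(os_months, event) ~ x * trt * tmb, data = d)
  p_main <- 2 * pnorm(-abs(coef(f1)["x"] / sqrt(diag(vcov(f1))["x"])))
  p_3way <- 2 * pnorm(-abs(coef(f3)["x:trt:tmb"] / sqrt(vcov(f3)["x:trt:tmb", "x:trt:tmb"])))
  row <- casc[casc$marker_id == "CCM001", ]
  expect_equal(row$p_main_2x, unname(p_main), tolerance = 1e-8)
  expect_equal(row$p_three_way_2x, unname(p_3way), tolerance = 1e-8)
})

test_that("nested models are a likelihood hierarchy: M1 <= M2 <= M3", {
  co <- small_cohort(seed = 34, n = 300, n_markers = 3)
  pts <- co$patients
  for (mk in c("CCM001", "CCM002")) {
    d <- data.frame(os_months = pts$os_months, event = pts$event,
                    x = co$marker_calls[, mk, "1x"],
                    trt = as.integer(pts$arm == "avelumab_bsc"), tmb = pts$tmb)
    ll1 <- fit_cox(d, "x")$loglik[2]
    ll2 <- fit_cox(d, "x * trt")$loglik[2]
    ll3 <- fit_cox(d, "x * trt * tmb")$loglik[2]
    expect_gte(ll2, ll1 - 1e-6)
    expect_gte(ll3, ll2 - 1e-6)
  }
})

test_that("elastic-net path sparsity is monotone in the penalty", {
  set.seed(35)
  X <- random_features(400, 10, prev = 0.5, seed = 35)
  lp <- X[, 1] * 0.8 - X[, 2] * 0.8
  sv <- sim_surv(lp, admin = 48)
  en <- elastic_net_select(X, colnames(X), tiny_pc(seed = 36),
                           time = sv$time, event = sv$event)
  for (pth in en$paths) {
    # lambda is stored descending: nonzero count must be non-decreasing
    expect_true(all(diff(pth$df) >= 0))
  }
})

test_that("elastic-net selection is reproducible and respects the feature universe", {
  set.seed(37)
  X <- random_features(300, 8, prev = 0.5, seed = 37)
  sv <- sim_surv(X[, 1] * 1 - X[, 5] * 1, admin = 48)
  a <- elastic_net_select(X, colnames(X), tiny_pc(seed = 38),
                          time = sv$time, event = sv$event)
  b <- elastic_net_select(X, colnames(X), tiny_pc(seed = 38),
                          time = sv$time, event = sv$event)
  expect_identical(a$chosen_alpha, b$chosen_alpha)
  expect_identical(a$chosen_lambda, b$chosen_lambda)
  expect_identical(a$selected, b$selected)
  expect_true(all(a$selected %in% colnames(X)))
  expect_error(elastic_net_select(X, colnames(X)[1], tiny_pc(),
                                  time = sv$time, event = sv$event), ">= 2")
})

test_that("planted features are recovered with reference-fit signs", {
  set.seed(39)
  n <- 2000
  X <- random_features(n, 16, prev = 0.5, seed = 39)
  beta <- numeric(16); beta[c(2, 7, 12)] <- c(1, -1, 1)
  sv <- sim_surv(as.numeric(X %*% beta), admin = 48)
  en <- elastic_net_select(X, colnames(X), tiny_pc(seed = 40),
                           time = sv$time, event = sv$event)
  planted <- colnames(X)[c(2, 7, 12)]
  expect_true(all(planted %in% en$selected))
  # signs agree with an unpenalized reference Cox fit
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ X)
  ref_sign <- sign(coef(ref))[match(planted, colnames(X))]
  expect_equal(unname(sign(en$coefficients[planted])), unname(ref_sign))
})

test_that("pure-noise features yield sparse or empty selections", {
  set.seed(41)
  sizes <- integer(12)
  for (r in seq_len(12)) {
    X <- random_features(250, 8, prev = 0.5, seed = 100 + r)
    sv <- sim_surv(numeric(250), admin = 48)
    en <- elastic_net_select(X, colnames(X), tiny_pc(seed = r),
                             time = sv$time, event = sv$event)
    sizes[r] <- length(en$selected)
  }
  expect_lte(median(sizes), 2)
})

test_that("full prioritization terminates structurally on empty survivor sets", {
  co <- small_cohort(seed = 42, n = 30, n_markers = 3)  # too small for 40/15
  res <- run_prioritization(co, config = tiny_pc())
  expect_equal(res$status, "empty_after_filter")
  expect_s3_class(res$filter, "filter_report")
  expect_null(res$cascade)
  expect_length(res$selected, 0L)
})

test_that("end-to-end prioritization recovers a planted marker at its dilution", {
  # sharply attenuated detection away from the causal 1x dilution makes the
  # generative dilution identifiable
  bm <- c(0, -0.9, 0, 0, 0, 0)
  co <- generate_cohort(sim_config(
    n_patients = 1200, n_markers = 6, n_genes = 5, prevalence = 0.5,
    dilution_detection = c(1, 0.45, 0.25), beta_marker = bm, seed = 43))
  res <- run_prioritization(co, config = tiny_pc(seed = 44))
  expect_equal(res$status, "ok")
  expect_true("CCM002@1x" %in% res$selected)
  casc_row <- res$cascade[res$cascade$marker_id == "CCM002", ]
  expect_false(casc_row$tier == "eliminated")

  res2 <- run_prioritization(co, config = tiny_pc(seed = 44))
  expect_identical(res2$selected, res$selected)
  expect_identical(res2$cascade, res$cascade)
})
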