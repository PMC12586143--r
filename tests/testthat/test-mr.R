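test_that("wald ratio matches the hand-computed delta-method form", {
  h <- make_h(bx = 0.25, by = 0.1, sex = 0.02, sey = 0.04)
  res <- mr_wald_ratio(h)
  expect_identical(res$method, "wald_ratio")
  expect_equal(res$beta, 0.1 / 0.25)
  expect_equal(res$se, 0.04 / 0.25)
  expect_equal(res$pval, 2 * pnorm(-abs(0.4 / 0.16)))
  expect_equal(res$or_value, exp(0.4))
  expect_equal(res$ci_low, exp(0.4 - 1.96 * 0.16))
  expect_error(mr_wald_ratio(make_h(c(0.2, 0.3), c(0.1, 0.1))),
               "exactly one")
  expect_error(mr_wald_ratio(make_h(0, 0.1)), "zero exposure effect")
})

test_that("IVW matches the hand-computed weighted meta-analysis", {
  bx <- c(0.2, 0.4, 0.25)
  by <- c(0.08, 0.18, 0.09)
  sey <- c(0.05, 0.06, 0.04)
  res <- mr_ivw(make_h(bx, by, sey = sey))
  w <- bx^2 / sey^2
  ratios <- by / bx
  beta <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - beta)^2)
  se <- sqrt(1 / sum(w)) * if (q / 2 > 1) sqrt(q / 2) else 1
  expect_equal(res$beta, beta)
  expect_equal(res$se, se)
  expect_equal(res$q_stat, q)
  expect_equal(res$q_pval, pchisq(q, 2, lower.tail = FALSE))
  expect_identical(res$n_snps, 3L)
})

test_that("IVW inflates the SE only under overdispersion", {
  bx <- c(0.3, 0.3, 0.3, 0.3)
  sey <- rep(0.05, 4)
  homog <- mr_ivw(make_h(bx, by = 0.3 * c(0.299, 0.3, 0.301, 0.3),
                         sey = sey))
  expect_equal(homog$se, sqrt(1 / sum(bx^2 / sey^2)))
  heterog <- mr_ivw(make_h(bx, by = c(0.02, 0.2, -0.15, 0.4), sey = sey))
  expect_gt(heterog$q_stat / 3, 1)
  expect_equal(heterog$se,
               sqrt(1 / sum(bx^2 / sey^2)) * sqrt(heterog$q_stat / 3))
})

test_that("duplicating an instrument k times equals multiplying its weight", {
  bx <- c(0.2, 0.35, 0.4)
  by <- c(0.07, 0.1, 0.17)
  sey <- c(0.04, 0.05, 0.06)
  dup <- mr_ivw(make_h(c(bx, rep(bx[2], 2)), c(by, rep(by[2], 2)),
                       sey = c(sey, rep(sey[2], 2))))
  w <- bx^2 / sey^2
  w[2] <- 3 * w[2]
  expect_equal(dup$beta, sum(w * by / bx) / sum(w))
})

test_that("egger recovers an exact linear relationship exactly", {
  bx <- c(0.1, 0.2, 0.3, 0.45)
  by <- 0.1 + 0.4 * bx
  res <- mr_egger(make_h(bx, by))
  expect_equal(res$beta, 0.4)
  expect_equal(res$egger_intercept, 0.1)
})

test_that("egger is invariant to the reported allele orientation", {
  set.seed(4)
  bx <- runif(8, 0.1, 0.4)
  by <- 0.05 + 0.3 * bx + rnorm(8, 0, 0.02)
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  a <- mr_egger(make_h(bx, by))
  b <- mr_egger(make_h(bx * flip, by * flip))
  expect_equal(a$beta, b$beta)
  expect_equal(a$egger_intercept, b$egger_intercept)
  expect_equal(a$se, b$se)
})

test_that("weighted median interpolates the inverse cumulative weight", {
  # equal weights, ratios {1, 2, 100}: median robustness
  expect_equal(protmr:::weighted_median_estimate(c(1, 2, 100), rep(1, 3)), 2)
  # hand-interpolated case: p = (0.2, 0.5, 0.8) crosses 0.5 at the middle
  expect_equal(protmr:::weighted_median_estimate(c(1, 2, 3),
                                                 c(0.4, 0.2, 0.4)), 2)
  # equal weights, odd k: equals the plain median (and the L1 minimizer)
  set.seed(2)
  b <- rnorm(9)
  expect_equal(protmr:::weighted_median_estimate(b, rep(1, 9)), median(b))
})

test_that("weighted median converges to a dominant instrument", {
  est <- protmr:::weighted_median_estimate(c(1, 2, 3), c(0.98, 0.01, 0.01))
  expect_equal(est, 1, tolerance = 0.05)
})

test_that("mr_weighted_median is reproducible and scale-equivariant", {
  h <- make_h(bx = c(0.2, 0.3, 0.25, 0.4), by = c(0.06, 0.1, 0.08, 0.11),
              sey = c(0.04, 0.05, 0.03, 0.06))
  a <- mr_weighted_median(h, n_boot = 50, seed = 1)
  b <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  h2 <- h
  h2$beta_exposure <- h$beta_exposure * 2
  h2$se_exposure <- h$se_exposure * 2
  c_res <- mr_weighted_median(h2, n_boot = 50, seed = 1)
  expect_equal(c_res$beta, a$beta / 2)
})

test_that("weighted mode finds the dominant cluster", {
  expect_equal(protmr:::weighted_mode_estimate(rep(0.3, 4), rep(1, 4)), 0.3)
  est <- protmr:::weighted_mode_estimate(c(0.29, 0.3, 0.31, 5),
                                         rep(1, 4))
  expect_equal(est, 0.3, tolerance = 0.05)
  # weights can overrule counts
  est2 <- protmr:::weighted_mode_estimate(c(0, 0.02, 1, 1.02),
                                          c(5, 5, 0.1, 0.1))
  expect_lt(abs(est2 - 0.01), 0.1)
})

test_that("weighted mode argmax matches a brute-force dense-grid density", {
  set.seed(8)
  ratios <- c(rnorm(6, 0.3, 0.02), rnorm(3, 1, 0.02))
  w <- c(rep(2, 6), rep(0.5, 3))
  est <- protmr:::weighted_mode_estimate(ratios, w, grid_points = 4001)
  s <- 0.9 * min(sd(ratios), mad(ratios)) * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * s, max(ratios) + 3 * s,
              length.out = 4001)
  dens <- vapply(grid, function(x)
    sum(w / sum(w) * dnorm((ratios - x) / s)) / s, numeric(1))
  expect_equal(est, grid[which.max(dens)])
})

test_that("steiger_test follows the Fisher-z comparison", {
  out <- steiger_test(0.01, 35559, 1e-5, 314436)
  z_hand <- (atanh(sqrt(0.01)) - atanh(sqrt(1e-5))) /
    sqrt(1 / (35559 - 3) + 1 / (314436 - 3))
  expect_equal(out$steiger_z, z_hand)
  expect_equal(out$steiger_p, pnorm(z_hand, lower.tail = FALSE))
  expect_true(out$direction_valid)
  # equal variance explained cannot support the direction
  eq <- steiger_test(0.005, 10000, 0.005, 10000)
  expect_false(eq$direction_valid)
})

test_that("steiger_filter uses harmonization sample sizes and returns flags", {
  h <- make_h(bx = c(0.5, 0.01), by = c(0.05, 0.4),
              sex = c(0.01, 0.01), sey = c(0.05, 0.05),
              n_exposure = 20000, n_outcome = 20000)
  out <- steiger_filter(h)
  expect_identical(out$retained$variant_id, "rs001")
  expect_identical(nrow(out$flags), 2L)
  expect_true(out$flags$direction_valid[1])
  expect_false(out$flags$direction_valid[2])
  h_no <- make_h(0.2, 0.1)
  attr(h_no, "n_exposure") <- NULL
  attr(h_no, "n_outcome") <- NULL
  expect_error(steiger_filter(h_no), "sample sizes")
})

test_that("estimator dispatch follows the instrument count", {
  cfg <- protmr_config(n_boot = 20, steiger = FALSE)
  sim <- simulate_pair(mr_scenario("causal", n_snps = 8, n_exposure = 30000,
                                   n_outcome = 30000, case_fraction = 0.2,
                                   gamma_range = c(0.15, 0.3), seed = 21))
  iset <- build_instrument_set(sim$exposure, sim$truth$region,
                               sim$truth$ld^2)
  stopifnot(nrow(iset$instruments) >= 3)
  one <- iset
  one$instruments <- one$instruments[1, , drop = FALSE]
  two <- iset
  two$instruments <- two$instruments[1:2, , drop = FALSE]
  r1 <- run_mr(one, sim$outcome, cfg)
  expect_identical(r1$method, "wald_ratio")
  r2 <- run_mr(two, sim$outcome, cfg)
  expect_identical(r2$method, "ivw")
  r3 <- run_mr(iset, sim$outcome, cfg)
  expect_identical(r3$method,
                   c("ivw", "egger", "weighted_median", "weighted_mode"))
  empty <- iset
  empty$instruments <- empty$instruments[0, , drop = FALSE]
  r0 <- run_mr(empty, sim$outcome, cfg)
  expect_identical(nrow(r0), 0L)
  expect_identical(attr(r0, "status"), "no_instruments")
})

test_that("run_mr attaches steiger flags when filtering is on", {
  sim <- simulate_pair(mr_scenario("causal", n_snps = 8, n_exposure = 30000,
                                   n_outcome = 30000, case_fraction = 0.2,
                                   gamma_range = c(0.15, 0.3), seed = 21))
  iset <- build_instrument_set(sim$exposure, sim$truth$region,
                               sim$truth$ld^2)
  res <- run_mr(iset, sim$outcome, protmr_config(n_boot = 20))
  flags <- attr(res, "steiger_flags")
  expect_false(is.null(flags))
  expect_true(all(res$steiger_pass))
  expect_true(all(c("r2_exposure", "r2_outcome", "direction_valid") %in%
                    names(flags)))
})

test_that("reverse_mr selects at 5e-8, falls back to 5e-6, or gives up", {
  prot <- make_ss(10, beta = seq(0.01, 0.03, length.out = 10), se = 0.01,
                  pval = 0.2)
  # enough primary hits: no fallback
  disease_strong <- sumstats(make_records(10,
                                          beta = seq(0.08, 0.17,
                                                     length.out = 10),
                                          se = 0.01, pval = 1e-9),
                             "disease", "case_control", "bio")
  res <- reverse_mr(disease_strong, prot, config = protmr_config(
    n_boot = 20, steiger = FALSE))
  expect_identical(attr(res, "status"), "ok")
  expect_identical(attr(res, "threshold_used"), 5e-8)
  expect_false(attr(res, "fallback_used"))
  # hits only between 5e-8 and 5e-6: fallback engaged
  disease_weak <- sumstats(make_records(10,
                                        beta = seq(0.08, 0.17,
                                                   length.out = 10),
                                        se = 0.01, pval = 1e-6),
                           "disease", "case_control", "bio")
  res2 <- reverse_mr(disease_weak, prot, config = protmr_config(
    n_boot = 20, steiger = FALSE))
  expect_identical(attr(res2, "threshold_used"), 5e-6)
  expect_true(attr(res2, "fallback_used"))
  # nothing even at the lenient threshold: not testable
  disease_null <- sumstats(make_records(10, pval = 0.5),
                           "disease", "case_control", "bio")
  res3 <- reverse_mr(disease_null, prot, config = protmr_config(n_boot = 20))
  expect_identical(nrow(res3), 0L)
  expect_identical(attr(res3, "status"), "not_testable")
})
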