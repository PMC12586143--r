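test_that("mr_scenario applies named-scenario defaults and validates", {
  null_sc <- mr_scenario("null")
  expect_identical(null_sc$true_beta, 0)
  expect_identical(null_sc$n_snps, 30L)
  expect_identical(null_sc$ld_decay, 0)
  causal <- mr_scenario("causal")
  expect_identical(causal$true_beta, 0.3)
  pleio <- mr_scenario("directional_pleiotropy")
  expect_identical(pleio$pleiotropy_fraction, 0.4)
  expect_identical(pleio$pleiotropy_scale, 0.05)
  col <- mr_scenario("coloc_h4")
  expect_identical(col$n_snps, 200L)
  expect_identical(col$ld_decay, 0.9)
  rev <- mr_scenario("reverse_causal")
  expect_identical(rev$true_beta, 0.2)
  expect_equal(rev$gamma_range, c(0.1, 0.3))
  expect_error(mr_scenario("null", ld_decay = 1))
  expect_error(mr_scenario("null", case_fraction = 0))
})

test_that("make_ld_matrix is the AR(1) correlation structure", {
  m <- make_ld_matrix(4, 0.5)
  expect_equal(diag(m), rep(1, 4))
  expect_equal(m[1, 4], 0.5^3)
  expect_true(isSymmetric(m))
  expect_true(all(eigen(m, only.values = TRUE)$values > 0))
  expect_error(make_ld_matrix(3, 1))
})

test_that("simulate_pair is byte-identical under a fixed seed", {
  sc <- mr_scenario("causal", n_snps = 10, n_exposure = 2000,
                    n_outcome = 3000, case_fraction = 0.2, seed = 7)
  s1 <- simulate_pair(sc)
  s2 <- simulate_pair(sc)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  s3 <- simulate_pair(mr_scenario("causal", n_snps = 10, n_exposure = 2000,
                                  n_outcome = 3000, case_fraction = 0.2,
                                  seed = 8))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("simulated tables are valid sumstats with sane fields", {
  sim <- simulate_pair(mr_scenario("null", n_snps = 12, n_exposure = 3000,
                                   n_outcome = 4000, case_fraction = 0.2,
                                   seed = 3))
  for (tab in list(sim$exposure, sim$outcome)) {
    expect_s3_class(tab, "protmr_sumstats")
    expect_identical(nrow(tab), 12L)
    expect_true(all(tab$pval > 0 & tab$pval <= 1))
    expect_true(all(tab$se > 0))
    expect_true(all(tab$eaf >= 0 & tab$eaf <= 1))
  }
  expect_identical(attr(sim$exposure, "trait_type"), "quantitative")
  expect_identical(attr(sim$outcome, "trait_type"), "case_control")
  expect_identical(unique(sim$outcome$n_cases + sim$outcome$n_controls),
                   unique(sim$outcome$n))
  expect_equal(sim$truth$n_cases / 4000, 0.2, tolerance = 0.25)
  expect_length(sim$truth$gamma, 12)
})

test_that("reported EAF tracks the generating MAF when reporting is clean", {
  sim <- simulate_pair(mr_scenario("null", n_snps = 20, n_exposure = 8000,
                                   n_outcome = 2000, case_fraction = 0.3,
                                   flip_fraction = 0, seed = 11))
  expect_equal(sim$exposure$eaf, sim$truth$mafs, tolerance = 0.05)
})

test_that("adjacent dosage correlation matches ld_decay by calibration", {
  set.seed(5)
  mafs <- rep(0.3, 6)   # equal margins: the target is exactly attainable
  rho <- protmr:::latent_chain(mafs, 0.8)
  G <- protmr:::sim_genotypes(40000, mafs, rho)
  adj <- vapply(1:5, function(j) cor(G[, j], G[, j + 1]), numeric(1))
  expect_equal(adj, rep(0.8, 5), tolerance = 0.03)
  # unequal margins cannot exceed their Frechet bound: calibration caps
  # the latent correlation instead of failing
  rho_mix <- protmr:::latent_chain(c(0.1, 0.45), 0.9)
  G2 <- protmr:::sim_genotypes(40000, c(0.1, 0.45), rho_mix)
  # Frechet bound for these margins is ~0.37
  expect_lt(cor(G2[, 1], G2[, 2]), 0.9)
  expect_gt(cor(G2[, 1], G2[, 2]), 0.3)
  # and empirical_ld squares it
  r2 <- empirical_ld(G)
  expect_equal(diag(r2), rep(1, 6))
  expect_equal(r2[1, 2], adj[1]^2, tolerance = 1e-6)
})

test_that("empirical_ld flags monomorphic variants", {
  G <- cbind(rbinom(100, 2, 0.4), rep(2, 100))
  colnames(G) <- c("a", "b")
  r2 <- empirical_ld(G)
  expect_identical(unname(attr(r2, "monomorphic")), 2L)
  expect_identical(r2["a", "b"], 0)
})

test_that("standard errors scale as 1/sqrt(n)", {
  sc1 <- mr_scenario("null", n_snps = 15, n_exposure = 4000,
                     n_outcome = 4000, case_fraction = 0.2, seed = 2)
  sc4 <- mr_scenario("null", n_snps = 15, n_exposure = 16000,
                     n_outcome = 16000, case_fraction = 0.2, seed = 2)
  s1 <- simulate_pair(sc1)
  s4 <- simulate_pair(sc4)
  expect_equal(median(s1$exposure$se) / median(s4$exposure$se), 2,
               tolerance = 0.06)
  expect_equal(median(s1$outcome$se) / median(s4$outcome$se), 2,
               tolerance = 0.06)
})

test_that("null-scenario outcome z-scores look standard normal", {
  sim <- simulate_pair(mr_scenario("null", n_snps = 200, n_exposure = 500,
                                   n_outcome = 6000, case_fraction = 0.2,
                                   ld_decay = 0,
                                   gamma_range = c(0.01, 0.05), seed = 9))
  z <- sim$outcome$beta / sim$outcome$se
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("extreme associations clamp p-values instead of dropping variants", {
  set.seed(1)
  G <- matrix(rbinom(4000, 2, 0.4), 2000, 2)
  x <- 5 * G[, 1] + rnorm(2000, 0, 0.1)
  st <- protmr:::score_linear(G, x)
  expect_identical(st$pval[1], 1e-300)
  expect_true(all(st$pval > 0))
})

test_that("palindromic_fraction injects strand-ambiguous allele pairs", {
  sim <- simulate_pair(mr_scenario("null", n_snps = 40, n_exposure = 1000,
                                   n_outcome = 1000, case_fraction = 0.3,
                                   palindromic_fraction = 0.5, seed = 13))
  frac <- mean(is_palindromic(sim$exposure$effect_allele,
                              sim$exposure$other_allele))
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
})

test_that("simulate_panel returns a coherent, reproducible panel", {
  p1 <- simulate_panel(n_proteins = 4, n_causal = 1, n_protective = 0,
                       n_snps = 6, n_exposure = 1500, n_outcome = 2000,
                       case_fraction = 0.2, seed = 5)
  p2 <- simulate_panel(n_proteins = 4, n_causal = 1, n_protective = 0,
                       n_snps = 6, n_exposure = 1500, n_outcome = 2000,
                       case_fraction = 0.2, seed = 5)
  expect_s3_class(p1, "protmr_panel")
  expect_length(p1$proteins, 4)
  expect_identical(sum(p1$truth$causal), 1L)
  expect_identical(p1$truth$true_beta[p1$truth$causal], 0.4)
  pr <- p1$proteins[[2]]
  expect_setequal(names(pr$tables), c("decode", "ukbppp", "finngen", "ukb"))
  expect_identical(attr(pr$tables$decode, "trait_id"), pr$protein_id)
  expect_identical(attr(pr$tables$finngen, "trait_type"), "case_control")
  expect_identical(rownames(pr$ld_r2), pr$tables$decode$variant_id)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$proteins[[3]]$tables$ukb, p2$proteins[[3]]$tables$ukb)
})
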