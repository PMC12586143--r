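# Synthetic two-sample GWAS/pQTL summary statistics with known ground truth.
#
# Genotypes come from a Gaussian copula: per haplotype, an AR(1) latent
# Gaussian chain is thresholded at each variant's allele frequency, and the
# two haplotypes are summed to a 0/1/2 dosage. The latent correlations are
# calibrated (per adjacent pair, via the bivariate-normal CDF) so that the
# dosage correlation of adjacent variants matches `ld_decay`, i.e. the
# target dosage LD is ld_decay^|i-j|. This is a deliberate simplification
# relative to coalescent simulation: it reproduces the LD/clumping behaviour
# the pipeline needs, not human haplotype structure.

NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Define a simulation scenario
#'
#' Bundles the generative parameters for one exposure-outcome pair. Named
#' scenarios fix the causal architecture; remaining arguments override the
#' scenario's defaults. The default cohort sizes and case fraction mirror a
#' large pQTL study (n ~ 35,559 quantitative) paired with a rare-disease
#' biobank GWAS (244 cases in 314,436 individuals, case fraction ~7.7e-4);
#' simulation studies in this package's tests use smaller cohorts with
#' enriched case fractions for Monte-Carlo stability.
#'
#' @param scenario_name one of `"null"`, `"causal"`,
#'   `"directional_pleiotropy"`, `"balanced_pleiotropy"`, `"reverse_causal"`,
#'   `"coloc_h0"` ... `"coloc_h4"`.
#' @param true_beta causal effect of exposure on outcome, log-odds per SD of
#'   the protein (for `reverse_causal`, the effect of disease liability on
#'   the protein). Defaults: 0 (null, coloc scenarios), 0.3 (causal,
#'   pleiotropy), 0.2 (reverse).
#' @param n_exposure,n_outcome cohort sizes of the two non-overlapping
#'   samples.
#' @param case_fraction expected proportion of cases in the outcome cohort.
#' @param n_snps variants in the cis region (30 for MR scenarios, 200 for
#'   colocalization scenarios).
#' @param maf_range range the per-variant minor-allele frequencies are drawn
#'   from.
#' @param ld_decay target dosage correlation of adjacent variants, in
#'   `[0, 1)`; LD decays as `ld_decay^|i-j|`. 0 for MR scenarios (instruments
#'   as they look after clumping), 0.9 for colocalization scenarios.
#' @param n_causal_exposure number of variants with true effects on the
#'   exposure.
#' @param gamma_range range of the per-variant exposure effect magnitudes
#'   (SD of protein per allele); signs are random.
#' @param gamma_top effect size of the single causal variant in
#'   colocalization scenarios.
#' @param alpha_outcome direct (log-odds) outcome effect of the causal
#'   outcome variant in colocalization scenarios.
#' @param pleiotropy_fraction fraction of instruments with direct outcome
#'   effects (0.4 in the pleiotropy scenarios).
#' @param pleiotropy_scale SD of the direct outcome effects (log-odds);
#'   directional pleiotropy uses half-normal (all-positive) draws, balanced
#'   pleiotropy keeps the signs.
#' @param palindromic_fraction fraction of variants assigned A/T or C/G
#'   allele pairs (default 0; raise it to exercise harmonization drops).
#' @param flip_fraction fraction of variants whose reported effect allele is
#'   swapped, independently per cohort (exercises harmonization flips
#'   without changing the information content).
#' @param seed master seed; all randomness in [simulate_pair()] derives from
#'   it.
#' @return a list of class `protmr_scenario`.
#' @export
mr_scenario <- function(scenario_name = c("null", "causal",
                                          "directional_pleiotropy",
                                          "balanced_pleiotropy",
                                          "reverse_causal", "coloc_h0",
                                          "coloc_h1", "coloc_h2", "coloc_h3",
                                          "coloc_h4"),
                        true_beta = NULL, n_exposure = 35559,
                        n_outcome = 314436, case_fraction = 7.7e-4,
                        n_snps = NULL, maf_range = NULL, ld_decay = NULL,
                        n_causal_exposure = NULL, gamma_range = c(0.05, 0.3),
                        gamma_top = 0.15, alpha_outcome = 0.5,
                        pleiotropy_fraction = NULL, pleiotropy_scale = NULL,
                        palindromic_fraction = 0, flip_fraction = 0.5,
                        seed = 1L) {
  scenario_name <- match.arg(scenario_name)
  is_coloc <- grepl("^coloc_", scenario_name)
  if (is.null(n_snps)) n_snps <- if (is_coloc) 200L else 30L
  if (is.null(ld_decay)) ld_decay <- if (is_coloc) 0.9 else 0
  if (is.null(maf_range)) maf_range <- if (is_coloc) c(0.2, 0.4) else c(0.1, 0.5)
  if (is.null(n_causal_exposure)) {
    n_causal_exposure <- if (is_coloc) 1L else n_snps
  }
  if (is.null(true_beta)) {
    true_beta <- switch(scenario_name,
                        causal = 0.3, directional_pleiotropy = 0.3,
                        balanced_pleiotropy = 0.3, reverse_causal = 0.2, 0)
  }
  if (is.null(pleiotropy_fraction)) {
    pleiotropy_fraction <- if (scenario_name %in%
                               c("directional_pleiotropy",
                                 "balanced_pleiotropy")) 0.4 else 0
  }
  if (is.null(pleiotropy_scale)) {
    pleiotropy_scale <- if (pleiotropy_fraction > 0) 0.05 else 0
  }
  if (scenario_name == "reverse_causal" && missing(gamma_range)) {
    gamma_range <- c(0.1, 0.3)
  }
  stopifnot(ld_decay >= 0, ld_decay < 1,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            n_causal_exposure <= n_snps, n_snps >= 1,
            case_fraction > 0, case_fraction < 1)
  structure(list(
    scenario_name = scenario_name, true_beta = true_beta,
    n_exposure = n_exposure, n_outcome = n_outcome,
    case_fraction = case_fraction, n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_decay = ld_decay,
    n_causal_exposure = as.integer(n_causal_exposure),
    gamma_range = gamma_range, gamma_top = gamma_top,
    alpha_outcome = alpha_outcome,
    pleiotropy_fraction = pleiotropy_fraction,
    pleiotropy_scale = pleiotropy_scale,
    palindromic_fraction = palindromic_fraction,
    flip_fraction = flip_fraction, seed = as.integer(seed)
  ), class = "protmr_scenario")
}

#' AR(1) linkage-disequilibrium correlation matrix
#'
#' @param n_snps number of variants.
#' @param ld_decay decay parameter in `[0, 1)`.
#' @return `n_snps` x `n_snps` matrix with entries `ld_decay^|i-j|`
#'   (symmetric positive definite, unit diagonal). Square it for r-squared.
#' @export
make_ld_matrix <- function(n_snps, ld_decay) {
  stopifnot(n_snps >= 1, ld_decay >= 0, ld_decay < 1)
  idx <- seq_len(n_snps)
  ld_decay^abs(outer(idx, idx, "-"))
}

#' Empirical LD (r-squared) from genotype dosages
#'
#' @param dosages numeric matrix, samples x variants.
#' @return squared Pearson correlation matrix with unit diagonal.
#'   Monomorphic variants get r-squared 0 against all others and are listed
#'   in the `monomorphic` attribute.
#' @export
empirical_ld <- function(dosages) {
  stopifnot(is.matrix(dosages), nrow(dosages) >= 2)
  sds <- apply(dosages, 2, stats::sd)
  mono <- which(sds == 0)
  r <- suppressWarnings(stats::cor(dosages))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  if (!is.null(colnames(dosages))) dimnames(r2) <- list(colnames(dosages),
                                                        colnames(dosages))
  attr(r2, "monomorphic") <- mono
  r2
}

# Latent AR(1) chain correlations calibrated so adjacent dosage
# correlation equals ld_decay.
latent_chain <- function(mafs, ld_decay) {
  p <- length(mafs)
  if (p < 2L || ld_decay <= 0) return(numeric(max(0L, p - 1L)))
  vapply(seq_len(p - 1L), function(j) {
    solve_latent_rho(ld_decay, mafs[j], mafs[j + 1L])
  }, numeric(1))
}

# Draw n x p dosages at the given MAFs; AR(1) copula when rho chain given.
sim_genotypes <- function(n, mafs, rho_chain = NULL) {
  p <- length(mafs)
  if (is.null(rho_chain) || length(rho_chain) == 0L ||
      all(rho_chain == 0)) {
    return(matrix(stats::rbinom(n * p, 2L, rep(mafs, each = n)), n, p))
  }
  thr <- stats::qnorm(mafs)
  one_haplotype <- function() {
    h <- matrix(0, n, p)
    z <- stats::rnorm(n)
    h[, 1L] <- z < thr[1L]
    for (j in seq_len(p - 1L)) {
      z <- rho_chain[j] * z + sqrt(1 - rho_chain[j]^2) * stats::rnorm(n)
      h[, j + 1L] <- z < thr[j + 1L]
    }
    h
  }
  one_haplotype() + one_haplotype()
}

# Marginal ("score") regressions, one variant at a time, vectorized.
score_linear <- function(G, x) {
  n <- nrow(G)
  gbar <- colMeans(G)
  Sgg <- colSums(G^2) - n * gbar^2
  xc <- x - mean(x)
  Sgx <- as.vector(crossprod(G, xc))
  Sxx <- sum(xc^2)
  beta <- Sgx / Sgg
  sse <- pmax(Sxx - beta * Sgx, 0)
  se <- sqrt(sse / (n - 2) / Sgg)
  z <- beta / se
  data.frame(beta = beta, se = se,
             pval = clamp_pval(2 * stats::pnorm(-abs(z))))
}

# p-values are reported in (0, 1]; extreme z-scores are floored rather
# than underflowed to zero (as GWAS tools do).
clamp_pval <- function(p) pmin(1, pmax(p, 1e-300))

score_binary <- function(G, y) {
  n <- nrow(G)
  ybar <- mean(y)
  gbar <- colMeans(G)
  Sgg <- colSums(G^2) - n * gbar^2
  U <- as.vector(crossprod(G, y - ybar))
  V <- ybar * (1 - ybar) * Sgg
  beta <- U / V
  se <- 1 / sqrt(V)
  z <- U / sqrt(V)
  data.frame(beta = beta, se = se,
             pval = clamp_pval(2 * stats::pnorm(-abs(z))))
}

# Randomly swap the reported effect/other allele for a fraction of variants
# (beta and EAF re-expressed accordingly): same information, different
# orientation, so harmonization has real work to do.
flip_reporting <- function(df, frac) {
  if (frac <= 0) return(df)
  flip <- stats::runif(nrow(df)) < frac
  ea <- df$effect_allele
  df$effect_allele[flip] <- df$other_allele[flip]
  df$other_allele[flip] <- ea[flip]
  df$beta[flip] <- -df$beta[flip]
  df$eaf[flip] <- 1 - df$eaf[flip]
  df
}

# Logistic intercept giving the requested expected case fraction for a
# fixed vector of linear-predictor contributions.
calibrate_intercept <- function(eta, case_fraction) {
  stats::uniroot(function(c0) mean(stats::plogis(c0 + eta)) - case_fraction,
                 c(-50, 20), tol = 1e-8)$root
}

#' Simulate one exposure-outcome pair of summary-statistics tables
#'
#' Generates two independent cohorts over the same cis region. The exposure
#' cohort yields linear marginal regressions of a unit-variance protein level
#' `X = G gamma + noise`; the outcome cohort yields per-variant logistic
#' score statistics (log-odds scale) for a binary trait with
#' `logit P(case) = c0 + true_beta * X + G alpha`, where `alpha` holds direct
#' (pleiotropic or colocalization-scenario) variant effects and `c0` is
#' calibrated to the scenario's case fraction. `reverse_causal` swaps the
#' causal arrow: the variants drive disease liability and the protein is
#' downstream of it. Colocalization scenarios place single causal variants to
#' realize each hypothesis (no association; one trait only; two distinct
#' variants in LD; one shared variant).
#'
#' @param scenario a `protmr_scenario` from [mr_scenario()].
#' @return list of class `protmr_simulation`:
#'   `exposure` and `outcome` (`protmr_sumstats` tables) and `truth`
#'   (true causal effect, per-variant exposure effects `gamma`, direct
#'   outcome effects `alpha`, target LD matrix, shared causal variant id,
#'   gene region, realized case count).
#' @export
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "protmr_scenario"))
  s <- scenario
  p <- s$n_snps

  set.seed(derive_seed(s$seed, 11L))
  mafs <- stats::runif(p, s$maf_range[1], s$maf_range[2])
  alleles <- draw_alleles(p, s$palindromic_fraction)
  positions <- 2005000 + (seq_len(p) - (p + 1) / 2) * 4000
  ids <- sprintf("rs%08d", positions)
  rho_chain <- latent_chain(mafs, s$ld_decay)

  eff <- scenario_effects(s, mafs)
  gamma <- eff$gamma
  alpha <- eff$alpha

  # exposure cohort
  set.seed(derive_seed(s$seed, 12L))
  G1 <- sim_genotypes(s$n_exposure, mafs, rho_chain)
  x1 <- protein_level(G1, gamma, s, mafs)
  exp_stats <- score_linear(G1, x1$x)
  exp_df <- assemble_records(ids, positions, alleles, G1, exp_stats,
                             s$n_exposure, NULL)

  # outcome cohort
  set.seed(derive_seed(s$seed, 13L))
  G2 <- sim_genotypes(s$n_outcome, mafs, rho_chain)
  x2 <- protein_level(G2, gamma, s, mafs)
  eta <- if (s$scenario_name == "reverse_causal") x2$liability else
    s$true_beta * x2$x + as.vector(G2 %*% alpha)
  c0 <- calibrate_intercept(eta, s$case_fraction)
  y <- stats::rbinom(s$n_outcome, 1L, stats::plogis(c0 + eta))
  if (s$case_fraction * s$n_outcome < 20) {
    warning("expected case count below 20; logistic score statistics ",
            "will be unstable")
  }
  out_stats <- score_binary(G2, y)
  out_df <- assemble_records(ids, positions, alleles, G2, out_stats,
                             s$n_outcome, sum(y))

  set.seed(derive_seed(s$seed, 14L))
  exp_df <- flip_reporting(exp_df, s$flip_fraction)
  out_df <- flip_reporting(out_df, s$flip_fraction)

  exposure <- sumstats(exp_df, trait_id = "protein",
                       trait_type = "quantitative", cohort_id = "exposure_cohort")
  outcome <- sumstats(out_df, trait_id = "disease",
                      trait_type = "case_control", cohort_id = "outcome_cohort")
  truth <- list(
    true_beta = s$true_beta, gamma = gamma, alpha = alpha,
    ld = make_ld_matrix_named(p, s$ld_decay, ids),
    shared_causal_variant_id = if (!is.null(eff$shared_idx))
      ids[eff$shared_idx] else NULL,
    causal_outcome_variant_id = if (!is.null(eff$outcome_idx))
      ids[eff$outcome_idx] else NULL,
    variant_id = ids, mafs = mafs,
    region = gene_region("protein", "GENE", "1", 2000000, 2010000),
    n_cases = sum(y), scenario = s
  )
  structure(list(exposure = exposure, outcome = outcome, truth = truth),
            class = "protmr_simulation")
}

make_ld_matrix_named <- function(p, ld_decay, ids) {
  ld <- make_ld_matrix(p, ld_decay)
  dimnames(ld) <- list(ids, ids)
  ld
}

draw_alleles <- function(p, palindromic_fraction) {
  pal <- stats::runif(p) < palindromic_fraction
  i_np <- sample(nrow(NONPALINDROMIC_PAIRS), p, replace = TRUE)
  i_p <- sample(nrow(PALINDROMIC_PAIRS), p, replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[i_p, 1], NONPALINDROMIC_PAIRS[i_np, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[i_p, 2], NONPALINDROMIC_PAIRS[i_np, 2])
  list(effect = ea, other = oa)
}

# Per-variant true effects realizing each scenario.
scenario_effects <- function(s, mafs) {
  p <- s$n_snps
  gamma <- numeric(p)
  alpha <- numeric(p)
  shared_idx <- NULL
  outcome_idx <- NULL
  name <- s$scenario_name
  if (grepl("^coloc_", name)) {
    mid <- max(1L, p %/% 2L)
    sep <- min(5L, max(1L, p %/% 4L))
    if (name %in% c("coloc_h1", "coloc_h4")) {
      gamma[mid] <- s$gamma_top
      shared_idx <- mid
    }
    if (name == "coloc_h4") alpha[mid] <- s$alpha_outcome
    if (name == "coloc_h2") {
      alpha[mid] <- s$alpha_outcome
      outcome_idx <- mid
    }
    if (name == "coloc_h3") {
      gamma[max(1L, mid - sep)] <- s$gamma_top
      alpha[min(p, mid + sep)] <- s$alpha_outcome
      shared_idx <- max(1L, mid - sep)
      outcome_idx <- min(p, mid + sep)
    }
    if (name == "coloc_h4") outcome_idx <- mid
  } else {
    causal <- sample(p, s$n_causal_exposure)
    gamma[causal] <- stats::runif(s$n_causal_exposure, s$gamma_range[1],
                                  s$gamma_range[2]) *
      sample(c(-1, 1), s$n_causal_exposure, replace = TRUE)
    if (s$pleiotropy_fraction > 0) {
      k <- floor(s$pleiotropy_fraction * p)
      idx <- sample(p, k)
      draws <- stats::rnorm(k, 0, s$pleiotropy_scale)
      if (name == "directional_pleiotropy") {
        # direct effects all positive relative to the exposure-increasing
        # allele (directionality is allele-orientation-invariant)
        orient <- ifelse(gamma[idx] == 0, 1, sign(gamma[idx]))
        draws <- abs(draws) * orient
      }
      alpha[idx] <- draws
    }
  }
  list(gamma = gamma, alpha = alpha, shared_idx = shared_idx,
       outcome_idx = outcome_idx)
}

# Unit-variance protein level. For reverse_causal the protein is downstream
# of the (unit-variance) disease liability; `liability` is returned for the
# outcome cohort's logistic model.
protein_level <- function(G, gamma, s, mafs) {
  n <- nrow(G)
  var_g <- 2 * mafs * (1 - mafs)
  genetic_var <- sum(gamma^2 * var_g)
  if (genetic_var >= 0.95) {
    stop("genetic variance of the simulated trait exceeds 0.95; ",
         "reduce effect sizes or variant count")
  }
  base <- as.vector(G %*% gamma) +
    stats::rnorm(n, 0, sqrt(1 - genetic_var))
  if (s$scenario_name == "reverse_causal") {
    x <- s$true_beta * base + stats::rnorm(n, 0, sqrt(1 - s$true_beta^2))
    list(x = x, liability = base)
  } else {
    list(x = base, liability = base)
  }
}

assemble_records <- function(ids, positions, alleles, G, stats_df, n,
                             n_cases) {
  data.frame(
    variant_id = ids, chromosome = "1", position = positions,
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = colMeans(G) / 2, beta = stats_df$beta, se = stats_df$se,
    pval = stats_df$pval, n = n,
    n_cases = if (is.null(n_cases)) NA_real_ else n_cases,
    n_controls = if (is.null(n_cases)) NA_real_ else n - n_cases,
    stringsAsFactors = FALSE
  )
}

#' Simulate a proteome-wide three-analysis panel
#'
#' Generates a synthetic screening study: `n_proteins` independent cis
#' regions, each measured on two pQTL platforms (cohorts "decode" and
#' "ukbppp") and tested against a binary disease in two outcome biobanks
#' (cohorts "finngen" and "ukb"), giving the three overlap-free analysis
#' pairs decode-finngen, decode-ukb and ukbppp-finngen. A subset of proteins
#' truly cause the disease (mixed risk and protective log-odds effects);
#' the rest are null. Each protein has a dominant top cis-pQTL plus weaker
#' secondary variants, so both the MR estimators and regional colocalization
#' have realistic signal structure. Regions are simulated independently per
#' cohort draw; shared-cohort correlation across proteins is not modelled.
#'
#' @param n_proteins panel size.
#' @param n_causal number of truly causal proteins.
#' @param n_protective how many of the causal proteins are protective
#'   (negative log-odds effect); the rest are risk effects.
#' @param true_beta magnitude of the causal protein effects (log-odds per
#'   SD).
#' @param n_snps variants per cis region.
#' @param n_exposure,n_outcome per-cohort sample sizes.
#' @param case_fraction case fraction of the outcome cohorts.
#' @param maf_range,ld_decay regional genotype structure (see
#'   [mr_scenario()]).
#' @param gamma_top,gamma_other exposure effect of the top cis-pQTL and of
#'   the secondary variants.
#' @param seed master seed.
#' @return list of class `protmr_panel` with elements `proteins` (per-protein
#'   region, true LD r-squared, and the four summary-stat tables), `truth`
#'   (per-protein causal status and effect), `regions` (annotation table) and
#'   `params`.
#' @export
simulate_panel <- function(n_proteins = 100L, n_causal = 6L,
                           n_protective = 2L, true_beta = 0.4,
                           n_snps = 12L, n_exposure = 20000L,
                           n_outcome = 50000L, case_fraction = 0.1,
                           maf_range = c(0.25, 0.45), ld_decay = 0,
                           gamma_top = 0.35, gamma_other = 0.12,
                           seed = 1L) {
  stopifnot(n_causal <= n_proteins, n_protective <= n_causal)
  tb <- c(rep(true_beta, n_causal - n_protective),
          rep(-true_beta, n_protective), rep(0, n_proteins - n_causal))
  set.seed(derive_seed(seed, 1L))
  tb <- sample(tb)
  protein_ids <- sprintf("PROT%03d", seq_len(n_proteins))

  causal_idx <- unique(pmax(1L, round(n_snps * c(0.25, 0.5, 0.75))))
  proteins <- vector("list", n_proteins)
  regions <- data.frame(
    protein_id = protein_ids, gene_symbol = paste0("GENE", seq_len(n_proteins)),
    chromosome = as.character(seq_len(n_proteins)),
    start = 2000000, end = 2010000, stringsAsFactors = FALSE
  )

  for (i in seq_len(n_proteins)) {
    set.seed(derive_seed(seed, 100L + i))
    mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
    alleles <- draw_alleles(n_snps, 0)
    positions <- 2005000 + (seq_len(n_snps) - (n_snps + 1) / 2) * 4000
    ids <- sprintf("rs%02d%07d", i, positions %/% 10)
    rho_chain <- latent_chain(mafs, ld_decay)
    gamma <- numeric(n_snps)
    gamma[causal_idx] <- gamma_other
    gamma[causal_idx[ceiling(length(causal_idx) / 2)]] <- gamma_top
    var_g <- 2 * mafs * (1 - mafs)

    sim_exposure <- function(stream) {
      set.seed(derive_seed(seed, stream))
      G <- sim_genotypes(n_exposure, mafs, rho_chain)
      x <- as.vector(G %*% gamma) +
        stats::rnorm(n_exposure, 0, sqrt(1 - sum(gamma^2 * var_g)))
      st <- score_linear(G, x)
      df <- assemble_records(ids, positions, alleles, G, st, n_exposure, NULL)
      df$chromosome <- as.character(i)
      flip_reporting(df, 0.5)
    }
    sim_outcome <- function(stream) {
      set.seed(derive_seed(seed, stream))
      G <- sim_genotypes(n_outcome, mafs, rho_chain)
      x <- as.vector(G %*% gamma) +
        stats::rnorm(n_outcome, 0, sqrt(1 - sum(gamma^2 * var_g)))
      eta <- tb[i] * x
      c0 <- calibrate_intercept(eta, case_fraction)
      y <- stats::rbinom(n_outcome, 1L, stats::plogis(c0 + eta))
      st <- score_binary(G, y)
      df <- assemble_records(ids, positions, alleles, G, st, n_outcome, sum(y))
      df$chromosome <- as.character(i)
      flip_reporting(df, 0.5)
    }

    tabs <- list(
      decode = sumstats(sim_exposure(1000L + 4L * i), protein_ids[i],
                        "quantitative", "decode"),
      ukbppp = sumstats(sim_exposure(1001L + 4L * i), protein_ids[i],
                        "quantitative", "ukbppp"),
      finngen = sumstats(sim_outcome(1002L + 4L * i), "disease",
                         "case_control", "finngen"),
      ukb = sumstats(sim_outcome(1003L + 4L * i), "disease",
                     "case_control", "ukb")
    )
    ld_r2 <- make_ld_matrix_named(n_snps, ld_decay, ids)^2
    proteins[[i]] <- list(
      protein_id = protein_ids[i],
      region = gene_region(protein_ids[i], regions$gene_symbol[i],
                           as.character(i), 2000000, 2010000),
      ld_r2 = ld_r2, tables = tabs
    )
  }

  structure(list(
    proteins = proteins,
    truth = data.frame(protein_id = protein_ids, causal = tb != 0,
                       true_beta = tb, stringsAsFactors = FALSE),
    regions = regions,
    params = list(n_proteins = n_proteins, n_causal = n_causal,
                  n_protective = n_protective, true_beta = true_beta,
                  n_snps = n_snps, n_exposure = n_exposure,
                  n_outcome = n_outcome, case_fraction = case_fraction,
                  maf_range = maf_range, ld_decay = ld_decay,
                  gamma_top = gamma_top, gamma_other = gamma_other),
    seed = seed
  ), class = "protmr_panel")
}
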