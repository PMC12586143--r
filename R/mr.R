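# Two-sample MR estimators, heterogeneity/pleiotropy diagnostics, Steiger
# directionality filtering and the forward/reverse orchestration.
#
# Estimator definitions follow the source publications of the named
# methods: ratio-based IVW with multiplicative random effects when
# overdispersed, MR-Egger with exposure effects oriented positive,
# Bowden's interpolated weighted median, and Hartwig's weighted mode with
# a modified-Silverman bandwidth.

new_mr_result <- function(protein_id, cohort_pair, method, n_snps, beta, se,
                          pval, q_stat = NA_real_, q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_pval = NA_real_,
                          steiger_pass = NA) {
  data.frame(
    protein_id = protein_id, cohort_pair = cohort_pair, method = method,
    n_snps = as.integer(n_snps), beta = beta, se = se, pval = pval,
    or_value = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se), q_stat = q_stat, q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_pval = egger_intercept_pval,
    steiger_pass = steiger_pass, stringsAsFactors = FALSE
  )
}

empty_mr_result <- function() {
  new_mr_result(character(0), character(0), character(0), integer(0),
                numeric(0), numeric(0), numeric(0),
                q_stat = numeric(0), q_pval = numeric(0),
                egger_intercept = numeric(0),
                egger_intercept_pval = numeric(0),
                steiger_pass = logical(0))
}

check_harmonized <- function(h, min_snps, method) {
  if (nrow(h) < min_snps) {
    stop(method, " requires at least ", min_snps, " harmonized variant(s), got ",
         nrow(h))
  }
  if (any(h$beta_exposure == 0)) {
    stop(method, ": zero exposure effect for variant ",
         h$variant_id[which(h$beta_exposure == 0)[1L]])
  }
}

mr_meta <- function(h, protein_id, cohort_pair) {
  list(protein_id = if (is.null(protein_id)) "protein" else protein_id,
       cohort_pair = if (is.null(cohort_pair)) "exposure-outcome"
                     else cohort_pair)
}

#' Wald ratio estimate from a single variant
#'
#' Causal estimate `beta_outcome / beta_exposure` with first-order
#' delta-method standard error `se_outcome / |beta_exposure|` and a
#' two-sided normal test.
#'
#' @param h a one-row harmonized data.frame (see [harmonize()]).
#' @param protein_id,cohort_pair labels carried into the result.
#' @return a one-row MR result data.frame (estimate, SE, p, OR with 95% CI).
#' @export
mr_wald_ratio <- function(h, protein_id = NULL, cohort_pair = NULL) {
  check_harmonized(h, 1L, "wald_ratio")
  if (nrow(h) != 1L) stop("wald_ratio takes exactly one variant")
  m <- mr_meta(h, protein_id, cohort_pair)
  beta <- h$beta_outcome / h$beta_exposure
  se <- h$se_outcome / abs(h$beta_exposure)
  new_mr_result(m$protein_id, m$cohort_pair, "wald_ratio", 1L, beta, se,
                2 * stats::pnorm(-abs(beta / se)))
}

#' Inverse-variance weighted estimate
#'
#' Meta-analyses the per-variant Wald ratios with weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2` (equivalent to weighted
#' regression of outcome on exposure effects through the origin). The
#' fixed-effect standard error `1/sqrt(sum w)` is inflated by
#' `sqrt(Q / (n - 1))` when Cochran's Q exceeds its degrees of freedom
#' (multiplicative random effects under overdispersion).
#'
#' @param h harmonized data.frame with at least two variants.
#' @param protein_id,cohort_pair labels carried into the result.
#' @return one-row MR result including `q_stat` and `q_pval`.
#' @export
mr_ivw <- function(h, protein_id = NULL, cohort_pair = NULL) {
  check_harmonized(h, 2L, "ivw")
  m <- mr_meta(h, protein_id, cohort_pair)
  ratios <- h$beta_outcome / h$beta_exposure
  w <- h$beta_exposure^2 / h$se_outcome^2
  beta <- sum(w * ratios) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (ratios - beta)^2)
  n <- nrow(h)
  if (q / (n - 1) > 1) se <- se * sqrt(q / (n - 1))
  new_mr_result(m$protein_id, m$cohort_pair, "ivw", n, beta, se,
                2 * stats::pnorm(-abs(beta / se)),
                q_stat = q, q_pval = stats::pchisq(q, n - 1,
                                                   lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1/se_outcome^2`, after orienting every variant so the
#' exposure effect is non-negative. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy, with its own test.
#' Standard errors are divided by `min(1, sigma)` so residual
#' underdispersion cannot shrink them; tests use the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param h harmonized data.frame with at least three variants.
#' @param protein_id,cohort_pair labels carried into the result.
#' @return one-row MR result including `egger_intercept` and
#'   `egger_intercept_pval`.
#' @export
mr_egger <- function(h, protein_id = NULL, cohort_pair = NULL) {
  check_harmonized(h, 3L, "egger")
  m <- mr_meta(h, protein_id, cohort_pair)
  flip <- sign(h$beta_exposure)
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  if (stats::var(bx) == 0) {
    stop("egger: no variance in exposure effects (degenerate design)")
  }
  fit <- stats::lm(by ~ bx, weights = 1 / h$se_outcome^2)
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  adj <- min(1, sm$sigma)
  n <- nrow(h)
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"] / adj
  int <- coefs["(Intercept)", "Estimate"]
  int_se <- coefs["(Intercept)", "Std. Error"] / adj
  new_mr_result(m$protein_id, m$cohort_pair, "egger", n, slope, slope_se,
                2 * stats::pt(-abs(slope / slope_se), n - 2),
                egger_intercept = int,
                egger_intercept_pval = 2 * stats::pt(-abs(int / int_se),
                                                     n - 2))
}

# Bowden's interpolated weighted median of the ratio estimates.
weighted_median_estimate <- function(ratios, w) {
  ord <- order(ratios)
  b <- ratios[ord]
  ww <- w[ord]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  if (p[1L] >= 0.5) return(b[1L])
  k <- length(b)
  if (p[k] <= 0.5) return(b[k])
  j <- max(which(p < 0.5))
  b[j] + (b[j + 1L] - b[j]) * (0.5 - p[j]) / (p[j + 1L] - p[j])
}

#' Weighted-median estimate
#'
#' Orders the per-variant ratio estimates and interpolates the inverse of
#' the standardized cumulative weight at one half; consistent when valid
#' instruments carry more than 50% of the weight. The standard error comes
#' from a parametric bootstrap: exposure and outcome effects are redrawn
#' from their normal sampling distributions and the estimate recomputed.
#'
#' @param h harmonized data.frame with at least three variants.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @param protein_id,cohort_pair labels carried into the result.
#' @return one-row MR result.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = NULL,
                               protein_id = NULL, cohort_pair = NULL) {
  check_harmonized(h, 3L, "weighted_median")
  m <- mr_meta(h, protein_id, cohort_pair)
  ratios <- h$beta_outcome / h$beta_exposure
  w <- h$beta_exposure^2 / h$se_outcome^2
  beta <- weighted_median_estimate(ratios, w)
  se <- boot_se(h, n_boot, seed, weighted_median_estimate)
  new_mr_result(m$protein_id, m$cohort_pair, "weighted_median", nrow(h),
                beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

# Weighted normal-kernel density over the ratios; argmax on a fixed grid.
weighted_mode_estimate <- function(ratios, w, bandwidth_factor = 1,
                                   grid_points = 512L) {
  if (length(unique(ratios)) == 1L) return(ratios[1L])
  s <- 0.9 * min(stats::sd(ratios), stats::mad(ratios)) *
    length(ratios)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(ratios) * length(ratios)^(-1 / 5)
  bw <- bandwidth_factor * s
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw,
              length.out = grid_points)
  dens <- colSums((w / sum(w)) *
                    stats::dnorm(outer(ratios, grid, "-") / bw)) / bw
  grid[which.max(dens)]
}

#' Weighted-mode estimate
#'
#' Builds a weighted normal-kernel density over the per-variant ratio
#' estimates (bandwidth = `bandwidth_factor` times the modified-Silverman
#' bandwidth `0.9 min(sd, mad) n^{-1/5}`) and takes the density argmax on a
#' fixed grid; consistent when the largest homogeneous cluster of
#' instruments is valid. Standard error by parametric bootstrap.
#'
#' @param h harmonized data.frame with at least three variants.
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth.
#' @param n_boot,seed bootstrap controls.
#' @param grid_points density grid resolution.
#' @param protein_id,cohort_pair labels carried into the result.
#' @return one-row MR result.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000L,
                             seed = NULL, grid_points = 512L,
                             protein_id = NULL, cohort_pair = NULL) {
  check_harmonized(h, 3L, "weighted_mode")
  m <- mr_meta(h, protein_id, cohort_pair)
  ratios <- h$beta_outcome / h$beta_exposure
  w <- h$beta_exposure^2 / h$se_outcome^2
  beta <- weighted_mode_estimate(ratios, w, bandwidth_factor, grid_points)
  se <- boot_se(h, n_boot, seed, function(r, w)
    weighted_mode_estimate(r, w, bandwidth_factor, grid_points))
  new_mr_result(m$protein_id, m$cohort_pair, "weighted_mode", nrow(h),
                beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

# Parametric bootstrap of an estimator of (ratios, weights).
boot_se <- function(h, n_boot, seed, estimator) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(h)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    estimator(by / bx, bx^2 / h$se_outcome^2)
  }, numeric(1))
  stats::sd(est)
}

#' Steiger directionality test
#'
#' Tests whether a variant explains more variance in the exposure than in
#' the outcome (Fisher-z comparison of the implied correlations, each with
#' its own sample size). Supports the assumed exposure-to-outcome direction
#' when `r2_exposure > r2_outcome` with a one-sided p below alpha.
#'
#' @param r2_exposure,r2_outcome per-variant variance explained.
#' @param n_exposure,n_outcome sample sizes.
#' @return data.frame with `steiger_z`, `steiger_p` (one-sided) and
#'   `direction_valid`.
#' @export
steiger_test <- function(r2_exposure, n_exposure, r2_outcome, n_outcome,
                         alpha = 0.05) {
  r1 <- sqrt(pmin(pmax(r2_exposure, 0), 1 - 1e-12))
  r2 <- sqrt(pmin(pmax(r2_outcome, 0), 1 - 1e-12))
  z <- (atanh(r1) - atanh(r2)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(steiger_z = z, steiger_p = p,
             direction_valid = r2_exposure > r2_outcome & p < alpha)
}

#' Steiger filtering of harmonized variants
#'
#' Computes per-variant variance explained on each side from the z-score
#' form `r^2 = z^2 / (z^2 + n - 2)` (used for both traits for comparability;
#' for the binary outcome this is the observed-scale approximation, with no
#' liability-scale correction) and retains variants whose direction test
#' supports exposure-to-outcome causality.
#'
#' @param h harmonized data.frame.
#' @param n_exposure,n_outcome sample sizes (default: medians recorded at
#'   harmonization).
#' @param alpha one-sided test level (default 0.05).
#' @return list with `retained` (filtered harmonized data.frame) and `flags`
#'   (per-variant r-squared values and test results).
#' @export
steiger_filter <- function(h, n_exposure = NULL, n_outcome = NULL,
                           alpha = 0.05) {
  if (is.null(n_exposure)) n_exposure <- attr(h, "n_exposure")
  if (is.null(n_outcome)) n_outcome <- attr(h, "n_outcome")
  if (is.null(n_exposure) || is.null(n_outcome) ||
      is.na(n_exposure) || is.na(n_outcome)) {
    stop("sample sizes are required for Steiger filtering")
  }
  zx <- h$beta_exposure / h$se_exposure
  zy <- h$beta_outcome / h$se_outcome
  r2x <- zx^2 / (zx^2 + n_exposure - 2)
  r2y <- zy^2 / (zy^2 + n_outcome - 2)
  tst <- steiger_test(r2x, n_exposure, r2y, n_outcome, alpha)
  flags <- cbind(data.frame(variant_id = h$variant_id, r2_exposure = r2x,
                            r2_outcome = r2y, stringsAsFactors = FALSE), tst)
  retained <- h[tst$direction_valid, , drop = FALSE]
  rownames(retained) <- NULL
  for (a in c("n_exposure", "n_outcome")) attr(retained, a) <- attr(h, a)
  class(retained) <- class(h)
  list(retained = retained, flags = flags)
}

# Estimator dispatch shared by forward and reverse runs:
# 1 variant -> Wald ratio only; 2 -> IVW only (no sensitivity analyses);
# >= 3 -> IVW plus MR-Egger, weighted median and weighted mode.
mr_dispatch <- function(h, protein_id, cohort_pair, n_boot = 1000L,
                        seed = NULL, bandwidth_factor = 1,
                        steiger_pass = NA) {
  n <- nrow(h)
  if (n == 0L) {
    out <- empty_mr_result()
    attr(out, "status") <- "no_variants"
    return(out)
  }
  res <- if (n == 1L) {
    mr_wald_ratio(h, protein_id, cohort_pair)
  } else if (n == 2L) {
    mr_ivw(h, protein_id, cohort_pair)
  } else {
    rbind(
      mr_ivw(h, protein_id, cohort_pair),
      mr_egger(h, protein_id, cohort_pair),
      mr_weighted_median(h, n_boot = n_boot, seed = seed,
                         protein_id = protein_id, cohort_pair = cohort_pair),
      mr_weighted_mode(h, bandwidth_factor = bandwidth_factor,
                       n_boot = n_boot, seed = seed,
                       protein_id = protein_id, cohort_pair = cohort_pair)
    )
  }
  res$steiger_pass <- steiger_pass
  res
}

#' Run the MR analysis for one protein against one outcome
#'
#' Harmonizes the instrument records to the outcome table, applies Steiger
#' filtering (when enabled), and dispatches on the surviving instrument
#' count: one variant gives the Wald ratio only; two give IVW only (no
#' sensitivity analyses); three or more give IVW plus MR-Egger, weighted
#' median and weighted mode.
#'
#' @param instrument_set a `protmr_instruments` object.
#' @param outcome a `protmr_sumstats` table for the disease trait.
#' @param config analysis settings from [protmr_config()] (Steiger toggle
#'   and level, bootstrap reps, bandwidth factor, seed).
#' @return data.frame of MR results, one row per method, with a
#'   `steiger_flags` attribute holding the per-variant directionality test.
#'   Zero surviving instruments yield a zero-row result with a `status`
#'   attribute.
#' @export
run_mr <- function(instrument_set, outcome, config = protmr_config()) {
  stopifnot(inherits(instrument_set, "protmr_instruments"))
  if (nrow(instrument_set$instruments) == 0L) {
    out <- empty_mr_result()
    attr(out, "status") <- "no_instruments"
    return(out)
  }
  exp_table <- structure(
    instrument_set$instruments[SUMSTATS_COLS],
    trait_id = instrument_set$protein_id, trait_type = "quantitative",
    cohort_id = instrument_set$cohort_id,
    class = c("protmr_sumstats", "data.frame"))
  h <- harmonize(exp_table, outcome)
  flags <- NULL
  if (isTRUE(config$steiger)) {
    sf <- steiger_filter(h, alpha = config$steiger_alpha)
    h <- sf$retained
    flags <- sf$flags
  }
  pair <- paste(instrument_set$cohort_id, attr(outcome, "cohort_id"),
                sep = "_")
  out <- mr_dispatch(h, instrument_set$protein_id, pair,
                     n_boot = config$n_boot, seed = config$seed,
                     bandwidth_factor = config$bandwidth_factor,
                     steiger_pass = if (isTRUE(config$steiger)) TRUE else NA)
  attr(out, "steiger_flags") <- flags
  out
}

#' Reverse MR: disease as exposure, protein as outcome
#'
#' Selects genome-wide instruments for the disease at the primary threshold;
#' if fewer than `config$min_reverse_instruments` survive, re-selects at the
#' lenient fallback threshold. Instruments are clumped when an LD matrix is
#' supplied, palindromic variants are excluded, Steiger filtering is applied
#' (which also removes variants whose disease association is driven by the
#' protein itself), and the usual estimator dispatch runs with the roles
#' swapped.
#'
#' @param disease a `protmr_sumstats` table for the disease (the reverse
#'   exposure).
#' @param protein a `protmr_sumstats` table for the protein (the reverse
#'   outcome).
#' @param ld_r2 optional r-squared matrix for clumping the disease
#'   instruments; when `NULL` the selected variants are assumed independent.
#' @param config settings from [protmr_config()] (`p_reverse`,
#'   `p_reverse_fallback`, `min_reverse_instruments`, Steiger and bootstrap
#'   controls).
#' @return MR result data.frame with attributes `threshold_used`,
#'   `fallback_used` and `status` (`"ok"` or `"not_testable"` when no
#'   instruments survive even the lenient threshold).
#' @export
reverse_mr <- function(disease, protein, ld_r2 = NULL,
                       config = protmr_config()) {
  sel <- significance_filter(disease, config$p_reverse)
  threshold_used <- config$p_reverse
  fallback_used <- FALSE
  if (nrow(sel) < config$min_reverse_instruments) {
    sel <- significance_filter(disease, config$p_reverse_fallback)
    threshold_used <- config$p_reverse_fallback
    fallback_used <- TRUE
  }
  if (nrow(sel) > 1L && !is.null(ld_r2)) {
    sel <- clump(sel, ld_r2, config$clump_r2)
  }
  if (nrow(sel) > 0L) {
    pal <- is_palindromic(sel$effect_allele, sel$other_allele)
    sel <- subset_rows(sel, !pal)
  }
  if (nrow(sel) == 0L) {
    out <- empty_mr_result()
    attr(out, "status") <- "not_testable"
    attr(out, "threshold_used") <- threshold_used
    attr(out, "fallback_used") <- fallback_used
    return(out)
  }
  h <- tryCatch(harmonize(sel, protein), error = function(e) NULL)
  flags <- NULL
  if (!is.null(h) && isTRUE(config$steiger)) {
    sf <- steiger_filter(h, alpha = config$steiger_alpha)
    h <- sf$retained
    flags <- sf$flags
  }
  if (is.null(h) || nrow(h) == 0L) {
    out <- empty_mr_result()
    attr(out, "status") <- "not_testable"
    attr(out, "threshold_used") <- threshold_used
    attr(out, "fallback_used") <- fallback_used
    return(out)
  }
  pair <- paste(attr(disease, "cohort_id"), attr(protein, "cohort_id"),
                sep = "_")
  out <- mr_dispatch(h, attr(protein, "trait_id"), pair,
                     n_boot = config$n_boot, seed = config$seed,
                     bandwidth_factor = config$bandwidth_factor,
                     steiger_pass = if (isTRUE(config$steiger)) TRUE else NA)
  attr(out, "status") <- "ok"
  attr(out, "threshold_used") <- threshold_used
  attr(out, "fallback_used") <- fallback_used
  attr(out, "steiger_flags") <- flags
  out
}
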