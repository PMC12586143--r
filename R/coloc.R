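# Bayesian colocalization under a single-causal-variant model, via
# Wakefield approximate Bayes factors and enumeration of the five
# hypotheses:
#   H0 neither trait associated in the region
#   H1 trait 1 only; H2 trait 2 only
#   H3 both associated, through distinct causal variants
#   H4 both associated, through one shared causal variant
# All sums are carried in log space so regions with very large z-scores
# remain finite.

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect prior with standard deviation `prior_sd`: with `z = beta/se`,
#' `V = se^2`, `W = prior_sd^2` and `r = W/(V+W)`,
#' `lABF = 0.5 log(1 - r) + 0.5 r z^2`.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param prior_sd prior effect-size standard deviation (`> 0`): 0.15 is the
#'   conventional default for a standardized quantitative trait, 0.2 for a
#'   case-control trait on the log-odds scale.
#' @return numeric vector of log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + 0.5 * r * z^2
}

#' Colocalization posterior probabilities for one region
#'
#' Computes per-variant log approximate Bayes factors for each trait and
#' enumerates the five single-causal-variant hypotheses with priors `p1`
#' (causal for trait 1 only), `p2` (trait 2 only) and `p12` (shared). With
#' `S1 = sum_i exp(lABF1_i)`, `S2 = sum_j exp(lABF2_j)` and
#' `S12 = sum_i exp(lABF1_i + lABF2_i)`, the unnormalized weights are
#' `H0 = 1`, `H1 = p1 S1`, `H2 = p2 S2`, `H3 = p1 p2 (S1 S2 - S12)` and
#' `H4 = p12 S12`; posteriors are their normalization. In a single-variant
#' region the distinct-variant term is an empty sum, so `PP(H3) = 0`.
#'
#' @param beta1,se1 per-variant effects and standard errors for trait 1
#'   (the quantitative protein trait).
#' @param beta2,se2 the same variants' effects for trait 2 (the
#'   case-control trait, log-odds scale).
#' @param snp optional variant ids.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5);
#'   must satisfy `p1 + p2 + p12 < 1`.
#' @param prior_sd1,prior_sd2 effect priors per trait (defaults 0.15, 0.2).
#' @param protein_id,cohort_pair labels carried into the result.
#' @return list of class `protmr_coloc`: `pp` (named posterior vector
#'   `pp_h0` ... `pp_h4`, summing to 1), `decision_sum = pp_h3 + pp_h4`,
#'   `passes` (strict `> 0.5` on the default threshold), `n_snps`, and
#'   `labf` (per-variant log ABFs for regional plots).
#' @export
coloc_abf <- function(beta1, se1, beta2, se2, snp = NULL,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.2,
                      protein_id = "protein",
                      cohort_pair = "trait1_trait2") {
  n <- length(beta1)
  stopifnot(n >= 1, length(se1) == n, length(beta2) == n, length(se2) == n)
  if (min(p1, p2, p12) <= 0 || p1 + p2 + p12 >= 1) {
    stop("priors must be positive with p1 + p2 + p12 < 1")
  }
  if (is.null(snp)) snp <- paste0("snp", seq_len(n))
  l1 <- wakefield_labf(beta1, se1, prior_sd1)
  l2 <- wakefield_labf(beta2, se2, prior_sd2)
  logS1 <- logsumexp(l1)
  logS2 <- logsumexp(l2)
  logS12 <- logsumexp(l1 + l2)
  logw <- c(
    h0 = 0,
    h1 = log(p1) + logS1,
    h2 = log(p2) + logS2,
    h3 = if (n == 1L) -Inf else
      log(p1) + log(p2) + logdiffexp(logS1 + logS2, logS12),
    h4 = log(p12) + logS12
  )
  pp <- exp(logw - logsumexp(logw))
  names(pp) <- paste0("pp_", names(logw))
  decision_sum <- unname(pp["pp_h3"] + pp["pp_h4"])
  structure(list(
    protein_id = protein_id, cohort_pair = cohort_pair, n_snps = n,
    pp = pp, decision_sum = decision_sum,
    passes = decision_sum > 0.5,
    labf = data.frame(snp = snp, labf_trait1 = l1, labf_trait2 = l2,
                      stringsAsFactors = FALSE),
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    prior_sd = c(trait1 = prior_sd1, trait2 = prior_sd2)
  ), class = "protmr_coloc")
}

#' Colocalization decision rule
#'
#' Declares colocalization evidence when the posterior probability of a
#' regional association shared with or linked to the outcome,
#' `PP(H3) + PP(H4)`, strictly exceeds the threshold. A sum of exactly 0.5
#' fails the default gate.
#'
#' @param result a `protmr_coloc` object.
#' @param threshold decision threshold (default 0.5, strict).
#' @return logical.
#' @export
coloc_decision <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "protmr_coloc"))
  unname(result$pp["pp_h3"] + result$pp["pp_h4"]) > threshold
}

#' Colocalize a harmonized region
#'
#' Convenience wrapper running [coloc_abf()] on a harmonized exposure/outcome
#' region (all shared variants, no significance filtering: colocalization
#' uses the full regional signal).
#'
#' @param h harmonized data.frame from [harmonize()].
#' @param ... passed to [coloc_abf()].
#' @return a `protmr_coloc` object.
#' @export
coloc_region <- function(h, ...) {
  coloc_abf(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome,
            snp = h$variant_id, ...)
}

#' @export
print.protmr_coloc <- function(x, ...) {
  cat("Colocalization (", x$protein_id, ", ", x$cohort_pair, "), ",
      x$n_snps, " variants\n", sep = "")
  print(round(x$pp, 4))
  cat("PP(H3)+PP(H4) =", format(round(x$decision_sum, 4)),
      if (x$passes) "(passes > 0.5)" else "(fails > 0.5)", "\n")
  invisible(x)
}
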