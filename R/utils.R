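# Internal numeric helpers shared across modules.

.protmr_env <- new.env(parent = emptyenv())

#' Numerically stable log of a sum of exponentials
#' @param x numeric vector of log-scale values
#' @return log(sum(exp(x)))
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (used for the distinct-causal-variant term, which is an
# empty sum in single-variant regions).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Derive a reproducible sub-seed from a master seed. Keeps results
# independent across pipeline stages while everything flows from one
# user-supplied integer. Result stays below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) + as.double(stream) * 1000003) %% 2147483629)
}

# Gauss-Legendre nodes/weights on [0, 1] via Golub-Welsch; cached.
gauss_legendre_01 <- function(n = 48L) {
  key <- paste0("gl", n)
  if (!is.null(.protmr_env[[key]])) return(.protmr_env[[key]])
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  ord <- order(x)
  out <- list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
  .protmr_env[[key]] <- out
  out
}

# Bivariate standard-normal CDF P(Z1 < h, Z2 < k) with correlation rho,
# by quadrature of the Drezner-Wesolowsky identity
#   Phi2(h, k; rho) = Phi(h) Phi(k) +
#     (1 / 2pi) * Int_0^rho exp(-(h^2 + k^2 - 2 r h k) / (2 (1 - r^2))) /
#                  sqrt(1 - r^2) dr
pbvn <- function(h, k, rho) {
  if (abs(rho) < .Machine$double.eps) return(stats::pnorm(h) * stats::pnorm(k))
  gl <- gauss_legendre_01(48L)
  r <- rho * gl$x
  integrand <- exp(-(h^2 + k^2 - 2 * r * h * k) / (2 * (1 - r^2))) /
    sqrt(1 - r^2)
  stats::pnorm(h) * stats::pnorm(k) + rho * sum(gl$w * integrand) / (2 * pi)
}

# Latent Gaussian correlation that yields a target Pearson correlation
# between two Bernoulli haplotype indicators with the given allele
# frequencies. Capped when the target exceeds the Frechet bound for
# unequal frequencies (as for real variants with mismatched MAFs).
solve_latent_rho <- function(target, m1, m2, cap = 0.9995) {
  if (target <= 0) return(0)
  q1 <- stats::qnorm(m1)
  q2 <- stats::qnorm(m2)
  denom <- sqrt(m1 * (1 - m1) * m2 * (1 - m2))
  f <- function(rho) (pbvn(q1, q2, rho) - m1 * m2) / denom - target
  if (f(cap) < 0) return(cap)
  stats::uniroot(f, c(0, cap), tol = 1e-7)$root
}

# Write a data.frame as plain TSV (the package's on-disk dialect).
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
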