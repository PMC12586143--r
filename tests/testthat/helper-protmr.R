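# Shared builders for unit tests.

# Minimal valid variant records; every argument is recycled to length n.
make_records <- function(n = 5, variant_id = sprintf("rs%03d", seq_len(n)),
                         chromosome = "1",
                         position = seq(1000, by = 1000, length.out = n),
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-10,
                         n_samples = 10000) {
  data.frame(
    variant_id = variant_id, chromosome = chromosome, position = position,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n_samples,
    stringsAsFactors = FALSE
  )
}

make_ss <- function(..., trait_id = "protein",
                    trait_type = "quantitative", cohort_id = "cohortA") {
  sumstats(make_records(...), trait_id = trait_id, trait_type = trait_type,
           cohort_id = cohort_id)
}

# Direct harmonized-style frame for estimator tests (bypasses harmonize()).
make_h <- function(bx, by, sex = rep(0.01, length(bx)),
                   sey = rep(0.05, length(by)),
                   n_exposure = 30000, n_outcome = 60000) {
  h <- data.frame(
    variant_id = sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sex,
    beta_outcome = by, se_outcome = sey,
    stringsAsFactors = FALSE
  )
  attr(h, "n_exposure") <- n_exposure
  attr(h, "n_outcome") <- n_outcome
  h
}

# Independent step-up BH implementation, straight from the definition:
# adjusted p for the i-th smallest p-value is min_{j >= i} min(1, m p_(j)/j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    adj_sorted[i] <- running
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Independent greedy clumping straight from the definition: repeatedly pick
# the smallest-p remaining variant (ties by id), drop all remaining variants
# with r2 >= threshold to it.
oracle_clump_ids <- function(df, r2, thr) {
  remaining <- df[order(df$pval, df$variant_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    top <- remaining$variant_id[1L]
    kept <- c(kept, top)
    remaining <- remaining[-1L, , drop = FALSE]
    if (nrow(remaining) > 0L) {
      conflict <- r2[remaining$variant_id, top] >= thr
      remaining <- remaining[!conflict, , drop = FALSE]
    }
  }
  sort(kept)
}

# Direct five-term colocalization enumeration (no log-space), for small
# regions with moderate z-scores.
oracle_coloc <- function(beta1, se1, beta2, se2, p1 = 1e-4, p2 = 1e-4,
                         p12 = 1e-5, sd1 = 0.15, sd2 = 0.2) {
  abf <- function(beta, se, w) {
    v <- se^2
    sqrt(v / (v + w^2)) * exp(w^2 / (v + w^2) * (beta / se)^2 / 2)
  }
  a1 <- abf(beta1, se1, sd1)
  a2 <- abf(beta2, se2, sd2)
  s1 <- sum(a1)
  s2 <- sum(a2)
  s12 <- sum(a1 * a2)
  w <- c(1, p1 * s1, p2 * s2, p1 * p2 * (s1 * s2 - s12), p12 * s12)
  w / sum(w)
}

# Fast exact evaluation of the weighted L1 objective sum w|x - b| on a grid.
l1_objective <- function(grid, b, w) {
  ord <- order(b)
  bs <- b[ord]
  ws <- w[ord]
  cw <- cumsum(ws)
  cwb <- cumsum(ws * bs)
  W <- cw[length(cw)]
  WB <- cwb[length(cwb)]
  k <- findInterval(grid, bs)
  wl <- ifelse(k == 0, 0, cw[pmax(k, 1)])
  sl <- ifelse(k == 0, 0, cwb[pmax(k, 1)])
  grid * (2 * wl - W) - (2 * sl - WB)
}
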