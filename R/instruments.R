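# Cis-pQTL instrument selection: window, significance, LD clumping,
# palindromic exclusion and instrument-strength filtering, applied in that
# order with per-stage accounting.

#' Gene region annotation for one protein
#'
#' @param protein_id,gene_symbol identifiers.
#' @param chromosome chromosome label (character).
#' @param start,end transcript boundaries, 1-based inclusive base pairs.
#' @return list of class `protmr_region`.
#' @export
gene_region <- function(protein_id, gene_symbol, chromosome, start, end) {
  stopifnot(start <= end, start >= 1)
  structure(list(protein_id = protein_id, gene_symbol = gene_symbol,
                 chromosome = as.character(chromosome),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "protmr_region")
}

#' Read a gene-region annotation table
#'
#' @param path TSV with columns `protein_id`, `gene_symbol`, `chromosome`,
#'   `start`, `end` (1-based inclusive coordinates).
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("protein_id", "gene_symbol", "chromosome", "start", "end")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("region table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Restrict a summary-statistics table to a cis window around a gene
#'
#' Retains variants on the gene's chromosome with position in
#' `[start - window, end + window]` (boundaries inclusive, clipped at 1).
#' The window is measured from the annotated gene boundaries, not the TSS.
#'
#' @param table a `protmr_sumstats` table.
#' @param region a `protmr_region`.
#' @param window flank in base pairs (default 1 Mb).
#' @return the filtered table (empty, with a warning, if the chromosome is
#'   absent).
#' @export
cis_filter <- function(table, region, window = 1e6) {
  stopifnot(window >= 0)
  df <- as.data.frame(table)
  lo <- max(1, region$start - window)
  hi <- region$end + window
  keep <- df$chromosome == region$chromosome & df$position >= lo &
    df$position <= hi
  if (!any(df$chromosome == region$chromosome)) {
    warning("chromosome ", region$chromosome, " absent from table ",
            attr(table, "trait_id"))
  }
  subset_rows(table, keep)
}

#' Retain genome-wide significant associations
#'
#' Strict inequality: a p-value exactly at the threshold is excluded.
#'
#' @param table a `protmr_sumstats` table.
#' @param threshold p-value threshold (default 5e-8).
#' @return the filtered table.
#' @export
significance_filter <- function(table, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  subset_rows(table, as.data.frame(table)$pval < threshold)
}

# Subset a sumstats table preserving metadata; allows zero rows (unlike the
# constructor) because downstream stages decide what an empty set means.
subset_rows <- function(table, keep) {
  df <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            cohort_id = attr(table, "cohort_id"),
            class = c("protmr_sumstats", "data.frame"))
}

#' Greedy LD clumping by p-value
#'
#' Sorts variants by ascending p-value (ties broken lexicographically by
#' variant id, for determinism), repeatedly accepts the best remaining
#' variant and discards all others with r-squared at or above the threshold
#' to any accepted variant.
#'
#' @param table a `protmr_sumstats` table.
#' @param ld_r2 square r-squared matrix with variant ids as dimnames,
#'   covering every variant in `table`.
#' @param r2_threshold clumping threshold (default 0.001); variants with
#'   `r2 >= r2_threshold` to an accepted variant are removed.
#' @return the clumped table.
#' @export
clump <- function(table, ld_r2, r2_threshold = 0.001) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  df <- as.data.frame(table)
  if (nrow(df) <= 1L) return(table)
  ids <- df$variant_id
  missing_ids <- setdiff(ids, rownames(ld_r2))
  if (length(missing_ids) > 0L) {
    stop("LD matrix lacks entries for variant(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  r2 <- ld_r2[ids, ids, drop = FALSE]
  if (any(is.na(r2))) {
    bad <- which(is.na(r2), arr.ind = TRUE)[1L, ]
    stop("missing LD entry for pair ", ids[bad[1L]], " / ", ids[bad[2L]])
  }
  ord <- order(df$pval, df$variant_id)
  accepted <- logical(nrow(df))
  removed <- logical(nrow(df))
  for (i in ord) {
    if (removed[i]) next
    accepted[i] <- TRUE
    removed <- removed | (r2[, i] >= r2_threshold & !accepted)
  }
  subset_rows(table, accepted)
}

#' Instrument strength: variance explained and F-statistic
#'
#' For a standardized quantitative exposure the per-variant variance
#' explained is `R^2 = 2 eaf (1 - eaf) beta^2`, and the strength statistic is
#' `F = R^2 (n - 2) / (1 - R^2)`. A missing effect-allele frequency is a
#' precondition error: no silent fallback to the z-score form is applied.
#'
#' @param eaf effect-allele frequency vector (no missing values).
#' @param beta per-allele effect in SD units.
#' @param n sample size (at least 3).
#' @return data.frame with columns `r_squared` and `f_stat`.
#' @examples
#' instrument_strength(0.5, 0.1, 35559)  # R^2 = 0.005, F ~ 178.7
#' @export
instrument_strength <- function(eaf, beta, n) {
  if (any(is.na(eaf))) {
    stop("effect-allele frequency is required to compute R^2; ",
         "missing EAF is not imputed")
  }
  stopifnot(all(n >= 3))
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1)) stop("variance explained at or above 1; check the scale ",
                         "of beta (SD units expected)")
  data.frame(r_squared = r2, f_stat = r2 * (n - 2) / (1 - r2))
}

#' Select cis instruments for one protein
#'
#' Applies the selection criteria in order: cis window, genome-wide
#' significance, LD clumping, palindromic exclusion, F-statistic strength.
#' Per-stage removal counts are logged. An empty surviving set is returned
#' (flagged), not raised as an error: downstream code decides how to treat
#' uninstrumentable proteins.
#'
#' @param exposure a `protmr_sumstats` table of pQTL associations.
#' @param region the protein's `protmr_region`.
#' @param ld_r2 r-squared matrix covering the significant cis variants (see
#'   [clump()]).
#' @param p_threshold significance threshold (default 5e-8, strict).
#' @param clump_r2 clumping threshold (default 0.001).
#' @param f_min minimum F-statistic (default 10; instruments with F below it
#'   are excluded).
#' @param window cis window in bp (default 1 Mb).
#' @return list of class `protmr_instruments`: `protein_id`, `cohort_id`,
#'   `instruments` (variant records plus `r_squared`, `f_stat`), `n_input`,
#'   and `filter_log` (removals per stage, summing with the retained count to
#'   `n_input`).
#' @export
build_instrument_set <- function(exposure, region, ld_r2,
                                 p_threshold = 5e-8, clump_r2 = 0.001,
                                 f_min = 10, window = 1e6) {
  n_input <- nrow(exposure)
  t_cis <- cis_filter(exposure, region, window)
  t_sig <- significance_filter(t_cis, p_threshold)
  t_clump <- if (nrow(t_sig) > 0L) clump(t_sig, ld_r2, clump_r2) else t_sig
  df <- as.data.frame(t_clump)
  pal <- if (nrow(df) > 0L) is_palindromic(df$effect_allele, df$other_allele)
         else logical(0)
  df <- df[!pal, , drop = FALSE]
  if (nrow(df) > 0L) {
    strength <- instrument_strength(df$eaf, df$beta, df$n)
    weak <- strength$f_stat < f_min
    df <- cbind(df, strength)[!weak, , drop = FALSE]
  } else {
    weak <- logical(0)
    df <- cbind(df, r_squared = numeric(0), f_stat = numeric(0))
  }
  rownames(df) <- NULL
  filter_log <- c(
    cis = n_input - nrow(t_cis),
    significance = nrow(t_cis) - nrow(t_sig),
    clump = nrow(t_sig) - nrow(t_clump),
    palindromic = sum(pal),
    strength = sum(weak)
  )
  structure(list(protein_id = region$protein_id,
                 cohort_id = attr(exposure, "cohort_id"),
                 instruments = df, n_input = n_input,
                 filter_log = filter_log,
                 thresholds = list(p_threshold = p_threshold,
                                   clump_r2 = clump_r2, f_min = f_min,
                                   window = window)),
            class = "protmr_instruments")
}

#' @export
print.protmr_instruments <- function(x, ...) {
  cat("Instrument set for", x$protein_id, "(", x$cohort_id, "):",
      nrow(x$instruments), "of", x$n_input, "variants retained\n")
  cat("removed per stage:",
      paste(names(x$filter_log), x$filter_log, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
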