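# Summary-statistic containers, file I/O and allele harmonization.

SUMSTATS_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n",
                   "n_cases", "n_controls")
MANDATORY_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                    "other_allele", "beta", "se", "pval", "n")
ACGT <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a validated summary-statistics table
#'
#' Builds the container used throughout the package for one trait's GWAS or
#' pQTL summary statistics: one row per variant with alleles, effect-allele
#' frequency, marginal effect (log-odds for case-control traits, SD units for
#' quantitative traits), standard error, p-value and sample size. Rows
#' violating the per-variant invariants (identical alleles, non-ACGT alleles,
#' `se <= 0`, `pval` outside (0, 1], `eaf` outside [0, 1], inconsistent
#' case/control counts, duplicated variant id) are dropped and counted.
#'
#' @param records data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `n`,
#'   and optionally `eaf`, `n_cases`, `n_controls`. `eaf` may be `NA`
#'   (recorded as unknown); operations that need it raise an error rather
#'   than impute.
#' @param trait_id trait label (protein or disease identifier).
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param cohort_id cohort label (e.g. the source biobank).
#' @return an object of class `protmr_sumstats`: the validated records sorted
#'   by chromosome and position, with attributes `trait_id`, `trait_type`,
#'   `cohort_id` and `drop_log` (named counts of rows removed per reason).
#' @export
sumstats <- function(records, trait_id, trait_type = c("quantitative", "case_control"),
                     cohort_id = "cohort") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLS, names(records))) records[[col]] <- NA
  records <- records[SUMSTATS_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chromosome <- as.character(records$chromosome)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("position", "eaf", "beta", "se", "pval", "n", "n_cases",
                "n_controls")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  v <- validate_variant_records(records)
  records <- v$records
  if (nrow(records) == 0L) stop("no valid variant records after validation")
  records <- records[order(records$chromosome, records$position), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_type = trait_type,
            cohort_id = cohort_id, drop_log = v$drop_log,
            class = c("protmr_sumstats", "data.frame"))
}

# Row-level invariant enforcement; returns kept rows plus per-reason counts.
validate_variant_records <- function(records) {
  reasons <- c(missing_field = 0L, bad_allele = 0L, bad_eaf = 0L,
               bad_se = 0L, bad_pval = 0L, bad_n = 0L,
               bad_case_counts = 0L, duplicate_id = 0L)
  bad_missing <- is.na(records$variant_id) | is.na(records$chromosome) |
    is.na(records$position) | is.na(records$beta)
  bad_allele <- !(records$effect_allele %in% ACGT) |
    !(records$other_allele %in% ACGT) |
    records$effect_allele == records$other_allele
  bad_allele[is.na(bad_allele)] <- TRUE
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  bad_se <- is.na(records$se) | records$se <= 0
  bad_pval <- is.na(records$pval) | records$pval <= 0 | records$pval > 1
  bad_n <- is.na(records$n) | records$n < 1
  has_cases <- !is.na(records$n_cases) | !is.na(records$n_controls)
  bad_cc <- has_cases & (is.na(records$n_cases) | is.na(records$n_controls) |
                           (records$n_cases + records$n_controls != records$n))
  drop <- bad_missing | bad_allele | bad_eaf | bad_se | bad_pval | bad_n | bad_cc
  drop[is.na(drop)] <- TRUE
  reasons["missing_field"] <- sum(bad_missing, na.rm = TRUE)
  reasons["bad_allele"] <- sum(bad_allele & !bad_missing, na.rm = TRUE)
  reasons["bad_eaf"] <- sum(bad_eaf & !bad_missing & !bad_allele, na.rm = TRUE)
  reasons["bad_se"] <- sum(bad_se & !bad_missing & !bad_allele & !bad_eaf,
                           na.rm = TRUE)
  reasons["bad_pval"] <- sum(bad_pval & !bad_missing & !bad_allele & !bad_eaf &
                               !bad_se, na.rm = TRUE)
  reasons["bad_n"] <- sum(bad_n & !bad_missing & !bad_allele & !bad_eaf &
                            !bad_se & !bad_pval, na.rm = TRUE)
  reasons["bad_case_counts"] <- sum(bad_cc & !bad_missing & !bad_allele &
                                      !bad_eaf & !bad_se & !bad_pval & !bad_n,
                                    na.rm = TRUE)
  records <- records[!drop, , drop = FALSE]
  dup <- duplicated(records$variant_id)
  reasons["duplicate_id"] <- sum(dup)
  list(records = records[!dup, , drop = FALSE], drop_log = reasons)
}

#' Read summary statistics from a delimited file
#'
#' Reads a headered TSV or CSV of GWAS/pQTL summary statistics, optionally
#' renaming source columns to the canonical names, and validates the result
#' through [sumstats()].
#'
#' @param path file path; tab- or comma-separated with a header row. The
#'   delimiter is taken from the first line (tab wins if present).
#' @param column_map optional named character vector mapping canonical field
#'   names to source column names, e.g.
#'   `c(variant_id = "SNP", position = "BP", pval = "P")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param trait_id,trait_type,cohort_id trait descriptor passed to
#'   [sumstats()].
#' @return a `protmr_sumstats` table; the `drop_log` attribute counts rows
#'   removed per validation rule.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = basename(path),
                          trait_type = c("quantitative", "case_control"),
                          cohort_id = "cohort") {
  trait_type <- match.arg(trait_type)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0L) {
      stop("column_map names source column(s) absent from file: ",
           paste(missing_src, collapse = ", "))
    }
    for (canonical in names(column_map)) {
      names(raw)[names(raw) == column_map[[canonical]]] <- canonical
    }
  }
  sumstats(raw, trait_id = trait_id, trait_type = trait_type,
           cohort_id = cohort_id)
}

#' Write a summary-statistics table as TSV
#'
#' @param x a `protmr_sumstats` table.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs are strand-ambiguous in summary data: the reported
#' alleles are identical on both strands, so effect orientation cannot be
#' resolved. Such variants are excluded outright, both at instrument
#' selection and at harmonization.
#'
#' @param effect_allele,other_allele character vectors of single bases
#'   (A, C, G or T).
#' @return logical vector, `TRUE` where the pair is A/T or C/G.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!all(effect_allele %in% ACGT) || !all(other_allele %in% ACGT)) {
    stop("alleles must be one of A, C, G, T")
  }
  (effect_allele == "A" & other_allele == "T") |
    (effect_allele == "T" & other_allele == "A") |
    (effect_allele == "C" & other_allele == "G") |
    (effect_allele == "G" & other_allele == "C")
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Matches variants present in both tables and aligns the outcome effect to
#' the exposure's effect allele. Outcome records whose alleles are swapped
#' relative to the exposure have their beta negated and effect-allele
#' frequency reflected (`1 - eaf`). Non-palindromic strand mismatches are
#' resolved by complementing the outcome alleles (unambiguous for
#' non-palindromic pairs). Palindromic variants on either side are excluded,
#' as are allele sets that neither match, swap, nor complement-resolve.
#'
#' @param exposure,outcome `protmr_sumstats` tables.
#' @param match_by `"variant_id"` (default; rsIDs are the join key on both
#'   pQTL platforms) or `"position"` (chromosome:position fallback).
#' @return data.frame of class `protmr_harmonized` with one row per retained
#'   variant: exposure and outcome beta/se/pval/eaf aligned to the exposure's
#'   effect allele, and an `action` column (`"none"` or `"flipped_outcome"`).
#'   Excluded variants are recorded in the `dropped` attribute with actions
#'   `"dropped_palindromic"` / `"dropped_incompatible"`; per-action counts are
#'   in the `action_log` attribute.
#' @export
harmonize <- function(exposure, outcome, match_by = c("variant_id", "position")) {
  match_by <- match.arg(match_by)
  e <- as.data.frame(exposure)
  o <- as.data.frame(outcome)
  if (match_by == "position") {
    e$.key <- paste(e$chromosome, e$position, sep = ":")
    o$.key <- paste(o$chromosome, o$position, sep = ":")
  } else {
    e$.key <- e$variant_id
    o$.key <- o$variant_id
  }
  idx <- match(e$.key, o$.key)
  keep <- !is.na(idx)
  e <- e[keep, , drop = FALSE]
  o <- o[idx[keep], , drop = FALSE]
  n <- nrow(e)
  if (n == 0L) {
    stop("no shared variants between exposure and outcome tables")
  }

  pal <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  o_ea_c <- unname(COMPLEMENT[o$effect_allele])
  o_oa_c <- unname(COMPLEMENT[o$other_allele])
  comp_same <- o_ea_c == e$effect_allele & o_oa_c == e$other_allele
  comp_swapped <- o_ea_c == e$other_allele & o_oa_c == e$effect_allele

  action <- rep("dropped_incompatible", n)
  action[(same | comp_same) & !pal] <- "none"
  action[(swapped | comp_swapped) & !pal] <- "flipped_outcome"
  action[pal] <- "dropped_palindromic"

  flip <- action == "flipped_outcome"
  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)

  h <- data.frame(
    variant_id = e$variant_id,
    chromosome = e$chromosome,
    position = e$position,
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    beta_exposure = e$beta,
    se_exposure = e$se,
    pval_exposure = e$pval,
    eaf_exposure = e$eaf,
    beta_outcome = beta_out,
    se_outcome = o$se,
    pval_outcome = o$pval,
    eaf_outcome = eaf_out,
    action = action,
    stringsAsFactors = FALSE
  )
  retained <- h[h$action %in% c("none", "flipped_outcome"), , drop = FALSE]
  rownames(retained) <- NULL
  dropped <- h[!(h$action %in% c("none", "flipped_outcome")), , drop = FALSE]
  rownames(dropped) <- NULL
  structure(retained,
            dropped = dropped,
            action_log = table(factor(action, levels = c(
              "none", "flipped_outcome", "dropped_palindromic",
              "dropped_incompatible"))),
            n_exposure = stats::median(e$n),
            n_outcome = stats::median(o$n),
            class = c("protmr_harmonized", "data.frame"))
}

# Rebuild a protmr_sumstats from a subset of rows of another (keeps trait
# metadata; used when passing an instrument set's records back through
# harmonization).
subset_sumstats <- function(x, rows) {
  sumstats(as.data.frame(x)[rows, , drop = FALSE],
           trait_id = attr(x, "trait_id"),
           trait_type = attr(x, "trait_type"),
           cohort_id = attr(x, "cohort_id"))
}
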