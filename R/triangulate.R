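# Triangulation of the three exposure-outcome analyses into candidate
# calls: nominal-significance intersection, directional consistency,
# per-analysis FDR labelling, colocalization gating and risk/protective
# classification.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1; input order is preserved. Thin wrapper over
#' `stats::p.adjust(method = "BH")`, kept as a named operation so the
#' multiple-testing rule used for significance labelling is explicit.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order (empty in, empty out).
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Triangulate per-protein MR results across the three analyses
#'
#' Applies the screening rule: a protein is a candidate when it is nominally
#' significant (`p < alpha`) in at least two analyses AND its effect
#' direction agrees across all analyses. The rule presupposes presence in
#' every analysis: proteins missing from any analysis (platform coverage)
#' are ineligible for candidacy. Candidates are classified as risk (all ORs
#' above 1) or protective (all below 1). FDR labelling adjusts p-values
#' within each analysis across its tested proteins; `fdr_significant` marks
#' proteins whose minimum per-analysis adjusted p-value is below
#' `fdr_alpha`.
#'
#' @param primary data.frame of primary MR estimates with columns
#'   `protein_id`, `analysis`, `beta`, `se`, `pval` (one row per protein per
#'   analysis; the primary estimate is IVW for two or more instruments, the
#'   Wald ratio for one).
#' @param alpha nominal significance level (default 0.05).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param n_analyses number of analyses a protein must appear in (default:
#'   all analyses present in `primary`).
#' @return data.frame of verdicts: per-protein nominal count, direction
#'   consistency, FDR flag, candidacy and classification, plus the
#'   per-analysis adjusted p-values in the `fdr` attribute.
#' @export
triangulate_proteins <- function(primary, alpha = 0.05, fdr_alpha = 0.05,
                                 n_analyses = NULL) {
  needed <- c("protein_id", "analysis", "beta", "pval")
  missing_cols <- setdiff(needed, names(primary))
  if (length(missing_cols) > 0L) {
    stop("primary results are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(primary) == 0L) stop("no primary MR results to triangulate")
  analyses <- sort(unique(primary$analysis))
  if (is.null(n_analyses)) n_analyses <- length(analyses)

  primary$pfdr <- NA_real_
  for (a in analyses) {
    idx <- primary$analysis == a
    primary$pfdr[idx] <- bh_fdr(primary$pval[idx])
  }

  verdicts <- do.call(rbind, lapply(split(primary, primary$protein_id),
                                    function(d) {
    present <- nrow(d)
    n_nominal <- sum(d$pval < alpha)
    direction_consistent <- present == n_analyses &&
      (all(d$beta > 0) || all(d$beta < 0))
    candidate <- n_nominal >= 2L && direction_consistent
    classification <- if (candidate && all(d$beta > 0)) "risk"
      else if (candidate && all(d$beta < 0)) "protective" else "none"
    data.frame(
      protein_id = d$protein_id[1L], n_analyses_present = present,
      n_nominal = n_nominal, direction_consistent = direction_consistent,
      min_pval = min(d$pval), min_pfdr = min(d$pfdr),
      fdr_significant = min(d$pfdr) < fdr_alpha,
      candidate = candidate, classification = classification,
      stringsAsFactors = FALSE
    )
  }))
  rownames(verdicts) <- NULL
  verdicts <- verdicts[order(verdicts$protein_id), , drop = FALSE]
  attr(verdicts, "fdr") <- primary[c("protein_id", "analysis", "pval",
                                     "pfdr")]
  attr(verdicts, "analyses") <- analyses
  verdicts
}

#' Gate candidates on colocalization and reverse-MR evidence
#'
#' Annotates each triangulation verdict with the number of analyses showing
#' colocalization evidence (`PP(H3) + PP(H4)` above the threshold) and with
#' whether reverse MR is clear of a disease-to-protein association. The
#' "validated" tier requires candidacy, colocalization support in all three
#' analyses, and a clear reverse MR. Proteins whose reverse MR was not
#' testable (no disease instruments survived) count as clear but are
#' flagged.
#'
#' @param verdicts output of [triangulate_proteins()].
#' @param coloc data.frame with columns `protein_id`, `analysis`,
#'   `decision_sum` (the posterior sum `PP(H3) + PP(H4)`).
#' @param reverse data.frame with columns `protein_id`, `pval` (primary
#'   reverse-MR p-value) and optionally `status` (`"not_testable"` rows
#'   count as clear). May be zero rows.
#' @param coloc_threshold decision threshold (default 0.5, strict).
#' @param alpha reverse-MR significance level (default 0.05).
#' @param n_analyses analyses required for full colocalization support
#'   (default 3).
#' @return the verdicts with `coloc_pass_count`, `reverse_mr_clear`,
#'   `reverse_testable` and `validated` columns appended.
#' @export
gate_candidates <- function(verdicts, coloc, reverse,
                            coloc_threshold = 0.5, alpha = 0.05,
                            n_analyses = 3L) {
  out <- verdicts
  out$coloc_pass_count <- vapply(out$protein_id, function(pid) {
    d <- coloc[coloc$protein_id == pid, , drop = FALSE]
    sum(d$decision_sum > coloc_threshold)
  }, integer(1))
  rev_clear <- vapply(out$protein_id, function(pid) {
    d <- reverse[reverse$protein_id == pid, , drop = FALSE]
    if (nrow(d) == 0L) return(TRUE)
    if (!is.null(d$status) && all(d$status == "not_testable")) return(TRUE)
    all(is.na(d$pval) | d$pval >= alpha)
  }, logical(1))
  out$reverse_mr_clear <- rev_clear
  out$reverse_testable <- vapply(out$protein_id, function(pid) {
    d <- reverse[reverse$protein_id == pid, , drop = FALSE]
    nrow(d) > 0L && (is.null(d$status) || any(d$status != "not_testable"))
  }, logical(1))
  out$validated <- out$candidate & out$coloc_pass_count == n_analyses &
    out$reverse_mr_clear
  out
}
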