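# Run configuration and end-to-end orchestration: instruments -> MR ->
# Steiger/reverse -> colocalization -> triangulation, per analysis pair,
# with per-stage accounting and a machine-readable manifest.

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline under a named key so
#' deviations from the defaults are explicit and logged in the run
#' manifest. Defaults: cis window 1 Mb around the gene boundaries;
#' instrument p-value 5e-8 (strict); LD clumping r-squared 0.001; minimum
#' F-statistic 10; reverse-MR selection at 5e-8 with a 5e-6 fallback when
#' fewer than 3 instruments survive; nominal and FDR significance at 0.05;
#' colocalization priors p1 = p2 = 1e-4, p12 = 1e-5 with effect priors 0.15
#' (quantitative) and 0.2 (log-odds), decision threshold 0.5; Steiger
#' filtering enabled at one-sided 0.05; 1000 bootstrap resamples.
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of class `protmr_config`.
#' @export
protmr_config <- function(...) {
  cfg <- list(
    cis_window = 1e6, p_instrument = 5e-8, clump_r2 = 0.001, f_min = 10,
    p_reverse = 5e-8, p_reverse_fallback = 5e-6,
    min_reverse_instruments = 3L,
    alpha = 0.05, fdr_alpha = 0.05,
    steiger = TRUE, steiger_alpha = 0.05,
    coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
    coloc_sd_quant = 0.15, coloc_sd_cc = 0.2, coloc_threshold = 0.5,
    n_boot = 1000L, bandwidth_factor = 1, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$p_instrument > 0, cfg$p_instrument <= 1,
            cfg$clump_r2 > 0, cfg$clump_r2 <= 1, cfg$f_min >= 0,
            cfg$cis_window >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$coloc_p1 + cfg$coloc_p2 + cfg$coloc_p12 < 1,
            cfg$coloc_threshold > 0, cfg$coloc_threshold < 1,
            cfg$n_boot >= 1)
  structure(cfg, class = c("protmr_config", "list"))
}

#' Read / write a configuration as YAML
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `protmr_config`; [write_config()]
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  do.call(protmr_config, yaml::read_yaml(path))
}

#' @param config a `protmr_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Instruments -> MR -> coloc for one analysis pair. `proteins` is a list of
# list(protein_id, exposure, outcome, region, ld_r2).
analyze_one_analysis <- function(proteins, analysis_id, config) {
  mr_rows <- list()
  primary_rows <- list()
  coloc_rows <- list()
  iset_rows <- list()
  skipped <- character(0)
  for (pr in proteins) {
    iset <- build_instrument_set(pr$exposure, pr$region, pr$ld_r2,
                                 p_threshold = config$p_instrument,
                                 clump_r2 = config$clump_r2,
                                 f_min = config$f_min,
                                 window = config$cis_window)
    if (nrow(iset$instruments) > 0L) {
      iset_rows[[pr$protein_id]] <- data.frame(
        protein_id = pr$protein_id, analysis = analysis_id,
        iset$instruments[c("variant_id", "beta", "se", "pval", "eaf",
                           "r_squared", "f_stat")],
        stringsAsFactors = FALSE)
    }
    res <- run_mr(iset, pr$outcome, config)
    if (nrow(res) == 0L) {
      skipped <- c(skipped, pr$protein_id)
    } else {
      res$analysis <- analysis_id
      mr_rows[[pr$protein_id]] <- res
      prim <- res[res$method == if (res$n_snps[1L] >= 2L) "ivw"
                  else "wald_ratio", , drop = FALSE][1L, , drop = FALSE]
      primary_rows[[pr$protein_id]] <- prim
    }
    h_region <- tryCatch(harmonize(pr$exposure, pr$outcome),
                         error = function(e) NULL)
    if (!is.null(h_region) && nrow(h_region) > 0L) {
      cres <- coloc_region(h_region,
                           p1 = config$coloc_p1, p2 = config$coloc_p2,
                           p12 = config$coloc_p12,
                           prior_sd1 = config$coloc_sd_quant,
                           prior_sd2 = config$coloc_sd_cc,
                           protein_id = pr$protein_id,
                           cohort_pair = analysis_id)
      coloc_rows[[pr$protein_id]] <- data.frame(
        protein_id = pr$protein_id, analysis = analysis_id,
        n_snps = cres$n_snps, t(cres$pp),
        decision_sum = cres$decision_sum,
        passes = cres$passes, stringsAsFactors = FALSE)
    }
  }
  list(
    mr = if (length(mr_rows)) do.call(rbind, c(mr_rows,
                                               make.row.names = FALSE))
         else cbind(empty_mr_result(), analysis = character(0)),
    primary = if (length(primary_rows))
      do.call(rbind, c(primary_rows, make.row.names = FALSE)) else NULL,
    coloc = if (length(coloc_rows))
      do.call(rbind, c(coloc_rows, make.row.names = FALSE)) else
        data.frame(protein_id = character(0), analysis = character(0),
                   decision_sum = numeric(0)),
    instruments = if (length(iset_rows))
      do.call(rbind, c(iset_rows, make.row.names = FALSE)) else NULL,
    skipped = skipped
  )
}

PANEL_ANALYSES <- list(
  decode_finngen = c(exposure = "decode", outcome = "finngen"),
  decode_ukb = c(exposure = "decode", outcome = "ukb"),
  ukbppp_finngen = c(exposure = "ukbppp", outcome = "finngen")
)

#' Analyze a simulated three-analysis panel end to end
#'
#' Runs instrument selection, MR with Steiger filtering, regional
#' colocalization, per-analysis FDR, triangulation, reverse MR for the
#' candidates, and the evidence gate over a [simulate_panel()] object. The
#' three analyses pair the first exposure platform with both outcome
#' biobanks and the second platform with the first biobank, so no cohort
#' contributes to both sides of any analysis.
#'
#' Reverse MR uses the concatenated regional disease statistics of the
#' analysis's outcome cohort as a genome-wide proxy and the candidate's
#' exposure-platform statistics as the reverse outcome; because pQTL tables
#' only cover the protein's own cis region, reverse instruments there are
#' typically removed by Steiger filtering (the disease association is
#' driven by the protein) and the reverse test is recorded as not testable.
#'
#' @param panel a `protmr_panel`.
#' @param config a [protmr_config()].
#' @return list of class `protmr_report`: `mr` (all estimator rows),
#'   `primary` (one row per protein per analysis), `coloc`, `verdicts`,
#'   `reverse`, `gated` (final tiered table), `instruments`, `skipped`.
#' @export
analyze_panel <- function(panel, config = protmr_config()) {
  stopifnot(inherits(panel, "protmr_panel"))
  per_analysis <- lapply(names(PANEL_ANALYSES), function(aid) {
    roles <- PANEL_ANALYSES[[aid]]
    proteins <- lapply(panel$proteins, function(pr) {
      list(protein_id = pr$protein_id,
           exposure = pr$tables[[roles[["exposure"]]]],
           outcome = pr$tables[[roles[["outcome"]]]],
           region = pr$region, ld_r2 = pr$ld_r2)
    })
    analyze_one_analysis(proteins, aid, config)
  })
  names(per_analysis) <- names(PANEL_ANALYSES)

  primary <- do.call(rbind, c(lapply(per_analysis, `[[`, "primary"),
                              make.row.names = FALSE))
  if (is.null(primary) || nrow(primary) == 0L) {
    stop("no primary MR results across the panel")
  }
  verdicts <- triangulate_proteins(primary, alpha = config$alpha,
                                   fdr_alpha = config$fdr_alpha,
                                   n_analyses = length(PANEL_ANALYSES))
  coloc_df <- do.call(rbind, c(lapply(per_analysis, `[[`, "coloc"),
                               make.row.names = FALSE))

  # genome-wide disease proxies for reverse MR, one per outcome cohort
  disease_tables <- lapply(c(finngen = "finngen", ukb = "ukb"),
                           function(cohort) {
    df <- do.call(rbind, lapply(panel$proteins, function(pr)
      as.data.frame(pr$tables[[cohort]])))
    sumstats(df, trait_id = "disease", trait_type = "case_control",
             cohort_id = cohort)
  })

  candidates <- verdicts$protein_id[verdicts$candidate]
  reverse <- reverse_for_candidates(candidates, panel, disease_tables,
                                    config)
  gated <- gate_candidates(verdicts, coloc_df, reverse,
                           coloc_threshold = config$coloc_threshold,
                           alpha = config$alpha,
                           n_analyses = length(PANEL_ANALYSES))
  structure(list(
    mr = do.call(rbind, c(lapply(per_analysis, `[[`, "mr"),
                          make.row.names = FALSE)),
    primary = primary, verdicts = verdicts, coloc = coloc_df,
    reverse = reverse, gated = gated,
    instruments = do.call(rbind, c(lapply(per_analysis, `[[`,
                                          "instruments"),
                                   make.row.names = FALSE)),
    skipped = lapply(per_analysis, `[[`, "skipped"),
    config = config
  ), class = "protmr_report")
}

reverse_for_candidates <- function(candidates, panel, disease_tables,
                                   config) {
  rows <- list()
  for (pid in candidates) {
    pr <- panel$proteins[[match(pid, vapply(panel$proteins, `[[`,
                                            character(1), "protein_id"))]]
    for (aid in names(PANEL_ANALYSES)) {
      roles <- PANEL_ANALYSES[[aid]]
      res <- reverse_mr(disease_tables[[roles[["outcome"]]]],
                        pr$tables[[roles[["exposure"]]]],
                        ld_r2 = NULL, config = config)
      status <- attr(res, "status")
      if (nrow(res) == 0L) {
        rows[[paste(pid, aid)]] <- data.frame(
          protein_id = pid, analysis = aid, method = NA_character_,
          n_snps = 0L, beta = NA_real_, pval = NA_real_, status = status,
          threshold_used = attr(res, "threshold_used"),
          stringsAsFactors = FALSE)
      } else {
        prim <- res[res$method == if (res$n_snps[1L] >= 2L) "ivw"
                    else "wald_ratio", , drop = FALSE][1L, , drop = FALSE]
        rows[[paste(pid, aid)]] <- data.frame(
          protein_id = pid, analysis = aid, method = prim$method,
          n_snps = prim$n_snps, beta = prim$beta, pval = prim$pval,
          status = "ok", threshold_used = attr(res, "threshold_used"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), analysis = character(0),
                      method = character(0), n_snps = integer(0),
                      beta = numeric(0), pval = numeric(0),
                      status = character(0), threshold_used = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full pipeline and write a report directory
#'
#' Either analyzes a supplied panel or simulates one from
#' `config_extra$simulate` (arguments to [simulate_panel()]), then writes
#' per-stage TSV outputs and a machine-readable `manifest.json` capturing
#' every threshold and seed, so that two runs with equal manifests produce
#' equal results.
#'
#' @param config a [protmr_config()].
#' @param out_dir report directory (created if needed).
#' @param panel optional `protmr_panel`; when `NULL`, `simulate_args` must
#'   be given.
#' @param simulate_args optional named list of arguments to
#'   [simulate_panel()].
#' @return the `protmr_report`, invisibly, with the directory path in the
#'   `out_dir` attribute.
#' @export
run_pipeline <- function(config = protmr_config(), out_dir,
                         panel = NULL, simulate_args = NULL) {
  if (is.null(panel)) {
    if (is.null(simulate_args)) {
      stop("supply either a panel or simulate_args")
    }
    if (is.null(simulate_args$seed)) simulate_args$seed <- config$seed
    panel <- do.call(simulate_panel, simulate_args)
  }
  report <- analyze_panel(panel, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$mr, file.path(out_dir, "mr_results.tsv"))
  write_tsv(report$primary, file.path(out_dir, "mr_primary.tsv"))
  write_tsv(report$coloc, file.path(out_dir, "coloc.tsv"))
  write_tsv(report$gated, file.path(out_dir, "triangulation.tsv"))
  write_tsv(report$gated[report$gated$candidate, , drop = FALSE],
            file.path(out_dir, "candidates.tsv"))
  if (!is.null(report$instruments)) {
    write_tsv(report$instruments, file.path(out_dir, "instruments.tsv"))
  }
  write_tsv(report$reverse, file.path(out_dir, "reverse_mr.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("protmr")),
    config = unclass(config),
    panel = if (!is.null(panel$params)) c(panel$params,
                                          seed = panel$seed) else NULL,
    outputs = c("mr_results.tsv", "mr_primary.tsv", "coloc.tsv",
                "triangulation.tsv", "candidates.tsv", "instruments.tsv",
                "reverse_mr.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(report, "out_dir") <- out_dir
  invisible(report)
}
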