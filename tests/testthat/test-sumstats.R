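test_that("sumstats validates, sorts and records metadata", {
  rec <- make_records(4, chromosome = c("2", "1", "1", "2"),
                      position = c(500, 900, 100, 100))
  ss <- sumstats(rec, trait_id = "P1", trait_type = "case_control",
                 cohort_id = "bio1")
  expect_s3_class(ss, "protmr_sumstats")
  expect_identical(attr(ss, "trait_id"), "P1")
  expect_identical(attr(ss, "trait_type"), "case_control")
  expect_identical(attr(ss, "cohort_id"), "bio1")
  expect_identical(ss$chromosome, c("1", "1", "2", "2"))
  expect_identical(ss$position, c(100, 900, 100, 500))
  expect_true(all(attr(ss, "drop_log") == 0))
})

test_that("invalid rows are dropped and counted per reason", {
  rec <- make_records(8)
  rec$effect_allele[2] <- "X"          # bad allele
  rec$other_allele[3] <- "A"           # identical alleles
  rec$se[4] <- 0                       # non-positive se
  rec$pval[5] <- 0                     # p outside (0, 1]
  rec$eaf[6] <- 1.2                    # eaf outside [0, 1]
  rec$variant_id[8] <- rec$variant_id[7]  # duplicate id
  ss <- sumstats(rec, trait_id = "P")
  log <- attr(ss, "drop_log")
  expect_identical(nrow(ss), 2L)
  expect_identical(unname(log[["bad_allele"]]), 2L)
  expect_identical(unname(log[["bad_se"]]), 1L)
  expect_identical(unname(log[["bad_pval"]]), 1L)
  expect_identical(unname(log[["bad_eaf"]]), 1L)
  expect_identical(unname(log[["duplicate_id"]]), 1L)
})

test_that("missing mandatory columns and fully invalid input are errors", {
  rec <- make_records(3)
  expect_error(sumstats(rec[, setdiff(names(rec), "beta")], "P"),
               "missing mandatory")
  rec$se <- 0
  expect_error(sumstats(rec, "P"), "no valid variant records")
})

test_that("missing eaf is allowed and recorded as NA", {
  rec <- make_records(3)
  rec$eaf <- NA
  ss <- sumstats(rec, "P")
  expect_identical(nrow(ss), 3L)
  expect_true(all(is.na(ss$eaf)))
})

test_that("read_sumstats round-trips a written table and maps columns", {
  ss <- make_ss(5, eaf = c(0.1, 0.2, 0.3, 0.4, 0.5))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path, trait_id = "protein", cohort_id = "cohortA")
  expect_equal(as.data.frame(back), as.data.frame(ss))

  # CSV with nonstandard headers through column_map
  df <- make_records(3)
  names(df)[names(df) == "variant_id"] <- "SNP"
  names(df)[names(df) == "pval"] <- "P"
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  mapped <- read_sumstats(csv, column_map = c(variant_id = "SNP", pval = "P"),
                          trait_id = "protein")
  expect_identical(nrow(mapped), 3L)
  expect_identical(mapped$variant_id, sprintf("rs%03d", 1:3))
  expect_error(
    read_sumstats(csv, column_map = c(variant_id = "NOPE")),
    "absent from file")
})

test_that("is_palindromic identifies exactly A/T and C/G pairs", {
  expect_identical(is_palindromic(c("A", "T", "C", "G", "A", "C"),
                                  c("T", "A", "G", "C", "G", "T")),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(is_palindromic("A", "N"), "A, C, G, T")
})

test_that("harmonize resolves match, swap, complement and drops the rest", {
  exp_rec <- make_records(6, effect_allele = c("A", "A", "A", "A", "A", "A"),
                          other_allele = c("G", "G", "G", "G", "T", "G"),
                          beta = 0.2, eaf = 0.3)
  out_rec <- make_records(6, beta = 0.1, se = 0.04, eaf = 0.25,
                          n_samples = 50000)
  out_rec$effect_allele <- c("A", "G", "T", "C", "A", "A")
  out_rec$other_allele <- c("G", "A", "C", "T", "T", "C")
  # 1 exact match, 2 swapped, 3 complement match (T/C ~ A/G),
  # 4 complement swapped (C/T ~ G/A), 5 palindromic, 6 incompatible
  ss_e <- sumstats(exp_rec, "P", cohort_id = "e")
  ss_o <- sumstats(out_rec, "D", "case_control", cohort_id = "o")
  h <- harmonize(ss_e, ss_o)
  expect_s3_class(h, "protmr_harmonized")
  expect_identical(nrow(h), 4L)
  expect_identical(h$action[h$variant_id %in% c("rs001", "rs003")],
                   c("none", "none"))
  expect_identical(h$action[h$variant_id %in% c("rs002", "rs004")],
                   c("flipped_outcome", "flipped_outcome"))
  flipped <- h$variant_id %in% c("rs002", "rs004")
  expect_equal(h$beta_outcome[flipped], c(-0.1, -0.1))
  expect_equal(h$eaf_outcome[flipped], c(0.75, 0.75))
  expect_equal(h$beta_outcome[!flipped], c(0.1, 0.1))
  dropped <- attr(h, "dropped")
  expect_setequal(dropped$variant_id, c("rs005", "rs006"))
  expect_identical(sort(dropped$action),
                   c("dropped_incompatible", "dropped_palindromic"))
  log <- attr(h, "action_log")
  expect_identical(as.integer(log), c(2L, 2L, 1L, 1L))
  expect_equal(attr(h, "n_exposure"), 10000)
  expect_equal(attr(h, "n_outcome"), 50000)
})

test_that("harmonizing a table against itself is the identity", {
  ss <- make_ss(6, beta = rnorm(6), eaf = runif(6))
  h <- harmonize(ss, ss)
  expect_identical(nrow(h), 6L)
  expect_true(all(h$action == "none"))
  expect_equal(h$beta_outcome, h$beta_exposure)
  expect_equal(h$eaf_outcome, h$eaf_exposure)
})

test_that("harmonized effects are invariant to reported allele orientation", {
  ss_e <- make_ss(10, beta = rnorm(10), eaf = runif(10, 0.1, 0.9))
  out <- make_records(10, beta = rnorm(10), eaf = runif(10, 0.1, 0.9),
                      se = 0.03)
  flipped <- out
  flip <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  ea <- flipped$effect_allele
  flipped$effect_allele[flip] <- flipped$other_allele[flip]
  flipped$other_allele[flip] <- ea[flip]
  flipped$beta[flip] <- -flipped$beta[flip]
  flipped$eaf[flip] <- 1 - flipped$eaf[flip]
  h1 <- harmonize(ss_e, sumstats(out, "D", "case_control"))
  h2 <- harmonize(ss_e, sumstats(flipped, "D", "case_control"))
  expect_equal(h1$beta_outcome, h2$beta_outcome)
  expect_equal(h1$eaf_outcome, h2$eaf_outcome)
})

test_that("harmonize can match on position and errors with no overlap", {
  ss_e <- make_ss(4)
  out <- make_records(4, variant_id = sprintf("other%02d", 1:4))
  ss_o <- sumstats(out, "D", "case_control")
  expect_error(harmonize(ss_e, ss_o), "no shared variants")
  h <- harmonize(ss_e, ss_o, match_by = "position")
  expect_identical(nrow(h), 4L)
})
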