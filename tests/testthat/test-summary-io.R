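test_that("reading a summary table preserves rows, maps columns and ignores extras", {
  df <- data.frame(snp = paste0("rs", 1:7), ea = "a", oa = "g",
                   beta = seq(0.01, 0.07, by = 0.01), se = 0.005,
                   junk = "x", more_junk = 1:7)
  path <- write_temp_gwas(df)
  rec <- read_gwas_table(path, c(rsid = "snp", effect_allele = "ea",
                                 other_allele = "oa", beta = "beta",
                                 se = "se"))
  expect_equal(nrow(rec), 7)
  expect_equal(rec$effect_allele, rep("A", 7)) # upper-cased
  expect_false("junk" %in% names(rec))
  expect_true(all(is.na(rec$eaf)))

  # comma-separated dialect auto-detected
  path_csv <- write_temp_gwas(df, sep = ",", ext = ".csv")
  rec_csv <- read_gwas_table(path_csv, c(rsid = "snp", effect_allele = "ea",
                                         other_allele = "oa"))
  expect_equal(rec_csv$beta, rec$beta)
})

test_that("invalid rows are rejected with the offending rsid", {
  df <- data.frame(rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
                   other_allele = c("G", "T"), beta = c(0.1, 0.2),
                   se = c(0.01, 0))
  expect_error(read_gwas_table(write_temp_gwas(df)), "rs2")

  df$se <- c(0.01, 0.02)
  df$other_allele <- c("G", "C") # same as effect allele
  expect_error(read_gwas_table(write_temp_gwas(df)), "rs2")

  expect_error(
    read_gwas_table(write_temp_gwas(df), c(beta = "not_a_column")),
    "not_a_column")
})

test_that("harmonization resolves orientation, strand and palindromes", {
  exposure <- make_gwas_records(
    c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    ea = c("A", "A", "A", "A", "A", "C"),
    oa = c("G", "G", "G", "T", "T", "G"),
    beta = 0.02, se = 0.005,
    eaf = c(NA, NA, NA, 0.50, 0.20, 0.30))
  outcome <- make_gwas_records(
    c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    ea = c("A", "G", "T", "A", "T", "A"),
    oa = c("G", "A", "C", "T", "A", "C"),
    beta = 0.01, se = 0.004,
    eaf = c(NA, NA, NA, 0.50, 0.79, 0.30))

  h <- harmonize(exposure, outcome)
  expect_equal(h$status,
               c("aligned", "flipped", "aligned", "palindromic_ambiguous",
                 "flipped", "allele_mismatch"))
  # rs2: swapped alleles -> beta negated; rs3: strand complement, aligned
  expect_equal(h$beta_y[1:3], c(0.01, -0.01, 0.01))
  # rs5: palindromic but eaf-informative, frequencies discordant -> flipped
  expect_equal(h$beta_y[5], -0.01)
  expect_equal(nrow(usable_instruments(h)), 4)
})

test_that("palindromic SNPs near 0.5 frequency are excluded at the window boundary", {
  exposure <- make_gwas_records("rs1", "A", "T", 0.02, 0.005, eaf = 0.42)
  outcome_close <- make_gwas_records("rs1", "A", "T", 0.01, 0.004, eaf = 0.43)
  # |0.43 - 0.5| = 0.07 < 0.08: uninformative under the default window
  expect_equal(harmonize(exposure, outcome_close)$status,
               "palindromic_ambiguous")
  # wider margin on both sides: resolvable, same side of 0.5 -> aligned
  outcome_far <- make_gwas_records("rs1", "A", "T", 0.01, 0.004, eaf = 0.40)
  expect_equal(harmonize(exposure, outcome_far)$status, "aligned")
  # shrinking the window makes the close pair resolvable too
  expect_equal(harmonize(exposure, outcome_close,
                         palindromic_eaf_window = 0.05)$status, "aligned")
})

test_that("missing outcome rsids are reported and analysis proceeds on the intersection", {
  exposure <- make_gwas_records(c("rs1", "rs2", "rs3"), "A", "G",
                                c(0.02, 0.03, 0.04), 0.005)
  outcome <- make_gwas_records(c("rs1", "rs3"), "A", "G", 0.01, 0.004)
  expect_message(h <- harmonize(exposure, outcome), "rs2")
  expect_equal(nrow(h), 2)
  expect_equal(attr(h, "missing_rsids"), "rs2")
  rep_df <- harmonization_report(h)
  expect_equal(rep_df$status[rep_df$rsid == "rs2"], "missing_in_outcome")
})

test_that("harmonization is idempotent on already-aligned pairs", {
  set.seed(11)
  for (i in 1:5) {
    exposure <- make_gwas_records(paste0("rs", 1:6),
                                  ea = sample(c("A", "C"), 6, TRUE),
                                  oa = "G",
                                  beta = rnorm(6, 0.05, 0.01), se = 0.005,
                                  eaf = runif(6, 0.1, 0.4))
    outcome <- make_gwas_records(exposure$rsid, exposure$effect_allele,
                                 exposure$other_allele, rnorm(6, 0, 0.01),
                                 0.004, eaf = exposure$eaf)
    h1 <- harmonize(exposure, outcome)
    # feed the harmonized outcome back: nothing should change
    outcome2 <- make_gwas_records(h1$rsid, h1$effect_allele, h1$other_allele,
                                  h1$beta_y, h1$se_y, eaf = h1$eaf_y)
    h2 <- harmonize(exposure, outcome2)
    expect_equal(h2$beta_y, h1$beta_y)
    expect_equal(h2$status, rep("aligned", 6))
  }
})

test_that("flipping outcome alleles and negating beta leaves every estimator unchanged", {
  set.seed(42)
  exposure <- make_gwas_records(paste0("rs", 1:6), "A", "G",
                                runif(6, 0.03, 0.09), 0.006,
                                eaf = runif(6, 0.1, 0.45))
  outcome <- make_gwas_records(exposure$rsid, "A", "G",
                               rnorm(6, -0.01, 0.01), 0.012,
                               eaf = exposure$eaf)
  flipped <- outcome
  flipped$effect_allele <- "G"
  flipped$other_allele <- "A"
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf

  cfg <- mr_config(bootstrap_reps = 200)
  h1 <- harmonize(exposure, outcome)
  h2 <- harmonize(exposure, flipped)
  expect_equal(h2$status, rep("flipped", 6))
  expect_equal(ivw_pool(wald_ratios(h1), cfg)$beta,
               ivw_pool(wald_ratios(h2), cfg)$beta)
  expect_equal(egger_regression(h1, cfg)$beta, egger_regression(h2, cfg)$beta)
  expect_equal(weighted_median_mr(h1, cfg)$beta,
               weighted_median_mr(h2, cfg)$beta)
})

test_that("built-in instrument sets match the published subset structure", {
  sets <- builtin_instrument_sets()
  expect_named(sets, c("7snp", "5snp", "4snp", "2snp", "10snp"))
  expect_length(sets[["7snp"]], 7)
  expect_true("rs900400" %in% sets[["7snp"]])
  expect_setequal(sets[["5snp"]],
                  setdiff(sets[["7snp"]], c("rs724577", "rs1042725")))
  expect_setequal(sets[["4snp"]], setdiff(sets[["5snp"]], "rs1801253"))
  expect_setequal(sets[["2snp"]], c("rs900400", "rs4432842"))
  expect_length(sets[["10snp"]], 10)
  expect_true(all(c("rs5415", "rs5758511", "rs7780752") %in%
                    sets[["10snp"]]))
})

test_that("select_set returns members in set order and errors on absent rsids", {
  fx <- paperlike_fixture()
  s5 <- select_set(fx$instruments, "5snp")
  expect_equal(nrow(s5), 5)
  expect_false(any(c("rs724577", "rs1042725") %in% s5$rsid))
  s2 <- select_set(fx$instruments, "2snp")
  expect_setequal(s2$rsid, c("rs900400", "rs4432842"))
  custom <- c("rs4432842", "rs900400")
  expect_equal(select_set(fx$instruments, custom)$rsid, custom)
  expect_error(select_set(fx$instruments, c("rs900400", "rs99999")),
               "rs99999")
})

test_that("curated pleiotropy annotations attach to the known instruments", {
  ann <- default_pleiotropy_annotations()
  expect_setequal(ann$rsid[ann$trait_tag == "height"],
                  c("rs724577", "rs1042725"))
  fx <- paperlike_fixture()
  expect_equal(fx$instruments$annotations[fx$instruments$rsid == "rs1801253"],
               "blood_pressure")
  expect_equal(fx$instruments$annotations[fx$instruments$rsid == "rs900400"],
               "")
})

test_that("correlated instrument pairs above the r2 threshold are flagged", {
  ld <- data.frame(rsid1 = c("rs1", "rs1"), rsid2 = c("rs2", "rs3"),
                   r2 = c(0.01, 0.2))
  expect_warning(bad <- check_ld_independence(ld), "rs1-rs3")
  expect_equal(nrow(bad), 1)
  expect_silent(check_ld_independence(ld[1, ]))
})
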