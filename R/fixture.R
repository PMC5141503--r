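# Deterministic synthetic fixture shaped like the birth-weight MR inputs:
# the 7 genome-wide-significant birth-weight instruments plus the 3
# relaxed-threshold SNPs, with per-allele effect magnitudes and standard
# errors typical of consortium-scale GWAS. All numeric values are synthetic
# (generated, not extracted from any consortium release); rsids, locus
# labels and trait annotations match the published instrument list so the
# named subsets resolve.

fixture_snp_table <- function() {
  data.frame(
    rsid = c("rs724577", "rs900400", "rs1042725", "rs1801253", "rs4432842",
             "rs6931514", "rs9883204", "rs5415", "rs5758511", "rs7780752"),
    locus = c("LCORL", "CCNL1", "HMGA2", "ADRB1", "5q11.2", "CDKAL1",
              "ADCY5", "SLC2A4", "CENPM", "CALCR"),
    effect_allele = c("A", "T", "C", "G", "T", "A", "C", "T", "A", "A"),
    other_allele = c("C", "C", "T", "A", "C", "G", "T", "C", "G", "G"),
    eaf = c(0.27, 0.39, 0.49, 0.73, 0.37, 0.72, 0.76, 0.85, 0.42, 0.67),
    # true per-allele birth-weight z-score effects; rs900400 is by far the
    # strongest instrument, as in the published GWAS
    gamma = c(0.046, 0.086, 0.041, 0.038, 0.036, 0.044, 0.063,
              0.030, 0.028, 0.027),
    se_x = c(0.0061, 0.0059, 0.0058, 0.0066, 0.0059, 0.0062, 0.0068,
             0.0060, 0.0057, 0.0061),
    stringsAsFactors = FALSE
  )
}

# per-SD true effects for each synthetic outcome; binary outcomes on the
# log-odds scale, lipids in SD units
fixture_outcome_specs <- function() {
  list(
    ihd_1000g = list(name = "IHD", source = "1000G-like case-control",
                     outcome_type = "log_odds", theta = -0.20,
                     se_scale = 0.012, seed_offset = 11L),
    mi_1000g = list(name = "MI", source = "1000G-like case-control",
                    outcome_type = "log_odds", theta = -0.20,
                    se_scale = 0.014, seed_offset = 12L),
    ihd_metabochip = list(name = "IHD", source = "metabochip-like",
                          outcome_type = "log_odds", theta = -0.20,
                          se_scale = 0.019, seed_offset = 13L),
    mi_metabochip = list(name = "MI", source = "metabochip-like",
                         outcome_type = "log_odds", theta = -0.20,
                         se_scale = 0.022, seed_offset = 14L),
    hdl = list(name = "HDL cholesterol", source = "lipids consortium-like",
               outcome_type = "sd_units", theta = -0.068,
               se_scale = 0.0048, seed_offset = 15L),
    ldl = list(name = "LDL cholesterol", source = "lipids consortium-like",
               outcome_type = "sd_units", theta = -0.046,
               se_scale = 0.0049, seed_offset = 16L),
    trig = list(name = "Triglycerides", source = "lipids consortium-like",
                outcome_type = "sd_units", theta = -0.004,
                se_scale = 0.0047, seed_offset = 17L)
  )
}

FIXTURE_BASE_SEED <- 38420L

#' Synthetic exposure and outcome summary tables in the study's shape
#'
#' Builds, deterministically, a synthetic birth-weight exposure table (10
#' SNPs: the 7 genome-wide-significant instruments plus the 3
#' relaxed-threshold SNPs) and seven synthetic outcome tables (IHD and MI
#' from two case-control-style sources; HDL, LDL and triglycerides in SD
#' units), every one in the dialect [read_gwas_table()] reads. One outcome
#' record (rs9883204 in the first IHD source) is reported with swapped
#' alleles to exercise harmonization. All values are synthetic; only the
#' rsids and the subset structure mirror the real instrument list.
#'
#' @return List with elements `exposure` (GWAS record data frame),
#'   `outcomes` (named list of GWAS record data frames) and `specs`
#'   (per-outcome name, source label, outcome type and true effect).
#' @export
paperlike_tables <- function() {
  snp <- fixture_snp_table()
  set.seed(FIXTURE_BASE_SEED)
  beta_x <- stats::rnorm(nrow(snp), snp$gamma, snp$se_x)
  exposure <- data.frame(
    rsid = snp$rsid,
    effect_allele = snp$effect_allele,
    other_allele = snp$other_allele,
    eaf = snp$eaf,
    beta = beta_x,
    se = snp$se_x,
    pvalue = 2 * stats::pnorm(-abs(beta_x / snp$se_x)),
    n = 69308,
    stringsAsFactors = FALSE
  )

  specs <- fixture_outcome_specs()
  outcomes <- lapply(specs, function(sp) {
    set.seed(FIXTURE_BASE_SEED + sp$seed_offset)
    se_y <- sp$se_scale * stats::runif(nrow(snp), 0.9, 1.25)
    beta_y <- stats::rnorm(nrow(snp), sp$theta * snp$gamma, se_y)
    data.frame(
      rsid = snp$rsid,
      effect_allele = snp$effect_allele,
      other_allele = snp$other_allele,
      eaf = snp$eaf,
      beta = beta_y,
      se = se_y,
      pvalue = 2 * stats::pnorm(-abs(beta_y / se_y)),
      n = if (sp$outcome_type == "log_odds") 184305 else 188577,
      stringsAsFactors = FALSE
    )
  })

  # report one SNP with swapped alleles (flip exercised downstream)
  i <- match("rs9883204", outcomes$ihd_1000g$rsid)
  outcomes$ihd_1000g$effect_allele[i] <- snp$other_allele[match("rs9883204", snp$rsid)]
  outcomes$ihd_1000g$other_allele[i] <- snp$effect_allele[match("rs9883204", snp$rsid)]
  outcomes$ihd_1000g$beta[i] <- -outcomes$ihd_1000g$beta[i]
  outcomes$ihd_1000g$eaf[i] <- 1 - outcomes$ihd_1000g$eaf[i]

  list(exposure = exposure, outcomes = outcomes, specs = specs)
}

#' Packaged deterministic 7-SNP dataset
#'
#' The harmonized 7-instrument dataset for the first IHD source of
#' [paperlike_tables()], with trait annotations attached, plus the
#' generative truth (true causal effect, per-SNP gamma and alpha) for
#' scoring. Byte-identical across calls.
#'
#' @return List of class `sim_dataset` (see [sim_generate()]).
#' @export
#' @examples
#' fx <- paperlike_fixture()
#' fx$instruments$rsid
paperlike_fixture <- function() {
  tabs <- paperlike_tables()
  inst <- suppressMessages(harmonize(tabs$exposure, tabs$outcomes$ihd_1000g))
  inst <- annotate_instruments(inst)
  inst <- select_set(inst, "7snp")
  snp <- fixture_snp_table()
  keep <- match(inst$rsid, snp$rsid)
  structure(
    list(instruments = inst,
         truth = list(theta = fixture_outcome_specs()$ihd_1000g$theta,
                      gamma = snp$gamma[keep],
                      alpha = rep(0, nrow(inst))),
         scenario = NULL),
    class = "sim_dataset"
  )
}
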