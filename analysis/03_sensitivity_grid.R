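#!/usr/bin/env Rscript
# The full sensitivity matrix on the synthetic dataset: binary outcomes x
# two sources x five instrument subsets x {IVW, weighted median}, and the
# lipids x three subsets, plus the harmonization report and the MR-Egger
# intercept screen. Mirrors the layout of the published sensitivity tables.

suppressPackageStartupMessages(library(bwmr))

dir.create("results", showWarnings = FALSE)
tabs <- paperlike_tables()
cfg <- mr_config(bootstrap_reps = 10000)

binary <- list(
  ihd_1000g = list(name = "IHD", source = "1000G-like",
                   data = tabs$outcomes$ihd_1000g),
  mi_1000g = list(name = "MI", source = "1000G-like",
                  data = tabs$outcomes$mi_1000g),
  ihd_metabo = list(name = "IHD", source = "metabochip-like",
                    data = tabs$outcomes$ihd_metabochip),
  mi_metabo = list(name = "MI", source = "metabochip-like",
                   data = tabs$outcomes$mi_metabochip))
t1 <- reproduce_table1(tabs$exposure, binary, config = cfg,
                       out = "results/table1_synthetic.tsv")
cat("Disease table (per-100 g odds ratios), synthetic data:\n")
print(t1$wide, right = FALSE)

lipids <- list(
  hdl = list(name = "HDL cholesterol", source = "lipids-like",
             data = tabs$outcomes$hdl),
  ldl = list(name = "LDL cholesterol", source = "lipids-like",
             data = tabs$outcomes$ldl),
  trig = list(name = "Triglycerides", source = "lipids-like",
              data = tabs$outcomes$trig))
t2 <- reproduce_table2(tabs$exposure, lipids, config = cfg,
                       out = "results/table2_synthetic.tsv")
cat("\nLipid table (per-100 g mean differences), synthetic data:\n")
print(t2$wide, right = FALSE)

# harmonization report for the primary outcome
h <- suppressMessages(harmonize(tabs$exposure, tabs$outcomes$ihd_1000g))
harmonization_report(h, "results/harmonization_report.tsv")

# Egger intercept screen per (outcome, set with J >= 3)
rows <- list()
for (nm in names(binary)) {
  harm <- suppressMessages(harmonize(tabs$exposure, binary[[nm]]$data))
  for (set_name in c("7snp", "5snp", "4snp", "10snp")) {
    sc <- egger_screen(select_set(harm, set_name), cfg)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(outcome = binary[[nm]]$name,
                 source = binary[[nm]]$source, set = set_name), sc)
  }
}
screen <- do.call(rbind, rows)
write_results_tsv(screen, "results/egger_screen.tsv")
cat("\nEgger intercept screen (flagged cells have intercept p <",
    cfg$alpha, "):\n")
print(screen[screen$flagged, ], digits = 3)
cat("\nNote: any flagged cell here is a false positive by construction -\n")
cat("the synthetic generator includes no pleiotropy for these outcomes.\n")
cat("\nWrote results/table1_synthetic.tsv, table2_synthetic.tsv,\n")
cat("harmonization_report.tsv and egger_screen.tsv.\n")
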