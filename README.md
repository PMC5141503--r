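# bwmr

Two-sample Mendelian randomization (MR) of birth weight on ischemic heart
disease (IHD), myocardial infarction (MI) and blood lipids, from GWAS
summary statistics alone. The package is for epidemiologists who want to
re-run or stress-test this analysis — or the same design with their own
exposure — without genotype-level data: you supply per-SNP summary tables,
the package handles allele harmonization, estimation, sensitivity grids
and unit conversion.

## The method

For instrument SNP *j* with exposure association (β̂_Xj, σ_Xj) and outcome
association (β̂_Yj, σ_Yj) from non-overlapping samples:

- **Wald ratio** θ̂_j = β̂_Yj / β̂_Xj, with a confidence set from
  **Fieller's theorem** — the g solving
  (β̂_Yj − g β̂_Xj)² ≤ z²(σ_Yj² + g²σ_Xj²) — which is bounded only for
  individually significant instruments; a per-SNP variance
  ((upper − lower)/2z)² is derived from bounded intervals.
- **IVW (fixed effects)**: θ̂ = Σ w_j θ̂_j / Σ w_j, w_j = 1/var_j,
  SE = (Σ w_j)^(−1/2).
- **MR-Egger**: weighted regression of β̂_Yj on β̂_Xj with free intercept;
  the intercept (t test, J − 2 df) screens for directional pleiotropy.
- **Weighted median**: median of the θ̂_j under information weights
  β̂_Xj²/σ_Yj²; consistent while valid instruments hold > 50% of the
  information, and reported **N/A** when a single SNP exceeds that share
  (as happens in the 2-SNP subset). SE by parametric bootstrap (10,000
  replicates, fixed seed).

Birth-weight effects are in z-score units; results convert to 100-gram
units via SD(birth weight) = 484 g, so a log-odds estimate β per SD
becomes OR exp(β·100/484) per 100 g.

Five instrument subsets drive the sensitivity analysis: the 7 genome-wide
significant birth-weight SNPs; 5 after dropping the height loci
(rs724577/LCORL, rs1042725/HMGA2); 4 after also dropping blood pressure
(rs1801253/ADRB1); 2 after also dropping diabetes (rs6931514/CDKAL1,
rs9883204/ADCY5); and 10 adding three SNPs at p < 10⁻⁵ (rs5415,
rs5758511, rs7780752).

## Worked example

The package ships a deterministic synthetic 7-SNP dataset with the real
instrument rsids and a known true effect of OR 0.96 per 100 g
(θ = −0.2 per SD):

```r
library(bwmr)
fx <- paperlike_fixture()
wr <- wald_ratios(fx$instruments)          # per-SNP Wald + Fieller
ivw <- ivw_pool(wr, instruments = fx$instruments)
or_with_ci(convert_scale(ivw))
#>        or    or_low   or_high
#> 0.9708615 0.9341295 1.0090377
weighted_median_mr(select_set(fx$instruments, "2snp"), mr_config())
#> Weighted median [J = 2, scale = per_sd, outcome = log_odds]
#>   not available: one SNP contributes more than the allowed share of
#>   the information
```

The IVW odds ratio 0.97 (0.93 to 1.01) per 100 g is this dataset's
estimate of its simulated truth 0.96; the 2-SNP weighted median is N/A
because rs900400, the strongest birth-weight locus, carries over half the
pair's information.

The full analysis is organised as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R                  # synthetic summary tables
Rscript analysis/02_estimates.R                 # per-SNP + pooled, forest/funnel
Rscript analysis/03_sensitivity_grid.R          # outcome x source x subset x method
Rscript analysis/04_operating_characteristics.R # simulation study
```

Each writes TSVs (and basic plots) under `results/`.

## Using real consortium data

`read_gwas_table()` reads TSV/CSV summary statistics with an explicit
column mapping; `harmonize()` aligns outcome to exposure alleles (strand
flips resolved, palindromic SNPs with uninformative frequencies excluded);
`reproduce_table1()` / `reproduce_table2()` render the disease and lipid
sensitivity tables. Consortium per-SNP extracts (CARDIoGRAMplusC4D, GLGC)
are not redistributed here; place them as
`inst/extdata/birthweight_exposure.tsv`, `cad_1000g.tsv`, `mi_1000g.tsv`,
`cad_metabochip.tsv`, `glgc_hdl.tsv`, `glgc_ldl.tsv`, `glgc_trig.tsv`
before installing and the published-table checks in the test suite will
run against them.

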