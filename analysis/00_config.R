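# Shared settings for the analysis workflow. Each numbered script can be
# run in order from the repository root:
#   Rscript analysis/01_simulate_population.R
#   Rscript analysis/02_qc_and_estimators.R
#   Rscript analysis/03_inbreeding_depression.R
#   Rscript analysis/04_estimator_comparison.R
# All outputs land under results/.

library(ibdep)

SEED <- 20160606L
DATA_DIR <- "results/data"
OUT_DIR <- "results"

# Study population: ~1000 individuals over 10 cohorts with male reproductive
# skew and occasional close inbreeding; 16 autosomes (300 cM) carrying a
# 4500-SNP chip-density panel.
study_cfg <- function() {
  sim_config(n_cohorts = 10, n_founder_females = 35, n_founder_males = 18,
             offspring_per_cohort = 100, close_mating_rate = 0.15,
             n_chr = 16, total_cM = 300, n_snps = 4500)
}

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
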