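# How do the four inbreeding estimators compare, and how much pedigree-
# cryptic inbreeding is there? Correlation matrices by ancestry tier,
# cryptic-inbreeding fractions, and marker-subsampling stability curves.

source("analysis/00_config.R")

tab <- read.table(file.path(OUT_DIR, "inbreeding_table.tsv"), header = TRUE,
                  stringsAsFactors = FALSE)
tab$tier <- factor(tab$tier, levels = c("NO_PARENTS", "ONE_PARENT",
                                        "BOTH_PARENTS",
                                        "BOTH_PARENTS_PLUS_MATERNAL_GP",
                                        "FOUR_GRANDPARENTS"))
gm <- read_ped_map(file.path(DATA_DIR, "genotypes.ped"),
                   file.path(DATA_DIR, "genotypes.map"))
qc <- qc_filter(gm)

for (tier in c("BOTH_PARENTS_PLUS_MATERNAL_GP", "FOUR_GRANDPARENTS")) {
  C <- estimator_correlations(tab, tier = tier)
  cat("\nPearson correlations,", tier, "tier (n =",
      sum(in_tier(tab$tier, tier)), "):\n")
  print(round(C[1:4, 1:4], 2))
  write_kinship(round(C, 4),
                file.path(OUT_DIR, paste0("correlations_", tolower(tier), ".tsv")))
}

cat("\ncryptic inbreeding (F_ped = 0 but genomic F > 0.1):\n")
for (tier in c("BOTH_PARENTS", "BOTH_PARENTS_PLUS_MATERNAL_GP",
               "FOUR_GRANDPARENTS")) {
  fr_grm <- cryptic_inbreeding_fraction(tab, "F_GRM", tier = tier)
  fr_roh <- cryptic_inbreeding_fraction(tab, "F_ROH", tier = tier)
  cat(sprintf("  %-32s F_GRM %.1f%%  F_ROH %.1f%%\n", tier,
              100 * fr_grm, 100 * fr_roh))
}

curve <- marker_subsampling_curve(qc$gm,
                                  fractions = c(0.1, 0.2, 0.3, 0.5, 0.75, 1),
                                  n_reps = 10, seed = SEED + 20L)
cat("\nestimator stability under marker subsampling (r with full panel):\n")
print(curve, row.names = FALSE)
write.table(curve, file.path(OUT_DIR, "marker_subsampling.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
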