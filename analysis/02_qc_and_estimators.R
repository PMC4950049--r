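# Genotype QC, LD pruning, ROH detection, the four inbreeding estimators,
# and identity disequilibrium on the simulated study population.

source("analysis/00_config.R")

ped <- read_pedigree(file.path(DATA_DIR, "pedigree.tsv"))
gm <- read_ped_map(file.path(DATA_DIR, "genotypes.ped"),
                   file.path(DATA_DIR, "genotypes.map"))
truth <- read.table(file.path(DATA_DIR, "true_ibd.tsv"), header = TRUE)
true_ibd <- setNames(truth$true_ibd, truth$id)

qc <- qc_filter(gm)
print(qc$report)
write_qc_report(qc$report, file.path(OUT_DIR, "qc_report.tsv"))

kept <- ld_prune_vif(qc$gm)
gmp <- subset_geno(qc$gm, markers = kept)
cat(sprintf("LD pruning: %d -> %d markers (VIF <= 10, MAF >= 0.05), mean spacing %.0f kb\n",
            ncol(qc$gm$geno), length(kept),
            genome_length_kb(gmp$map) / length(kept)))

segs <- detect_roh(gmp)
cat(sprintf("ROH: %d segments; median length %.1f Mb (range %.1f-%.1f), median %d SNPs\n",
            nrow(segs), median(segs$length_kb) / 1000,
            min(segs$length_kb) / 1000, max(segs$length_kb) / 1000,
            median(segs$n_snps)))
write.table(segs, file.path(OUT_DIR, "roh_segments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- inbreeding_table(ped, qc$gm, gmp, true_ibd = true_ibd)
write.table(tab, file.path(OUT_DIR, "inbreeding_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("inbreeding table: %d individuals; SD(F_ped) %.3f, SD(F_hom) %.3f, SD(F_GRM) %.3f, SD(F_ROH) %.3f\n",
            nrow(tab), sd(tab$F_ped), sd(tab$F_hom, na.rm = TRUE),
            sd(tab$F_GRM, na.rm = TRUE), sd(tab$F_ROH, na.rm = TRUE)))

g2r <- g2_estimate(qc$gm, n_boot = 500, n_perm = 500, seed = SEED + 10L)
print(g2r)
hh <- hh_correlation(qc$gm, n_splits = 50, seed = SEED + 11L)
cat(sprintf("heterozygosity-heterozygosity half-panel correlation: F_hom %.3f +- %.3f, F_GRM %.3f +- %.3f\n",
            hh$mean_r_hom, hh$sd_r_hom, hh$mean_r_grm, hh$sd_r_grm))
writeLines(capture.output(print(g2r)), file.path(OUT_DIR, "g2.txt"))
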