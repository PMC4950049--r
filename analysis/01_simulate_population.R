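# Simulate the study population: pedigree, gene-dropped SNP genotypes with
# known realized autozygosity, body-size traits and annual fitness records.

source("analysis/00_config.R")

cfg <- study_cfg()
ped <- simulate_pedigree(cfg, seed = SEED)
cat(sprintf("pedigree: %d individuals, %d founders, max F_ped %.3f\n",
            nrow(ped), sum(ped$sire_idx == 0 & ped$dam_idx == 0),
            max(f_ped(ped))))

gd <- gene_drop(ped, cfg, seed = SEED + 1L)
cat(sprintf("gene drop: %d SNPs on %d chromosomes; realized IBD mean %.4f, max %.3f\n",
            ncol(gd$gm$geno), length(unique(gd$gm$map$chr)),
            mean(gd$true_ibd), max(gd$true_ibd)))

traits <- simulate_traits(ped, gd$true_ibd, cfg, seed = SEED + 2L)
fitness <- simulate_fitness(ped, gd$true_ibd, cfg, seed = SEED + 3L)
cat(sprintf("traits: %d records; first-year survival %.2f; %d sheep-years\n",
            nrow(traits), mean(fitness$first_year$fys), nrow(fitness$annual)))

write_pedigree(ped, file.path(DATA_DIR, "pedigree.tsv"))
write_ped_map(gd$gm, file.path(DATA_DIR, "genotypes.ped"),
              file.path(DATA_DIR, "genotypes.map"))
write.table(data.frame(id = names(gd$true_ibd), true_ibd = gd$true_ibd),
            file.path(DATA_DIR, "true_ibd.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(traits, file.path(DATA_DIR, "traits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fitness$first_year, file.path(DATA_DIR, "first_year.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fitness$annual, file.path(DATA_DIR, "annual_fitness.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# sexes are simulation metadata not carried by the pedigree file
write.table(data.frame(id = names(attr(ped, "sex")), sex = attr(ped, "sex")),
            file.path(DATA_DIR, "sex.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", DATA_DIR, "\n")
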