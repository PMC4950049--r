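# Individual and maternal inbreeding depression: birthweight age-correction,
# animal models for body size (pedigree relationship matrices, year +
# maternal genetic + maternal environment random effects), sex-specific
# GLMMs for fitness components, and effect-size conversions.

source("analysis/00_config.R")

ped <- read_pedigree(file.path(DATA_DIR, "pedigree.tsv"))
traits <- read.table(file.path(DATA_DIR, "traits.tsv"), header = TRUE,
                     stringsAsFactors = FALSE)
fy <- read.table(file.path(DATA_DIR, "first_year.tsv"), header = TRUE,
                 stringsAsFactors = FALSE)
tab <- read.table(file.path(OUT_DIR, "inbreeding_table.tsv"), header = TRUE,
                  stringsAsFactors = FALSE)

# birthweight is measured at capture, up to two weeks after birth: residuals
# from a cubic of capture weight on capture age (records <= 10 days only)
bw <- correct_birthweight_for_age(traits$cap_age, traits$cap_weight)
traits$birthweight_corrected <- bw$residual
cat(sprintf("age-corrected birthweight: %d of %d records usable\n",
            sum(bw$used), nrow(traits)))

fits <- list()
for (trait in c("birthweight", "august_weight", "hindleg")) {
  mf <- animal_model(traits, trait, ped)
  fits[[trait]] <- mf
  bi <- mf$fixed[mf$fixed$term == ".f_ind", ]
  bm <- mf$fixed[mf$fixed$term == ".f_mat", ]
  cat(sprintf("%-14s individual beta %7.2f (SE %5.2f, P %.3g) | maternal beta %7.2f (SE %5.2f, P %.3g)\n",
              trait, bi$estimate, bi$se, bi$p, bm$estimate, bm$se, bm$p))
  write_model_fit(mf, file.path(OUT_DIR, paste0("fit_", trait, ".tsv")))
}

# the same weight model using the genomic estimator instead of realized IBD
tabF <- tab[, c("id", "F_GRM")]
trG <- merge(traits, tabF, by = "id")
trG <- merge(trG, setNames(tabF, c("dam", "F_GRM_dam")), by = "dam")
mfG <- animal_model(trG, "august_weight", ped, f_ind = "F_GRM",
                    f_mat = "F_GRM_dam")
big <- mfG$fixed[mfG$fixed$term == ".f_ind", ]
cat(sprintf("august weight on F_GRM: individual beta %.2f (SE %.2f)\n",
            big$estimate, big$se))

# sex-specific first-year survival GLMMs
for (sx in c("F", "M")) {
  d <- fy[fy$sex == sx & fy$has_dam, ]
  d$year <- factor(d$year)
  mg <- fit_glmm(fys ~ F_ind + F_dam + (1 | year) + (1 | dam), d,
                 family = "binomial")
  sl <- mg$fixed[mg$fixed$term == "F_ind", ]
  cat(sprintf("first-year survival (%s): individual slope %.2f (CI %.2f, %.2f)\n",
              sx, sl$estimate, sl$ci_lo, sl$ci_hi))
  write_model_fit(mg, file.path(OUT_DIR, paste0("fit_fys_", sx, ".tsv")))
  if (sx == "M") male_slope <- sl$estimate
}

# effect sizes on interpretable scales
wt <- fits[["august_weight"]]$fixed
b_wt <- wt$estimate[wt$term == ".f_ind"]
cat(sprintf("weight: %.1f%% change per 10%% increase in F\n",
            pct_change_per_deltaF(b_wt, mean(traits$august_weight))))
cat(sprintf("male first-year survival: odds reduced %.0f%% per 10%% increase in F\n",
            odds_reduction_per_deltaF(male_slope)))
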