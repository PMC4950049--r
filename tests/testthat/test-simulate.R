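small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cohorts = 4, n_founder_females = 15, n_founder_males = 8,
         offspring_per_cohort = 30, n_chr = 4, total_cM = 120,
         n_snps = 300), list(...))
  do.call(sim_config, args)
}

test_that("identical seed and config reproduce bit-identical outputs", {
  cfg <- small_cfg()
  p1 <- simulate_pedigree(cfg, seed = 5)
  p2 <- simulate_pedigree(cfg, seed = 5)
  expect_identical(p1, p2)
  g1 <- gene_drop(p1, cfg, seed = 6)
  g2 <- gene_drop(p2, cfg, seed = 6)
  expect_identical(g1$gm$geno, g2$gm$geno)
  expect_identical(g1$true_ibd, g2$true_ibd)
  t1 <- simulate_traits(p1, g1$true_ibd, cfg, seed = 7)
  t2 <- simulate_traits(p1, g1$true_ibd, cfg, seed = 7)
  expect_identical(t1, t2)
  f1 <- simulate_fitness(p1, g1$true_ibd, cfg, seed = 8)
  f2 <- simulate_fitness(p1, g1$true_ibd, cfg, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(simulate_pedigree(cfg, seed = 9)$sire, p1$sire))
})

test_that("pedigree simulation honors close-mating rate and cohort depth", {
  # rate 0 with 2 cohorts: close kin are avoided, so every F_ped is 0
  cfg0 <- small_cfg(close_mating_rate = 0)
  cfg0$n_cohorts <- 2
  ped0 <- simulate_pedigree(cfg0, seed = 3)
  expect_true(all(f_ped(ped0) == 0))

  # positive rate over many cohorts produces close inbreeding (F >= 0.125)
  cfg1 <- sim_config(n_cohorts = 8, n_founder_females = 20,
                     n_founder_males = 10, offspring_per_cohort = 50,
                     close_mating_rate = 0.3)
  ped1 <- simulate_pedigree(cfg1, seed = 3)
  expect_gt(sum(f_ped(ped1) >= 0.125), 0)

  # generation depth never exceeds the cohort count
  depth <- numeric(nrow(ped1))
  for (i in seq_len(nrow(ped1))) {
    si <- ped1$sire_idx[i]; di <- ped1$dam_idx[i]
    depth[i] <- 1 + max(if (si > 0) depth[si] else -1,
                        if (di > 0) depth[di] else -1, 0)
  }
  expect_lte(max(depth) - 1, cfg1$n_cohorts)
  # sexes recorded for every individual
  expect_setequal(unique(attr(ped1, "sex")), c("F", "M"))
})

test_that("forced matings give the textbook expected inbreeding", {
  # full-sib mating via a hand-built pedigree
  ped <- pedigree(c("A", "B", "C", "D", "E"), c(NA, NA, "A", "A", "C"),
                  c(NA, NA, "B", "B", "D"))
  expect_equal(unname(f_ped(ped)["E"]), 0.25)

  # selfing (test construction): realized IBD averages 0.5
  cfg <- small_cfg()
  pedS <- pedigree(c("A", "X"), c(NA, "A"), c(NA, "A"))
  ibd <- replicate(150, gene_drop(pedS, cfg, seed = sample.int(1e6, 1),
                                  genotypes = FALSE)$true_ibd["X"])
  se <- stats::sd(ibd) / sqrt(length(ibd))
  expect_lt(abs(mean(ibd) - 0.5), 3 * se + 0.01)
})

test_that("mean realized IBD over replicate gene-drops equals F_ped", {
  set.seed(77)
  ped <- fixture_pedigree()
  cfg <- small_cfg()
  n_rep <- 250
  ibd <- sapply(seq_len(n_rep), function(r) {
    gene_drop(ped, cfg, seed = 1e5 + r, genotypes = FALSE)$true_ibd
  })
  fp <- f_ped(ped)
  inbred <- names(fp)[fp > 0]
  expect_true(length(inbred) >= 3)
  for (id in inbred) {
    m <- mean(ibd[id, ])
    se <- stats::sd(ibd[id, ]) / sqrt(n_rep)
    expect_lt(abs(m - fp[id]), 3 * se + 0.005)
  }
  # founders have exactly zero realized IBD
  expect_true(all(ibd["A", ] == 0))
})

test_that("realized IBD varies around F_ped and tightens on longer maps", {
  # many independent full-sib offspring, one class F_ped = 0.25
  n_fam <- 120
  ids <- c(t(outer(seq_len(n_fam), c("s", "d", "c1", "c2", "x"), paste0)))
  sire <- dam <- rep(NA_character_, length(ids))
  for (f in seq_len(n_fam)) {
    base <- (f - 1) * 5
    sire[base + 3] <- ids[base + 1]; dam[base + 3] <- ids[base + 2]
    sire[base + 4] <- ids[base + 1]; dam[base + 4] <- ids[base + 2]
    sire[base + 5] <- ids[base + 3]; dam[base + 5] <- ids[base + 4]
  }
  ped <- pedigree(ids, sire, dam)
  offs <- ids[grepl("x", ids)]
  cfg_short <- small_cfg(total_cM = 100)
  cfg_long <- small_cfg(total_cM = 800)
  v_short <- var(gene_drop(ped, cfg_short, seed = 9,
                           genotypes = FALSE)$true_ibd[offs])
  v_long <- var(gene_drop(ped, cfg_long, seed = 9,
                          genotypes = FALSE)$true_ibd[offs])
  expect_gt(v_short, 0)
  expect_gt(v_long, 0)
  expect_lt(v_long, v_short)
})

test_that("founder-pool diversity controls LD strength with distance decay", {
  ped <- pedigree(sprintf("f%03d", 1:150), rep(NA, 150), rep(NA, 150))
  adj_r2 <- function(n_templates, seed) {
    cfg <- small_cfg(n_chr = 2, total_cM = 100, n_snps = 600,
                     n_templates = n_templates, missing_rate = 0)
    gm <- gene_drop(ped, cfg, seed = seed)$gm
    g <- gm$geno
    keep <- apply(g, 2, stats::sd) > 0
    g <- g[, keep]; map <- gm$map[keep, ]
    same <- map$chr[-1] == map$chr[-nrow(map)]
    r2 <- sapply(which(same), function(j) stats::cor(g[, j], g[, j + 1])^2)
    # distant pairs on the same chromosome (~50 markers apart)
    far <- sapply(which(map$chr[-(1:50)] == map$chr[seq_len(nrow(map) - 50)]),
                  function(j) stats::cor(g[, j], g[, j + 50])^2)
    c(adj = mean(r2), far = mean(far))
  }
  r_div <- adj_r2(16, seed = 4)
  r_few <- adj_r2(3, seed = 4)   # default template diversity
  expect_gt(r_few["adj"], r_div["adj"])   # fewer templates -> stronger LD
  expect_gt(r_few["adj"], r_few["far"])   # LD decays with distance
  expect_gt(r_few["adj"], 0.2)            # chip-scale mean adjacent r2 ~0.3
})

test_that("trait simulation is exact in the degenerate case and shares maternal effects", {
  traits0 <- data.frame(trait = "august_weight", mean = 13.18, sd = 0,
                        beta_ind = 0, beta_mat = 0, sex_effect = 0.8)
  cfg <- small_cfg(traits = traits0[, ])
  cfg$traits <- traits0
  ped <- pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", "A"),
                  c(NA, NA, "B", "B"), cohort = c(0, 0, 1, 1))
  attr(ped, "sex") <- stats::setNames(c("F", "M", "F", "M"), ped$id)
  ibd0 <- stats::setNames(rep(0, 4), ped$id)
  tr <- simulate_traits(ped, ibd0, cfg, seed = 1)
  expect_equal(tr$august_weight,
               13.18 + ifelse(tr$sex == "M", 0.8, 0))

  # maternal genetic + environment contributions identical for full sibs
  traits1 <- data.frame(trait = "august_weight", mean = 0, sd = 2,
                        beta_ind = 0, beta_mat = 0, sex_effect = 0)
  cfgm <- small_cfg(var_prop = c(va = 0, mat_gen = 0.5, mat_env = 0.49,
                                 year = 0))
  cfgm$traits <- traits1
  trm <- simulate_traits(ped, ibd0, cfgm, seed = 2)
  # residual variance is 0.01 * 4; sib difference is pure residual
  sib_diff <- abs(diff(trm$august_weight))
  expect_lt(sib_diff, 6 * sqrt(2 * 0.01 * 4))
})

test_that("fitness simulation matches its link-scale expectations at null slopes", {
  cfg <- sim_config(n_cohorts = 5, n_founder_females = 40,
                    n_founder_males = 20, offspring_per_cohort = 150,
                    n_chr = 2, total_cM = 60, n_snps = 60)
  cfg$fitness$first_year <- list(alpha = c(F = stats::qlogis(0.7),
                                           M = stats::qlogis(0.7)),
                                 beta_ind = c(F = 0, M = 0),
                                 beta_mat = c(F = 0, M = 0),
                                 sd_year = 0, sd_mother = 0)
  cfg$fitness$abs <- list(alpha = c(F = log(1.5), M = log(1.5)),
                          beta_ind = c(F = 0, M = 0),
                          beta_mat = c(F = 0, M = 0),
                          sd_year = 0, sd_id = 0)
  ped <- simulate_pedigree(cfg, seed = 4)
  ibd0 <- stats::setNames(rep(0, nrow(ped)), ped$id)
  fit <- simulate_fitness(ped, ibd0, cfg, seed = 5)
  n <- nrow(fit$first_year)
  expect_lt(abs(mean(fit$first_year$fys) - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  nab <- nrow(fit$annual)
  expect_lt(abs(mean(fit$annual$abs) - 1.5), 3 * sqrt(1.5 / nab))
})

test_that("trait slopes on realized inbreeding are recoverable by regression", {
  cfg <- sim_config(n_cohorts = 7, n_founder_females = 40,
                    n_founder_males = 20, offspring_per_cohort = 150,
                    close_mating_rate = 0.15, n_chr = 6, total_cM = 150,
                    n_snps = 60)
  ped <- simulate_pedigree(cfg, seed = 41)
  ibd <- gene_drop(ped, cfg, seed = 42, genotypes = FALSE)$true_ibd
  tr <- simulate_traits(ped, ibd, cfg, seed = 43)
  dat <- tr[tr$has_dam, ]
  fit <- stats::lm(august_weight ~ F_true + F_true_dam + sex + factor(year),
                   data = dat)
  est <- summary(fit)$coefficients["F_true", ]
  expect_lt(abs(est["Estimate"] - (-8.36)), 3 * est["Std. Error"])
})
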