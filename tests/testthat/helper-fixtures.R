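# Shared fixture builders and independent oracles.

# geno_matrix from a plain dosage matrix with uniformly spaced markers
make_gm <- function(geno, spacing_kb = 100, chr = NULL) {
  m <- ncol(geno)
  if (is.null(chr)) chr <- rep("chr1", m)
  bp <- stats::ave(seq_len(m), chr, FUN = function(i) seq_along(i)) * spacing_kb * 1000
  geno_matrix(geno, data.frame(chr = chr, bp = bp))
}

# small multi-loop pedigree used across tests: E is a full-sib offspring,
# Z a first-cousin offspring, K a half-sib offspring
fixture_pedigree <- function() {
  pedigree(
    id   = c("A", "B", "C", "D", "E", "P", "Q", "S1", "S2", "X", "Y", "Z",
             "M1", "M2", "K"),
    sire = c(NA, NA, "A", "A", "C", NA, NA, "A", "A", "P", "Q", "X",
             "A", "A", "M1"),
    dam  = c(NA, NA, "B", "B", "D", NA, NA, "B", "B", "S1", "S2", "Y",
             "B", "P", "M2"))
}

# Single-locus gene-dropping oracle for kinship: drops one unlinked locus
# down the pedigree n_rep times and estimates kinship(i, j) as the mean
# probability that a random allele from i matches (is IBD to) a random
# allele from j. Independent of the tabular kinship implementation.
drop_allele_kinship <- function(ped, n_rep = 20000, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  for (i in seq_len(n)) {
    si <- ped$sire_idx[i]
    di <- ped$dam_idx[i]
    a1[, i] <- if (si > 0L) {
      ifelse(stats::runif(n_rep) < 0.5, a1[, si], a2[, si])
    } else rep(2L * i - 1L, n_rep)
    a2[, i] <- if (di > 0L) {
      ifelse(stats::runif(n_rep) < 0.5, a1[, di], a2[, di])
    } else rep(2L * i, n_rep)
  }
  kin <- function(i, j) {
    mean((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
           (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
  }
  list(kin = kin, f = function(i) mean(a1[, i] == a2[, i]))
}

# Exact-enumeration oracle for the HWE test: enumerates every genotype
# configuration consistent with the allele counts and sums the exact
# conditional probabilities of configurations no more probable than the
# observed one.
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
          lfactorial(hom_c) + h * log(2) +
          lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)  # guard rounding; sums to 1 analytically
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Brute-force quadruple-loop g2 oracle following the defining sums over
# ordered locus pairs and (pairs of) individuals, with every term involving
# a missing call excluded from numerator and denominator alike.
g2_bruteforce <- function(h) {
  n <- nrow(h)
  L <- ncol(h)
  num_w <- den_w <- 0
  num_b <- den_b <- 0
  for (l in seq_len(L)) for (k in seq_len(L)) {
    if (l == k) next
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (is.na(h[i, l]) || is.na(h[j, k])) next
        if (i == j) {
          num_w <- num_w + h[i, l] * h[i, k]
          den_w <- den_w + 1
        } else {
          num_b <- num_b + h[i, l] * h[j, k]
          den_b <- den_b + 1
        }
      }
    }
  }
  (num_w / den_w) / (num_b / den_b) - 1
}

# Link-deletion replicate study shared by the estimator-validity and
# estimator-comparison acceptance checks: simulate a polygynous population,
# gene-drop a chip-density panel, delete 30% of parentage links, and build
# the inbreeding table (F_ped from the damaged pedigree, genomic estimators
# from the genotypes, truth from the gene drop).
deletion_study <- local({
  cache <- NULL
  function(n_reps = 6) {
    if (!is.null(cache) && length(cache) >= n_reps) return(cache[seq_len(n_reps)])
    cfg <- sim_config(n_cohorts = 8, n_founder_females = 30,
                      n_founder_males = 15, offspring_per_cohort = 80,
                      close_mating_rate = 0.2, n_chr = 12, total_cM = 250,
                      n_snps = 3750, missing_rate = 0)
    cache <<- lapply(seq_len(n_reps), function(r) {
      ped <- simulate_pedigree(cfg, seed = 500 + r)
      gd <- gene_drop(ped, cfg, seed = 600 + r)
      ped_del <- delete_pedigree_links(ped, 0.3, seed = 700 + r)
      qc <- qc_filter(gd$gm)
      gmp <- subset_geno(qc$gm, markers = ld_prune_vif(qc$gm))
      tab <- inbreeding_table(ped_del, qc$gm, gmp, true_ibd = gd$true_ibd)
      tab
    })
    cache
  }
})

# small simulated population shared by several expensive tests
shared_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cohorts = 8, n_founder_females = 25,
                        n_founder_males = 12, offspring_per_cohort = 60,
                        close_mating_rate = 0.15, n_chr = 8,
                        total_cM = 130, n_snps = 2000, missing_rate = 0)
      sp <- simulate_pedigree(cfg, seed = 11)
      gd <- gene_drop(sp, cfg, seed = 12)
      cache <<- list(cfg = cfg, ped = sp, gm = gd$gm, true_ibd = gd$true_ibd)
    }
    cache
  }
})
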