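#' Simulation configuration
#'
#' Defaults emulate a small, polygynous, overlapping-generation ungulate
#' population genotyped on a medium-density SNP chip: ~10 cohorts with
#' strong male reproductive skew and occasional close inbreeding, 26
#' autosomes totalling ~24.3 Morgans of map (1 cM ~ 1 Mb), a few thousand
#' SNPs with LD generated by a finite founder-haplotype pool, and three
#' body-size traits (means/SDs 2.08 (0.60) kg, 13.18 (2.76) kg,
#' 159.48 (10.49) mm) with additive genetic, maternal genetic, maternal
#' environment and year variance plus negative individual and maternal
#' inbreeding slopes. Fitness components use logit/log links with
#' sex-specific slopes.
#'
#' @param n_cohorts number of offspring cohorts (default 10).
#' @param n_founder_females,n_founder_males founder population.
#' @param offspring_per_cohort lambs born per cohort.
#' @param polygyny_top_fraction fraction of sires fathering ~80% of
#'   offspring (lognormal quality weights are calibrated to this).
#' @param close_mating_rate probability a dam's mate is drawn among her
#'   relatives with kinship >= 0.125 (when any exist); otherwise mates are
#'   drawn among non-close-kin.
#' @param female_survival,male_survival annual adult survival.
#' @param n_chr,total_cM chromosome count and total map length (cM). The
#'   default scales the genome down with the marker panel so that marker
#'   density (and hence ROH detectability under the fixed caller
#'   parameters) matches a medium-density chip.
#' @param n_snps marker panel size.
#' @param n_pool_haplotypes,n_templates,template_switch_per_cM,template_mutation
#'   founder-haplotype pool: `n_pool_haplotypes` haplotypes built as mosaics
#'   of `n_templates` ancestral haplotypes (switch probability per cM, plus
#'   per-locus mutation), which sets the strength and decay of LD.
#' @param geno_error,missing_rate genotyping error and missing-call rates.
#' @param traits data.frame of trait parameters (mean, sd, beta_ind,
#'   beta_mat, sex_effect).
#' @param var_prop named proportions of phenotypic variance assigned to the
#'   additive genetic, maternal genetic, maternal environment and year
#'   components (remainder is residual).
#' @param fitness list of link-scale parameters for first-year survival,
#'   annual survival and annual breeding success (sex-specific intercepts
#'   and individual/maternal F slopes, year/mother/individual random SDs).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 10,
                       n_founder_females = 60, n_founder_males = 40,
                       offspring_per_cohort = 100,
                       polygyny_top_fraction = 0.2,
                       close_mating_rate = 0.08,
                       female_survival = 0.75, male_survival = 0.6,
                       n_chr = 26, total_cM = 400,
                       n_snps = 6000,
                       n_pool_haplotypes = 200, n_templates = 3,
                       template_switch_per_cM = 0.4,
                       template_mutation = 0.002,
                       geno_error = 0, missing_rate = 0.001,
                       traits = NULL,
                       var_prop = c(va = 0.25, mat_gen = 0.10,
                                    mat_env = 0.10, year = 0.15),
                       fitness = NULL) {
  if (is.null(traits)) {
    traits <- data.frame(
      trait = c("birthweight", "august_weight", "hindleg"),
      mean = c(2.08, 13.18, 159.48),
      sd = c(0.60, 2.76, 10.49),
      beta_ind = c(-0.42, -8.36, -28.03),
      beta_mat = c(0.03, -7.89, -10.78),
      sex_effect = c(0.08, 0.8, 3.0),
      stringsAsFactors = FALSE)
  }
  if (is.null(fitness)) {
    fitness <- list(
      first_year = list(alpha = c(F = stats::qlogis(0.60), M = stats::qlogis(0.50)),
                        beta_ind = c(F = -6.42, M = -22.66),
                        beta_mat = c(F = 2.23, M = -20.63),
                        sd_year = 0.7, sd_mother = 0.3),
      annual_survival = list(alpha = c(F = stats::qlogis(0.80), M = stats::qlogis(0.70)),
                             beta_ind = c(F = -5.58, M = -5.02),
                             beta_mat = c(F = 2.37, M = -40.42),
                             sd_year = 0.7, sd_id = 0.3),
      abs = list(alpha = c(F = log(0.9), M = log(1.2)),
                 beta_ind = c(F = -2.31, M = -18.42),
                 beta_mat = c(F = 0.87, M = 6.25),
                 sd_year = 0.4, sd_id = 0.3))
  }
  stopifnot(n_cohorts >= 1, offspring_per_cohort >= 1,
            n_founder_females >= 2, n_founder_males >= 1,
            polygyny_top_fraction > 0, polygyny_top_fraction < 1,
            close_mating_rate >= 0, close_mating_rate <= 1,
            n_chr >= 1, total_cM > 0, n_snps >= n_chr,
            all(var_prop >= 0), sum(var_prop) < 1,
            missing_rate >= 0, missing_rate < 1, geno_error >= 0)
  # chromosome lengths: decreasing, scaled to the total map length
  raw <- seq(3, 1, length.out = n_chr)
  chr_cM <- raw * total_cM / sum(raw)
  structure(list(
    n_cohorts = n_cohorts, n_founder_females = n_founder_females,
    n_founder_males = n_founder_males,
    offspring_per_cohort = offspring_per_cohort,
    polygyny_top_fraction = polygyny_top_fraction,
    close_mating_rate = close_mating_rate,
    female_survival = female_survival, male_survival = male_survival,
    n_chr = n_chr, chr_cM = chr_cM, total_cM = total_cM,
    n_snps = n_snps, n_pool_haplotypes = n_pool_haplotypes,
    n_templates = n_templates,
    template_switch_per_cM = template_switch_per_cM,
    template_mutation = template_mutation,
    geno_error = geno_error, missing_rate = missing_rate,
    traits = traits, var_prop = var_prop, fitness = fitness),
    class = "sim_config")
}

#' Simulate an overlapping-generation, polygynous pedigree
#'
#' Founders form cohort 0. Each later cohort's lambs draw dams uniformly
#' from living adult females and sires from living adult males with
#' lognormal quality weights calibrated so that the top
#' `polygyny_top_fraction` of sires father ~80% of offspring. With
#' probability `close_mating_rate` the sire is drawn (quality-weighted)
#' among the dam's relatives with kinship >= 0.125 when available;
#' otherwise among non-close-kin. Adults survive between cohorts with the
#' sex-specific annual rates. Sexes are recorded in the `sex` attribute.
#'
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @return a [pedigree] with attribute `sex` (named "F"/"M" vector).
#' @export
simulate_pedigree <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  nF <- cfg$n_founder_females
  nM <- cfg$n_founder_males
  n_max <- nF + nM + cfg$n_cohorts * cfg$offspring_per_cohort
  id <- sprintf("i%04d", seq_len(n_max))
  sex <- character(n_max)
  sire <- rep(NA_character_, n_max)
  dam <- rep(NA_character_, n_max)
  cohort <- integer(n_max)
  alive <- logical(n_max)
  quality <- numeric(n_max)
  # lognormal sigma such that the top q fraction holds 80% of the mass
  sigma <- stats::qnorm(0.8) + stats::qnorm(1 - cfg$polygyny_top_fraction)

  K <- matrix(0, n_max, n_max)  # kinship, filled incrementally
  n <- 0
  add_ind <- function(s_idx, d_idx) {
    # updates K in the enclosing environment; returns the new index
    i <- n + 1
    if (i > 1) {
      ks <- if (s_idx > 0) K[s_idx, 1:(i - 1)] else numeric(i - 1)
      kd <- if (d_idx > 0) K[d_idx, 1:(i - 1)] else numeric(i - 1)
      K[i, 1:(i - 1)] <<- 0.5 * (ks + kd)
      K[1:(i - 1), i] <<- K[i, 1:(i - 1)]
    }
    fpar <- if (s_idx > 0 && d_idx > 0) K[s_idx, d_idx] else 0
    K[i, i] <<- 0.5 * (1 + fpar)
    n <<- i
    i
  }
  for (i in seq_len(nF + nM)) {
    add_ind(0, 0)
    sex[i] <- if (i <= nF) "F" else "M"
    cohort[i] <- 0L
    alive[i] <- TRUE
    quality[i] <- stats::rlnorm(1, 0, sigma)
  }
  for (t in seq_len(cfg$n_cohorts)) {
    fem <- which(alive & sex == "F" & cohort < t)
    mal <- which(alive & sex == "M" & cohort < t)
    if (length(fem) < 1 || length(mal) < 1) {
      stop("population died out at cohort ", t,
           "; inconsistent cohort sizes / survival rates")
    }
    for (k in seq_len(cfg$offspring_per_cohort)) {
      d <- if (length(fem) == 1) fem else sample(fem, 1)
      kin <- K[d, mal]
      close_kin <- mal[kin >= 0.125]
      open_kin <- mal[kin < 0.125]
      pool <- if (stats::runif(1) < cfg$close_mating_rate &&
                  length(close_kin)) close_kin
              else if (length(open_kin)) open_kin else mal
      s <- if (length(pool) == 1) pool else
        sample(pool, 1, prob = quality[pool])
      i <- add_ind(s, d)
      sire[i] <- id[s]
      dam[i] <- id[d]
      sex[i] <- sample(c("F", "M"), 1)
      cohort[i] <- t
      alive[i] <- TRUE
      quality[i] <- stats::rlnorm(1, 0, sigma)
    }
    adults <- which(alive & cohort < t)
    surv_p <- ifelse(sex[adults] == "F", cfg$female_survival,
                     cfg$male_survival)
    alive[adults] <- stats::runif(length(adults)) < surv_p
  }
  ped <- pedigree(id[1:n], sire[1:n], dam[1:n], cohort[1:n])
  sx <- sex[match(ped$id, id[1:n])]
  names(sx) <- ped$id
  attr(ped, "sex") <- sx
  ped
}

# Evenly spaced marker map over the configured chromosomes; deterministic.
make_marker_map <- function(cfg) {
  per_chr <- pmax(1L, round(cfg$n_snps * cfg$chr_cM / sum(cfg$chr_cM)))
  maps <- lapply(seq_len(cfg$n_chr), function(c) {
    m <- per_chr[c]
    cM <- seq(0.5, cfg$chr_cM[c] - 0.5, length.out = m)
    data.frame(chr = paste0("chr", c), snp = sprintf("snp%d_%d", c, seq_len(m)),
               cM = cM, bp = round(cM * 1e6))
  })
  do.call(rbind, maps)
}

# Founder-haplotype pool for one chromosome: mosaics of `n_templates`
# ancestral haplotypes with per-cM template switching and per-locus
# mutation. Returns an n_pool x m 0/1 allele matrix.
make_pool <- function(cfg, cM) {
  m <- length(cM)
  p_anc <- stats::runif(m, 0.1, 0.9)
  templates <- matrix(stats::rbinom(cfg$n_templates * m, 1,
                                    rep(p_anc, each = cfg$n_templates)),
                      cfg$n_templates, m)
  # every assayed locus segregates among the templates (chip markers are
  # ascertained to be polymorphic)
  mono <- colSums(templates) %in% c(0L, cfg$n_templates)
  while (any(mono)) {
    k <- sum(mono)
    templates[, mono] <- matrix(stats::rbinom(cfg$n_templates * k, 1,
                                              rep(p_anc[mono], each = cfg$n_templates)),
                                cfg$n_templates, k)
    mono <- colSums(templates) %in% c(0L, cfg$n_templates)
  }
  d <- c(0, diff(cM))
  p_switch <- 1 - exp(-cfg$template_switch_per_cM * d)
  pool <- matrix(0L, cfg$n_pool_haplotypes, m)
  for (h in seq_len(cfg$n_pool_haplotypes)) {
    tmpl <- integer(m)
    cur <- sample.int(cfg$n_templates, 1)
    sw <- stats::runif(m) < p_switch
    for (j in seq_len(m)) {
      if (sw[j]) cur <- sample.int(cfg$n_templates, 1)
      tmpl[j] <- cur
    }
    al <- templates[cbind(tmpl, seq_len(m))]
    mut <- stats::runif(m) < cfg$template_mutation
    al[mut] <- 1L - al[mut]
    pool[h, ] <- al
  }
  pool
}

# One meiosis: recombine two segment lists (end positions in cM + integer
# labels; last end = chromosome length) with crossovers from a Poisson
# process (no interference) and a random starting haplotype.
meiose <- function(hapA, hapB, len) {
  nx <- stats::rpois(1, len / 100)
  cur <- sample(1:2, 1)
  if (nx == 0) return(if (cur == 1) hapA else hapB)
  xp <- sort(stats::runif(nx, 0, len))
  bounds <- c(xp, len)
  out_end <- numeric(0)
  out_lab <- integer(0)
  lo <- 0
  for (b in bounds) {
    h <- if (cur == 1) hapA else hapB
    # first segment of h intersecting (lo, b]: first end strictly > lo
    k <- min(findInterval(lo, h$end) + 1, length(h$end))
    while (TRUE) {
      e <- min(h$end[k], b)
      if (length(out_lab) && out_lab[length(out_lab)] == h$lab[k]) {
        out_end[length(out_end)] <- e  # merge with previous same-label segment
      } else {
        out_end <- c(out_end, e)
        out_lab <- c(out_lab, h$lab[k])
      }
      if (h$end[k] >= b) break
      k <- k + 1
    }
    lo <- b
    cur <- 3 - cur
  }
  list(end = out_end, lab = out_lab)
}

# label of a segment list at each query position
hap_labels_at <- function(hap, pos) {
  idx <- findInterval(pos, hap$end, left.open = TRUE) + 1
  idx[idx > length(hap$lab)] <- length(hap$lab)
  hap$lab[idx]
}

# shared-label (autozygous) length between two segment lists
ibd_length <- function(hap1, hap2, len) {
  ends <- sort(unique(c(hap1$end, hap2$end)))
  starts <- c(0, ends[-length(ends)])
  mid <- (starts + ends) / 2
  sum((ends - starts)[hap_labels_at(hap1, mid) == hap_labels_at(hap2, mid)])
}

#' Gene-drop genotypes and realized autozygosity down a pedigree
#'
#' Founders receive haplotypes drawn from a finite pool (generating LD),
#' each tagged with a unique founder-allele label. Meioses place crossovers
#' as a Poisson process on the cM map (Haldane, no interference). SNP
#' genotypes are read off the transmitted pool haplotypes, with optional
#' genotyping error and missingness. Realized inbreeding is the fraction of
#' the map where an individual's maternal and paternal founder labels
#' coincide -- the ground truth that pedigree and genomic estimators try to
#' recover.
#'
#' @param ped a [pedigree].
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @param genotypes if `FALSE`, skip the SNP panel and return realized
#'   IBD only (fast path for trait simulations).
#' @return list with `true_ibd` (named vector) and, when requested,
#'   `gm` (a [geno_matrix]).
#' @export
gene_drop <- function(ped, cfg, seed = 1, genotypes = TRUE) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(seed)
  map <- make_marker_map(cfg)
  chrs <- unique(map$chr)
  if (length(chrs) != cfg$n_chr) stop("map/cfg mismatch")
  n <- nrow(ped)
  total_len <- sum(cfg$chr_cM)
  ibd <- numeric(n)
  G <- if (genotypes) matrix(NA_integer_, n, nrow(map),
                             dimnames = list(ped$id, map$snp)) else NULL
  founder <- ped$sire_idx == 0L & ped$dam_idx == 0L
  lab_pat <- 2 * seq_len(n) - 1  # founder label space
  lab_mat <- 2 * seq_len(n)
  # two distinct pool haplotypes per founder: whole-haplotype identity must
  # arise from the pedigree, never from the pool draw
  label_pool <- integer(2 * n)
  for (i in seq_len(n)) {
    label_pool[c(2 * i - 1, 2 * i)] <-
      sample.int(cfg$n_pool_haplotypes, 2, replace = FALSE)
  }

  for (c in seq_len(cfg$n_chr)) {
    len <- cfg$chr_cM[c]
    jj <- which(map$chr == chrs[c])
    cM <- map$cM[jj]
    pool <- if (genotypes) make_pool(cfg, cM) else NULL
    pat <- vector("list", n)
    mat <- vector("list", n)
    for (i in seq_len(n)) {
      if (founder[i]) {
        pat[[i]] <- list(end = len, lab = lab_pat[i])
        mat[[i]] <- list(end = len, lab = lab_mat[i])
      } else {
        si <- ped$sire_idx[i]
        di <- ped$dam_idx[i]
        pat[[i]] <- if (si > 0L) meiose(pat[[si]], mat[[si]], len) else
          list(end = len, lab = lab_pat[i])
        mat[[i]] <- if (di > 0L) meiose(pat[[di]], mat[[di]], len) else
          list(end = len, lab = lab_mat[i])
      }
      ibd[i] <- ibd[i] + ibd_length(pat[[i]], mat[[i]], len)
      if (genotypes) {
        a1 <- pool[cbind(label_pool[hap_labels_at(pat[[i]], cM)], seq_along(jj))]
        a2 <- pool[cbind(label_pool[hap_labels_at(mat[[i]], cM)], seq_along(jj))]
        G[i, jj] <- a1 + a2
      }
    }
  }
  true_ibd <- ibd / total_len
  names(true_ibd) <- ped$id
  out <- list(true_ibd = true_ibd)
  if (genotypes) {
    if (cfg$geno_error > 0) {
      err <- stats::runif(length(G)) < cfg$geno_error
      G[err] <- sample(0:2, sum(err), replace = TRUE)
    }
    if (cfg$missing_rate > 0) {
      G[stats::runif(length(G)) < cfg$missing_rate] <- NA_integer_
    }
    out$gm <- geno_matrix(G, map)
  }
  out
}

#' Simulate body-size traits with individual and maternal inbreeding depression
#'
#' For each configured trait, phenotype = mean + beta_ind * F_true(i) +
#' beta_mat * F_true(dam) + sex effect + a_i + m_dam + c_dam + year effect +
#' residual, where a (additive genetic) and m (maternal genetic) are drawn
#' through the pedigree by Mendelian-sampling recursion (so relatives
#' covary according to the relationship matrix), c is an iid maternal
#' environment effect shared by a dam's offspring, and year effects are
#' shared within cohorts. Variance components are the configured
#' proportions of each trait's phenotypic variance. Records for
#' individuals with an unknown dam omit the maternal terms and are flagged
#' (`has_dam = FALSE`). A capture age (days) and capture weight following a
#' cubic growth curve are included for birthweight age-correction.
#'
#' @param ped a [pedigree] with a `sex` attribute (or sexes drawn at random).
#' @param true_ibd named realized-IBD vector from [gene_drop].
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @return data.frame: one row per non-founder with id, dam, sex, cohort
#'   (as `year`), F_true, F_true_dam, has_dam, one column per trait, and
#'   `cap_age` / `cap_weight`.
#' @export
simulate_traits <- function(ped, true_ibd, cfg, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- nrow(ped)
  sx <- attr(ped, "sex")
  if (is.null(sx)) {
    sx <- sample(c("F", "M"), n, replace = TRUE)
    names(sx) <- ped$id
  }
  fp <- f_ped(ped)
  vp <- cfg$var_prop
  keep <- ped$sire_idx > 0L | ped$dam_idx > 0L
  has_dam <- ped$dam_idx > 0L
  dam_id <- ped$dam
  F_true <- unname(true_ibd[ped$id])
  F_dam <- ifelse(has_dam, true_ibd[dam_id], NA_real_)
  year <- ped$cohort
  year[is.na(year)] <- 0L
  yr_levels <- sort(unique(year))

  out <- data.frame(id = ped$id, dam = dam_id, sex = unname(sx[ped$id]),
                    year = year, F_true = F_true, F_true_dam = F_dam,
                    has_dam = has_dam, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[r, ]
    vtot <- tr$sd^2
    a <- pedigree_effects(ped, fp, vtot * vp[["va"]])
    m <- pedigree_effects(ped, fp, vtot * vp[["mat_gen"]])
    cenv <- stats::rnorm(n, 0, sqrt(vtot * vp[["mat_env"]]))
    yeff <- stats::rnorm(length(yr_levels), 0, sqrt(vtot * vp[["year"]]))
    ve <- vtot * (1 - sum(vp))
    y <- tr$mean + tr$beta_ind * F_true +
      ifelse(out$sex == "M", tr$sex_effect, 0) +
      a + yeff[match(year, yr_levels)] +
      stats::rnorm(n, 0, sqrt(ve))
    midx <- ped$dam_idx
    matpart <- ifelse(has_dam,
                      tr$beta_mat * F_dam + m[pmax(midx, 1)] + cenv[pmax(midx, 1)],
                      0)
    out[[tr$trait]] <- y + matpart
  }
  # capture-age structure for the birthweight age-correction step
  if ("birthweight" %in% names(out)) {
    out$cap_age <- sample(0:14, n, replace = TRUE,
                          prob = c(rep(0.085, 11), rep(0.013, 4)))
    growth <- function(t) 0.22 * t + 0.004 * t^2 - 1e-4 * t^3
    out$cap_weight <- out$birthweight + growth(out$cap_age) +
      stats::rnorm(n, 0, 0.05)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Additive genetic values through the pedigree: founders N(0, V); offspring
# get the parent average plus Mendelian sampling with variance
# V * (0.5 - 0.25 (F_s + F_d)); an unknown parent contributes an
# independent founder-level draw, keeping var(a_i) = V for non-inbred lines.
pedigree_effects <- function(ped, fp, V) {
  n <- nrow(ped)
  a <- numeric(n)
  if (V <= 0) return(a)
  for (i in seq_len(n)) {
    si <- ped$sire_idx[i]
    di <- ped$dam_idx[i]
    if (si == 0L && di == 0L) {
      a[i] <- stats::rnorm(1, 0, sqrt(V))
    } else {
      as_ <- if (si > 0L) a[si] else stats::rnorm(1, 0, sqrt(V))
      ad_ <- if (di > 0L) a[di] else stats::rnorm(1, 0, sqrt(V))
      fs <- if (si > 0L) fp[si] else 0
      fd <- if (di > 0L) fp[di] else 0
      a[i] <- 0.5 * (as_ + ad_) +
        stats::rnorm(1, 0, sqrt(V * (0.5 - 0.25 * (fs + fd))))
    }
  }
  a
}

#' Simulate fitness components with inbreeding depression on the link scale
#'
#' First-year survival is Bernoulli with a logit-linear predictor
#' (sex-specific intercept and individual/maternal F slopes, year and
#' mother random effects); annual survival likewise per sheep-year; annual
#' breeding success is Poisson with a log link. Adult observation spans are
#' geometric with the configured survival rates. Individuals with an
#' unknown dam are retained without the maternal term (`has_dam = FALSE`).
#'
#' @inheritParams simulate_traits
#' @return list with data.frames `first_year` (one row per lamb: fys 0/1)
#'   and `annual` (one row per sheep-year: survived 0/1, abs count, age).
#' @export
simulate_fitness <- function(ped, true_ibd, cfg, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(seed)
  sx <- attr(ped, "sex")
  if (is.null(sx)) {
    sx <- stats::setNames(sample(c("F", "M"), nrow(ped), TRUE), ped$id)
  }
  nonf <- which(ped$sire_idx > 0L | ped$dam_idx > 0L)
  id <- ped$id[nonf]
  sex <- unname(sx[id])
  year <- ped$cohort[nonf]
  year[is.na(year)] <- 0L
  has_dam <- ped$dam_idx[nonf] > 0L
  dam <- ped$dam[nonf]
  Fi <- unname(true_ibd[id])
  Fd <- ifelse(has_dam, true_ibd[dam], NA_real_)

  fy <- cfg$fitness$first_year
  yrs <- sort(unique(year))
  yeff <- stats::setNames(stats::rnorm(length(yrs), 0, fy$sd_year), yrs)
  moms <- unique(dam[has_dam])
  meff <- stats::setNames(stats::rnorm(length(moms), 0, fy$sd_mother), moms)
  eta <- fy$alpha[sex] + fy$beta_ind[sex] * Fi +
    ifelse(has_dam, fy$beta_mat[sex] * Fd + meff[dam], 0) +
    yeff[as.character(year)]
  first_year <- data.frame(id = id, sex = sex, year = year, dam = dam,
                           has_dam = has_dam, F_ind = Fi, F_dam = Fd,
                           fys = stats::rbinom(length(eta), 1, stats::plogis(eta)),
                           stringsAsFactors = FALSE)

  # adult sheep-years: geometric observation span per individual
  surv_p <- ifelse(sex == "F", cfg$female_survival, cfg$male_survival)
  n_years <- 1 + stats::rgeom(length(id), 1 - surv_p)
  n_years <- pmin(n_years, 8)
  as_cfg <- cfg$fitness$annual_survival
  ab_cfg <- cfg$fitness$abs
  idx <- rep(seq_along(id), n_years)
  age <- unlist(lapply(n_years, seq_len))
  obs_year <- year[idx] + age
  yrs2 <- sort(unique(obs_year))
  yeff_as <- stats::setNames(stats::rnorm(length(yrs2), 0, as_cfg$sd_year), yrs2)
  yeff_ab <- stats::setNames(stats::rnorm(length(yrs2), 0, ab_cfg$sd_year), yrs2)
  ieff_as <- stats::rnorm(length(id), 0, as_cfg$sd_id)
  ieff_ab <- stats::rnorm(length(id), 0, ab_cfg$sd_id)
  sexi <- sex[idx]
  eta_as <- as_cfg$alpha[sexi] + as_cfg$beta_ind[sexi] * Fi[idx] +
    ifelse(has_dam[idx], as_cfg$beta_mat[sexi] * Fd[idx], 0) +
    yeff_as[as.character(obs_year)] + ieff_as[idx]
  eta_ab <- ab_cfg$alpha[sexi] + ab_cfg$beta_ind[sexi] * Fi[idx] +
    ifelse(has_dam[idx], ab_cfg$beta_mat[sexi] * Fd[idx], 0) +
    yeff_ab[as.character(obs_year)] + ieff_ab[idx]
  annual <- data.frame(id = id[idx], sex = sexi, year = obs_year,
                       age = age, dam = dam[idx], has_dam = has_dam[idx],
                       F_ind = Fi[idx], F_dam = Fd[idx],
                       survived = stats::rbinom(length(eta_as), 1,
                                                stats::plogis(eta_as)),
                       abs = stats::rpois(length(eta_ab), exp(eta_ab)),
                       stringsAsFactors = FALSE)
  list(first_year = first_year, annual = annual)
}

#' Simulate a full study population
#'
#' Convenience wrapper: pedigree, gene drop (genotypes + realized IBD),
#' traits and fitness, with sub-seeds derived from one master seed.
#'
#' @param cfg a [sim_config].
#' @param seed master integer seed.
#' @return list `ped`, `gm`, `true_ibd`, `traits`, `fitness`.
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1) {
  ped <- simulate_pedigree(cfg, seed = seed)
  gd <- gene_drop(ped, cfg, seed = seed + 1000L)
  traits <- simulate_traits(ped, gd$true_ibd, cfg, seed = seed + 2000L)
  fitness <- simulate_fitness(ped, gd$true_ibd, cfg, seed = seed + 3000L)
  list(ped = ped, gm = gd$gm, true_ibd = gd$true_ibd,
       traits = traits, fitness = fitness, cfg = cfg, seed = seed)
}
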