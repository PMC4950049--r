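#' Identity disequilibrium (g2)
#'
#' Two-locus heterozygosity disequilibrium: with h_il the indicator that
#' individual i is heterozygous at locus l (on non-missing calls), over
#' ordered pairs of distinct loci (l, k)
#' \deqn{g_2 = m_{within} / m_{between} - 1}
#' where m_within averages (1/n) sum_i h_il h_ik and m_between averages
#' (1/(n(n-1))) sum_{i != j} h_il h_jk. Variance in inbreeding across
#' individuals makes heterozygosity covary among loci within individuals,
#' so g2 > 0. Missing calls are excluded pairwise in ratio-of-sums form:
#' every (individual, locus-pair) product with a missing call drops out of
#' both the numerator and the denominator count, which keeps the estimator
#' exact under missingness and computable in O(nL).
#'
#' Uncertainty is a bootstrap SD over individuals; significance is an
#' upper-tail permutation test that shuffles each locus column independently
#' across individuals, destroying within-individual correlation while
#' keeping locus heterozygosities fixed.
#'
#' @param gm a [geno_matrix] (or a 0/1/NA heterozygosity matrix).
#' @param n_boot bootstrap replicates (default 1000).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed; identical seeds reproduce identical results.
#' @return list of class `g2_result`: `g2`, `bootstrap_sd`,
#'   `permutation_p`, `n_boot`, `n_perm`, `seed`, `n_ind`, `n_loci`,
#'   `degenerate`.
#' @export
g2_estimate <- function(gm, n_boot = 1000, n_perm = 1000, seed = 1) {
  h <- het_matrix(gm)
  if (ncol(h) < 2 || nrow(h) < 3) stop("need >= 2 loci and >= 3 individuals")
  nhet <- colSums(h, na.rm = TRUE)
  if (any(nhet == 0)) {
    warning(sum(nhet == 0), " locus/loci with zero observed heterozygotes dropped")
    h <- h[, nhet > 0, drop = FALSE]
    if (ncol(h) < 2) stop("fewer than 2 informative loci remain")
  }
  g2 <- g2_stat(h)
  degenerate <- is.na(g2) || nrow(unique(h)) < 2 ||
    all(h == h[rep(1, nrow(h)), ], na.rm = TRUE)
  if (degenerate && !is.na(g2)) {
    warning("degenerate input: individuals share one heterozygosity pattern; ",
            "within- and between-individual means coincide")
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    g2_stat(h[sample.int(nrow(h), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  n <- nrow(h)
  L <- ncol(h)
  if (!anyNA(h)) {
    # complete data: a column permutation only changes the row sums, so
    # each permuted g2 is computed from accumulated shuffled columns
    cl <- colSums(h)
    Csq <- sum(cl)^2 - sum(cl^2)
    den_w <- n * L * (L - 1)
    den_b <- n * (n - 1) * L * (L - 1)
    perm <- vapply(seq_len(n_perm), function(b) {
      # permuting a 0/1 column is placing its c_l ones uniformly, so only
      # the hit positions need to be drawn
      S <- numeric(n)
      for (l in seq_len(L)) {
        idx <- sample.int(n, cl[l])
        S[idx] <- S[idx] + 1
      }
      within_sum <- sum(S * (S - 1))
      m_within <- within_sum / den_w
      m_between <- (Csq - within_sum) / den_b
      if (m_between == 0) NA_real_ else m_within / m_between - 1
    }, numeric(1))
  } else {
    perm <- vapply(seq_len(n_perm), function(b) {
      g2_stat(apply(h, 2, function(col) col[sample.int(length(col))]))
    }, numeric(1))
  }
  structure(list(
    g2 = g2,
    bootstrap_sd = stats::sd(boot, na.rm = TRUE),
    permutation_p = (1 + sum(perm >= g2, na.rm = TRUE)) / (n_perm + 1),
    n_boot = n_boot, n_perm = n_perm, seed = seed,
    n_ind = nrow(h), n_loci = ncol(h),
    degenerate = degenerate), class = "g2_result")
}

# heterozygosity indicator matrix from genotypes (NA preserved)
het_matrix <- function(gm) {
  g <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  if (inherits(gm, "geno_matrix")) (g == 1) + 0 else g
}

# The within/between ratio in ratio-of-sums form. Because h is a 0/1
# indicator, the sum over ordered locus pairs (l != k) of h_il h_ik for one
# individual is S_i (S_i - 1) with S_i the individual's heterozygote count,
# and likewise for the typed-call indicator; missing calls therefore drop
# out of numerator and denominator pairwise and the whole statistic is
# O(nL). Returns NA when the between-individual mean is zero.
g2_stat <- function(h) {
  H <- h
  H[is.na(H)] <- 0
  M <- (!is.na(h)) + 0
  S <- rowSums(H)          # heterozygous typed calls per individual
  Tt <- rowSums(M)         # typed calls per individual
  cl <- colSums(H)
  nl <- colSums(M)
  num_w <- sum(S * (S - 1))
  den_w <- sum(Tt * (Tt - 1))
  num_b <- sum(cl)^2 - sum(cl^2) - num_w
  den_b <- sum(nl)^2 - sum(nl^2) - den_w
  if (den_w == 0 || den_b == 0) return(NA_real_)
  m_within <- num_w / den_w
  m_between <- num_b / den_b
  if (!is.finite(m_between) || m_between == 0) return(NA_real_)
  m_within / m_between - 1
}

#' @export
print.g2_result <- function(x, ...) {
  cat(sprintf("g2 = %.5f +- %.5f (bootstrap SD), permutation P = %.4g\n",
              x$g2, x$bootstrap_sd, x$permutation_p))
  cat(sprintf("  %d individuals, %d loci, %d bootstraps, %d permutations, seed %d\n",
              x$n_ind, x$n_loci, x$n_boot, x$n_perm, x$seed))
  if (x$degenerate) cat("  NOTE: degenerate input (m_between = 0)\n")
  invisible(x)
}

#' Heterozygosity-heterozygosity correlation across marker halves
#'
#' Randomly partitions the marker panel into halves, computes per-individual
#' F_hom (and F_GRM) on each half, and correlates them; repeated over
#' `n_splits` random splits. High values mean the panel captures a stable
#' individual signal (variance in inbreeding) rather than noise.
#'
#' @param gm a [geno_matrix].
#' @param n_splits number of random half splits (default 100).
#' @param seed integer seed.
#' @param use_grm also correlate F_GRM halves (default TRUE).
#' @return list with `mean_r_hom`, `sd_r_hom` and (optionally)
#'   `mean_r_grm`, `sd_r_grm`, plus the per-split correlations.
#' @export
hh_correlation <- function(gm, n_splits = 100, seed = 1, use_grm = TRUE) {
  m <- ncol(gm$geno)
  if (m < 2) stop("need >= 2 markers")
  set.seed(seed)
  p <- allele_freq(gm)
  r_hom <- numeric(n_splits)
  r_grm <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    half <- sample.int(m, floor(m / 2))
    g1 <- subset_geno(gm, markers = sort(half))
    g2_ <- subset_geno(gm, markers = sort(setdiff(seq_len(m), half)))
    r_hom[s] <- suppressWarnings(stats::cor(f_hom(g1), f_hom(g2_),
                                            use = "pairwise.complete.obs"))
    if (use_grm) {
      ok1 <- allele_freq(g1); ok2 <- allele_freq(g2_)
      poly1 <- ok1 > 0 & ok1 < 1
      poly2 <- ok2 > 0 & ok2 < 1
      r_grm[s] <- suppressWarnings(stats::cor(
        f_grm(subset_geno(g1, markers = which(poly1))),
        f_grm(subset_geno(g2_, markers = which(poly2))),
        use = "pairwise.complete.obs"))
    }
  }
  out <- list(mean_r_hom = mean(r_hom, na.rm = TRUE),
              sd_r_hom = stats::sd(r_hom, na.rm = TRUE),
              r_hom = r_hom, n_splits = n_splits, seed = seed)
  if (use_grm) {
    out$mean_r_grm <- mean(r_grm, na.rm = TRUE)
    out$sd_r_grm <- stats::sd(r_grm, na.rm = TRUE)
    out$r_grm <- r_grm
  }
  out
}
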