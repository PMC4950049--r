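#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability (given the minor-allele count, a
#' hypergeometric-type distribution over genotype configurations) does not
#' exceed that of the observed count. No mid-p correction. Stable at very
#' small p, which matters at the conventional chip-QC threshold 1e-5.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  n_a <- 2 * n_aa + n_Aa          # allele a count
  rare <- min(n_a, 2 * n - n_a)   # minor allele count
  if (rare == 0) return(1.0)
  # support: heterozygote counts with the parity of `rare`, 0..rare
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized log-probabilities: P(het | rare) proportional to
  # n! / (hom_r! het! hom_c!) * 2^het  with hom_r = (rare - het)/2
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- min(n_Aa, rare)  # observed het count (in terms of minor allele)
  p_obs <- p[match(obs, hets)]
  if (is.na(p_obs)) stop("internal: observed het count not in support")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Chip-style QC mirroring common practice: individuals with call rate below
#' `ind_call_rate` are removed first; then, on the remaining individuals,
#' loci are discarded if their minor allele frequency is below `maf_min`,
#' their call rate is below `locus_call_rate`, or the exact
#' Hardy-Weinberg test rejects at `hwe_p_min`.
#'
#' @param gm a [geno_matrix].
#' @param ind_call_rate individuals retained iff call rate > this (default 0.95).
#' @param locus_call_rate loci discarded iff call rate < this (default 0.99).
#' @param maf_min loci discarded iff MAF < this (default 0.01).
#' @param hwe_p_min loci discarded iff exact HWE p < this (default 1e-5).
#' @return list with elements `gm` (filtered [geno_matrix]) and `report`
#'   (class `qc_report`: counts removed per criterion).
#' @export
qc_filter <- function(gm, ind_call_rate = 0.95, locus_call_rate = 0.99,
                      maf_min = 0.01, hwe_p_min = 1e-5) {
  g <- gm$geno
  ind_cr <- rowMeans(!is.na(g))
  keep_ind <- ind_cr > ind_call_rate
  g2 <- g[keep_ind, , drop = FALSE]

  loc_cr <- colMeans(!is.na(g2))
  p <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(g2)), function(j) {
    x <- g2[, j]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, numeric(1))

  fail_cr <- loc_cr < locus_call_rate
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep_loc <- !(fail_cr | fail_maf | fail_hwe)

  report <- structure(list(
    n_ind_in = nrow(g), n_loci_in = ncol(g),
    ind_removed_call_rate = sum(!keep_ind),
    loci_removed_call_rate = sum(fail_cr),
    loci_removed_maf = sum(fail_maf),
    loci_removed_hwe = sum(fail_hwe),
    n_ind_out = sum(keep_ind), n_loci_out = sum(keep_loc),
    thresholds = c(ind_call_rate = ind_call_rate,
                   locus_call_rate = locus_call_rate,
                   maf_min = maf_min, hwe_p_min = hwe_p_min)),
    class = "qc_report")
  if (!any(keep_loc)) {
    print(report)
    stop("QC removed all loci")
  }
  list(gm = subset_geno(gm, which(keep_ind), which(keep_loc)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  input: %d individuals x %d loci\n", x$n_ind_in, x$n_loci_in))
  cat(sprintf("  individuals removed (call rate <= %.2f): %d\n",
              x$thresholds["ind_call_rate"], x$ind_removed_call_rate))
  cat(sprintf("  loci removed: call rate %d, MAF %d, HWE %d (criteria overlap)\n",
              x$loci_removed_call_rate, x$loci_removed_maf,
              x$loci_removed_hwe))
  cat(sprintf("  output: %d individuals x %d loci\n", x$n_ind_out, x$n_loci_out))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  flat <- report[setdiff(names(report), "thresholds")]
  utils::write.table(
    data.frame(key = c(names(flat), names(report$thresholds)),
               value = c(unlist(flat), unname(report$thresholds))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' LD pruning by variance inflation factor
#'
#' Sliding-window VIF pruning: within each window of `window_snps` markers
#' (stepping by `step_snps`, per chromosome), the marker whose regression on
#' the other retained window markers gives the largest VIF = 1 / (1 - R^2)
#' above `vif_max` is dropped, iterating until all window VIFs are at most
#' `vif_max`. A pair of markers with squared correlation r2 exceeds
#' `vif_max` = 10 at r2 > 0.9. Perfectly collinear duplicates are resolved
#' by dropping the later marker. Markers with MAF below `maf_min` are
#' excluded up front, mirroring the convention of pruning only informative
#' markers before ROH detection.
#'
#' @param gm a [geno_matrix].
#' @param vif_max VIF threshold (default 10).
#' @param window_snps,step_snps window size and step in markers (50 / 5).
#' @param maf_min minimum MAF to enter pruning (default 0.05).
#' @return integer vector of retained marker column indices (sorted).
#' @export
ld_prune_vif <- function(gm, vif_max = 10, window_snps = 50, step_snps = 5,
                         maf_min = 0.05) {
  if (ncol(gm$geno) < 2) stop("need at least two markers")
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  candidate <- which(!is.na(maf) & maf >= maf_min)
  keep <- rep(FALSE, ncol(gm$geno))
  keep[candidate] <- TRUE
  g <- gm$geno
  for (ch in unique(gm$map$chr)) {
    idx <- which(gm$map$chr == ch & keep)
    if (length(idx) < 2) next
    last_start <- max(1, length(idx) - window_snps + 1)
    starts <- unique(c(seq(1, last_start, by = step_snps), last_start))
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1, length(idx))]
      w <- w[keep[w]]
      keep[w] <- prune_window(g[, w, drop = FALSE], vif_max)
    }
    # `idx` is fixed per chromosome; windows see current keep state
  }
  which(keep)
}

# Iteratively drop the worst-VIF marker inside one window. Returns logical
# keep mask over the window's columns. Ties and perfect collinearity drop
# the later marker.
prune_window <- function(G, vif_max) {
  k <- ncol(G)
  keep <- rep(TRUE, k)
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    C <- suppressWarnings(stats::cor(G[, act, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    C[is.na(C)] <- 0
    diag(C) <- 1
    # resolve exact duplicates first: solve() would be singular
    dup <- which(abs(C) > 1 - 1e-10 & upper.tri(C), arr.ind = TRUE)
    if (nrow(dup)) {
      keep[act[max(dup[, 2])]] <- FALSE
      next
    }
    Cinv <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(Cinv)) {
      # numerically singular without an exact duplicate: drop the marker
      # with the largest mean squared correlation, later index on ties
      msq <- colMeans(C^2)
      keep[act[max(which(msq == max(msq)))]] <- FALSE
      next
    }
    vif <- diag(Cinv)
    if (max(vif) <= vif_max) break
    keep[act[max(which(vif == max(vif)))]] <- FALSE
  }
  keep
}
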