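#' Multilocus homozygosity (F_hom)
#'
#' Proportion of successfully genotyped loci which are homozygous.
#'
#' @param gm a [geno_matrix].
#' @return named numeric vector per individual; `NA` for an individual with
#'   zero non-missing calls.
#' @export
f_hom <- function(gm) {
  g <- gm$geno
  called <- rowSums(!is.na(g))
  hom <- rowSums(g != 1, na.rm = TRUE)
  out <- ifelse(called > 0, hom / called, NA_real_)
  names(out) <- rownames(g)
  out
}

#' GRM-diagonal inbreeding estimator (F_GRM)
#'
#' The allele-frequency-weighted single-SNP estimator averaged over loci
#' (`Fhat3` in the GCTA family): for dosage x and reference-allele frequency
#' p, per-locus value \deqn{[x^2 - (1 + 2p)x + 2p^2] / [2p(1-p)]}
#' averaged over an individual's non-missing markers. It estimates the
#' correlation between uniting gametes, up-weights homozygotes of the minor
#' allele, and can be negative.
#'
#' @param gm a [geno_matrix]; all markers must be polymorphic (QC first).
#' @param p optional allele frequencies to use (defaults to the sample
#'   frequencies of `gm`).
#' @return named numeric vector per individual.
#' @export
f_grm <- function(gm, p = NULL) {
  if (is.null(p)) p <- allele_freq(gm)
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic marker(s) present; run QC (MAF filter) first")
  }
  g <- gm$geno
  a <- matrix(1 + 2 * p, nrow(g), ncol(g), byrow = TRUE)
  b <- matrix(2 * p^2, nrow(g), ncol(g), byrow = TRUE)
  den <- matrix(2 * p * (1 - p), nrow(g), ncol(g), byrow = TRUE)
  val <- (g^2 - a * g + b) / den
  out <- rowMeans(val, na.rm = TRUE)
  names(out) <- rownames(g)
  out
}

#' Parameters of the scanning-window ROH caller
#'
#' Defaults mirror conventional SNP-chip ROH calling for a ~50k panel at
#' moderate density: 5-SNP scanning windows allowing no heterozygote and up
#' to 2 missing calls, candidate segments of at least 15 SNPs and 5 Mb,
#' split at inter-SNP gaps over 1 Mb, and at most 275 kb per SNP on
#' average. `hit_proportion` is the minimum fraction of overlapping
#' homozygous windows that makes a SNP part of a run.
#'
#' @param window_snps,window_het_max,window_missing_max scanning window.
#' @param min_snps,min_kb,max_gap_kb,density_kb_per_snp segment filters.
#' @param window_kb_max maximum physical span of a scanning window (kb).
#' @param hit_proportion SNP hit threshold.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 5, window_het_max = 0,
                       window_missing_max = 2, min_snps = 15,
                       min_kb = 5000, max_gap_kb = 1000,
                       density_kb_per_snp = 275, window_kb_max = 200000,
                       hit_proportion = 0.05) {
  p <- list(window_snps = window_snps, window_het_max = window_het_max,
            window_missing_max = window_missing_max, min_snps = min_snps,
            min_kb = min_kb, max_gap_kb = max_gap_kb,
            density_kb_per_snp = density_kb_per_snp,
            window_kb_max = window_kb_max, hit_proportion = hit_proportion)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))),
            window_snps >= 1, min_snps >= 1, min_kb > 0)
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity
#'
#' Scanning-window ROH caller. Per individual and chromosome: (1) every
#' window of `window_snps` consecutive SNPs spanning at most `window_kb_max`
#' is homozygous iff it contains at most `window_het_max` heterozygous and
#' `window_missing_max` missing calls; (2) a SNP is a hit iff the fraction
#' of windows overlapping it that are homozygous is at least
#' `hit_proportion`; (3) maximal runs of hit SNPs are candidate segments,
#' split wherever adjacent SNPs are more than `max_gap_kb` apart;
#' (4) candidates are kept iff they have at least `min_snps` SNPs, span at
#' least `min_kb`, and average at most `density_kb_per_snp` kb per SNP.
#' With `window_het_max = 0` a reported segment contains no heterozygous
#' call. Callers should supply LD-pruned, MAF-filtered genotypes so that
#' long homozygous stretches reflect autozygosity rather than chance.
#'
#' @param gm a [geno_matrix] (map sorted within chromosome; enforced).
#' @param params a [roh_params].
#' @return data.frame with columns `id`, `chr`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`; zero rows if no segment found.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  map <- gm$map
  out <- list()
  for (ch in unique(map$chr)) {
    jj <- which(map$chr == ch)
    if (any(diff(map$bp[jj]) <= 0)) stop("map unsorted on chromosome ", ch)
    bp <- map$bp[jj]
    G <- gm$geno[, jj, drop = FALSE]
    hits <- roh_hits(G, bp, params)
    for (i in seq_len(nrow(G))) {
      segs <- roh_segments(hits[i, ], bp, params)
      if (nrow(segs)) {
        segs$id <- rownames(G)[i]
        segs$chr <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), chr = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_kb = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("id", "chr", "start_bp", "end_bp", "n_snps", "length_kb")]
}

# Hit mask (individuals x SNPs of one chromosome): fraction of overlapping
# homozygous windows >= hit_proportion. Windows that exceed the kb cap count
# as non-homozygous but stay in the denominator.
roh_hits <- function(G, bp, params) {
  n <- nrow(G)
  m <- ncol(G)
  w <- params$window_snps
  if (m < w) return(matrix(FALSE, n, m))
  nw <- m - w + 1
  het <- (G == 1)
  het[is.na(het)] <- FALSE
  mis <- is.na(G)
  # rolling window sums via cumulative sums over columns
  roll <- function(M) {
    cs <- cbind(0, t(apply(M, 1, cumsum)))
    cs[, (w + 1):(m + 1), drop = FALSE] - cs[, 1:nw, drop = FALSE]
  }
  span_ok <- (bp[w:m] - bp[1:nw]) / 1000 <= params$window_kb_max
  homwin <- roll(het) <= params$window_het_max &
    roll(mis) <= params$window_missing_max
  homwin <- sweep(homwin, 2, span_ok, `&`)
  # per SNP j, windows covering it are starts max(1, j-w+1)..min(j, nw)
  hitnum <- matrix(0, n, m)
  hitden <- integer(m)
  cw <- cbind(0, t(apply(homwin, 1, cumsum)))
  for (j in seq_len(m)) {
    s1 <- max(1, j - w + 1)
    s2 <- min(j, nw)
    if (s2 < s1) next
    hitnum[, j] <- cw[, s2 + 1] - cw[, s1]
    hitden[j] <- s2 - s1 + 1
  }
  frac <- sweep(hitnum, 2, pmax(hitden, 1), `/`)
  frac >= params$hit_proportion & hitden > 0
}

# Turn one individual's hit mask on one chromosome into filtered segments.
roh_segments <- function(hit, bp, params) {
  empty <- data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_kb = numeric())
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  segs <- list()
  for (k in runs) {
    idx <- starts[k]:ends[k]
    # split at physical gaps
    gap <- which(diff(bp[idx]) / 1000 > params$max_gap_kb)
    bounds <- c(0, gap, length(idx))
    for (b in seq_len(length(bounds) - 1)) {
      sub <- idx[(bounds[b] + 1):bounds[b + 1]]
      n_snps <- length(sub)
      length_kb <- (bp[sub[n_snps]] - bp[sub[1]]) / 1000
      if (n_snps >= params$min_snps && length_kb >= params$min_kb &&
          length_kb / n_snps <= params$density_kb_per_snp) {
        segs[[length(segs) + 1]] <- data.frame(
          start_bp = bp[sub[1]], end_bp = bp[sub[n_snps]],
          n_snps = n_snps, length_kb = length_kb)
      }
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' ROH-based inbreeding coefficient (F_ROH)
#'
#' Summed ROH length divided by the assayed genome length (first to last
#' marker per chromosome), per individual.
#'
#' @param segments data.frame from [detect_roh].
#' @param map marker map (for the genome length) or a single numeric
#'   genome length in kb.
#' @param ids individuals to report (default: rows present in `segments`);
#'   individuals without segments get 0.
#' @return named numeric vector in [0, 1].
#' @export
f_roh <- function(segments, map, ids = NULL) {
  L <- if (is.numeric(map) && length(map) == 1) map else genome_length_kb(map)
  if (L <= 0) stop("genome length must be positive")
  if (is.null(ids)) ids <- unique(segments$id)
  tot <- tapply(segments$length_kb, segments$id, sum)
  out <- rep(0, length(ids))
  names(out) <- ids
  hit <- intersect(ids, names(tot))
  out[hit] <- tot[hit] / L
  out
}

#' Expected ROH length for a common ancestor g generations back
#'
#' The length of an autozygous segment descending from a single common
#' ancestor `g` generations ago is exponentially distributed with mean
#' 1/(2g) Morgans; at 1 cM ~ 1 Mb that is 100/(2g) Mb. A 5 Mb threshold
#' therefore targets inbreeding loops reaching back about 10 generations.
#'
#' @param g generations to the common ancestor (>= 1 for a meaningful loop).
#' @return expected segment length in Mb.
#' @export
expected_roh_length_mb <- function(g) {
  if (any(g <= 0)) stop("g must be positive")
  100 / (2 * g)
}

#' Assemble the per-individual inbreeding table
#'
#' Joins F_ped, F_hom, F_GRM, F_ROH (and, for simulated data, true realized
#' IBD) with ancestry tier, the common input for estimator comparison and
#' depression models.
#'
#' @param ped a [pedigree].
#' @param gm_qc QC'd [geno_matrix] for F_hom / F_GRM.
#' @param gm_pruned LD-pruned [geno_matrix] for ROH detection.
#' @param params a [roh_params].
#' @param true_ibd optional named vector of realized IBD fractions.
#' @return data.frame `id, tier, F_ped, F_hom, F_GRM, F_ROH[, F_true]`.
#' @export
inbreeding_table <- function(ped, gm_qc, gm_pruned = gm_qc,
                             params = roh_params(), true_ibd = NULL) {
  ids <- rownames(gm_qc$geno)
  fp <- f_ped(ped)
  tiers <- classify_ancestry(ped)
  segs <- detect_roh(gm_pruned, params)
  fr <- f_roh(segs, gm_pruned$map, ids = ids)
  tab <- data.frame(id = ids,
                    tier = tiers[ids],
                    F_ped = unname(fp[ids]),
                    F_hom = unname(f_hom(gm_qc)[ids]),
                    F_GRM = unname(f_grm(gm_qc)[ids]),
                    F_ROH = unname(fr[ids]),
                    stringsAsFactors = FALSE)
  if (!is.null(true_ibd)) tab$F_true <- unname(true_ibd[ids])
  tab
}
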