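test_that("F_hom is the homozygous fraction of successful calls", {
  g <- rbind(allhet = c(1, 1, 1, 1, 1),
             allhom = c(0, 2, 0, 2, 2),
             mixed = c(0, 2, 0, 1, NA))
  gm <- make_gm(g)
  fh <- f_hom(gm)
  expect_equal(unname(fh), c(0, 1, 0.75))
  gna <- rbind(c(NA, NA), c(0, 1))
  expect_true(is.na(f_hom(make_gm(gna))[1]))
})

test_that("F_GRM evaluates the weighted single-SNP formula and centers at HWE", {
  gm <- make_gm(matrix(c(1, 0, 2), 3, 1))
  expect_equal(unname(f_grm(gm, p = 0.5)), c(-1, 1, 1))
  expect_error(f_grm(make_gm(matrix(c(2, 2), 2, 1))), "monomorphic")

  # population at exact HWE genotype proportions has mean F_GRM = 0,
  # using the true p, for any allele frequency
  for (p in c(0.1, 0.3, 0.5)) {
    n <- 100
    counts <- round(n * c(p^2, 2 * p * (1 - p), (1 - p)^2))
    x <- rep(c(2, 1, 0), counts)
    gm <- make_gm(matrix(x, ncol = 1))
    expect_equal(mean(f_grm(gm, p = p)), 0, tolerance = 1e-12)
  }
})

test_that("ROH caller traces the scanning-window algorithm on fixtures", {
  p <- roh_params()
  # helper: single individual, one chromosome, given genotypes and bp
  call1 <- function(geno, bp) {
    gm <- geno_matrix(matrix(geno, 1, length(geno), dimnames = list("i1", NULL)),
                      data.frame(chr = "chr1", bp = bp))
    detect_roh(gm, p)
  }
  # flank ending (and, reversed, starting) with a heterozygote so runs
  # cannot legitimately extend into the flanks
  het_flank <- function(k) rep(c(0, 1), length.out = k)

  # 40 homozygous SNPs spanning 6.63 Mb at uniform 170 kb spacing,
  # heterozygous-rich flanks -> exactly one segment of 40 SNPs
  geno <- c(het_flank(10), rep(0, 40), rev(het_flank(10)))
  bp <- seq_along(geno) * 170000
  segs <- call1(geno, bp)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 40)
  expect_equal(segs$length_kb, 39 * 170)
  expect_equal(segs$start_bp, bp[11])
  expect_equal(segs$end_bp, bp[50])

  # same run but spanning only 4.9 Mb -> rejected by the 5 Mb minimum
  bp49 <- c(seq_len(10) * 170000,
            bp[10] + cumsum(rep(4900 / 39, 40)) * 1000 + 170000,
            max(bp) + seq_len(10) * 170000 + 6000000)
  segs49 <- call1(geno, round(bp49))
  expect_equal(nrow(segs49), 0)

  # 14 homozygous SNPs over 6 Mb -> rejected by the 15-SNP minimum
  geno14 <- c(het_flank(10), rep(2, 14), rev(het_flank(10)))
  bp14 <- c(seq_len(10) * 100000, 1e6 + seq_len(14) * (6000 / 13) * 1000,
            8e6 + seq_len(10) * 100000)
  expect_equal(nrow(call1(geno14, round(bp14))), 0)

  # internal 1.2 Mb gap splits the run; neither side reaches 5 Mb
  genog <- c(het_flank(10), rep(0, 20), rep(0, 20), rev(het_flank(10)))
  bpg <- c(seq_len(10) * 170000,
           bp[10] + seq_len(20) * 170000,
           bp[10] + 20 * 170000 + 1200000 + seq_len(20) * 170000,
           bp[10] + 40 * 170000 + 1200000 + seq_len(10) * 170000)
  expect_equal(nrow(call1(genog, bpg)), 0)

  # missing calls are tolerated (up to 2 per window) inside a run
  genom <- c(het_flank(10), rep(0, 40), rev(het_flank(10)))
  genom[30] <- NA
  expect_equal(call1(genom, bp)$n_snps, 40)

  expect_error(
    detect_roh(geno_matrix(matrix(0, 1, 2),
                           data.frame(chr = c("c1", "c1"), bp = c(2, 1))),
               p), "strictly increasing")
})

test_that("10 Mb threshold yields a subset of the 5 Mb segments", {
  pop <- shared_pop()
  qc <- qc_filter(pop$gm)
  gmp <- subset_geno(qc$gm, markers = ld_prune_vif(qc$gm))
  s5 <- detect_roh(gmp, roh_params(min_kb = 5000))
  s10 <- detect_roh(gmp, roh_params(min_kb = 10000))
  expect_gt(nrow(s5), 0)
  key <- function(s) paste(s$id, s$chr, s$start_bp, s$end_bp)
  expect_true(all(key(s10) %in% key(s5)))
  expect_true(all(s10$length_kb >= 10000))
  expect_true(all(s5$length_kb >= 5000))
})

test_that("F_ROH divides summed segment length by assayed genome length", {
  segs <- data.frame(id = "i1", chr = "chr1", start_bp = 1,
                     end_bp = 6600001, n_snps = 36, length_kb = 6600)
  expect_equal(unname(f_roh(segs, 2434125)), 6600 / 2434125,
               tolerance = 1e-12)
  expect_equal(unname(f_roh(segs, 2434125)), 0.0027114, tolerance = 1e-4)
  expect_equal(unname(f_roh(segs[0, ], 2434125, ids = "i1")), 0)
  # full coverage -> 1
  segs2 <- data.frame(id = "i1", chr = "c1", start_bp = 0, end_bp = 1e7,
                      n_snps = 100, length_kb = 1000)
  expect_equal(unname(f_roh(segs2, 1000)), 1)
})

test_that("expected ROH length follows the 1/(2g) Morgan exponential mean", {
  expect_equal(expected_roh_length_mb(10), 5)
  expect_equal(expected_roh_length_mb(5), 10)
  g <- 1:60
  len <- expected_roh_length_mb(g)
  expect_true(all(diff(len) < 0))
  expect_lt(expected_roh_length_mb(1000), 0.06)
  expect_error(expected_roh_length_mb(0), "positive")
})
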