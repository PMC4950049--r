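test_that("pedigree files parse, sort topologically, and reject bad input", {
  tf <- tempfile()
  writeLines(c("A 0 0", "B 0 0", "C A B"), tf)
  ped <- read_pedigree(tf)
  expect_setequal(ped$id, c("A", "B", "C"))
  expect_identical(ped$sire[ped$id == "C"], "A")
  expect_true(all(is.na(ped$sire[ped$id %in% c("A", "B")])))

  # child listed first: same pedigree after topological sort
  tf2 <- tempfile()
  writeLines(c("C A B", "A 0 0", "B 0 0"), tf2)
  ped2 <- read_pedigree(tf2)
  expect_identical(ped2[order(ped2$id), c("id", "sire", "dam")],
                   ped[order(ped$id), c("id", "sire", "dam")])
  # parents always precede offspring in storage order
  expect_true(match("C", ped2$id) > max(match(c("A", "B"), ped2$id)))

  tf3 <- tempfile()
  writeLines(c("A A 0"), tf3)
  expect_error(read_pedigree(tf3), "cycle.*A")
  expect_error(pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(pedigree(c("A", "B"), c("B", "A"), c(NA, NA)), "cycle")

  # referenced parents are auto-added as founders; round-trip via writer
  ped4 <- pedigree("X", "S", "D", cohort = 3L)
  expect_setequal(ped4$id, c("X", "S", "D"))
  tf4 <- tempfile()
  write_pedigree(ped4, tf4)
  expect_identical(read_pedigree(tf4)[, c("id", "sire", "dam")],
                   ped4[, c("id", "sire", "dam")])
})

test_that("F_ped reproduces the canonical close-inbreeding coefficients", {
  ped <- fixture_pedigree()
  f <- f_ped(ped)
  expect_equal(unname(f["A"]), 0)            # founder
  expect_equal(unname(f["E"]), 0.25)         # full-sib mating
  expect_equal(unname(f["Z"]), 0.0625)       # first-cousin mating
  expect_equal(unname(f["K"]), 0.125)        # half-sib mating
  # one known parent -> F = 0 (unknown parent assumed unrelated)
  ped1 <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, NA))
  expect_equal(unname(f_ped(ped1)["C"]), 0)
})

test_that("kinship matrix has textbook structure and matches gene-drop oracle", {
  ped <- fixture_pedigree()
  K <- kinship_matrix(ped)
  expect_equal(K["A", "B"], 0)
  expect_equal(K["A", "A"], 0.5)
  expect_equal(K["A", "C"], 0.25)                     # parent-offspring
  expect_equal(diag(K), (1 + f_ped(ped)) / 2, ignore_attr = TRUE)
  expect_equal(K, t(K))
  expect_error(kinship_matrix(ped, subset = "nope"), "not in pedigree")
  expect_equal(relationship_matrix(ped), 2 * K)

  # Monte-Carlo single-locus gene-dropping oracle
  oracle <- drop_allele_kinship(ped, n_rep = 40000)
  for (pair in list(c("C", "D"), c("E", "Z"), c("K", "E"), c("A", "Z"))) {
    i <- match(pair[1], ped$id)
    j <- match(pair[2], ped$id)
    est <- oracle$kin(i, j)
    se <- sqrt(est * (1 - est) / 40000) + 1e-4
    expect_lt(abs(est - K[pair[1], pair[2]]), 3 * se + 0.004)
  }
  fE <- oracle$f(match("E", ped$id))
  expect_lt(abs(fE - 0.25), 3 * sqrt(0.25 * 0.75 / 40000) + 0.004)
})

test_that("F_ped is monotone under added inbreeding loops", {
  # half-sib loop only
  base <- pedigree(c("A", "B", "C", "S", "D", "X"),
                   c(NA, NA, NA, "A", "A", "S"),
                   c(NA, NA, NA, "B", "C", "D"))
  # same, plus the dams B and C now share a father -> extra ancestral path
  more <- pedigree(c("G", "H1", "H2", "A", "B", "C", "S", "D", "X"),
                   c(NA, NA, NA, NA, "G", "G", "A", "A", "S"),
                   c(NA, NA, NA, NA, "H1", "H2", "B", "C", "D"))
  expect_gt(f_ped(more)["X"], f_ped(base)["X"])
})

test_that("ancestry tiers classify and nest correctly", {
  ped <- fixture_pedigree()
  tiers <- classify_ancestry(ped)
  expect_equal(as.character(tiers["A"]), "NO_PARENTS")
  # C has both parents known but both are founders -> no grandparents
  expect_equal(as.character(tiers["C"]), "BOTH_PARENTS")
  expect_equal(as.character(tiers["Z"]), "FOUR_GRANDPARENTS")
  # K's dam M2 has sire A known, dam P known -> but sire side M1 also known
  expect_equal(as.character(tiers["K"]), "FOUR_GRANDPARENTS")
  ped1 <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, NA))
  expect_equal(as.character(classify_ancestry(ped1)["C"]), "ONE_PARENT")

  # nesting: FOUR_GRANDPARENTS subset of BOTH_PARENTS_PLUS_MATERNAL_GP subset
  # of BOTH_PARENTS
  in4 <- in_tier(tiers, "FOUR_GRANDPARENTS")
  inm <- in_tier(tiers, "BOTH_PARENTS_PLUS_MATERNAL_GP")
  inb <- in_tier(tiers, "BOTH_PARENTS")
  expect_true(all(!in4 | inm))
  expect_true(all(!inm | inb))
})

test_that("stricter tiers enrich for nonzero F_ped under random link loss", {
  pop <- shared_pop()
  fracs <- sapply(1:6, function(r) {
    ped_del <- delete_pedigree_links(pop$ped, 0.3, seed = r)
    f <- f_ped(ped_del)
    tiers <- classify_ancestry(ped_del)
    c(relaxed = mean(f[in_tier(tiers, "BOTH_PARENTS")] > 0),
      strict = mean(f[in_tier(tiers, "FOUR_GRANDPARENTS")] > 0))
  })
  expect_gt(mean(fracs["strict", ] - fracs["relaxed", ]), 0)
})
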