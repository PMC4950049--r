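#' Construct a validated pedigree
#'
#' A pedigree is a directed acyclic parent map. Individuals referenced as a
#' sire or dam but absent from `id` are auto-added as founders. Unknown
#' parents are coded `NA` (readers also accept `"0"`). The returned object is
#' stored in topological order (parents before offspring), which every
#' downstream algorithm (tabular kinship, gene dropping, Mendelian sampling)
#' relies on.
#'
#' @param id character vector of individual identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` or `"0"`
#'   for unknown.
#' @param cohort optional integer birth cohort (e.g. birth year).
#' @return An object of class `pedigree`, a data.frame with columns
#'   `id`, `sire`, `dam`, `cohort` in topological order, plus integer
#'   attribute columns `sire_idx`/`dam_idx` (0 = unknown).
#' @export
pedigree <- function(id, sire, dam, cohort = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  unk <- function(x) is.na(x) | x == "0" | x == "NA" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (is.null(cohort)) cohort <- rep(NA_integer_, length(id))
  cohort <- as.integer(cohort)

  # auto-add referenced-but-missing parents as founders
  parents <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(parents)) {
    id <- c(id, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
    cohort <- c(cohort, rep(NA_integer_, length(parents)))
  }

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  ord <- topo_order(si, di, id)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    cohort = cohort[ord], stringsAsFactors = FALSE)
  pos <- match(seq_len(n), ord)  # old index -> new position
  remap <- function(p) {
    p <- p[ord]
    p[p > 0L] <- pos[p[p > 0L]]
    p
  }
  ped$sire_idx <- remap(si)
  ped$dam_idx <- remap(di)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort over the parent->offspring DAG; errors on a cycle,
# naming one individual involved.
topo_order <- function(si, di, id) {
  n <- length(id)
  indeg <- integer(n)
  for (p in list(si, di)) {
    known <- p > 0L
    if (any(p == seq_len(n))) {
      stop("pedigree cycle: individual ", id[which(p == seq_len(n))[1]],
           " is its own parent")
    }
    indeg <- indeg + as.integer(known)
  }
  # children lists
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) kids[[si[i]]] <- c(kids[[si[i]]], i)
    if (di[i] > 0L) kids[[di[i]]] <- c(kids[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    stop("pedigree cycle detected involving individual ",
         id[setdiff(seq_len(n), out)[1]])
  }
  out
}

#' Read a pedigree from a text file
#'
#' Whitespace- or tab-separated columns `id sire dam [cohort]`; unknown
#' parents coded `0` or `NA`. A header row is autodetected (non-numeric
#' third field named e.g. `dam` is treated as a header only when it matches
#' the conventional column names).
#'
#' @param path path to the text file.
#' @return a [pedigree] object.
#' @export
read_pedigree <- function(path) {
  first <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  header <- length(first) >= 3 &&
    all(tolower(first[1:3]) %in% c("id", "iid", "animal", "sire", "father",
                                   "dam", "mother", "cohort", "year"))
  tab <- utils::read.table(path, header = header, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("pedigree file needs >= 3 columns (id, sire, dam)")
  cohort <- if (ncol(tab) >= 4) suppressWarnings(as.integer(tab[[4]])) else NULL
  pedigree(tab[[1]], tab[[2]], tab[[3]], cohort)
}

#' Write a pedigree to TSV
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "sire", "dam", "cohort")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Additive (numerator) relationship and kinship matrices
#'
#' Tabular method on the topologically sorted pedigree: processing
#' individuals parents-first, kinship(i, j) for j earlier than i is the mean
#' of the kinships of i's parents with j, and kinship(i, i) = (1 + F_i) / 2
#' with F_i the kinship of i's parents. Unknown parents contribute zero
#' (assumed unrelated, non-inbred founders). The numerator relationship
#' matrix A is twice the kinship matrix.
#'
#' @param ped a [pedigree].
#' @param subset optional character vector of ids for which to return the
#'   (sub)matrix; the computation always runs over the full pedigree.
#' @return symmetric matrix of kinship coefficients, dimnames = ids.
#' @export
kinship_matrix <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_idx
  di <- ped$dam_idx
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fs <- if (si[i] > 0L) K[si[i], ] else numeric(n)
    fd <- if (di[i] > 0L) K[di[i], ] else numeric(n)
    row <- 0.5 * (fs + fd)
    fpar <- if (si[i] > 0L && di[i] > 0L) K[si[i], di[i]] else 0
    if (i > 1L) {
      K[i, 1:(i - 1L)] <- row[1:(i - 1L)]
      K[1:(i - 1L), i] <- row[1:(i - 1L)]
    }
    K[i, i] <- 0.5 * (1 + fpar)
  }
  dimnames(K) <- list(ped$id, ped$id)
  if (!is.null(subset)) {
    miss <- setdiff(subset, ped$id)
    if (length(miss)) stop("subset id(s) not in pedigree: ",
                           paste(miss, collapse = ", "))
    K <- K[subset, subset, drop = FALSE]
  }
  K
}

#' Numerator relationship matrix (A = 2 x kinship)
#' @inheritParams kinship_matrix
#' @export
relationship_matrix <- function(ped, subset = NULL) {
  2 * kinship_matrix(ped, subset)
}

#' Pedigree inbreeding coefficients (F_ped)
#'
#' The expected proportion of the genome identical by descent given the
#' pedigree: the kinship coefficient of an individual's parents. Founders
#' and individuals with any unknown parent get F = 0 (an unknown parent is
#' assumed unrelated, which is exactly the downward bias that motivates
#' comparing F_ped with genomic estimators).
#'
#' @param ped a [pedigree].
#' @return named numeric vector of F in pedigree order.
#' @export
f_ped <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  K <- kinship_matrix(ped)
  f <- numeric(nrow(ped))
  both <- ped$sire_idx > 0L & ped$dam_idx > 0L
  f[both] <- K[cbind(ped$sire_idx[both], ped$dam_idx[both])]
  names(f) <- ped$id
  f
}

#' Ancestry-completeness tiers
#'
#' Classifies each individual by how much immediate ancestry is recorded:
#' `NO_PARENTS`, `ONE_PARENT`, `BOTH_PARENTS`, `BOTH_PARENTS_PLUS_MATERNAL_GP`
#' (both parents and at least one maternal grandparent known) and
#' `FOUR_GRANDPARENTS`. The last three are nested, so analyses can be
#' restricted to increasingly reliable F_ped values at the cost of sample
#' size.
#'
#' @param ped a [pedigree].
#' @return named factor with the tier levels above, in pedigree order.
#' @export
classify_ancestry <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  si <- ped$sire_idx
  di <- ped$dam_idx
  known <- function(i) i > 0L
  n <- nrow(ped)
  tier <- character(n)
  for (i in seq_len(n)) {
    np <- known(si[i]) + known(di[i])
    if (np == 0L) { tier[i] <- "NO_PARENTS"; next }
    if (np == 1L) { tier[i] <- "ONE_PARENT"; next }
    mgs <- si[di[i]]; mgd <- di[di[i]]   # maternal grandparents
    pgs <- si[si[i]]; pgd <- di[si[i]]   # paternal grandparents
    if (known(mgs) && known(mgd) && known(pgs) && known(pgd)) {
      tier[i] <- "FOUR_GRANDPARENTS"
    } else if (known(mgs) || known(mgd)) {
      tier[i] <- "BOTH_PARENTS_PLUS_MATERNAL_GP"
    } else {
      tier[i] <- "BOTH_PARENTS"
    }
  }
  out <- factor(tier, levels = c("NO_PARENTS", "ONE_PARENT", "BOTH_PARENTS",
                                 "BOTH_PARENTS_PLUS_MATERNAL_GP",
                                 "FOUR_GRANDPARENTS"))
  names(out) <- ped$id
  out
}

#' Tier membership including nested (stricter) tiers
#'
#' `BOTH_PARENTS` includes individuals classified into either stricter tier,
#' and `BOTH_PARENTS_PLUS_MATERNAL_GP` includes `FOUR_GRANDPARENTS` whenever
#' a maternal grandparent is among the four.
#'
#' @param tiers factor from [classify_ancestry].
#' @param tier tier name to test membership of.
#' @return logical vector.
#' @export
in_tier <- function(tiers, tier) {
  lv <- levels(tiers)
  stopifnot(tier %in% lv)
  ranks <- match(tiers, lv)
  ranks >= match(tier, lv) & !is.na(ranks)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(x$sire_idx == 0L & x$dam_idx == 0L), "founders\n")
  utils::head(as.data.frame(x)[, c("id", "sire", "dam", "cohort")], 6) |>
    print()
  invisible(x)
}

#' Randomly delete parentage links
#'
#' Each recorded sire and dam link is independently set to unknown with
#' probability `frac`, emulating the incomplete pedigrees of field studies
#' (unobserved mothers, unassigned fathers). Used to study how missing
#' ancestry biases F_ped while genomic estimators are unaffected.
#'
#' @param ped a [pedigree].
#' @param frac per-link deletion probability.
#' @param seed integer seed.
#' @return a new [pedigree] (attributes such as `sex` are carried over).
#' @export
delete_pedigree_links <- function(ped, frac, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), frac >= 0, frac <= 1)
  set.seed(seed)
  sire <- ped$sire
  dam <- ped$dam
  sire[!is.na(sire) & stats::runif(length(sire)) < frac] <- NA_character_
  dam[!is.na(dam) & stats::runif(length(dam)) < frac] <- NA_character_
  out <- pedigree(ped$id, sire, dam, ped$cohort)
  sx <- attr(ped, "sex")
  if (!is.null(sx)) attr(out, "sex") <- sx[out$id]
  out
}

#' Write a kinship matrix as TSV with id header row/column
#' @param K kinship matrix with dimnames.
#' @param path output path.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(data.frame(id = rownames(K), K, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
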