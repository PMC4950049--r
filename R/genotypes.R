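#' Genotype matrix with marker map
#'
#' Container pairing an individuals x markers dosage matrix (copies of the
#' reference allele: 0, 1, 2, or `NA` for a failed call) with a marker map
#' (chromosome, bp position, optional cM position). Dosages are counted with
#' respect to the first-listed allele per marker.
#'
#' @param geno integer/numeric matrix, rows = individuals (rownames = ids),
#'   columns = markers.
#' @param map data.frame with columns `chr`, `snp`, `bp` and optionally `cM`;
#'   one row per genotype column. When `cM` is absent it is derived from bp
#'   at 1 cM ~ 1 Mb.
#' @param alleles optional 2-column character matrix (reference, alternate)
#'   per marker, used when writing PED files.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, map, alleles = NULL) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) stop("map rows must match genotype columns")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  map <- as.data.frame(map)
  if (!all(c("chr", "bp") %in% names(map))) stop("map needs chr and bp columns")
  if (is.null(map$snp)) map$snp <- paste0("snp", seq_len(nrow(map)))
  if (is.null(map$cM)) map$cM <- map$bp / 1e6
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  for (ch in unique(map$chr)) {
    b <- map$bp[map$chr == ch]
    if (any(diff(b) <= 0)) stop("map positions not strictly increasing on chromosome ", ch)
  }
  colnames(geno) <- map$snp
  structure(list(geno = geno, map = map, alleles = alleles),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "markers on", length(unique(x$map$chr)), "chromosome(s)\n")
  cat(sprintf("missing rate %.4f\n", mean(is.na(x$geno))))
  invisible(x)
}

#' Reference-allele frequencies
#'
#' Per-marker frequency of the reference allele among non-missing calls in
#' the current sample.
#'
#' @param gm a [geno_matrix].
#' @return numeric vector, length = number of markers.
#' @export
allele_freq <- function(gm) {
  colMeans(gm$geno, na.rm = TRUE) / 2
}

#' Total assayed genome length in kb
#'
#' Physical span from the first to the last marker summed over chromosomes,
#' the denominator of F_ROH.
#'
#' @param map marker map data.frame (chr, bp).
#' @return length in kb.
#' @export
genome_length_kb <- function(map) {
  sum(tapply(map$bp, map$chr, function(b) (max(b) - min(b)) / 1000))
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' PED: FID IID PAT MAT SEX PHENO then two allele columns per marker, `0`
#' for a missing allele. MAP: chromosome, snp id, cM, bp. Dosage is the
#' count of the first-listed (first non-missing symbol encountered) allele.
#'
#' @param ped_path,map_path file paths.
#' @return a [geno_matrix].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp", "cM", "bp"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop("PED has ", (ncol(ped) - 6) / 2, " markers but MAP lists ", m)
  }
  ids <- ped[[2]]
  geno <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map$snp))
  alleles <- matrix(NA_character_, m, 2)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    obs <- c(rbind(a1, a2))
    obs <- obs[obs != "0"]
    sym <- unique(obs)
    if (length(sym) > 2) {
      stop("marker ", map$snp[j], ": more than two alleles observed (",
           paste(sym, collapse = ","), ")")
    }
    ref <- if (length(sym)) sym[1] else NA_character_
    alt <- if (length(sym) == 2) sym[2] else NA_character_
    alleles[j, ] <- c(ref, alt)
    miss <- a1 == "0" | a2 == "0"
    geno[, j] <- ifelse(miss, NA_integer_,
                        (a1 == ref) + (a2 == ref))
  }
  geno_matrix(geno, map, alleles)
}

#' Write genotypes as PLINK text PED/MAP
#' @param gm a [geno_matrix].
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  map <- gm$map
  utils::write.table(map[, c("chr", "snp", "cM", "bp")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  al <- gm$alleles
  if (is.null(al)) al <- matrix(rep(c("A", "G"), each = ncol(gm$geno)),
                                ncol = 2)
  n <- nrow(gm$geno)
  m <- ncol(gm$geno)
  out <- matrix("0", n, 6 + 2 * m)
  out[, 1] <- "0"
  out[, 2] <- rownames(gm$geno)
  out[, 5] <- "0"
  out[, 6] <- "-9"
  for (j in seq_len(m)) {
    x <- gm$geno[, j]
    a1 <- ifelse(is.na(x), "0", ifelse(x >= 1, al[j, 1], al[j, 2]))
    a2 <- ifelse(is.na(x), "0", ifelse(x == 2, al[j, 1], al[j, 2]))
    out[, 6 + 2 * j - 1] <- a1
    out[, 6 + 2 * j] <- a2
  }
  utils::write.table(out, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a genotype-matrix TSV plus map TSV
#'
#' TSV dialect: first column `id`, remaining columns one marker each with
#' values 0/1/2/NA; map TSV has header `chr snp bp [cM]`.
#'
#' @param geno_path,map_path file paths.
#' @return a [geno_matrix].
#' @export
read_geno_tsv <- function(geno_path, map_path) {
  tab <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  geno <- as.matrix(tab[, -1, drop = FALSE])
  rownames(geno) <- tab[[1]]
  geno_matrix(geno, map)
}

#' Write a genotype-matrix TSV plus map TSV
#' @param gm a [geno_matrix].
#' @param geno_path,map_path output paths.
#' @export
write_geno_tsv <- function(gm, geno_path, map_path) {
  utils::write.table(data.frame(id = rownames(gm$geno), gm$geno,
                                check.names = FALSE),
                     geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Subset a genotype matrix
#' @param gm a [geno_matrix].
#' @param individuals row indices or ids (default all).
#' @param markers column indices or logical mask (default all).
#' @return a [geno_matrix].
#' @export
subset_geno <- function(gm, individuals = NULL, markers = NULL) {
  g <- gm$geno
  map <- gm$map
  al <- gm$alleles
  if (!is.null(individuals)) g <- g[individuals, , drop = FALSE]
  if (!is.null(markers)) {
    g <- g[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    if (!is.null(al)) al <- al[markers, , drop = FALSE]
  }
  geno_matrix(g, map, al)
}
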