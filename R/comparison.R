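#' Pearson correlations between inbreeding estimators
#'
#' Correlation matrix of `F_ped`, `F_hom`, `F_GRM`, `F_ROH` (plus `F_true`
#' when present) on pairwise-complete observations, optionally restricted
#' to an ancestry tier (nested membership via [in_tier]). Constant columns
#' yield `NA` correlations.
#'
#' @param table an [inbreeding_table] data.frame.
#' @param tier tier name (e.g. `"BOTH_PARENTS_PLUS_MATERNAL_GP"`,
#'   `"FOUR_GRANDPARENTS"`) or `NULL` for all individuals.
#' @param listwise use complete cases only instead of pairwise-complete.
#' @return symmetric correlation matrix.
#' @export
estimator_correlations <- function(table, tier = NULL, listwise = FALSE) {
  cols <- intersect(c("F_ped", "F_hom", "F_GRM", "F_ROH", "F_true"),
                    names(table))
  dat <- table
  if (!is.null(tier)) dat <- dat[in_tier(dat$tier, tier), , drop = FALSE]
  if (nrow(dat) < 3) stop("fewer than 3 individuals after tier filter")
  use <- if (listwise) "complete.obs" else "pairwise.complete.obs"
  suppressWarnings(stats::cor(dat[, cols], use = use))
}

#' Fraction of pedigree-noninbred individuals that are genomically inbred
#'
#' Among individuals with F_ped = 0 (within the chosen ancestry tier), the
#' fraction whose genomic estimator exceeds `genomic_threshold` -- inbreeding
#' that the pedigree misses entirely.
#'
#' @param table an [inbreeding_table] data.frame.
#' @param genomic_col `"F_GRM"` or `"F_ROH"`.
#' @param genomic_threshold threshold (default 0.1, which captures
#'   individuals around F = 0.125 and higher).
#' @param fped_zero_only restrict the denominator to F_ped == 0 (default).
#' @param tier optional tier restriction.
#' @return fraction in [0, 1].
#' @export
cryptic_inbreeding_fraction <- function(table, genomic_col = "F_GRM",
                                        genomic_threshold = 0.1,
                                        fped_zero_only = TRUE, tier = NULL) {
  dat <- table
  if (!is.null(tier)) dat <- dat[in_tier(dat$tier, tier), , drop = FALSE]
  if (fped_zero_only) dat <- dat[dat$F_ped == 0, , drop = FALSE]
  dat <- dat[!is.na(dat[[genomic_col]]), , drop = FALSE]
  if (!nrow(dat)) stop("empty denominator: no qualifying individuals")
  mean(dat[[genomic_col]] > genomic_threshold)
}

#' Estimator stability under marker subsampling
#'
#' For each fraction and replicate, recomputes F_hom and F_GRM on a random
#' marker subset and correlates them with the full-panel values (and
#' optionally with a trait). Shows how many markers are needed before the
#' genomic estimators stabilize.
#'
#' @param gm a [geno_matrix] (QC'd).
#' @param fractions marker fractions in (0, 1].
#' @param n_reps replicates per fraction.
#' @param seed integer seed.
#' @param trait optional named numeric vector to correlate against as well.
#' @return data.frame: fraction, estimator, mean_r, sd_r (and trait
#'   columns when `trait` is given).
#' @export
marker_subsampling_curve <- function(gm, fractions = c(0.1, 0.3, 0.5, 0.75, 1),
                                     n_reps = 10, seed = 1, trait = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  set.seed(seed)
  m <- ncol(gm$geno)
  full_hom <- f_hom(gm)
  p <- allele_freq(gm)
  poly <- p > 0 & p < 1
  full_grm <- f_grm(subset_geno(gm, markers = which(poly)))
  rows <- list()
  for (fr in fractions) {
    r_hom <- r_grm <- rt_hom <- rt_grm <- numeric(n_reps)
    for (b in seq_len(n_reps)) {
      sub <- sort(sample.int(m, max(2, round(fr * m))))
      gsub <- subset_geno(gm, markers = sub)
      fh <- f_hom(gsub)
      psub <- allele_freq(gsub)
      fg <- f_grm(subset_geno(gsub, markers = which(psub > 0 & psub < 1)))
      r_hom[b] <- stats::cor(fh, full_hom, use = "pairwise.complete.obs")
      r_grm[b] <- stats::cor(fg, full_grm, use = "pairwise.complete.obs")
      if (!is.null(trait)) {
        ids <- intersect(names(trait), names(fh))
        rt_hom[b] <- stats::cor(fh[ids], trait[ids], use = "pairwise.complete.obs")
        rt_grm[b] <- stats::cor(fg[ids], trait[ids], use = "pairwise.complete.obs")
      }
    }
    add <- function(est, r, rt) {
      out <- data.frame(fraction = fr, estimator = est,
                        mean_r = mean(r), sd_r = stats::sd(r))
      if (!is.null(trait)) {
        out$mean_r_trait <- mean(rt)
        out$sd_r_trait <- stats::sd(rt)
      }
      out
    }
    rows[[length(rows) + 1]] <- add("F_hom", r_hom, rt_hom)
    rows[[length(rows) + 1]] <- add("F_GRM", r_grm, rt_grm)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a simulated (or supplied) dataset
#'
#' Orchestrates simulate -> QC -> LD pruning -> estimators -> g2 ->
#' estimator comparison (and, optionally, depression models), writing all
#' tables, a run log with seeds, and a markdown summary to `outdir`.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config list with components `cfg` (a [sim_config]; used when no
#'   data supplied), optional `data` (list `ped`, `gm`, plus optional
#'   `true_ibd`, `traits`), `seed`, `outdir`, and logical switches
#'   `run_g2`, `run_models`.
#' @return invisibly, a list with every intermediate object.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "setup"
  res <- list(seed = seed)
  tryCatch({
    cat(sprintf("pipeline seed %d\n", seed), file = log_path)
    if (is.null(config$data)) {
      stage <- "simulate"
      pop <- simulate_population(config$cfg %||% sim_config(), seed = seed)
      logf(stage, "simulated %d individuals, %d SNPs", nrow(pop$ped),
           ncol(pop$gm$geno))
      write_pedigree(pop$ped, file.path(outdir, "pedigree.tsv"))
      utils::write.table(
        data.frame(id = names(pop$true_ibd), true_ibd = pop$true_ibd),
        file.path(outdir, "true_ibd.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(pop$traits, file.path(outdir, "traits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      pop <- config$data
      if (is.null(pop$ped) || is.null(pop$gm)) {
        stop("supplied data must include ped and gm")
      }
    }
    res$pop <- pop

    stage <- "qc"
    qc <- qc_filter(pop$gm)
    logf(stage, "QC kept %d/%d individuals, %d/%d loci",
         qc$report$n_ind_out, qc$report$n_ind_in,
         qc$report$n_loci_out, qc$report$n_loci_in)
    write_qc_report(qc$report, file.path(outdir, "qc_report.tsv"))
    res$qc <- qc

    stage <- "ld_prune"
    kept <- ld_prune_vif(qc$gm)
    gm_pruned <- subset_geno(qc$gm, markers = kept)
    logf(stage, "pruned to %d markers (VIF <= 10, MAF >= 0.05)", length(kept))
    res$gm_pruned <- gm_pruned

    stage <- "estimators"
    tab <- inbreeding_table(pop$ped, qc$gm, gm_pruned,
                            true_ibd = pop$true_ibd)
    segs <- detect_roh(gm_pruned)
    utils::write.table(segs, file.path(outdir, "roh_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab, file.path(outdir, "inbreeding_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf(stage, "%d ROH segments; inbreeding table for %d individuals",
         nrow(segs), nrow(tab))
    res$inbreeding <- tab
    res$roh <- segs

    if (isTRUE(config$run_g2 %||% TRUE)) {
      stage <- "g2"
      g2 <- g2_estimate(qc$gm, n_boot = config$n_boot %||% 200,
                        n_perm = config$n_perm %||% 200, seed = seed)
      logf(stage, "g2 = %.5f +- %.5f (P = %.4g)", g2$g2, g2$bootstrap_sd,
           g2$permutation_p)
      res$g2 <- g2
    }

    stage <- "comparison"
    cors <- estimator_correlations(tab, tier = "BOTH_PARENTS_PLUS_MATERNAL_GP")
    write_kinship(round(cors, 4), file.path(outdir, "estimator_correlations.tsv"))
    res$correlations <- cors
    res$cryptic <- c(
      F_GRM = cryptic_inbreeding_fraction(tab, "F_GRM"),
      F_ROH = cryptic_inbreeding_fraction(tab, "F_ROH"))
    logf(stage, "cryptic inbreeding fractions: F_GRM %.4f, F_ROH %.4f",
         res$cryptic["F_GRM"], res$cryptic["F_ROH"])

    if (isTRUE(config$run_models %||% FALSE)) {
      stage <- "models"
      if (is.null(pop$traits)) stop("trait table missing")
      mf <- animal_model(pop$traits, "august_weight", pop$ped)
      write_model_fit(mf, file.path(outdir, "august_weight_fit.tsv"))
      logf(stage, "august weight: beta_ind %.2f (SE %.2f), beta_mat %.2f",
           mf$fixed$estimate[mf$fixed$term == ".f_ind"],
           mf$fixed$se[mf$fixed$term == ".f_ind"],
           mf$fixed$estimate[mf$fixed$term == ".f_mat"])
      res$weight_fit <- mf
    }

    stage <- "summary"
    writeLines(pipeline_summary(res), file.path(outdir, "summary.md"))
    logf(stage, "done")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_summary <- function(res) {
  tab <- res$inbreeding
  lines <- c(
    "# Inbreeding analysis summary", "",
    sprintf("Seed: %d", res$seed),
    sprintf("Individuals in inbreeding table: %d", nrow(tab)),
    sprintf("Mean (SD) F_ped: %.4f (%.4f); F_GRM: %.4f (%.4f); F_ROH: %.4f (%.4f)",
            mean(tab$F_ped), stats::sd(tab$F_ped),
            mean(tab$F_GRM, na.rm = TRUE), stats::sd(tab$F_GRM, na.rm = TRUE),
            mean(tab$F_ROH, na.rm = TRUE), stats::sd(tab$F_ROH, na.rm = TRUE)),
    sprintf("ROH segments: %d", nrow(res$roh)), "",
    "## Estimator correlations (both parents + maternal grandparent tier)", "",
    paste(utils::capture.output(print(round(res$correlations, 3))),
          collapse = "\n"), "",
    sprintf("Cryptic inbreeding (F_ped = 0, genomic F > 0.1): F_GRM %.4f, F_ROH %.4f",
            res$cryptic["F_GRM"], res$cryptic["F_ROH"]))
  if (!is.null(res$g2)) {
    lines <- c(lines, "",
               sprintf("g2 = %.5f +- %.5f (permutation P = %.4g)",
                       res$g2$g2, res$g2$bootstrap_sd, res$g2$permutation_p))
  }
  lines
}
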