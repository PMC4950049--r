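#' Age-correct birthweight via a cubic capture-age polynomial
#'
#' Lambs are weighed up to several days after birth, so capture weight
#' confounds birthweight with early growth. Records captured more than
#' `max_age` days after birth are excluded; a third-order polynomial of
#' weight on age (days) is fitted to the rest and its residuals returned as
#' age-corrected birthweights.
#'
#' @param age capture age in days (>= 0).
#' @param weight capture weight.
#' @param max_age latest usable capture age in days (default 10).
#' @return list: `residual` (NA for excluded/missing records), `fit` (the
#'   `lm` object), `used` (logical mask of records entering the fit).
#' @export
correct_birthweight_for_age <- function(age, weight, max_age = 10) {
  stopifnot(length(age) == length(weight))
  if (any(age < 0, na.rm = TRUE)) stop("ages must be >= 0")
  used <- !is.na(age) & !is.na(weight) & age <= max_age
  if (sum(used) < 8) stop("need >= 8 usable records to fit a cubic")
  dat <- data.frame(age = age[used], weight = weight[used])
  fit <- stats::lm(weight ~ poly(age, 3, raw = TRUE), data = dat)
  res <- rep(NA_real_, length(age))
  res[used] <- stats::resid(fit)
  list(residual = res, fit = fit, used = used)
}

# Upper-Cholesky factor of a relationship matrix over given levels, with a
# small ridge so pedigree A matrices (PSD up to rounding) always factor.
rel_factor <- function(A, levels) {
  miss <- setdiff(levels, rownames(A))
  if (length(miss)) stop("relationship matrix missing levels: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  M <- A[levels, levels, drop = FALSE]
  chol(M + diag(1e-8, nrow(M)))
}

#' Linear mixed model with pedigree-structured random effects (animal model)
#'
#' REML fit of an lme4-style formula in which named grouping factors carry a
#' relationship-matrix covariance: for a factor `g` listed in `relmat`, the
#' random effect is u ~ N(0, sigma^2 A_g) instead of iid. The random-effect
#' design matrix is post-multiplied by the Cholesky factor of A_g (so the
#' standard iid machinery estimates the transformed effects), which leaves
#' the REML criterion identical to the explicit mixed-model-equation
#' formulation. This is the standard quantitative-genetics animal model:
#' an additive genetic effect structured by the numerator relationship
#' matrix, plus e.g. year, maternal genetic (dam factor with A), and
#' maternal environment (iid dam factor) effects.
#'
#' Fixed effects are tested with Wald statistics (z and the equivalent
#' 1-df F = z^2). Fits that fail lme4 convergence checks are returned
#' flagged, not as errors.
#'
#' @param formula lme4 formula, e.g.
#'   `y ~ F_ind + F_mat + sex + (1|year) + (1|id) + (1|dam_gen) + (1|dam_env)`.
#' @param data model frame; grouping variables must be factors or coercible.
#' @param relmat named list of relationship matrices (dimnames = ids) keyed
#'   by grouping-factor name, e.g. `list(id = A, dam_gen = A)`.
#' @return object of class `model_fit`.
#' @export
fit_lmm_reml <- function(formula, data, relmat = list()) {
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  parsed <- lme4::lFormula(formula, data = data, REML = TRUE, control = ctrl)
  reTrms <- parsed$reTrms
  fnms <- names(reTrms$cnms)
  for (nm in names(relmat)) {
    hit <- which(fnms == nm)
    if (!length(hit)) stop("no random term uses grouping factor ", nm)
    for (ti in hit) {
      rows <- (reTrms$Gp[ti] + 1):reTrms$Gp[ti + 1]
      levs <- levels(reTrms$flist[[nm]])
      R <- rel_factor(relmat[[nm]], levs)
      reTrms$Zt[rows, ] <- as(R %*% reTrms$Zt[rows, , drop = FALSE],
                              "CsparseMatrix")
    }
  }
  parsed$reTrms <- reTrms
  devfun <- do.call(lme4::mkLmerDevfun, parsed)
  opt <- lme4::optimizeLmer(devfun,
                            optimizer = "bobyqa",
                            control = list(rhobeg = 0.4, rhoend = 1e-5,
                                           maxfun = 100000))
  fit <- lme4::mkMerMod(environment(devfun), opt, reTrms, fr = parsed$fr)
  as_model_fit(fit, converged = is.null(fit@optinfo$conv$lme4$messages) &&
                 opt$conv == 0)
}

#' Generalized linear mixed model for fitness components
#'
#' Laplace-approximation GLMM (binomial-logit for survival, Poisson-log for
#' breeding success) with iid random intercepts (year, mother, individual
#' for repeated measures). Slopes are reported with Wald 95% intervals.
#' Complete separation / degenerate fits are flagged via huge standard
#' errors rather than raised.
#'
#' @param formula lme4 formula with random intercepts.
#' @param data model frame.
#' @param family `"binomial"` or `"poisson"` (or a family object).
#' @return object of class `model_fit`.
#' @export
fit_glmm <- function(formula, data, family = "binomial") {
  if (is.character(family)) {
    family <- switch(family,
                     binomial = stats::binomial(),
                     poisson = stats::poisson(),
                     stop("unsupported family: ", family))
  }
  fit <- suppressMessages(lme4::glmer(
    formula, data = data, family = family,
    control = lme4::glmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE)))
  mf <- as_model_fit(fit, converged = is.null(fit@optinfo$conv$lme4$messages))
  mf$separation <- any(mf$fixed$se > 25 & abs(mf$fixed$estimate) > 25)
  if (mf$separation) mf$converged <- FALSE
  mf
}

# Shared extraction into the package's fit container.
as_model_fit <- function(fit, converged = TRUE) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                          vc$grp))
  structure(list(
    fixed = data.frame(term = names(b), estimate = unname(b), se = unname(se),
                       z = unname(z), wald_F = unname(z^2), p = unname(p),
                       ci_lo = unname(b - 1.96 * se),
                       ci_hi = unname(b + 1.96 * se),
                       stringsAsFactors = FALSE),
    varcomp = comp,
    n_obs = stats::nobs(fit),
    logLik = as.numeric(stats::logLik(fit)),
    REML = lme4::isREML(fit),
    converged = converged,
    fit = fit), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Mixed-model fit (%s, %d obs)%s\n",
              if (x$REML) "REML" else "ML/Laplace", x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  f <- x$fixed
  f[, c("estimate", "se", "z", "p", "ci_lo", "ci_hi")] <-
    signif(f[, c("estimate", "se", "z", "p", "ci_lo", "ci_hi")], 4)
  print(f[, c("term", "estimate", "se", "z", "p", "ci_lo", "ci_hi")],
        row.names = FALSE)
  cat("variance components:\n")
  print(signif(x$varcomp, 4))
  invisible(x)
}

#' Write a model fit as TSV
#' @param mf a `model_fit`.
#' @param path output path.
#' @export
write_model_fit <- function(mf, path) {
  utils::write.table(mf$fixed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Convenience animal-model fit of a trait on individual and maternal F
#'
#' Builds the standard structure: fixed effects for the chosen inbreeding
#' column, the dam's inbreeding, sex (plus extra covariates); random
#' effects for year, additive genetic (pedigree A), maternal genetic
#' (dam factor with A) and maternal environment (iid dam factor).
#'
#' @param data trait table with columns `id`, `dam`, `year`, `sex`, the
#'   response, and the F columns.
#' @param response response column name.
#' @param ped a [pedigree] for the relationship matrix.
#' @param f_ind,f_mat column names of individual and maternal F.
#' @param extra_fixed character vector of additional fixed-effect columns.
#' @param maternal include maternal F and maternal random effects
#'   (default TRUE; requires known dams).
#' @return a `model_fit`.
#' @export
animal_model <- function(data, response, ped, f_ind = "F_true",
                         f_mat = "F_true_dam", extra_fixed = "sex",
                         maternal = TRUE) {
  dat <- data
  dat$.y <- dat[[response]]
  dat$.f_ind <- dat[[f_ind]]
  dat$id <- factor(dat$id)
  dat$year <- factor(dat$year)
  A <- relationship_matrix(ped)
  if (maternal) {
    dat <- dat[dat$has_dam & !is.na(dat[[f_mat]]), , drop = FALSE]
    dat$.f_mat <- dat[[f_mat]]
    dat$dam_gen <- factor(dat$dam)
    dat$dam_env <- factor(dat$dam)
    rhs <- paste(c(".f_ind", ".f_mat", extra_fixed,
                   "(1|year)", "(1|id)", "(1|dam_gen)", "(1|dam_env)"),
                 collapse = " + ")
    relmat <- list(id = A, dam_gen = A)
  } else {
    rhs <- paste(c(".f_ind", extra_fixed, "(1|year)", "(1|id)"),
                 collapse = " + ")
    relmat <- list(id = A)
  }
  fit_lmm_reml(stats::as.formula(paste(".y ~", rhs)), dat, relmat = relmat)
}

#' Percent trait change per increment of inbreeding
#'
#' Converts a fitted slope on F into the percent change in the trait mean
#' for an increase of `deltaF` in inbreeding:
#' 100 * |slope| * deltaF / trait_mean.
#'
#' @param slope fitted slope of the trait on F.
#' @param trait_mean population trait mean (nonzero).
#' @param deltaF inbreeding increment (default 0.1).
#' @return percent change (nonnegative).
#' @export
pct_change_per_deltaF <- function(slope, trait_mean, deltaF = 0.1) {
  if (any(trait_mean == 0)) stop("trait mean must be nonzero")
  100 * abs(slope) * deltaF / abs(trait_mean)
}

#' Percent odds reduction per increment of inbreeding
#'
#' For a logit-link slope, the percent reduction in the odds of the outcome
#' for an increase of `deltaF` in inbreeding: 100 * (1 - exp(deltaF * slope)).
#'
#' @param logit_slope slope on the logit scale (finite).
#' @param deltaF inbreeding increment (default 0.1).
#' @return percent reduction (negative slopes give positive reductions).
#' @export
odds_reduction_per_deltaF <- function(logit_slope, deltaF = 0.1) {
  stopifnot(is.finite(logit_slope))
  100 * (1 - exp(deltaF * logit_slope))
}
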