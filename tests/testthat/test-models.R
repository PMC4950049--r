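test_that("birthweight age-correction fits a cubic and excludes late captures", {
  set.seed(51)
  n <- 500
  age <- sample(0:14, n, replace = TRUE)
  bw <- rnorm(n, 2.08, 0.6)
  truth <- c(0.25, 0.01, -0.002)
  wt <- bw + truth[1] * age + truth[2] * age^2 + truth[3] * age^3
  out <- correct_birthweight_for_age(age, wt)
  expect_true(all(is.na(out$residual[age > 10])))
  expect_false(any(is.na(out$residual[age <= 10])))
  co <- summary(out$fit)$coefficients
  for (k in 1:3) {
    expect_lt(abs(co[k + 1, "Estimate"] - truth[k]), 3 * co[k + 1, "Std. Error"])
  }
  # residuals recover birthweight variation up to the grand mean
  expect_gt(stats::cor(out$residual[age <= 10], bw[age <= 10]), 0.95)

  # weight independent of age: residuals are weight minus the mean
  wt2 <- rnorm(n, 10, 1)
  out2 <- correct_birthweight_for_age(age, wt2)
  use <- age <= 10
  expect_lt(max(abs(out2$residual[use] - (wt2[use] - mean(wt2[use])))), 0.5)
  expect_error(correct_birthweight_for_age(rep(2, 5), rnorm(5)), ">= 8")
  expect_error(correct_birthweight_for_age(-1:6, rnorm(8)), ">= 0")
})

test_that("REML reduces to OLS when random variances vanish", {
  set.seed(61)
  n <- 200
  dat <- data.frame(x = rnorm(n), year = factor(sample(1:8, n, TRUE)))
  dat$y <- 2 + 3 * dat$x + rnorm(n)  # no year effect at all
  mf <- fit_lmm_reml(y ~ x + (1 | year), dat)
  ols <- stats::lm(y ~ x, dat)
  expect_equal(mf$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-3)
  expect_lt(mf$varcomp[["year"]], 0.05)
})

test_that("REML fixed effects equal closed-form GLS at the estimated variances", {
  set.seed(62)
  n <- 300
  year <- factor(sample(1:10, n, TRUE))
  x <- rnorm(n)
  u <- rnorm(10, 0, 1.5)
  y <- 1 + 2.5 * x + u[as.integer(year)] + rnorm(n)
  dat <- data.frame(y, x, year)
  mf <- fit_lmm_reml(y ~ x + (1 | year), dat)
  Z <- stats::model.matrix(~ year - 1, dat)
  V <- mf$varcomp[["year"]] * tcrossprod(Z) +
    mf$varcomp[["residual"]] * diag(n)
  X <- stats::model.matrix(~x, dat)
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(mf$fixed$estimate, as.numeric(beta_gls), tolerance = 1e-4)
})

test_that("REML estimates are invariant to record order and rescale affinely", {
  set.seed(63)
  n <- 250
  dat <- data.frame(x = rnorm(n), year = factor(sample(1:6, n, TRUE)))
  dat$y <- 1 + 2 * dat$x + rnorm(6, 0, 1)[as.integer(dat$year)] + rnorm(n)
  m1 <- fit_lmm_reml(y ~ x + (1 | year), dat)
  perm <- sample(n)
  m2 <- fit_lmm_reml(y ~ x + (1 | year), dat[perm, ])
  expect_equal(m1$fixed$estimate, m2$fixed$estimate, tolerance = 1e-5)
  expect_equal(m1$varcomp, m2$varcomp, tolerance = 1e-4)
  dat$x10 <- dat$x / 10
  m3 <- fit_lmm_reml(y ~ x10 + (1 | year), dat)
  expect_equal(m3$fixed$estimate[2], m1$fixed$estimate[2] * 10,
               tolerance = 1e-3)
})

test_that("the animal model recovers simulated inbreeding depression slopes", {
  cfg <- sim_config(n_cohorts = 6, n_founder_females = 30,
                    n_founder_males = 15, offspring_per_cohort = 70,
                    close_mating_rate = 0.15, n_chr = 6, total_cM = 150,
                    n_snps = 60)
  ped <- simulate_pedigree(cfg, seed = 71)
  ibd <- gene_drop(ped, cfg, seed = 72, genotypes = FALSE)$true_ibd
  tr <- simulate_traits(ped, ibd, cfg, seed = 73)
  mf <- animal_model(tr, "august_weight", ped)
  expect_true(mf$converged)
  bi <- mf$fixed[mf$fixed$term == ".f_ind", ]
  bm <- mf$fixed[mf$fixed$term == ".f_mat", ]
  expect_lt(abs(bi$estimate - (-8.36)), 3 * bi$se)
  expect_lt(abs(bm$estimate - (-7.89)), 3 * bm$se)
  expect_true(all(mf$varcomp >= 0))
  expect_true(all(mf$fixed$se > 0))
  # Wald F is the squared z statistic
  expect_equal(mf$fixed$wald_F, mf$fixed$z^2)
})

test_that("GLMMs recover link-scale slopes and flag separation", {
  set.seed(81)
  n <- 800
  Fv <- stats::rbeta(n, 0.4, 4) * 0.4
  year <- factor(sample(1:8, n, TRUE))
  u <- rnorm(8, 0, 0.5)
  eta <- 0.5 - 8 * Fv + u[as.integer(year)]
  dat <- data.frame(y = rbinom(n, 1, stats::plogis(eta)), F_ind = Fv, year)
  mf <- fit_glmm(y ~ F_ind + (1 | year), dat, family = "binomial")
  sl <- mf$fixed[mf$fixed$term == "F_ind", ]
  expect_lt(abs(sl$estimate - (-8)), 3 * sl$se)
  expect_false(mf$separation)

  # Poisson intercept recovery
  datp <- data.frame(y = rpois(n, exp(0.3 + u[as.integer(year)])), year)
  mp <- fit_glmm(y ~ 1 + (1 | year), datp, family = "poisson")
  ip <- mp$fixed[1, ]
  expect_lt(abs(ip$estimate - 0.3), 3 * max(ip$se, 0.17))

  # complete separation is flagged, not raised
  sep <- data.frame(y = rep(c(0, 1), each = 30),
                    x = rep(c(0, 1), each = 30),
                    g = factor(rep(1:6, 10)))
  ms <- suppressMessages(suppressWarnings(
    fit_glmm(y ~ x + (1 | g), sep, family = "binomial")))
  expect_true(ms$separation || max(ms$fixed$se) > 25)
  expect_error(fit_glmm(y ~ x + (1 | g), sep, family = "gamma"),
               "unsupported family")
})

test_that("effect-size conversions reproduce the discussion arithmetic", {
  # percent change per 10% increase in F, from the trait-table inputs
  expect_equal(round(pct_change_per_deltaF(-8.36, 13.18), 1), 6.3)
  expect_equal(round(pct_change_per_deltaF(-4.04, 13.18), 1), 3.1)
  expect_equal(round(pct_change_per_deltaF(-28.03, 159.48), 1), 1.8)
  expect_equal(round(pct_change_per_deltaF(-15.05, 159.48), 1), 0.9)
  expect_equal(pct_change_per_deltaF(0, 5), 0)
  expect_error(pct_change_per_deltaF(1, 0), "nonzero")

  # odds-scale reduction for survival
  expect_equal(round(odds_reduction_per_deltaF(-22.66)), 90)
  expect_equal(odds_reduction_per_deltaF(0), 0)
  expect_gt(odds_reduction_per_deltaF(-200), 99.99)
  expect_error(odds_reduction_per_deltaF(Inf), "is.finite")
})
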