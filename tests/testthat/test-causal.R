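test_that("first-stage F follows its null expectation and passes on real signal", {
  set.seed(13)
  fs <- replicate(300, {
    g <- rbinom(500, 1, 0.3)
    lpa <- rlnorm(500)
    validate_instrument(g, lpa)$f_statistic
  })
  expect_lt(abs(mean(fs) - 1), 0.2)  # E[F(1, n-2)] = (n-2)/(n-4)
  # default generator: relevance passes comfortably
  cfg <- quick_config(n = 2000, seed = 19)
  g <- simulate_genotypes(cfg)
  coh <- simulate_exposures(g, cfg)
  grp <- grs_groups01(build_grs(g))
  chk <- validate_instrument(grp, coh$lpa,
                             confounders = coh[, c("age", "sex", "bmi")])
  expect_true(chk$relevance_pass)
  expect_gt(chk$f_statistic, 10)
  expect_equal(nrow(chk$independence_table), 3)
  # covariates are generated independent of genotype: screen should be null
  expect_true(all(chk$independence_table$p > 0.001))
  # exact determination reports the +Inf sentinel
  g2 <- c(rep(0, 5), rep(1, 5))
  chk2 <- validate_instrument(g2, exp(g2))
  expect_identical(chk2$f_statistic, Inf)
  expect_true(chk2$relevance_pass)
})

test_that("MR group-contrast ratio and two-stage estimator agree where they must", {
  # arithmetic: outcome diff 0.5 over exposure diff 10 -> 0.05 per unit
  g <- rep(c(0, 1), each = 20)
  expo <- ifelse(g == 1, 20, 10) + rep(c(-0.5, 0.5), 20)
  outc <- ifelse(g == 1, 1.5, 1.0) + rep(c(-0.01, 0.01), 20)
  est <- mr_estimate(g, expo, outc, method = "grs_contrast", boot_reps = 0)
  expect_equal(est$estimate, 0.05, tolerance = 1e-12)
  # binary instrument, no covariates: two-stage == contrast exactly
  est2 <- mr_estimate(g, expo, outc, method = "two_stage", boot_reps = 0)
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-12)
  # affine rescaling of the outcome rescales the estimate
  est3 <- mr_estimate(g, expo, 3 * outc + 7, method = "two_stage", boot_reps = 0)
  expect_equal(est3$estimate, 3 * est2$estimate, tolerance = 1e-12)
  # degenerate exposure contrast is a weak-instrument error
  expect_error(mr_estimate(g, rep(5, 40), outc, boot_reps = 0),
               "weak instrument")
})

test_that("two-stage MR recovers the generator's eNOS slope with a calibrated CI", {
  cfg <- quick_config(n = 20000, seed = 29)
  g <- simulate_genotypes(cfg)
  coh <- simulate_exposures(g, cfg)
  coh <- derive_redox_indices(coh)
  grp <- grs_groups01(build_grs(g))
  nd <- coh$diabetes == 0
  est <- mr_estimate(grp[nd], coh$lpa[nd], coh$lname_delta_derived[nd],
                     method = "two_stage", boot_reps = 400, seed = 3)
  theta <- cfg$redox_params$theta_lpa_enos
  expect_true(est$ci[1] <= theta && theta <= est$ci[2])
  expect_lt(abs(est$estimate - theta) / theta, 0.10)
})

test_that("MR-Egger reduces to exact identities in structured cases", {
  set.seed(17)
  bx <- runif(7, 0.2, 1)
  sex <- rep(0.05, 7); sey <- runif(7, 0.05, 0.2)
  # exact proportionality: slope = theta, intercept = 0, p = 1
  eg <- mr_egger(bx, sex, 0.7 * bx, sey)
  expect_equal(eg$slope, 0.7, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$intercept_p, 1, tolerance = 1e-8)
  # single variant with intercept constrained: the Wald ratio
  eg1 <- mr_egger(bx[1], sex[1], 0.31, sey[1], intercept = FALSE)
  expect_equal(eg1$slope, 0.31 / bx[1], tolerance = 1e-12)
  # fewer than 3 variants cannot support intercept inference
  expect_error(mr_egger(bx[1:2], sex[1:2], bx[1:2], sey[1:2]), "3 variants")
})

test_that("MR-Egger equals the hand-computed weighted normal equations", {
  bx <- c(0.4, 0.8, 1.3)
  by <- c(0.35, 0.60, 1.10)
  sy <- c(0.10, 0.05, 0.20)
  eg <- mr_egger(bx, rep(0.05, 3), by, sy)
  hand <- hand_wls(bx, by, 1 / sy^2)
  expect_equal(eg$slope, hand$slope, tolerance = 1e-12)
  expect_equal(eg$intercept, hand$intercept, tolerance = 1e-12)
  # hand dispersion: weighted residual mean square on k - 2 df
  w <- 1 / sy^2
  res <- by - hand$intercept - hand$slope * bx
  s2 <- sum(w * res^2) / (3 - 2)
  expect_equal(eg$dispersion, s2, tolerance = 1e-12)
  expect_equal(eg$slope_se, hand$se_slope * sqrt(s2), tolerance = 1e-12)
  expect_equal(eg$intercept_se, hand$se_intercept * sqrt(s2), tolerance = 1e-12)
})

test_that("constraining the Egger intercept to zero gives the IVW estimate", {
  set.seed(18)
  for (i in 1:10) {
    k <- sample(3:9, 1)
    bx <- runif(k, 0.1, 1); by <- rnorm(k, 0.5 * bx, 0.1)
    sy <- runif(k, 0.05, 0.3)
    eg0 <- mr_egger(bx, rep(0.05, k), by, sy, intercept = FALSE)
    ivw <- sum(by / sy^2 * bx) / sum(bx^2 / sy^2)
    expect_equal(eg0$slope, ivw, tolerance = 1e-12)
  }
})

test_that("variants are oriented to the exposure-increasing allele before Egger", {
  bx <- c(0.4, -0.8, 1.3)
  by <- 0.5 * bx
  eg <- mr_egger(bx, rep(0.05, 3), by, rep(0.1, 3))
  expect_equal(eg$slope, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
})

test_that("a no-mediation generator shows no attenuation of a direct effect", {
  cfg <- quick_config(n = 20000, seed = 37,
                      survival_params = list(baseline_rate = 5e-4,
                                             beta_o2 = 0, beta_lpa_direct = 0.6,
                                             beta_age = 0, beta_diabetes = 0,
                                             censor_rate = 0.12,
                                             max_followup_years = 10))
  g <- simulate_genotypes(cfg)
  coh <- simulate_survival(simulate_exposures(g, cfg), cfg)
  grp <- grs_groups01(build_grs(g))
  keep <- !is.na(grp)
  md <- mediation_cox(coh$followup_years[keep], coh$cv_death[keep],
                      grp[keep], log(coh$basal_o2[keep]))
  expect_gt(md$unadjusted$ci[1], 1)       # unadjusted effect present
  expect_gt(md$mediator_adjusted$ci[1], 1)  # and survives adjustment
  expect_lt(abs(md$attenuation_pct), 20)
})

test_that("partial mediation attenuates the exposure effect without removing it", {
  cfg <- quick_config(n = 20000, seed = 41,
                      survival_params = list(baseline_rate = 1e-5,
                                             beta_o2 = 1, beta_lpa_direct = 0.4,
                                             beta_age = 0, beta_diabetes = 0,
                                             censor_rate = 0.12,
                                             max_followup_years = 10))
  g <- simulate_genotypes(cfg)
  coh <- simulate_survival(simulate_exposures(g, cfg), cfg)
  grp <- grs_groups01(build_grs(g))
  keep <- !is.na(grp)
  md <- mediation_cox(coh$followup_years[keep], coh$cv_death[keep],
                      grp[keep], log(coh$basal_o2[keep]))
  expect_gt(md$attenuation_pct, 0)
  expect_lt(md$attenuation_pct, 100)
})
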