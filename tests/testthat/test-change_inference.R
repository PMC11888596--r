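test_that("first-difference coefficients equal the within estimator", {
  fix <- make_fem_fixture(n = 600, seed = 2,
                          beta = c(smoking = -0.3, alcohol = 0.1,
                                   diet = -0.2, exercise = 0, sleep = 0.05))
  spec <- fix$spec; spec$variant <- "standard"
  fem <- fit_fem(fix$data, fix$ba, fix$hli, spec)
  oracle <- within_estimator(fix)
  expect_equal(fem$estimate, unname(oracle[fem$term]), tolerance = 1e-10)
})

test_that("a known single-factor effect is recovered", {
  fix <- make_fem_fixture(n = 4000, seed = 5)
  fem <- fit_fem(fix$data, fix$ba, fix$hli, fix$spec)
  diet <- fem[fem$term == "healthy_diet", ]
  expect_lt(abs(diet$estimate - (-0.2)), 3 * diet$se)
  expect_equal(fem$ci_low, fem$estimate - 1.96 * fem$se, tolerance = 1e-12)
})

test_that("exposures without within-person variation are an error", {
  fix <- make_fem_fixture(n = 200, seed = 7)
  frozen <- fix$hli
  w0_smoking <- frozen$healthy_smoking[frozen$wave == 0]
  frozen$healthy_smoking[frozen$wave == 1] <- w0_smoking
  expect_error(fit_fem(fix$data, fix$ba, frozen, fix$spec),
               "no within-person variation.*smoking")
})

test_that("a time-constant covariate differences to zero and is dropped", {
  fix <- make_fem_fixture(n = 500, seed = 8)
  fix$data$height <- rep(rnorm(500, 165, 8), 2)  # identical both waves
  spec <- fix$spec
  spec$time_varying <- "height"
  expect_warning(fem2 <- fit_fem(fix$data, fix$ba, fix$hli, spec),
                 "no variation.*height")
  fem1 <- fit_fem(fix$data, fix$ba, fix$hli, fix$spec)
  expect_equal(fem1$estimate, fem2$estimate, tolerance = 1e-12)
})

test_that("Cochran's Q matches hand computation and the boundary rule", {
  # strata (-0.5, 0.1) with SE 0.1: weights 100, pooled mean -0.2,
  # Q = 100*0.09 + 100*0.09 = 18
  q <- cochran_q(c(-0.5, 0.1), c(0.1, 0.1))
  expect_equal(q$Q, 18, tolerance = 1e-12)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(18, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(q$significant)

  same <- cochran_q(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(same$Q, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  expect_error(cochran_q(c(0, 1), c(0, 1)), "positive")
  expect_error(cochran_q(0.5, 0.1), "two strata")
})

test_that("Q agrees with the fixed-effect meta-analytic oracle", {
  set.seed(3)
  beta <- rnorm(4); se <- runif(4, 0.05, 0.3)
  mine <- cochran_q(beta, se)
  ref <- metafor::rma(yi = beta, sei = se, method = "EE")
  expect_equal(mine$Q, unname(ref$QE), tolerance = 1e-8)
  expect_equal(mine$p, unname(ref$QEp), tolerance = 1e-8)
})

test_that("subgroup fits partition the cohort and feed the Q test", {
  co <- generate_cohort(cohort_demo_config(n = 1200, seed = 19))
  hli <- classify_lifestyle(co$data)
  sp <- score_panels(co$data, kdm_panels()["comprehensive"])
  spec <- fem_spec(panel = "comprehensive", exposure = "hli")
  full <- suppressMessages(fit_fem(co$data, sp$ba, hli, spec))
  # stratum fits legitimately drop covariates that are constant within a
  # stratum (e.g. menopausal status among men) with a warning
  sub <- suppressWarnings(suppressMessages(
    fit_fem_subgroups(co$data, sp$ba, hli, spec, variable = "sex")))
  expect_setequal(unique(sub$strata$stratum), c("female", "male"))
  expect_equal(sum(unique(sub$strata[, c("stratum", "n")])$n), full$n[1])
  expect_equal(sub$q$hli$df, 1)
  expect_gte(sub$q$hli$Q, 0)
  # stratified covariate is excluded from the stratum fits (no error from
  # a constant sex column)
  expect_false(any(grepl("sex", names(attr(sub, "fit")))))
})

test_that("the sensitivity suite spans variants and definition overlays", {
  co <- generate_cohort(cohort_demo_config(n = 800, seed = 29))
  sp <- score_panels(co$data, kdm_panels()["comprehensive"])
  suite <- suppressWarnings(suppressMessages(
    run_sensitivity_suite(co$data, sp$ba,
                          fem_spec(panel = "comprehensive",
                                   exposure = "hli"))))
  expect_setequal(unique(suite$analysis),
                  c("primary", "standard_fem", "bmi_adjusted",
                    paste0("alt_", lifestyle_factors())))
  # re-running the primary configuration reproduces it bit-for-bit
  hli <- classify_lifestyle(co$data)
  again <- suppressMessages(
    fit_fem(co$data, sp$ba, hli,
            fem_spec(panel = "comprehensive", exposure = "hli")))
  prim <- suite[suite$analysis == "primary", ]
  expect_identical(prim$estimate, again$estimate)
  # BMI is generated as pure noise, so adjusting for it moves the estimate
  # by less than one standard error
  bmi <- suite[suite$analysis == "bmi_adjusted", ]
  expect_lt(abs(bmi$estimate - prim$estimate), prim$se)
})
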