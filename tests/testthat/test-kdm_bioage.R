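test_that("a noiseless linear marker is recovered exactly", {
  set.seed(1)
  d <- data.frame(person_id = 1:100, wave = 0L,
                  age = runif(100, 30, 79),
                  sex = rep(c("female", "male"), 50))
  d$m1 <- 10 + 0.2 * d$age
  params <- fit_kdm(d, "m1")
  for (sx in c("female", "male")) {
    est <- params$strata[[sx]]$estimates
    expect_equal(est$q, 10, tolerance = 1e-8)
    expect_equal(est$k, 0.2, tolerance = 1e-8)
    expect_lt(est$s, 1e-6)
  }
  # single marker on its regression line inverts to chronological age
  ba <- estimate_ba(d, params, use_ca_anchor = FALSE)
  expect_equal(ba$ba, d$age, tolerance = 1e-8)
  expect_equal(ba$ba_acceleration, rep(0, 100), tolerance = 1e-8)
})

test_that("constant markers and degenerate training data are rejected", {
  d <- data.frame(person_id = 1:50, wave = 0L, age = runif(50, 30, 79),
                  sex = "female", m1 = 5)
  expect_error(fit_kdm(d, "m1"), "zero or undefined")
  d2 <- d; d2$age <- 40; d2$m1 <- rnorm(50)
  expect_error(fit_kdm(d2, "m1"), "two distinct ages")
})

test_that("hand-computed toy estimate and anchor behavior", {
  params <- manual_kdm_params(
    markers = c("m1", "m2"), q = c(10, 100), k = c(0.2, -1.0),
    s = c(1, 5), s_ba = 5)
  rec <- data.frame(person_id = 1, wave = 0L, age = 50, sex = "female",
                    m1 = 22, m2 = 45)
  # independent brute-force evaluation of the weighted-average estimate
  x <- c(22, 45); q <- c(10, 100); k <- c(0.2, -1); s <- c(1, 5)
  ba_e_oracle <- sum((x - q) * k / s^2) / sum((k / s)^2)
  ba_e <- estimate_ba(rec, params, use_ca_anchor = FALSE)$ba
  expect_equal(ba_e, ba_e_oracle, tolerance = 1e-12)
  expect_equal(ba_e, 57.5)

  # the corrected estimate lies strictly between BA_E and CA
  ba_ec <- estimate_ba(rec, params, use_ca_anchor = TRUE)$ba
  expect_gt(ba_ec, 50); expect_lt(ba_ec, ba_e)

  # s_BA -> Inf recovers BA_E; s_BA -> 0 collapses to CA
  wide <- manual_kdm_params(c("m1", "m2"), q, k, s, s_ba = 1e9)
  expect_equal(estimate_ba(rec, wide)$ba, ba_e, tolerance = 1e-6)
  tight <- manual_kdm_params(c("m1", "m2"), q, k, s, s_ba = 1e-6)
  expect_equal(estimate_ba(rec, tight)$ba, 50, tolerance = 1e-6)
})

test_that("BA_E is a convex combination of inverse-regression ages", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    q <- rnorm(m, 50, 20); k <- rnorm(m, 0, 0.5)
    k[k == 0] <- 0.1
    s <- runif(m, 0.5, 5)
    params <- manual_kdm_params(paste0("m", 1:m), q, k, s, s_ba = 5)
    x <- q + k * 50 + rnorm(m, 0, s)
    rec <- cbind(data.frame(person_id = 1, wave = 0L, age = 50,
                            sex = "female"),
                 as.data.frame(as.list(setNames(x, paste0("m", 1:m)))))
    ba_e <- estimate_ba(rec, params, use_ca_anchor = FALSE)$ba
    inv <- (x - q) / k
    expect_gte(ba_e, min(inv) - 1e-9)
    expect_lte(ba_e, max(inv) + 1e-9)
    # monotone in each marker in the direction of its slope sign
    for (j in 1:m) {
      rec2 <- rec
      rec2[[paste0("m", j)]] <- rec2[[paste0("m", j)]] + 1
      ba2 <- estimate_ba(rec2, params, use_ca_anchor = TRUE)$ba
      if (k[j] > 0) expect_gt(ba2, estimate_ba(rec, params)$ba)
      else expect_lt(ba2, estimate_ba(rec, params)$ba)
    }
  }
})

test_that("s_BA matches an independent evaluation of the variance formula", {
  set.seed(8)
  n <- 4000
  d <- data.frame(person_id = 1:n, wave = 0L, age = runif(n, 30, 79),
                  sex = "female")
  d$m1 <- 20 + 0.5 * d$age + rnorm(n, 0, 6)
  params <- fit_kdm(d, "m1")
  st <- params$strata$female

  # oracle: closed-form OLS via covariances, then the variance decomposition
  k_hat <- cov(d$m1, d$age) / var(d$age)
  q_hat <- mean(d$m1) - k_hat * mean(d$age)
  res <- d$m1 - q_hat - k_hat * d$age
  s_hat <- sqrt(sum(res^2) / (n - 2))
  r <- cor(d$m1, d$age)
  ba_e <- (d$m1 - q_hat) / k_hat
  r_char <- abs(r)  # single marker: weighted mean of one value
  s_ba2 <- mean((ba_e - d$age)^2) -
    (1 - r_char^2) / r_char^2 * diff(range(d$age))^2 / 12
  expect_equal(st$estimates$k, k_hat, tolerance = 1e-10)
  expect_equal(st$estimates$q, q_hat, tolerance = 1e-10)
  expect_equal(st$estimates$s, s_hat, tolerance = 1e-10)
  expect_equal(st$r_char, r_char, tolerance = 1e-10)
  expect_equal(st$s_ba, sqrt(max(s_ba2, 1e-2)), tolerance = 1e-8)
})

test_that("sex strata are fit independently", {
  co <- tiny_cohort(n = 400, seed = 13)
  d0 <- co$data[co$data$wave == 0, ]
  p1 <- fit_kdm(d0, c("sbp", "ggt"))
  # permuting rows within a stratum changes nothing
  fem_rows <- which(d0$sex == "female")
  d_perm <- d0
  d_perm[fem_rows, ] <- d0[sample(fem_rows), ]
  p2 <- fit_kdm(d_perm, c("sbp", "ggt"))
  expect_equal(p1$strata$female$estimates, p2$strata$female$estimates,
               tolerance = 1e-12)
  # corrupting the male stratum leaves female parameters untouched
  d_male <- d0
  d_male$sbp[d_male$sex == "male"] <- rev(d_male$sbp[d_male$sex == "male"])
  p3 <- fit_kdm(d_male, c("sbp", "ggt"))
  expect_equal(p1$strata$female$estimates, p3$strata$female$estimates,
               tolerance = 1e-12)
})

test_that("biomarker screening applies the missingness and correlation rules", {
  co <- tiny_cohort(n = 2000, seed = 17)
  d <- co$data
  # a marker over the missingness cap is excluded
  d_miss <- inject_missingness(d, rates = c(ggt = 0.35), seed = 2)
  kept <- screen_biomarkers(d_miss, c("sbp", "ggt"))
  expect_false("ggt" %in% kept)
  expect_true("sbp" %in% kept)
  # an age-independent marker is excluded at the default threshold
  set.seed(1); d$null_marker <- rnorm(nrow(d), 100, 10)
  kept2 <- screen_biomarkers(d, c("sbp", "null_marker"))
  expect_identical(kept2, "sbp")
  # a marker whose configured signal implies |r| well above threshold stays
  spec <- default_marker_specs()
  spec_sbp <- spec[spec$marker == "sbp" & spec$sex == "female", ]
  r_analytic <- abs(spec_sbp$k) * sd(d$age[d$sex == "female"]) /
    sqrt(spec_sbp$k^2 * var(d$age[d$sex == "female"]) + spec_sbp$s^2)
  expect_gt(r_analytic, 0.10)
  expect_error(screen_biomarkers(d, "null_marker"), "no marker survived")
})
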