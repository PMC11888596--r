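# Shared fixtures, built in code at test time.

# A small default-configuration cohort, generated once per test run.
tiny_cohort <- function(n = 400, seed = 11, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

# Manual KDM parameter object (both strata share the same table), for
# closed-form estimator checks with printed toy parameters.
manual_kdm_params <- function(markers, q, k, s, s_ba) {
  est <- data.frame(marker = markers, q = q, k = k, s = s, r = NA_real_)
  stratum <- list(estimates = est, r_char = NA_real_, s_ba = s_ba,
                  age_range = c(30, 79), n = NA_integer_)
  structure(list(strata = list(female = stratum, male = stratum),
                 markers = markers),
            class = "kdm_params")
}

# Fabricated two-wave inputs for the fixed-effects and QGC fits: five
# lifestyle flags change at random between waves and the outcome change is
# a linear combination of the flag changes plus noise. `beta` is on the
# healthy-flag scale (negative = protective).
make_fem_fixture <- function(n = 2000, seed = 1,
                             beta = c(smoking = 0, alcohol = 0,
                                      diet = -0.2, exercise = 0, sleep = 0),
                             noise_sd = 1,
                             change_prob = 0.35) {
  set.seed(seed)
  factors <- lifestyle_factors()
  flags0 <- matrix(rbinom(n * 5, 1, 0.5), n, 5, dimnames = list(NULL, factors))
  flip <- matrix(runif(n * 5) < change_prob, n, 5)
  flags1 <- ifelse(flip, 1L - flags0, flags0)
  d_flags <- flags1 - flags0
  dy <- drop(d_flags %*% beta[factors]) + rnorm(n, 0, noise_sd)

  make_wave <- function(w, flags, accel) {
    hli <- compute_hli(as.data.frame(flags))
    list(
      data = data.frame(person_id = seq_len(n), wave = w,
                        age = 50 + w * 2, sex = "female"),
      ba = data.frame(panel = "comprehensive", person_id = seq_len(n),
                      wave = w, age = 50 + w * 2, ba = 50 + accel,
                      ba_acceleration = accel),
      hli = cbind(data.frame(person_id = seq_len(n), wave = w),
                  as.data.frame(flags) |>
                    stats::setNames(paste0("healthy_", factors)),
                  hli)
    )
  }
  w0 <- make_wave(0L, flags0, accel = rep(0, n))
  w1 <- make_wave(1L, flags1, accel = dy)
  spec <- fem_spec(panel = "comprehensive", exposure = "factors",
                   time_varying = character(0),
                   time_invariant = character(0),
                   baseline_age_term = FALSE)
  list(data = rbind(w0$data, w1$data), ba = rbind(w0$ba, w1$ba),
       hli = rbind(w0$hli, w1$hli), spec = spec, beta = beta,
       d_flags = d_flags, dy = dy)
}

# Independent within-transformation (demeaned two-wave) OLS oracle for the
# fixed-effects estimator; returns coefficients on the exposure columns.
within_estimator <- function(fix) {
  factors <- paste0("healthy_", lifestyle_factors())
  both <- merge(fix$ba[, c("person_id", "wave", "ba_acceleration")],
                fix$hli[, c("person_id", "wave", factors)],
                by = c("person_id", "wave"))
  demean <- function(x, id) x - ave(x, id)
  y <- demean(both$ba_acceleration, both$person_id)
  wv <- demean(both$wave, both$person_id)
  X <- sapply(factors, function(cl) demean(both[[cl]], both$person_id))
  fit <- lm(y ~ 0 + wv + X)
  cf <- coef(fit)[-1]
  names(cf) <- factors
  cf
}

# Zero-noise, zero-effect, zero-frailty configuration: biological age must
# equal chronological age downstream.
null_cohort_config <- function(n = 600, seed = 3) {
  cohort_config(
    n = n, seed = seed,
    lifestyle_effects = default_lifestyle_effects() * 0,
    frailty = list(shared_sd = 0, organ_sd = 0),
    marker_specs = default_marker_specs(noise_scale = 0)
  )
}
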