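#' Lifestyle factor and organ-system name constants
#'
#' @return Character vectors naming the five lifestyle factors and the five
#'   organ systems used throughout the package.
#' @export
lifestyle_factors <- function() {
  c("smoking", "alcohol", "diet", "exercise", "sleep")
}

#' @rdname lifestyle_factors
#' @export
organ_systems <- function() {
  c("cardiopulmonary", "metabolic", "liver", "renal", "immune")
}

#' Default biomarker generating specifications
#'
#' Per-marker, per-sex linear age trends used by the synthetic cohort
#' generator: each biomarker is drawn as
#' \code{x = q + k * (age + accel) + Normal(0, s)} where \code{accel} is the
#' latent acceleration of the marker's organ system. Intercepts, slopes and
#' noise SDs are physiologically plausible values for an adult cohort aged
#' 30-79 (SBP mmHg, PEF L/min, WHR ratio, lipids mmol/L, HBA1C %, enzymes
#' U/L, ALB g/L, Cr umol/L, urea mmol/L, MCV fL, PLT 10^9/L). They are
#' configuration, not empirical claims.
#'
#' @param noise_scale multiplier applied to every noise SD `s`; values
#'   below 1 emulate lower-noise assays (used by the demo and
#'   parameter-recovery configurations).
#' @return data.frame with columns `marker`, `organ`, `sex`, `q`, `k`, `s`.
#' @export
default_marker_specs <- function(noise_scale = 1) {
  spec <- data.frame(
    marker = c("sbp", "pef", "whr", "ldl", "hdl", "tg", "hba1c",
               "ast", "ggt", "alp", "alb", "cr", "urea", "mcv", "plt"),
    organ  = c("cardiopulmonary", "cardiopulmonary",
               "metabolic", "metabolic", "metabolic", "metabolic", "metabolic",
               "liver", "liver", "liver", "liver",
               "renal", "renal", "immune", "immune"),
    q_female = c(98, 420, 0.80, 2.1, 1.45, 0.70, 4.7,
                 18, 14, 52, 49.0, 52, 3.6, 87, 280),
    k_female = c(0.55, -2.6, 0.0016, 0.014, 0.0035, 0.011, 0.014,
                 0.09, 0.16, 0.55, -0.060, 0.16, 0.040, 0.070, -0.90),
    s_female = c(13, 55, 0.05, 0.70, 0.28, 0.70, 0.50,
                 6, 11, 17, 2.4, 8, 1.1, 4, 55),
    q_male = c(108, 600, 0.85, 2.3, 1.25, 1.00, 4.8,
               21, 24, 62, 49.5, 68, 3.9, 88, 255),
    k_male = c(0.45, -3.2, 0.0012, 0.009, 0.0030, 0.009, 0.012,
               0.07, 0.20, 0.40, -0.055, 0.18, 0.037, 0.065, -0.80),
    s_male = c(13, 65, 0.05, 0.70, 0.26, 0.90, 0.55,
               7, 14, 18, 2.4, 9, 1.1, 4, 52)
  )
  long <- rbind(
    data.frame(marker = spec$marker, organ = spec$organ, sex = "female",
               q = spec$q_female, k = spec$k_female, s = spec$s_female),
    data.frame(marker = spec$marker, organ = spec$organ, sex = "male",
               q = spec$q_male, k = spec$k_male, s = spec$s_male)
  )
  long$s <- long$s * noise_scale
  rownames(long) <- NULL
  long
}

#' Default lifestyle effects on latent organ acceleration
#'
#' Additive penalty, in years of biological age acceleration, incurred per
#' organ system while a lifestyle factor is in its unhealthy state. A
#' positive entry means being unhealthy on that factor ages the organ;
#' estimation on healthy-flag exposures therefore recovers the negated
#' values. Rows are the five lifestyle factors, columns the five organ
#' systems.
#'
#' @return 5 x 5 numeric matrix (factors x organ systems).
#' @export
default_lifestyle_effects <- function() {
  eff <- rbind(
    cardiopulmonary = c(0.03, 0.02, 0.01, 0.03, 0.02),
    metabolic       = c(0.54, 0.18, 0.18, 0.09, -0.01),
    liver           = c(0.57, 0.59, 0.10, 0.05, 0.36),
    renal           = c(0.13, 0.17, 0.15, 0.16, 0.02),
    immune          = c(0.13, 0.17, 0.15, 0.16, 0.02)
  )
  eff <- t(eff)
  dimnames(eff) <- list(lifestyle_factors(), organ_systems())
  eff
}

#' Default disease generating links
#'
#' Logistic links from latent baseline organ acceleration to self-reported
#' disease flags: P(disease) = plogis(intercept + slope * accel). Diseases
#' with slope 0 (cancer, rheumatoid arthritis) are pure-prevalence noise, so
#' the immune panel has no true disease signal and fails validation by
#' construction, while cardiopulmonary, metabolic and liver panels carry
#' genuine links.
#'
#' @return data.frame with columns `disease`, `organ`, `intercept`, `slope`.
#' @export
default_disease_links <- function() {
  data.frame(
    disease = c("cvd", "diabetes", "cancer", "chronic_bronchitis",
                "hepatitis_cirrhosis", "rheumatoid_arthritis"),
    organ = c("cardiopulmonary", "metabolic", NA, "cardiopulmonary",
              "liver", "immune"),
    intercept = qlogis(c(0.17, 0.04, 0.008, 0.04, 0.03, 0.02)),
    slope = c(0.35, 0.70, 0, 0.50, 0.90, 0)
  )
}

#' Build a synthetic cohort configuration
#'
#' Assembles and validates the full parameter set for [generate_cohort()].
#' Defaults emulate a two-wave cohort of adults aged 30-79 with an
#' approximately 2-year inter-wave gap, a majority-female sample,
#' smoking/alcohol states that rarely change between waves (under 10%
#' of individuals), diet and sleep changing in over a third and exercise in
#' about 30%, and disease prevalence linked to organ-specific aging.
#'
#' @param n number of individuals (two rows each are generated).
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @param age_range baseline chronological age range in years (within
#'   30-79).
#' @param wave_gap list with `mean`, `sd`, `min`, `max` (years); the
#'   inter-wave gap is Normal(mean, sd) truncated to \code{[min, max]}.
#' @param sex_ratio_female proportion female.
#' @param lifestyle_prevalence named numeric, baseline P(healthy) per
#'   factor.
#' @param transition_probs data.frame with columns `factor`, `p_uh`
#'   (P(unhealthy at wave 0 -> healthy at wave 1)) and `p_hu`.
#' @param lifestyle_effects 5 x 5 matrix, see [default_lifestyle_effects()].
#' @param frailty list with `shared_sd` and `organ_sd` (years): a
#'   person-level acceleration component shared across organs plus an
#'   organ-specific one, both time-invariant.
#' @param latent_correlation loading of the shared "health consciousness"
#'   latent variable on each factor's healthy propensity (induces the
#'   positive cross-factor correlation seen in real cohorts).
#' @param marker_specs data.frame, see [default_marker_specs()].
#' @param disease_links data.frame, see [default_disease_links()].
#' @param missing_rate per-marker MCAR missingness proportion applied at
#'   generation time (default 0; see [inject_missingness()]).
#' @param diet_separation difference in log-intake of each diet component
#'   between latent healthy-diet and unhealthy-diet states; large values
#'   make the scored median-split diet flag agree with the latent flag.
#' @param diet_sigma log-scale SD of diet component intakes.
#'
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 8396,
                          seed = 1L,
                          age_range = c(30, 79),
                          wave_gap = list(mean = 2.0, sd = 0.25,
                                          min = 1, max = 3),
                          sex_ratio_female = 0.62,
                          lifestyle_prevalence = c(
                            smoking = 0.65, alcohol = 0.78, diet = 0.50,
                            exercise = 0.45, sleep = 0.55),
                          transition_probs = data.frame(
                            factor = lifestyle_factors(),
                            p_uh = c(0.06, 0.08, 0.38, 0.30, 0.40),
                            p_hu = c(0.03, 0.05, 0.38, 0.30, 0.35)),
                          lifestyle_effects = default_lifestyle_effects(),
                          frailty = list(shared_sd = 2.0, organ_sd = 1.5),
                          latent_correlation = 0.8,
                          marker_specs = default_marker_specs(),
                          disease_links = default_disease_links(),
                          missing_rate = 0,
                          diet_separation = 1.5,
                          diet_sigma = 0.4) {
  config <- list(
    n = as.integer(n), seed = as.integer(seed), age_range = age_range,
    wave_gap = wave_gap, sex_ratio_female = sex_ratio_female,
    lifestyle_prevalence = lifestyle_prevalence,
    transition_probs = transition_probs,
    lifestyle_effects = lifestyle_effects, frailty = frailty,
    latent_correlation = latent_correlation, marker_specs = marker_specs,
    disease_links = disease_links, missing_rate = missing_rate,
    diet_separation = diet_separation, diet_sigma = diet_sigma
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n < 1) stop("cohort_config: n must be a positive integer")
  if (config$age_range[1] < 30 || config$age_range[2] > 79 ||
      diff(config$age_range) <= 0) {
    stop("cohort_config: age_range must be an increasing interval within [30, 79]")
  }
  probs <- c(config$sex_ratio_female, config$lifestyle_prevalence,
             config$transition_probs$p_uh, config$transition_probs$p_hu,
             config$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config: all probabilities must lie in [0, 1]")
  }
  if (any(config$marker_specs$s < 0)) {
    stop("cohort_config: marker noise SDs must be nonnegative")
  }
  if (config$frailty$shared_sd < 0 || config$frailty$organ_sd < 0) {
    stop("cohort_config: frailty SDs must be nonnegative")
  }
  if (!all(dim(config$lifestyle_effects) == c(5, 5))) {
    stop("cohort_config: lifestyle_effects must be a 5 x 5 matrix")
  }
  invisible(config)
}

#' Demo configuration for end-to-end runs
#'
#' A smaller cohort with uniformly negative, identifiable lifestyle effects
#' (0.7-1.2 years of acceleration per unhealthy factor, identical across
#' organ systems) and lower-noise assays (noise SDs at a quarter of the
#' defaults) for smoke-testing the full pipeline: with all true health
#' effects negative and a favorable signal-to-noise ratio, the estimated
#' sign pattern is recoverable at moderate sample size.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_demo_config <- function(n = 2000, seed = 1L) {
  eff <- matrix(rep(c(1.2, 0.8, 1.0, 0.9, 0.7), 5), nrow = 5,
                dimnames = list(lifestyle_factors(), organ_systems()))
  cohort_config(n = n, seed = seed, lifestyle_effects = eff,
                marker_specs = default_marker_specs(noise_scale = 0.25))
}

#' Parameter-recovery calibration configuration
#'
#' A cohort in which every organ system shares one lifestyle-effect
#' vector, so each biological age panel carries the same known truth and
#' the mixture shares implied by that vector are exactly recoverable.
#' Assay noise is reduced (quarter-scale SDs) to make the per-factor
#' coefficients identifiable at the configured sample size; scaling an
#' effect vector by a constant leaves its sign-group shares unchanged.
#'
#' @param effects named length-5 numeric vector of unhealthy penalties in
#'   years (names `lifestyle_factors()`), applied to every organ system.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_recovery_config <- function(effects, n = 8000, seed = 1L) {
  stopifnot(length(effects) == 5)
  eff <- matrix(rep(unname(effects), 5), nrow = 5,
                dimnames = list(lifestyle_factors(), organ_systems()))
  cohort_config(n = n, seed = seed, lifestyle_effects = eff,
                marker_specs = default_marker_specs(noise_scale = 0.25))
}

# Solve for the per-factor intercept that yields the target marginal
# P(healthy) after integrating the shared latent loading out.
calibrate_intercept <- function(p, lambda) {
  z <- qnorm(ppoints(401))
  f <- function(a) mean(plogis(a + lambda * z)) - p
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  uniroot(f, c(-20, 20))$root
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Log-scale intake locations for the seven modified-aMED diet components.
diet_mu0 <- function() {
  c(diet_vegetables = log(250), diet_legumes = log(40),
    diet_fruits = log(150), diet_nuts = log(15),
    diet_whole_grains = log(80), diet_fish = log(30),
    diet_red_processed_meat = log(70))
}

draw_diet <- function(flag, delta, sigma) {
  mu0 <- diet_mu0()
  n <- length(flag)
  out <- matrix(NA_real_, n, length(mu0),
                dimnames = list(NULL, names(mu0)))
  for (comp in names(mu0)) {
    dir <- if (comp == "diet_red_processed_meat") -1 else 1
    out[, comp] <- rlnorm(n, mu0[[comp]] + dir * delta * flag, sigma)
  }
  as.data.frame(out)
}

draw_lifestyle_raw <- function(flags) {
  n <- nrow(flags)
  smoking <- ifelse(flags[, "smoking"] == 1, "never",
                    sample(c("current", "former"), n, TRUE, c(0.8, 0.2)))
  drink <- ifelse(flags[, "alcohol"] == 1,
                  sample(c(0, 0.25, 0.5), n, TRUE, c(0.7, 0.15, 0.15)),
                  sample(c(1, 2, 3, 5, 7), n, TRUE,
                         c(0.3, 0.25, 0.2, 0.15, 0.1)))
  exercise <- ifelse(flags[, "exercise"] == 1,
                     sample(c("1-2/week", "3-5/week", "daily"), n, TRUE,
                            c(0.35, 0.35, 0.30)),
                     "never/rare")
  short_sleep <- runif(n) < 0.7
  sleep <- ifelse(flags[, "sleep"] == 1, runif(n, 7, 8),
                  ifelse(short_sleep, runif(n, 4.5, 6.8), runif(n, 8.2, 10)))
  data.frame(smoking_status = smoking, drink_frequency = drink,
             exercise_frequency = exercise, sleep_hours = sleep)
}

menopause_from_age <- function(age, sex, jitter) {
  status <- rep("not_applicable", length(age))
  f <- sex == "female"
  a <- age[f] + jitter[f]
  status[f] <- ifelse(a < 47, "premenopausal",
                      ifelse(a < 51, "perimenopausal", "postmenopausal"))
  status
}

#' Generate a seeded two-wave synthetic cohort
#'
#' Draws a long-format person-by-wave panel with 15 clinical biomarkers,
#' raw lifestyle fields, covariates and disease flags, alongside the
#' generating ground truth (latent organ accelerations, latent healthy
#' flags, true effect sizes and the mixture weights they imply). Biomarkers
#' follow \code{x = q + k * (age + accel) + Normal(0, s)} sex-specifically,
#' where the organ acceleration is the sum of per-factor unhealthy
#' penalties and person-level frailty. Wave-1 lifestyle states are drawn
#' from the wave-0 states through the configured transition probabilities.
#' The ground truth is stored alongside the data and is never consumed by
#' any estimation code path.
#'
#' @param config a [cohort_config()].
#' @return list of class `orgaging_cohort` with elements `data` (the panel
#'   data.frame, two rows per person) and `truth` (list: `accel`, `flags`,
#'   `effects`, `frailty`, `qgc_weights`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n
  factors <- lifestyle_factors()
  organs <- organ_systems()

  sex <- ifelse(runif(n) < config$sex_ratio_female, "female", "male")
  age0 <- runif(n, config$age_range[1], config$age_range[2])
  gap <- rtruncnorm1(n, config$wave_gap$mean, config$wave_gap$sd,
                     config$wave_gap$min, config$wave_gap$max)
  age1 <- age0 + gap

  # latent healthy flags, correlated through a shared propensity
  lambda <- config$latent_correlation
  u <- rnorm(n)
  flags0 <- sapply(factors, function(f) {
    a <- calibrate_intercept(config$lifestyle_prevalence[[f]], lambda)
    as.integer(runif(n) < plogis(a + lambda * u))
  })
  tp <- config$transition_probs
  flags1 <- sapply(factors, function(f) {
    row <- tp[tp$factor == f, ]
    w0 <- flags0[, f]
    to_healthy <- runif(n) < row$p_uh
    to_unhealthy <- runif(n) < row$p_hu
    ifelse(w0 == 1, ifelse(to_unhealthy, 0L, 1L),
           ifelse(to_healthy, 1L, 0L))
  })

  frail_shared <- rnorm(n, 0, config$frailty$shared_sd)
  frail_organ <- matrix(rnorm(n * 5, 0, config$frailty$organ_sd), n, 5,
                        dimnames = list(NULL, organs))
  eff <- config$lifestyle_effects
  accel_wave <- function(flags) {
    unhealthy <- 1 - flags
    base <- unhealthy %*% eff   # n x organs
    sweep(base + frail_organ, 1, frail_shared, `+`)
  }
  accel0 <- accel_wave(flags0)
  accel1 <- accel_wave(flags1)

  draw_markers <- function(age, accel) {
    out <- list()
    for (m in unique(config$marker_specs$marker)) {
      x <- numeric(n)
      for (sx in c("female", "male")) {
        spec <- config$marker_specs[config$marker_specs$marker == m &
                                      config$marker_specs$sex == sx, ]
        idx <- sex == sx
        org <- spec$organ
        x[idx] <- spec$q + spec$k * (age[idx] + accel[idx, org]) +
          rnorm(sum(idx), 0, spec$s)
      }
      out[[m]] <- x
    }
    as.data.frame(out)
  }
  markers0 <- draw_markers(age0, accel0)
  markers1 <- draw_markers(age1, accel1)

  raw0 <- draw_lifestyle_raw(flags0)
  raw1 <- draw_lifestyle_raw(flags1)
  diet0 <- draw_diet(flags0[, "diet"], config$diet_separation,
                     config$diet_sigma)
  diet1 <- draw_diet(flags1[, "diet"], config$diet_separation,
                     config$diet_sigma)

  # covariates: four time-invariant, the rest time-varying
  ethnicity <- sample(c("majority", "minority"), n, TRUE, c(0.60, 0.40))
  urbanicity <- sample(c("urban", "rural"), n, TRUE, c(0.36, 0.64))
  education <- sample(c("none", "primary", "middle_high", "college"),
                      n, TRUE, c(0.26, 0.24, 0.39, 0.11))
  occupation0 <- sample(c("primary_industry", "secondary_industry",
                          "tertiary_industry", "unemployed"),
                        n, TRUE, c(0.33, 0.06, 0.41, 0.20))
  switch_occ <- runif(n) < 0.05
  occupation1 <- ifelse(switch_occ,
                        sample(c("primary_industry", "secondary_industry",
                                 "tertiary_industry", "unemployed"),
                               n, TRUE),
                        occupation0)
  marital0 <- sample(c("married", "not_married"), n, TRUE, c(0.89, 0.11))
  marital1 <- ifelse(runif(n) < 0.02,
                     ifelse(marital0 == "married", "not_married", "married"),
                     marital0)
  energy0 <- rlnorm(n, log(1800), 0.33)
  energy1 <- energy0 * 0.85 * rlnorm(n, 0, 0.15)
  depression0 <- rbinom(n, 1, 0.05); depression1 <- rbinom(n, 1, 0.035)
  anxiety0 <- rbinom(n, 1, 0.06); anxiety1 <- rbinom(n, 1, 0.03)
  meno_jitter <- rnorm(n, 0, 3)
  meno0 <- menopause_from_age(age0, sex, meno_jitter)
  meno1 <- menopause_from_age(age1, sex, meno_jitter)
  beverage0 <- sample(c("never", "former", "current"), n, TRUE,
                      c(0.93, 0.005, 0.065))
  beverage1 <- ifelse(runif(n) < 0.05,
                      sample(c("never", "former", "current"), n, TRUE,
                             c(0.93, 0.005, 0.065)),
                      beverage0)
  supplement0 <- rbinom(n, 1, 0.17)
  supplement1 <- ifelse(runif(n) < 0.15, rbinom(n, 1, 0.17), supplement0)
  bmi0 <- rnorm(n, 24.5, 3.3)
  bmi1 <- bmi0 + rnorm(n, 0.2, 0.8)

  links <- config$disease_links
  disease0 <- sapply(seq_len(nrow(links)), function(i) {
    lin <- links$intercept[i]
    if (!is.na(links$organ[i])) {
      lin <- lin + links$slope[i] * accel0[, links$organ[i]]
    }
    rbinom(n, 1, plogis(lin))
  })
  colnames(disease0) <- links$disease
  disease1 <- disease0
  for (d in links$disease) {
    disease1[, d] <- pmax(disease0[, d], rbinom(n, 1, 0.02))
  }

  assemble <- function(wave, age, markers, raw, diet, occupation, marital,
                       energy, depression, anxiety, meno, beverage,
                       supplement, bmi, disease) {
    cbind(
      data.frame(person_id = seq_len(n), wave = wave, age = age, sex = sex),
      markers, raw, diet,
      data.frame(ethnicity = ethnicity, urbanicity = urbanicity,
                 education = education, occupation = occupation,
                 marital_status = marital, energy_intake = energy,
                 depression = depression, anxiety = anxiety,
                 menopausal = meno, beverage = beverage,
                 supplement = supplement, bmi = bmi),
      as.data.frame(disease)
    )
  }
  data <- rbind(
    assemble(0L, age0, markers0, raw0, diet0, occupation0, marital0,
             energy0, depression0, anxiety0, meno0, beverage0, supplement0,
             bmi0, disease0),
    assemble(1L, age1, markers1, raw1, diet1, occupation1, marital1,
             energy1, depression1, anxiety1, meno1, beverage1, supplement1,
             bmi1, disease1)
  )
  data <- data[order(data$person_id, data$wave), ]
  rownames(data) <- NULL

  if (config$missing_rate > 0) {
    data <- inject_missingness(
      data, rates = setNames(rep(config$missing_rate,
                                 length(unique(config$marker_specs$marker))),
                             unique(config$marker_specs$marker)),
      seed = config$seed + 1L)
  }

  truth <- list(
    accel = rbind(
      data.frame(person_id = seq_len(n), wave = 0L, accel0),
      data.frame(person_id = seq_len(n), wave = 1L, accel1)
    ),
    flags = rbind(
      data.frame(person_id = seq_len(n), wave = 0L, flags0),
      data.frame(person_id = seq_len(n), wave = 1L, flags1)
    ),
    effects = eff,
    frailty = data.frame(person_id = seq_len(n), shared = frail_shared,
                         frail_organ),
    qgc_weights = true_qgc_weights(eff)
  )
  truth$accel <- truth$accel[order(truth$accel$person_id, truth$accel$wave), ]
  truth$flags <- truth$flags[order(truth$flags$person_id, truth$flags$wave), ]
  rownames(truth$accel) <- rownames(truth$flags) <- NULL

  structure(list(data = data, truth = truth, config = config),
            class = "orgaging_cohort")
}

# The mixture weights implied by an effect matrix: coefficients on the
# healthy-flag scale are the negated penalties; weights are grouped by sign
# and normalized within group.
true_qgc_weights <- function(effects) {
  lapply(setNames(colnames(effects), colnames(effects)), function(o) {
    coefs <- -effects[, o]
    neg <- coefs[coefs < 0]; pos <- coefs[coefs > 0]
    list(
      negative = if (length(neg)) abs(neg) / sum(abs(neg)) else numeric(0),
      positive = if (length(pos)) pos / sum(pos) else numeric(0)
    )
  })
}

#' @export
print.orgaging_cohort <- function(x, ...) {
  cat("orgaging synthetic cohort:", x$config$n, "individuals x 2 waves\n")
  cat("  seed:", x$config$seed, "\n")
  cat("  columns:", ncol(x$data), "\n")
  invisible(x)
}

#' Inject missing-completely-at-random values into biomarker columns
#'
#' @param data a panel data.frame.
#' @param rates named numeric vector of missingness proportions per marker
#'   column (names must be columns of `data`).
#' @param seed integer seed.
#' @return the data.frame with values set to `NA` at the requested rates.
#' @export
inject_missingness <- function(data, rates, seed = 1L) {
  if (any(rates < 0 | rates > 1)) {
    stop("inject_missingness: rates must lie in [0, 1]")
  }
  if (is.null(names(rates)) || !all(names(rates) %in% names(data))) {
    stop("inject_missingness: rates must be named by columns of `data`")
  }
  set.seed(seed)
  for (m in names(rates)) {
    if (rates[[m]] <= 0) next
    hit <- runif(nrow(data)) < rates[[m]]
    data[hit, m] <- NA
  }
  data
}

#' Write a synthetic cohort to disk
#'
#' Writes the panel as UTF-8 CSV (one row per person-wave) and the ground
#' truth as JSON.
#'
#' @param cohort an `orgaging_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "orgaging_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  write.csv(cohort$data, data_path, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(cohort$truth, truth_path, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(c(data = data_path, truth = truth_path))
}
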