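#' Specification for a two-wave fixed-effects model
#'
#' @param panel outcome biological age panel name.
#' @param exposure `"factors"` (the five lifestyle flags entered jointly),
#'   `"hli"` (continuous HLI) or `"hli_category"` (binary HLI).
#' @param variant `"primary"` (time-varying covariate changes plus
#'   time-invariant covariates and baseline age as level terms),
#'   `"standard"` (pure within estimator: time-varying terms only) or
#'   `"bmi"` (primary plus BMI).
#' @param time_varying time-varying covariate columns (differenced).
#' @param time_invariant time-invariant covariate columns (level terms in
#'   the differenced equation; dropped under the standard variant).
#' @param baseline_age_term include baseline chronological age as a level
#'   term (primary/bmi variants).
#' @return list of class `fem_spec`.
#' @export
fem_spec <- function(panel = "comprehensive",
                     exposure = c("factors", "hli", "hli_category"),
                     variant = c("primary", "standard", "bmi"),
                     time_varying = c("age", "occupation", "marital_status",
                                      "energy_intake", "depression",
                                      "anxiety", "menopausal", "beverage",
                                      "supplement", "diabetes", "cvd",
                                      "cancer"),
                     time_invariant = c("sex", "ethnicity", "urbanicity",
                                        "education"),
                     baseline_age_term = TRUE) {
  exposure <- match.arg(exposure)
  variant <- match.arg(variant)
  if (variant == "bmi" && !("bmi" %in% time_varying)) {
    time_varying <- c(time_varying, "bmi")
  }
  structure(list(panel = panel, exposure = exposure, variant = variant,
                 time_varying = time_varying,
                 time_invariant = time_invariant,
                 baseline_age_term = baseline_age_term),
            class = "fem_spec")
}

# Difference (or dummy-difference) one covariate between waves.
diff_columns <- function(x0, x1, name) {
  if (is.numeric(x0)) {
    out <- data.frame(x1 - x0)
    names(out) <- paste0("d_", name)
    return(out)
  }
  levels_all <- sort(unique(c(as.character(x0), as.character(x1))))
  if (length(levels_all) < 2) {
    out <- data.frame(rep(0, length(x0)))
    names(out) <- paste0("d_", name)
    return(out)
  }
  ref <- levels_all[-1]
  out <- as.data.frame(lapply(ref, function(lv) {
    as.numeric(x1 == lv) - as.numeric(x0 == lv)
  }))
  names(out) <- paste0("d_", name, "_", gsub("[^A-Za-z0-9]+", "_", ref))
  out
}

level_columns <- function(x, name) {
  if (is.numeric(x)) {
    out <- data.frame(x)
    names(out) <- name
    return(out)
  }
  levels_all <- sort(unique(as.character(x)))
  if (length(levels_all) < 2) return(NULL)
  ref <- levels_all[-1]
  out <- as.data.frame(lapply(ref, function(lv) as.numeric(x == lv)))
  names(out) <- paste0(name, "_", gsub("[^A-Za-z0-9]+", "_", ref))
  out
}

exposure_columns <- function(spec) {
  switch(spec$exposure,
         factors = paste0("healthy_", lifestyle_factors()),
         hli = "hli",
         hli_category = "hli_healthy")
}

#' Build person-level first-difference data for the two-wave models
#'
#' Merges the panel data, biological age results and lifestyle records,
#' and differences the outcome, exposures and time-varying covariates
#' between waves; time-invariant covariates and baseline age enter as
#' level terms. Categorical covariates are expanded to indicator columns
#' before differencing. Shared by the fixed-effects and quantile
#' G-computation fits so both answer the same estimand on the same design.
#'
#' @param data panel data.frame.
#' @param ba long biological-age data.frame from [score_panels()].
#' @param hli lifestyle records from [classify_lifestyle()].
#' @param spec a [fem_spec()].
#' @return list with `df` (one row per person; `d_outcome`, differenced
#'   exposure columns prefixed `d_`, covariate columns), `exposure_cols`
#'   and `covariate_cols`.
#' @export
build_difference_data <- function(data, ba, hli, spec) {
  pan <- ba[ba$panel == spec$panel, c("person_id", "wave",
                                      "ba_acceleration")]
  hl <- hli
  hl$hli_healthy <- as.numeric(hl$hli_category == "healthy")
  merged <- merge(merge(data, pan, by = c("person_id", "wave")),
                  hl[, c("person_id", "wave", exposure_columns(spec))],
                  by = c("person_id", "wave"))
  w0 <- merged[merged$wave == 0, ]
  w1 <- merged[merged$wave == 1, ]
  common <- intersect(w0$person_id, w1$person_id)
  w0 <- w0[match(common, w0$person_id), ]
  w1 <- w1[match(common, w1$person_id), ]

  df <- data.frame(person_id = common,
                   d_outcome = w1$ba_acceleration - w0$ba_acceleration)
  exp_cols <- character(0)
  for (col in exposure_columns(spec)) {
    d <- diff_columns(w0[[col]], w1[[col]], col)
    df <- cbind(df, d)
    exp_cols <- c(exp_cols, names(d))
  }
  cov_cols <- character(0)
  for (col in spec$time_varying) {
    d <- diff_columns(w0[[col]], w1[[col]], col)
    df <- cbind(df, d)
    cov_cols <- c(cov_cols, names(d))
  }
  if (spec$variant != "standard") {
    for (col in spec$time_invariant) {
      lv <- level_columns(w0[[col]], col)
      if (is.null(lv)) next
      df <- cbind(df, lv)
      cov_cols <- c(cov_cols, names(lv))
    }
    if (spec$baseline_age_term) {
      df$baseline_age <- w0$age
      cov_cols <- c(cov_cols, "baseline_age")
    }
  }
  list(df = df, exposure_cols = exp_cols, covariate_cols = cov_cols)
}

fit_difference_ols <- function(dd) {
  df <- dd$df[complete.cases(dd$df), ]
  n_drop <- nrow(dd$df) - nrow(df)
  if (n_drop > 0) {
    message("fit_fem: dropped ", n_drop, " person(s) with missing terms")
  }
  zero_exp <- dd$exposure_cols[vapply(dd$exposure_cols, function(cl) {
    all(df[[cl]] == 0)
  }, logical(1))]
  if (length(zero_exp)) {
    stop("fit_fem: exposure(s) with no within-person variation: ",
         paste(zero_exp, collapse = ", "))
  }
  no_var <- dd$covariate_cols[vapply(dd$covariate_cols, function(cl) {
    all(df[[cl]] == 0)
  }, logical(1))]
  if (length(no_var)) {
    warning("fit_fem: dropping covariate(s) with no variation: ",
            paste(no_var, collapse = ", "))
  }
  # dummy columns driven by fewer than 3 persons give leverage ~1 and an
  # unstable robust variance; treat them like empty levels
  near_empty <- dd$covariate_cols[vapply(dd$covariate_cols, function(cl) {
    nz <- sum(df[[cl]] != 0)
    nz > 0 && nz < 3 && all(df[[cl]] %in% c(-1, 0, 1))
  }, logical(1))]
  if (length(near_empty)) {
    message("fit_fem: dropping near-empty dummy covariate(s): ",
            paste(near_empty, collapse = ", "))
  }
  keep_cov <- setdiff(dd$covariate_cols, c(no_var, near_empty))
  fit_formula <- function(covs) {
    rhs <- c(dd$exposure_cols, covs)
    lm(stats::as.formula(paste("d_outcome ~",
                               paste(rhs, collapse = " + "))), data = df)
  }
  fit <- fit_formula(keep_cov)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (any(aliased %in% dd$exposure_cols)) {
    stop("fit_fem: rank-deficient design; collinear exposure term(s): ",
         paste(intersect(aliased, dd$exposure_cols), collapse = ", "))
  }
  if (length(aliased)) {
    # structurally redundant covariate dummies (e.g. a categorical whose
    # levels partition a time-invariant subgroup) are dropped, not fatal
    message("fit_fem: dropping collinear covariate(s): ",
            paste(aliased, collapse = ", "))
    keep_cov <- setdiff(keep_cov, aliased)
    fit <- fit_formula(keep_cov)
    if (anyNA(coef(fit))) {
      stop("fit_fem: rank-deficient design; collinear term(s): ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    }
  }
  list(fit = fit, df = df, exposure_cols = dd$exposure_cols,
       covariate_cols = keep_cov)
}

#' Fit the two-wave fixed-effects (first-difference) model
#'
#' Regresses the between-wave change in biological age acceleration on the
#' change in the lifestyle exposures and time-varying covariates, with
#' time-invariant covariates and baseline age as level terms (primary
#' variant). For two waves this first-difference estimator coincides
#' exactly with the within (demeaned) fixed-effects estimator.
#' Standard errors are heteroskedasticity-robust (HC1).
#'
#' @inheritParams build_difference_data
#' @return data.frame of class `fem_result` with one row per exposure
#'   term: `panel`, `exposure`, `variant`, `term`, `estimate` (years of
#'   acceleration), `se`, `ci_low`, `ci_high`, `n`.
#' @export
fit_fem <- function(data, ba, hli, spec = fem_spec()) {
  dd <- build_difference_data(data, ba, hli, spec)
  fo <- fit_difference_ols(dd)
  vc <- sandwich::vcovHC(fo$fit, type = "HC1")
  cf <- coef(fo$fit)
  terms <- dd$exposure_cols
  est <- cf[terms]
  se <- sqrt(diag(vc)[terms])
  out <- data.frame(
    panel = spec$panel, exposure = spec$exposure, variant = spec$variant,
    term = sub("^d_", "", terms), estimate = unname(est),
    se = unname(se), ci_low = unname(est - 1.96 * se),
    ci_high = unname(est + 1.96 * se), n = nrow(fo$df), row.names = NULL)
  class(out) <- c("fem_result", class(out))
  attr(out, "fit") <- fo
  out
}

#' Cochran's Q heterogeneity test across stratum estimates
#'
#' \eqn{Q = \sum_i w_i (\beta_i - \bar\beta_w)^2} with inverse-variance
#' weights \eqn{w_i = 1/se_i^2} and \eqn{\bar\beta_w} the weighted mean;
#' under homogeneity Q is chi-square with (strata - 1) degrees of freedom.
#' Heterogeneity is flagged at `alpha` = 0.1.
#'
#' @param estimates numeric stratum effect estimates.
#' @param ses their standard errors (all positive).
#' @param alpha significance level for the heterogeneity flag.
#' @return list with `Q`, `df`, `p`, `significant`.
#' @export
cochran_q <- function(estimates, ses, alpha = 0.1) {
  if (length(estimates) < 2) stop("cochran_q: need at least two strata")
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("cochran_q: all stratum SEs must be finite and positive")
  }
  w <- 1 / ses^2
  beta_bar <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - beta_bar)^2)
  df <- length(estimates) - 1
  p <- pchisq(q, df, lower.tail = FALSE)
  list(Q = q, df = df, p = p, significant = p < alpha)
}

subgroup_assignment <- function(data, ba, panel, variable) {
  w0 <- data[data$wave == 0, ]
  switch(variable,
    sex = setNames(w0$sex, w0$person_id),
    baseline_age = setNames(ifelse(w0$age < 60, "<60", ">=60"),
                            w0$person_id),
    ethnicity = setNames(w0$ethnicity, w0$person_id),
    urbanicity = setNames(w0$urbanicity, w0$person_id),
    baseline_accel = {
      b0 <- ba[ba$wave == 0 & ba$panel == panel, ]
      setNames(ifelse(b0$ba_acceleration < 0, "<0", ">=0"), b0$person_id)
    },
    baseline_disease = setNames(
      ifelse(w0$diabetes + w0$cvd + w0$cancer == 0, "free", "any"),
      w0$person_id),
    stop("subgroup_assignment: unknown subgroup variable '", variable, "'")
  )
}

#' Stratified fixed-effects fits with a heterogeneity Q test
#'
#' Fits the model within each stratum of a subgroup variable (sex,
#' baseline age below/at-or-above 60, ethnicity, urbanicity, baseline
#' acceleration sign, or baseline disease status), excluding the
#' stratified variable from the covariates, and tests between-stratum
#' heterogeneity of each exposure term with [cochran_q()].
#'
#' @inheritParams build_difference_data
#' @param variable subgroup variable name.
#' @param alpha heterogeneity significance level (default 0.1).
#' @return list with `strata` (combined `fem_result` rows plus a `stratum`
#'   column) and `q` (per exposure term: Q, df, p, significant).
#' @export
fit_fem_subgroups <- function(data, ba, hli, spec = fem_spec(),
                              variable = "sex", alpha = 0.1) {
  assign <- subgroup_assignment(data, ba, spec$panel, variable)
  if (variable %in% spec$time_invariant) {
    spec$time_invariant <- setdiff(spec$time_invariant, variable)
  }
  if (variable == "baseline_age") spec$baseline_age_term <- FALSE
  strata <- sort(unique(assign))
  fits <- lapply(strata, function(st) {
    ids <- as.integer(names(assign)[assign == st])
    res <- fit_fem(data[data$person_id %in% ids, ],
                   ba[ba$person_id %in% ids, ],
                   hli[hli$person_id %in% ids, ], spec)
    cbind(stratum = st, as.data.frame(res))
  })
  combined <- do.call(rbind, fits)
  qs <- lapply(setNames(unique(combined$term), unique(combined$term)),
               function(tm) {
                 sub <- combined[combined$term == tm, ]
                 cochran_q(sub$estimate, sub$se, alpha = alpha)
               })
  list(strata = combined, q = qs)
}

#' Sensitivity suite for the fixed-effects analysis
#'
#' Re-runs the primary fit under (i) the standard fixed-effects variant
#' (time-varying covariates only), (ii) additional BMI adjustment, and
#' (iii) one alternative lifestyle definition at a time (five refits, each
#' re-classifying lifestyle from the raw fields before refitting).
#'
#' @inheritParams build_difference_data
#' @return data.frame stacking the primary and sensitivity `fem_result`
#'   rows with an `analysis` label.
#' @export
run_sensitivity_suite <- function(data, ba, spec = fem_spec()) {
  primary_hli <- classify_lifestyle(data)
  runs <- list(primary = fit_fem(data, ba, primary_hli, spec))
  spec_std <- spec; spec_std$variant <- "standard"
  runs$standard_fem <- fit_fem(data, ba, primary_hli, spec_std)
  spec_bmi <- spec; spec_bmi$variant <- "bmi"
  spec_bmi$time_varying <- unique(c(spec$time_varying, "bmi"))
  runs$bmi_adjusted <- fit_fem(data, ba, primary_hli, spec_bmi)
  for (f in lifestyle_factors()) {
    alt_hli <- classify_lifestyle(data, alternative_definitions(f))
    runs[[paste0("alt_", f)]] <- fit_fem(data, ba, alt_hli, spec)
  }
  out <- do.call(rbind, lapply(names(runs), function(nm) {
    cbind(analysis = nm, as.data.frame(runs[[nm]]))
  }))
  rownames(out) <- NULL
  out
}
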