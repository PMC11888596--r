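#' Default biomarker panels
#'
#' The comprehensive panel carries all 15 markers; the five organ-system
#' panels partition them: cardiopulmonary (SBP, PEF), metabolic (LDL-CH,
#' HDL-CH, HBA1C, TG, WHR), liver (AST, GGT, ALP, ALB), renal (Cr, urea)
#' and immune (PLT, MCV).
#'
#' @return named list of marker-name vectors.
#' @export
kdm_panels <- function() {
  list(
    comprehensive = c("sbp", "whr", "pef", "ggt", "alb", "ldl", "hdl",
                      "tg", "ast", "cr", "alp", "urea", "mcv", "hba1c",
                      "plt"),
    cardiopulmonary = c("sbp", "pef"),
    metabolic = c("ldl", "hdl", "hba1c", "tg", "whr"),
    liver = c("ast", "ggt", "alp", "alb"),
    renal = c("cr", "urea"),
    immune = c("plt", "mcv")
  )
}

#' Read panel definitions from a YAML file
#'
#' @param path YAML file mapping panel name to a list of marker names.
#' @return named list of marker-name vectors.
#' @export
read_panels <- function(path) {
  panels <- yaml::read_yaml(path)
  lapply(panels, unlist)
}

#' Screen candidate biomarkers for biological age construction
#'
#' Retains markers whose missingness is below `max_missing` and whose
#' Pearson correlation with chronological age reaches
#' `min_age_correlation` in absolute value in both sex strata, with a
#' consistent sign across strata.
#'
#' @param data panel data.frame with `age`, `sex` and candidate columns.
#' @param candidates character vector of candidate marker columns.
#' @param max_missing maximum tolerated missingness proportion
#'   (default 0.30, exclusive).
#' @param min_age_correlation minimum absolute age correlation
#'   (default 0.10).
#' @return character vector of surviving markers.
#' @export
screen_biomarkers <- function(data, candidates, max_missing = 0.30,
                              min_age_correlation = 0.10) {
  keep <- vapply(candidates, function(m) {
    miss <- mean(is.na(data[[m]]))
    if (miss >= max_missing) return(FALSE)
    rs <- vapply(c("female", "male"), function(sx) {
      sub <- data[data$sex == sx, ]
      if (nrow(sub) < 3) return(NA_real_)
      cor(sub[[m]], sub$age, use = "complete.obs")
    }, numeric(1))
    if (any(is.na(rs))) return(FALSE)
    all(abs(rs) >= min_age_correlation) && length(unique(sign(rs))) == 1
  }, logical(1))
  survivors <- candidates[keep]
  if (!length(survivors)) {
    stop("screen_biomarkers: no marker survived the screen")
  }
  survivors
}

fit_kdm_stratum <- function(data, markers) {
  data <- data[complete.cases(data[, c("age", markers)]), ]
  if (length(unique(data$age)) < 2) {
    stop("fit_kdm: need at least two distinct ages in the training data")
  }
  n <- nrow(data)
  est <- lapply(markers, function(m) {
    if (var(data[[m]]) < .Machine$double.eps) {
      stop("fit_kdm: marker '", m, "' is constant (zero or undefined age slope)")
    }
    fit <- lm(data[[m]] ~ data$age)
    k <- unname(coef(fit)[2])
    if (!is.finite(k) || k == 0) {
      stop("fit_kdm: marker '", m, "' has zero or undefined age slope")
    }
    s <- sqrt(sum(resid(fit)^2) / (n - 2))
    data.frame(marker = m, q = unname(coef(fit)[1]), k = k,
               s = max(s, 1e-8), r = cor(data[[m]], data$age))
  })
  est <- do.call(rbind, est)

  # characteristic correlation: |r| weighted by r / sqrt(1 - r^2)
  r_abs <- pmin(abs(est$r), 1 - 1e-12)
  w <- r_abs / sqrt(1 - r_abs^2)
  r_char <- sum(r_abs * w) / sum(w)

  # s_BA^2: residual dispersion of BA_E around CA beyond what finite-panel
  # sampling noise explains
  m <- length(markers)
  ba_e <- kdm_ba_e(data[, markers, drop = FALSE], est)
  age_range <- diff(range(data$age))
  s_ba2 <- mean((ba_e - data$age)^2) -
    ((1 - r_char^2) / r_char^2) * age_range^2 / (12 * m)
  s_ba <- sqrt(max(s_ba2, 1e-2))

  list(estimates = est, r_char = r_char, s_ba = s_ba,
       age_range = range(data$age), n = n)
}

#' Fit sex-stratified Klemera-Doubal model parameters
#'
#' Per sex stratum and marker, ordinary least squares of the marker on
#' chronological age yields the intercept `q`, slope `k` and residual SD
#' `s`. The characteristic correlation `r_char` is the weighted mean
#' absolute marker-age correlation (weights \eqn{|r|/\sqrt{1-r^2}}), and
#' the age-anchor variance \eqn{s_{BA}^2} is estimated as the mean squared
#' deviation of the uncorrected estimate from chronological age minus the
#' model-implied sampling dispersion
#' \eqn{(1-r_{char}^2)/r_{char}^2 \cdot (\Delta age)^2 / (12m)}, floored at
#' a small positive constant. Fitting uses complete cases only.
#'
#' @param training panel data.frame (typically baseline-wave records).
#' @param markers character vector of marker columns.
#' @return object of class `kdm_params`: per-sex parameter tables plus
#'   `r_char`, `s_ba`, training age range and n.
#' @export
fit_kdm <- function(training, markers) {
  sexes <- intersect(c("female", "male"), unique(training$sex))
  if (!length(sexes)) stop("fit_kdm: no recognized sex stratum in training")
  strata <- lapply(setNames(sexes, sexes), function(sx) {
    fit_kdm_stratum(training[training$sex == sx, ], markers)
  })
  structure(list(strata = strata, markers = markers), class = "kdm_params")
}

#' @export
print.kdm_params <- function(x, ...) {
  cat("Klemera-Doubal parameters for", length(x$markers), "markers\n")
  for (sx in names(x$strata)) {
    st <- x$strata[[sx]]
    cat(sprintf("  %s: n = %d, r_char = %.3f, s_BA = %.2f years\n",
                sx, st$n, st$r_char, st$s_ba))
  }
  invisible(x)
}

# Uncorrected KDM estimate: slope/noise-weighted average of per-marker
# inverse-regression ages.
kdm_ba_e <- function(x, est) {
  x <- as.matrix(x[, est$marker, drop = FALSE])
  num <- sweep(sweep(x, 2, est$q, `-`), 2, est$k / est$s^2, `*`)
  denom <- sum((est$k / est$s)^2)
  rowSums(num) / denom
}

#' Estimate Klemera-Doubal biological age
#'
#' The uncorrected estimate is
#' \deqn{BA_E = \sum_j (x_j - q_j) k_j / s_j^2 \; / \; \sum_j (k_j/s_j)^2,}
#' a weighted average of per-marker inverse-regression ages. With
#' `use_ca_anchor` (the default, the headline estimator) chronological age
#' enters as one more pseudo-marker with variance \eqn{s_{BA}^2}:
#' \deqn{BA_{EC} = \left(\sum_j (x_j - q_j) k_j / s_j^2 + CA/s_{BA}^2\right)
#'   / \left(\sum_j (k_j/s_j)^2 + 1/s_{BA}^2\right).}
#' Acceleration is BA minus chronological age. Records missing any panel
#' marker are skipped (complete-case) with a message reporting the count.
#'
#' @param data panel data.frame with `person_id`, `wave`, `age`, `sex` and
#'   the marker columns.
#' @param params a [fit_kdm()] result.
#' @param use_ca_anchor logical; if `FALSE` the uncorrected \eqn{BA_E} is
#'   returned.
#' @return data.frame with `person_id`, `wave`, `age`, `ba`,
#'   `ba_acceleration`.
#' @export
estimate_ba <- function(data, params, use_ca_anchor = TRUE) {
  stopifnot(inherits(params, "kdm_params"))
  markers <- params$markers
  complete <- complete.cases(data[, c("age", "sex", markers)])
  n_skip <- sum(!complete)
  if (n_skip > 0) {
    message("estimate_ba: skipped ", n_skip,
            " record(s) with missing panel markers")
  }
  data <- data[complete, ]
  ba <- numeric(nrow(data))
  for (sx in names(params$strata)) {
    idx <- which(data$sex == sx)
    if (!length(idx)) next
    st <- params$strata[[sx]]
    est <- st$estimates
    num <- rowSums(sweep(
      sweep(as.matrix(data[idx, est$marker, drop = FALSE]), 2, est$q, `-`),
      2, est$k / est$s^2, `*`))
    denom <- sum((est$k / est$s)^2)
    if (use_ca_anchor) {
      ba[idx] <- (num + data$age[idx] / st$s_ba^2) / (denom + 1 / st$s_ba^2)
    } else {
      ba[idx] <- num / denom
    }
  }
  data.frame(person_id = data$person_id, wave = data$wave, age = data$age,
             ba = ba, ba_acceleration = ba - data$age)
}

#' Fit and score all biomarker panels
#'
#' Fits sex-stratified KDM parameters per panel on the training wave
#' (baseline by default) and scores every record of `data`, so both waves
#' are measured on one parameter set and within-person change is
#' interpretable.
#'
#' @param data panel data.frame.
#' @param panels named list of marker vectors, see [kdm_panels()].
#' @param training_wave wave used for fitting (default 0).
#' @param use_ca_anchor see [estimate_ba()].
#' @return list with `params` (per panel) and `ba` (long data.frame with a
#'   `panel` column).
#' @export
score_panels <- function(data, panels = kdm_panels(), training_wave = 0,
                         use_ca_anchor = TRUE) {
  params <- lapply(panels, function(markers) {
    fit_kdm(data[data$wave == training_wave, ], markers)
  })
  ba <- do.call(rbind, lapply(names(panels), function(p) {
    res <- estimate_ba(data, params[[p]], use_ca_anchor = use_ca_anchor)
    cbind(panel = p, res)
  }))
  rownames(ba) <- NULL
  list(params = params, ba = ba)
}
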