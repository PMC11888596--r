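#' Panel-to-disease validation map
#'
#' Which self-reported diseases each biological age is expected to reflect:
#' comprehensive - CVD, diabetes, cancer; cardiopulmonary - CVD, chronic
#' bronchitis; metabolic - CVD, diabetes; liver - chronic hepatitis or
#' cirrhosis; immune - rheumatoid arthritis. The renal panel has no mapped
#' disease and is unvalidatable. The cardiopulmonary acceleration is never
#' analyzed as a categorical variable (its values are small).
#'
#' @return data.frame with columns `panel`, `disease`, `categorize`.
#' @export
validation_disease_map <- function() {
  data.frame(
    panel = c("comprehensive", "comprehensive", "comprehensive",
              "cardiopulmonary", "cardiopulmonary",
              "metabolic", "metabolic", "liver", "immune"),
    disease = c("cvd", "diabetes", "cancer",
                "cvd", "chronic_bronchitis",
                "cvd", "diabetes", "hepatitis_cirrhosis",
                "rheumatoid_arthritis"),
    categorize = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Standardize and categorize biological age acceleration
#'
#' Standardizes acceleration against a reference population (z score) and
#' categorizes it with the +/-1 cut — mid (|value| <= 1, the reference
#' group), low (< -1) and high (> 1) — on the standardized scale by
#' default, switchable to raw years.
#'
#' @param accel numeric acceleration values (years).
#' @param reference numeric reference population (default `accel` itself).
#' @param cut cutoff (default 1).
#' @param scale `"z"` (cut on the z scale) or `"raw"` (cut on years).
#' @return data.frame with `z` and `category` (factor with reference level
#'   `mid`).
#' @export
standardize_and_categorize <- function(accel, reference = accel, cut = 1,
                                       scale = c("z", "raw")) {
  scale <- match.arg(scale)
  mu <- mean(reference, na.rm = TRUE)
  sigma <- sd(reference, na.rm = TRUE)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("standardize_and_categorize: reference SD must be positive")
  }
  z <- (accel - mu) / sigma
  basis <- if (scale == "z") z else accel
  category <- factor(ifelse(basis < -cut, "low",
                            ifelse(basis > cut, "high", "mid")),
                     levels = c("mid", "low", "high"))
  data.frame(z = z, category = category)
}

#' Logistic association between an exposure and a disease
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary outcome on one exposure term plus covariates, returning odds
#' ratios with Wald 95% confidence intervals per exposure coefficient.
#' Non-convergence or separation is flagged, never returned as a silent
#' `NaN`.
#'
#' @param data data.frame holding outcome, exposure and covariates.
#' @param outcome name of the 0/1 outcome column.
#' @param exposure name of the exposure column (numeric or factor).
#' @param covariates character vector of covariate columns.
#' @return data.frame with one row per exposure term: `term`, `estimate`
#'   (log odds), `or`, `ci_low`, `ci_high`, `p`, `flagged`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(0)) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("fit_logistic: outcome '", outcome, "' does not have both classes")
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- suppressWarnings(glm(form, data = data, family = binomial()))
  cf <- summary(fit)$coefficients
  terms <- grep(paste0("^", exposure), rownames(cf), value = TRUE)
  if (!length(terms)) stop("fit_logistic: exposure dropped from the fit")
  flagged <- !fit$converged || any(abs(cf[terms, "Estimate"]) > 10) ||
    any(cf[terms, "Std. Error"] > 10)
  data.frame(
    term = terms,
    estimate = cf[terms, "Estimate"],
    or = exp(cf[terms, "Estimate"]),
    ci_low = exp(cf[terms, "Estimate"] - 1.96 * cf[terms, "Std. Error"]),
    ci_high = exp(cf[terms, "Estimate"] + 1.96 * cf[terms, "Std. Error"]),
    p = cf[terms, "Pr(>|z|)"],
    flagged = flagged,
    row.names = NULL
  )
}

#' Cross-sectional disease validation of the biological age panels
#'
#' For each mapped panel-disease pair, regresses the baseline disease flag
#' on the standardized acceleration (per-SD continuous term) and, where
#' categorization is allowed, on the low/mid/high categories, adjusting
#' for the five lifestyle flags plus the covariate set.
#'
#' @param data baseline-wave panel data.frame with disease and covariate
#'   columns.
#' @param ba long biological-age data.frame from [score_panels()].
#' @param hli lifestyle record from [classify_lifestyle()] (baseline wave).
#' @param map see [validation_disease_map()].
#' @param covariates covariate columns adjusted for in addition to the five
#'   lifestyle flags.
#' @return data.frame report: `panel`, `disease`, `term`, `or`, `ci_low`,
#'   `ci_high`, `p`, `flagged`.
#' @export
validate_panels <- function(data, ba, hli,
                            map = validation_disease_map(),
                            covariates = c("age", "sex", "ethnicity",
                                           "urbanicity", "education")) {
  lifestyle_cols <- paste0("healthy_", lifestyle_factors())
  ba0 <- ba[ba$wave == 0, ]
  rows <- list()
  for (i in seq_len(nrow(map))) {
    p <- map$panel[i]; d <- map$disease[i]
    pan <- ba0[ba0$panel == p, ]
    sc <- standardize_and_categorize(pan$ba_acceleration)
    df <- cbind(pan[, "person_id", drop = FALSE], sc)
    df <- merge(df, data[data$wave == 0,
                         c("person_id", d, covariates)], by = "person_id")
    df <- merge(df, hli[hli$wave == 0, c("person_id", lifestyle_cols)],
                by = "person_id")
    covs <- c(lifestyle_cols, covariates)
    cont <- fit_logistic(df, d, "z", covs)
    cont$term <- "per_sd"
    out <- cbind(panel = p, disease = d, cont)
    if (map$categorize[i]) {
      cat_fit <- fit_logistic(df, d, "category", covs)
      cat_fit$term <- sub("^category", "category_", cat_fit$term)
      out <- rbind(out, cbind(panel = p, disease = d, cat_fit))
    }
    rows[[i]] <- out
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report
}

#' Decide which panels pass validation
#'
#' A panel passes when, for at least one of its mapped diseases, the
#' continuous per-SD odds ratio exceeds 1 with a 95% CI excluding 1.
#' Panels with no mapped disease are marked unvalidatable.
#'
#' @param report output of [validate_panels()].
#' @param map see [validation_disease_map()].
#' @param panels panel names under consideration.
#' @return list with `validated` (character vector) and `unvalidatable`.
#' @export
select_validated_panels <- function(report, map = validation_disease_map(),
                                    panels = names(kdm_panels())) {
  cont <- report[report$term == "per_sd", ]
  passed <- vapply(unique(cont$panel), function(p) {
    sub <- cont[cont$panel == p, ]
    any(sub$or > 1 & sub$ci_low > 1 & !sub$flagged)
  }, logical(1))
  validated <- names(passed)[passed]
  unvalidatable <- setdiff(panels, unique(map$panel))
  list(validated = validated, unvalidatable = unvalidatable)
}
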