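#' Quantile-score an exposure
#'
#' Bins a numeric exposure into integer scores 0..q-1 using right-closed
#' breaks at the empirical quantiles. Score-like exposures whose values
#' already lie in \{-1, 0, 1\} (binary flags and between-wave flag
#' changes) pass through unchanged regardless of `q`. A constant exposure
#' scores all zeros with a warning.
#'
#' @param x numeric exposure values.
#' @param q number of quantile groups (default 4).
#' @return integer scores.
#' @export
quantize <- function(x, q = 4) {
  if (q < 2) stop("quantize: q must be at least 2")
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= 1) {
    warning("quantize: constant exposure; all scores 0")
    return(ifelse(is.na(x), NA_integer_, 0L))
  }
  if (all(ux %in% c(-1, 0, 1))) {
    return(as.integer(x))
  }
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = q + 1),
                            na.rm = TRUE, names = FALSE, type = 7))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE,
                 right = TRUE)) - 1L
}

# Sign-grouped normalized contribution weights from exposure coefficients.
qgc_weights <- function(coefs) {
  neg <- coefs[coefs < 0]
  pos <- coefs[coefs > 0]
  list(
    negative = if (length(neg)) abs(neg) / sum(abs(neg)) else
      setNames(numeric(0), character(0)),
    positive = if (length(pos)) pos / sum(pos) else
      setNames(numeric(0), character(0))
  )
}

#' Quantile G-computation of the lifestyle mixture effect
#'
#' Linear quantile G-computation on the person-level differenced data
#' (same differencing convention and covariates as [fit_fem()], so the two
#' analyses answer the same estimand): the outcome change is regressed on
#' quantile-scored exposure changes plus covariates. The mixture effect
#' \eqn{\psi} — the expected outcome change per joint one-quantile increase
#' in every exposure — is the sum of the exposure coefficients; relative
#' contributions are the coefficients normalized within their sign group.
#' Negative-direction weights are the headline output (protective
#' contributions); positive weights are reported but flagged separately.
#' The \eqn{\psi} confidence interval comes from a seeded nonparametric
#' bootstrap over persons, or from the HC1 Wald interval when
#' `bootstrap_reps = 0`.
#'
#' @inheritParams build_difference_data
#' @param q number of quantile groups for non-score exposures.
#' @param bootstrap_reps bootstrap replicates (default 200; 0 for Wald).
#' @param seed bootstrap seed.
#' @return list of class `qgc_result`: `psi`, `se`, `ci_low`, `ci_high`,
#'   `coefs` (named per-factor coefficients), `weights_negative`,
#'   `weights_positive`, `n`, `bootstrap_reps`.
#' @export
fit_qgc <- function(data, ba, hli, spec = fem_spec(exposure = "factors"),
                    q = 4, bootstrap_reps = 200, seed = 1L) {
  if (bootstrap_reps < 0) stop("fit_qgc: bootstrap_reps must be >= 0")
  dd <- build_difference_data(data, ba, hli, spec)
  for (cl in dd$exposure_cols) {
    dd$df[[cl]] <- quantize(dd$df[[cl]], q = q)
  }
  fo <- fit_difference_ols(dd)
  cf <- coef(fo$fit)
  exp_coefs <- cf[dd$exposure_cols]
  names(exp_coefs) <- sub("^healthy_", "", sub("^d_", "",
                                               dd$exposure_cols))
  psi <- sum(exp_coefs)
  w <- qgc_weights(exp_coefs)

  if (bootstrap_reps > 0) {
    set.seed(seed)
    df <- fo$df
    rhs <- c(dd$exposure_cols, fo$covariate_cols)
    form <- stats::as.formula(paste("d_outcome ~",
                                    paste(rhs, collapse = " + ")))
    psis <- vapply(seq_len(bootstrap_reps), function(b) {
      idx <- sample.int(nrow(df), replace = TRUE)
      bfit <- lm(form, data = df[idx, ])
      sum(coef(bfit)[dd$exposure_cols], na.rm = TRUE)
    }, numeric(1))
    se <- sd(psis)
    ci <- unname(quantile(psis, c(0.025, 0.975), type = 7))
  } else {
    vc <- sandwich::vcovHC(fo$fit, type = "HC1")
    ones <- rep(1, length(dd$exposure_cols))
    se <- sqrt(drop(t(ones) %*% vc[dd$exposure_cols, dd$exposure_cols] %*%
                      ones))
    ci <- c(psi - 1.96 * se, psi + 1.96 * se)
  }

  structure(list(
    panel = spec$panel, psi = psi, se = se, ci_low = ci[1], ci_high = ci[2],
    coefs = exp_coefs, weights_negative = w$negative,
    weights_positive = w$positive, n = nrow(fo$df),
    bootstrap_reps = bootstrap_reps
  ), class = "qgc_result")
}

#' @export
print.qgc_result <- function(x, ...) {
  cat(sprintf("Quantile G-computation (%s): psi = %.3f (95%% CI %.3f, %.3f), n = %d\n",
              x$panel, x$psi, x$ci_low, x$ci_high, x$n))
  if (length(x$weights_negative)) {
    cat("  negative-direction weights:\n")
    for (nm in names(x$weights_negative)) {
      cat(sprintf("    %-10s %.3f\n", nm, x$weights_negative[[nm]]))
    }
  }
  if (length(x$weights_positive)) {
    cat("  positive-direction weights (reported, not headline):\n")
    for (nm in names(x$weights_positive)) {
      cat(sprintf("    %-10s %.3f\n", nm, x$weights_positive[[nm]]))
    }
  }
  invisible(x)
}

#' Tidy a QGC result for tabulation or plotting
#'
#' @param x a `qgc_result`.
#' @param fem optional `fem_result` for the same panel/exposures; when
#'   supplied, each factor's weight is annotated with whether its
#'   fixed-effects estimate is statistically significant (CI excluding 0),
#'   the convention used to shade contribution bars.
#' @return data.frame with `panel`, `factor`, `coef`, `direction`,
#'   `weight`, and optionally `fem_significant`.
#' @export
tidy_qgc <- function(x, fem = NULL) {
  out <- data.frame(
    panel = x$panel, factor = names(x$coefs), coef = unname(x$coefs),
    direction = ifelse(x$coefs < 0, "negative",
                       ifelse(x$coefs > 0, "positive", "zero")),
    weight = NA_real_, row.names = NULL)
  for (nm in names(x$weights_negative)) {
    out$weight[out$factor == nm] <- x$weights_negative[[nm]]
  }
  for (nm in names(x$weights_positive)) {
    out$weight[out$factor == nm] <- x$weights_positive[[nm]]
  }
  if (!is.null(fem)) {
    fem <- as.data.frame(fem)
    fem$factor <- sub("^healthy_", "", fem$term)
    sig <- fem$ci_low > 0 | fem$ci_high < 0
    out$fem_significant <- sig[match(out$factor, fem$factor)]
  }
  out
}
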