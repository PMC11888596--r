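#' Modified alternate Mediterranean diet score components
#'
#' Seven food-group components retained after dropping the alcohol item
#' (so the total ranges 7-35 with quintile scoring 1-5 per component).
#' `direction = 1` marks protective components (higher intake scores
#' higher); `direction = -1` marks red/processed meat (lower intake scores
#' higher). The component list is configurable wherever it is consumed.
#'
#' @return data.frame with columns `component`, `column`, `direction`.
#' @export
amed_components <- function() {
  data.frame(
    component = c("vegetables", "legumes", "fruits", "nuts",
                  "whole_grains", "fish", "red_processed_meat"),
    column = c("diet_vegetables", "diet_legumes", "diet_fruits",
               "diet_nuts", "diet_whole_grains", "diet_fish",
               "diet_red_processed_meat"),
    direction = c(1, 1, 1, 1, 1, 1, -1)
  )
}

# Quintile score 1-5 of x against a reference population, using average
# ranks with right-closed bins; a degenerate (constant) reference scores
# everyone 3.
quintile_score <- function(x, ref, direction = 1) {
  ref <- ref[!is.na(ref)]
  if (!length(ref)) stop("quintile_score: empty reference population")
  n <- length(ref)
  sref <- sort(ref)
  n_le <- findInterval(x, sref)                    # ref values <= x
  n_lt <- findInterval(x, sref, left.open = TRUE)  # ref values <  x
  ties <- n_le - n_lt
  p <- if (direction >= 0) {
    (n_lt + (ties + 1) / 2) / (n + 1)
  } else {
    ((n - n_le) + (ties + 1) / 2) / (n + 1)
  }
  score <- pmin(5L, pmax(1L, as.integer(ceiling(5 * p))))
  score[is.na(x)] <- NA_integer_
  score
}

#' Score the modified alternate Mediterranean diet (aMED)
#'
#' Each of the seven components is scored 1-5 by quintile rank within the
#' reference population, respecting consumption direction (protective
#' components score high when intake is high; red/processed meat scores
#' high when intake is low); the total is the component sum, ranging 7-35.
#' Records with any missing component score `NA` (complete-case handling
#' happens downstream).
#'
#' @param diet data.frame holding the component intake columns.
#' @param reference data.frame holding the same columns for the reference
#'   population whose quintiles define the scoring (typically the same-wave
#'   analysis population).
#' @param components component definition, see [amed_components()].
#' @return integer vector of aMED scores in \code{[7, 35]} (or `NA`).
#' @export
score_amed <- function(diet, reference = diet,
                       components = amed_components()) {
  missing_cols <- setdiff(components$column, names(diet))
  if (length(missing_cols)) {
    stop("score_amed: missing diet component columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(reference)) stop("score_amed: empty reference population")
  scores <- sapply(seq_len(nrow(components)), function(i) {
    col <- components$column[i]
    quintile_score(diet[[col]], reference[[col]], components$direction[i])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(diet))
  as.integer(rowSums(scores))
}

#' Healthy lifestyle definitions
#'
#' Primary criteria: never smoking; non-regular drinking (frequency below
#' once/week); diet with aMED at or above the same-wave population median;
#' regular exercise (1-2/week, 3-5/week or daily); sleep in the closed
#' interval 7-8 hours/night. `alternative_definitions()` supplies the
#' one-factor-at-a-time overlays used by the sensitivity suite: former
#' smokers also count as healthy; drinking up to 3 times/week; diet in the
#' top 40%; exercise at least 3 times/week; sleep 6-9 hours.
#'
#' @return named list of per-factor criterion parameters.
#' @export
lifestyle_definitions <- function() {
  list(
    smoking = list(healthy_statuses = "never"),
    alcohol = list(max_frequency = 1, inclusive = FALSE),
    diet = list(quantile = 0.5, rule = ">="),
    exercise = list(healthy_levels = c("1-2/week", "3-5/week", "daily")),
    sleep = list(range = c(7, 8))
  )
}

#' @rdname lifestyle_definitions
#' @param factor which factor's alternative definition to overlay onto the
#'   primary definitions.
#' @export
alternative_definitions <- function(factor = lifestyle_factors()) {
  factor <- match.arg(factor)
  alt <- switch(factor,
    smoking = list(healthy_statuses = c("never", "former")),
    alcohol = list(max_frequency = 3, inclusive = TRUE),
    diet = list(quantile = 0.6, rule = ">="),
    exercise = list(healthy_levels = c("3-5/week", "daily")),
    sleep = list(range = c(6, 9))
  )
  defs <- lifestyle_definitions()
  defs[[factor]] <- alt
  defs
}

smoking_levels <- function() c("never", "former", "current")
exercise_levels <- function() c("never/rare", "1-2/week", "3-5/week", "daily")

#' Classify the five healthy lifestyle flags and compute the HLI
#'
#' Applies the configured criteria to the raw lifestyle fields of a panel
#' data.frame. The diet flag is relative: the aMED score is computed within
#' each wave (the reference population for quintiles and the median
#' threshold is the same-wave analysis population).
#'
#' @param data panel data.frame with columns `smoking_status`,
#'   `drink_frequency`, `exercise_frequency`, `sleep_hours`, the diet
#'   component columns, and `wave`.
#' @param definitions see [lifestyle_definitions()].
#' @param components see [amed_components()].
#' @return data.frame with `person_id`, `wave`, the five `healthy_*` flags,
#'   `amed`, `hli` (0-5) and `hli_category` ("healthy" for 4-5 else
#'   "unfavorable").
#' @export
classify_lifestyle <- function(data, definitions = lifestyle_definitions(),
                               components = amed_components()) {
  bad_smoke <- setdiff(unique(data$smoking_status), smoking_levels())
  if (length(bad_smoke)) {
    stop("classify_lifestyle: unknown smoking_status level(s): ",
         paste(bad_smoke, collapse = ", "))
  }
  bad_ex <- setdiff(unique(data$exercise_frequency), exercise_levels())
  if (length(bad_ex)) {
    stop("classify_lifestyle: unknown exercise_frequency level(s): ",
         paste(bad_ex, collapse = ", "))
  }
  if (any(data$sleep_hours <= 0 | data$sleep_hours >= 24, na.rm = TRUE)) {
    stop("classify_lifestyle: sleep_hours must lie in (0, 24)")
  }

  healthy_smoking <-
    as.integer(data$smoking_status %in% definitions$smoking$healthy_statuses)
  alc <- definitions$alcohol
  healthy_alcohol <- if (isTRUE(alc$inclusive)) {
    as.integer(data$drink_frequency <= alc$max_frequency)
  } else {
    as.integer(data$drink_frequency < alc$max_frequency)
  }
  healthy_exercise <-
    as.integer(data$exercise_frequency %in% definitions$exercise$healthy_levels)
  rng <- definitions$sleep$range
  healthy_sleep <- as.integer(data$sleep_hours >= rng[1] &
                                data$sleep_hours <= rng[2])

  amed <- rep(NA_integer_, nrow(data))
  healthy_diet <- rep(NA_integer_, nrow(data))
  for (w in unique(data$wave)) {
    idx <- which(data$wave == w)
    ref <- data[idx, , drop = FALSE]
    amed[idx] <- score_amed(ref, reference = ref, components = components)
    threshold <- quantile(amed[idx], probs = definitions$diet$quantile,
                          na.rm = TRUE, names = FALSE, type = 7)
    healthy_diet[idx] <- if (definitions$diet$rule == ">=") {
      as.integer(amed[idx] >= threshold)
    } else {
      as.integer(amed[idx] > threshold)
    }
  }

  flags <- data.frame(
    healthy_smoking = healthy_smoking, healthy_alcohol = healthy_alcohol,
    healthy_diet = healthy_diet, healthy_exercise = healthy_exercise,
    healthy_sleep = healthy_sleep
  )
  hli <- compute_hli(flags)
  cbind(data.frame(person_id = data$person_id, wave = data$wave),
        flags, data.frame(amed = amed, hli = hli$hli,
                          hli_category = hli$hli_category))
}

#' Healthy Lifestyle Index from the five binary flags
#'
#' HLI is the straight sum of the five healthy-factor flags (0-5);
#' scores of 4-5 are dichotomized as "healthy", 0-3 as "unfavorable".
#'
#' @param flags data.frame or matrix with five 0/1 columns (order
#'   irrelevant).
#' @return data.frame with `hli` and `hli_category`.
#' @export
compute_hli <- function(flags) {
  flags <- as.matrix(flags)
  if (ncol(flags) != 5) stop("compute_hli: expected exactly five flags")
  if (!all(flags %in% c(0, 1, NA))) {
    stop("compute_hli: flags must be 0/1")
  }
  hli <- as.integer(rowSums(flags))
  data.frame(hli = hli,
             hli_category = ifelse(is.na(hli), NA_character_,
                                   ifelse(hli >= 4, "healthy", "unfavorable")))
}

change_level <- function(before, after) {
  factor(ifelse(after > before, "healthier",
                ifelse(after < before, "unhealthier", "unchanged")),
         levels = c("healthier", "unchanged", "unhealthier"))
}

#' Categorize between-wave lifestyle change
#'
#' For a single factor, "healthier" means unhealthy at wave 0 and healthy
#' at wave 1 (and vice versa); "unchanged" means the same state at both
#' waves. The continuous HLI change compares scores, the categorical HLI
#' change compares the healthy/unfavorable categories.
#'
#' @param wave0,wave1 outputs of [classify_lifestyle()] restricted to one
#'   wave each; matched on `person_id`.
#' @return data.frame with `person_id`, per-factor change columns,
#'   `hli_range_change` and `hli_category_change`, each a factor with
#'   levels healthier/unchanged/unhealthier.
#' @export
categorize_change <- function(wave0, wave1) {
  common <- intersect(wave0$person_id, wave1$person_id)
  w0 <- wave0[match(common, wave0$person_id), ]
  w1 <- wave1[match(common, wave1$person_id), ]
  out <- data.frame(person_id = common)
  for (f in lifestyle_factors()) {
    col <- paste0("healthy_", f)
    out[[paste0(f, "_change")]] <- change_level(w0[[col]], w1[[col]])
  }
  out$hli_range_change <- change_level(w0$hli, w1$hli)
  out$hli_category_change <- change_level(
    as.integer(w0$hli_category == "healthy"),
    as.integer(w1$hli_category == "healthy"))
  out
}
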