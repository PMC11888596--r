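ref_diet <- function(n = 200, seed = 2) {
  set.seed(seed)
  cols <- amed_components()$column
  as.data.frame(setNames(lapply(cols, function(cl) rlnorm(n, 3, 0.6)),
                         cols))
}

test_that("aMED attains its printed extremes under quintile scoring", {
  ref <- ref_diet()
  cols <- amed_components()$column
  best <- as.data.frame(as.list(setNames(
    vapply(cols, function(cl) max(ref[[cl]]) * 2, numeric(1)), cols)))
  best$diet_red_processed_meat <- 0  # least meat is most protective
  worst <- as.data.frame(as.list(setNames(
    vapply(cols, function(cl) 0, numeric(1)), cols)))
  worst$diet_red_processed_meat <- max(ref$diet_red_processed_meat) * 2
  expect_identical(score_amed(best, ref), 35L)
  expect_identical(score_amed(worst, ref), 7L)
  # every reference score lies within the printed range
  scores <- score_amed(ref, ref)
  expect_true(all(scores >= 7 & scores <= 35))
})

test_that("degenerate constant components score the midpoint", {
  cols <- amed_components()$column
  const <- as.data.frame(setNames(lapply(cols, function(cl) rep(5, 40)),
                                  cols))
  expect_true(all(score_amed(const, const) == 7L * 3L))
})

test_that("aMED is invariant to monotone transforms of a component", {
  ref <- ref_diet(n = 150, seed = 7)
  transformed <- ref
  transformed$diet_fish <- log(transformed$diet_fish)
  transformed$diet_red_processed_meat <-
    sqrt(transformed$diet_red_processed_meat)
  expect_identical(score_amed(ref, ref), score_amed(transformed, transformed))
})

test_that("records missing a diet component score NA", {
  ref <- ref_diet(n = 60, seed = 3)
  holey <- ref
  holey$diet_nuts[1] <- NA
  s <- score_amed(holey, ref)
  expect_true(is.na(s[1]))
  expect_false(anyNA(s[-1]))
  expect_error(score_amed(ref[, -1], ref), "missing diet component")
})

make_raw_panel <- function() {
  # four one-wave records with clearly separated diet quality
  ref <- ref_diet(n = 4, seed = 5)
  good <- lapply(ref, function(x) x * 4)
  bad <- lapply(ref, function(x) x / 4)
  diet <- as.data.frame(rbind(
    within(as.data.frame(good), diet_red_processed_meat <- 0.1),
    within(as.data.frame(bad), diet_red_processed_meat <- 500)
  ))[c(1, 5, 2, 6), ]  # persons 1,3 high-quality diet; 2,4 low-quality
  cbind(
    data.frame(
      person_id = 1:4, wave = 0L,
      smoking_status = c("never", "current", "former", "never"),
      drink_frequency = c(0, 7, 0.99, 1.0),
      exercise_frequency = c("3-5/week", "never/rare", "daily", "1-2/week"),
      sleep_hours = c(7.5, 5, 7.0, 6.99)),
    diet)
}

test_that("factor classification matches the stated criteria and boundaries", {
  hli <- classify_lifestyle(make_raw_panel())
  # person 1: never smoker, non-drinker, high-quality diet, regular
  # exercise, 7.5 h sleep -> all healthy
  expect_equal(unlist(hli[1, paste0("healthy_", lifestyle_factors())]),
               c(healthy_smoking = 1, healthy_alcohol = 1, healthy_diet = 1,
                 healthy_exercise = 1, healthy_sleep = 1))
  expect_equal(hli$hli[1], 5)
  expect_equal(hli$hli_category[1], "healthy")
  # person 2: fails every criterion
  expect_equal(hli$hli[2], 0)
  expect_equal(hli$hli_category[2], "unfavorable")
  # boundaries: sleep 7.0 healthy, 6.99 not; drink 0.99 healthy, 1.0 not
  expect_equal(hli$healthy_sleep[3], 1)
  expect_equal(hli$healthy_sleep[4], 0)
  expect_equal(hli$healthy_alcohol[3], 1)
  expect_equal(hli$healthy_alcohol[4], 0)
  # former smoker is unhealthy under the primary definition ...
  expect_equal(hli$healthy_smoking[3], 0)
  # ... but healthy under the alternative overlay
  alt <- classify_lifestyle(make_raw_panel(),
                            alternative_definitions("smoking"))
  expect_equal(alt$healthy_smoking[3], 1)
})

test_that("unknown categorical levels are rejected", {
  bad <- make_raw_panel()
  bad$smoking_status[1] <- "sometimes"
  expect_error(classify_lifestyle(bad), "unknown smoking_status")
  bad2 <- make_raw_panel()
  bad2$exercise_frequency[1] <- "weekly"
  expect_error(classify_lifestyle(bad2), "unknown exercise_frequency")
})

test_that("HLI is the flag sum, dichotomized at 4, and monotone", {
  combos <- expand.grid(rep(list(0:1), 5))
  names(combos) <- paste0("healthy_", lifestyle_factors())
  hli <- compute_hli(combos)
  expect_equal(hli$hli, rowSums(combos), ignore_attr = TRUE)
  expect_true(all(hli$hli >= 0 & hli$hli <= 5))
  expect_equal(hli$hli_category, ifelse(hli$hli >= 4, "healthy",
                                        "unfavorable"))
  # permutation invariance
  perm <- combos[, c(3, 1, 5, 2, 4)]
  expect_equal(compute_hli(perm)$hli, hli$hli)
  # monotone: turning any flag on never lowers the score
  for (j in 1:5) {
    up <- combos; up[, j] <- 1
    expect_true(all(compute_hli(up)$hli >= hli$hli))
  }
  expect_error(compute_hli(combos[, 1:4]), "five flags")
  expect_error(compute_hli(combos * 2), "0/1")
})

test_that("change categorization matches definitions and is antisymmetric", {
  mk <- function(ids, flags, hli, cat) {
    cbind(data.frame(person_id = ids, wave = NA), flags,
          data.frame(hli = hli, hli_category = cat))
  }
  flags0 <- data.frame(healthy_smoking = c(1, 1), healthy_alcohol = c(0, 1),
                       healthy_diet = c(0, 1), healthy_exercise = c(1, 1),
                       healthy_sleep = c(0, 1))
  flags1 <- data.frame(healthy_smoking = c(0, 1), healthy_alcohol = c(1, 1),
                       healthy_diet = c(1, 1), healthy_exercise = c(1, 1),
                       healthy_sleep = c(1, 1))
  w0 <- mk(1:2, flags0, c(2, 5), c("unfavorable", "healthy"))
  w1 <- mk(1:2, flags1, c(4, 5), c("healthy", "healthy"))
  ch <- categorize_change(w0, w1)
  expect_equal(as.character(ch$smoking_change), c("unhealthier", "unchanged"))
  expect_equal(as.character(ch$diet_change), c("healthier", "unchanged"))
  expect_equal(as.character(ch$hli_range_change), c("healthier", "unchanged"))
  expect_equal(as.character(ch$hli_category_change),
               c("healthier", "unchanged"))

  # antisymmetry on random flag data
  set.seed(4)
  n <- 200
  rand_wave <- function(w) {
    flags <- as.data.frame(matrix(rbinom(n * 5, 1, 0.5), n, 5))
    names(flags) <- paste0("healthy_", lifestyle_factors())
    cbind(data.frame(person_id = seq_len(n), wave = w), flags,
          compute_hli(flags))
  }
  a <- rand_wave(0); b <- rand_wave(1)
  fwd <- categorize_change(a, b); rev <- categorize_change(b, a)
  swap <- c(healthier = "unhealthier", unchanged = "unchanged",
            unhealthier = "healthier")
  for (cl in setdiff(names(fwd), "person_id")) {
    expect_equal(as.character(rev[[cl]]),
                 unname(swap[as.character(fwd[[cl]])]))
  }
})
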