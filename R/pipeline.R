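#' Assemble a pipeline run configuration
#'
#' @param cohort a [cohort_config()] for the simulate stage, or `NULL` to
#'   read an existing panel CSV from `input_csv`.
#' @param input_csv path to a long-format panel CSV (ignored when `cohort`
#'   is supplied).
#' @param panels named list of biomarker panels (see [kdm_panels()]).
#' @param definitions lifestyle definitions (see
#'   [lifestyle_definitions()]).
#' @param fem_panels panels to analyze; `NULL` means all validated panels.
#' @param exposures exposure modes to fit.
#' @param use_ca_anchor see [estimate_ba()].
#' @param bootstrap_reps QGC bootstrap replicates.
#' @param stages stage toggles.
#' @param force proceed past missing validation records in the fem stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       input_csv = NULL,
                       panels = kdm_panels(),
                       definitions = lifestyle_definitions(),
                       fem_panels = NULL,
                       exposures = c("factors", "hli", "hli_category"),
                       use_ca_anchor = TRUE,
                       bootstrap_reps = 200,
                       stages = c("simulate", "score", "kdm", "validate",
                                  "fem", "qgc", "report"),
                       force = FALSE) {
  if (is.null(cohort) && is.null(input_csv)) {
    stop("run_config: either a cohort config or an input CSV is required")
  }
  if (!is.null(cohort)) validate_cohort_config(cohort)
  structure(list(cohort = cohort, input_csv = input_csv, panels = panels,
                 definitions = definitions, fem_panels = fem_panels,
                 exposures = exposures, use_ca_anchor = use_ca_anchor,
                 bootstrap_reps = bootstrap_reps, stages = stages,
                 force = force),
            class = "run_config")
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> lifestyle scoring -> KDM fitting and biological
#' age scoring -> disease validation -> fixed-effects change models ->
#' quantile G-computation -> report. Every stage writes its artifact under
#' `out_dir` and a manifest records the seed, the stages run and an MD5
#' checksum per artifact, so a run is reproducible from the manifest
#' alone.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for stage artifacts.
#' @param seed seed overriding the cohort config seed (optional).
#' @return invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  results <- list()
  stages <- config$stages

  if ("simulate" %in% stages && !is.null(config$cohort)) {
    cohort_cfg <- config$cohort
    if (!is.null(seed)) cohort_cfg$seed <- as.integer(seed)
    cohort <- generate_cohort(cohort_cfg)
    paths <- write_cohort(cohort, out_dir)
    artifacts <- c(artifacts, paths)
    data <- cohort$data
    results$cohort <- cohort
  } else {
    data <- read.csv(config$input_csv, stringsAsFactors = FALSE)
  }
  results$data <- data

  hli <- classify_lifestyle(data, config$definitions)
  results$hli <- hli
  results$change <- categorize_change(hli[hli$wave == 0, ],
                                      hli[hli$wave == 1, ])
  if ("score" %in% stages) {
    artifacts <- c(artifacts, write_stage_csv(hli, out_dir, "hli.csv"))
    artifacts <- c(artifacts,
                   write_stage_csv(results$change, out_dir,
                                   "lifestyle_change.csv"))
  }

  scored <- score_panels(data, config$panels,
                         use_ca_anchor = config$use_ca_anchor)
  results$kdm <- scored
  if ("kdm" %in% stages) {
    artifacts <- c(artifacts,
                   write_stage_csv(scored$ba, out_dir, "ba_results.csv"))
    params_path <- file.path(out_dir, "kdm_params.json")
    jsonlite::write_json(
      lapply(scored$params, function(p) {
        lapply(p$strata, function(st) {
          list(estimates = st$estimates, r_char = st$r_char,
               s_ba = st$s_ba, age_range = st$age_range, n = st$n)
        })
      }),
      params_path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
    artifacts <- c(artifacts, params_path)
  }

  validated <- NULL
  if ("validate" %in% stages) {
    report <- validate_panels(data, scored$ba, hli)
    selection <- select_validated_panels(report)
    validated <- selection$validated
    results$validation <- list(report = report, selection = selection)
    artifacts <- c(artifacts,
                   write_stage_csv(report, out_dir,
                                   "validation_report.csv"))
    sel_path <- file.path(out_dir, "validated_panels.json")
    jsonlite::write_json(selection, sel_path, digits = NA,
                         auto_unbox = FALSE)
    artifacts <- c(artifacts, sel_path)
  }

  if ("fem" %in% stages) {
    fem_panels <- config$fem_panels
    if (is.null(fem_panels)) {
      if (is.null(validated)) {
        if (!config$force) {
          stop("run_pipeline: fem stage requires a validation record; ",
               "enable the validate stage, name fem_panels explicitly, ",
               "or set force = TRUE")
        }
        fem_panels <- names(config$panels)
      } else {
        fem_panels <- validated
      }
    } else if (!is.null(validated) && !config$force &&
               length(setdiff(fem_panels, validated))) {
      stop("run_pipeline: panel(s) without a validation pass: ",
           paste(setdiff(fem_panels, validated), collapse = ", "),
           " (set force = TRUE to analyze anyway)")
    }
    fem_rows <- list()
    qgc_rows <- list()
    results$qgc <- list()
    for (p in fem_panels) {
      for (ex in config$exposures) {
        spec <- fem_spec(panel = p, exposure = ex)
        fem_rows[[paste(p, ex)]] <-
          as.data.frame(fit_fem(data, scored$ba, hli, spec))
      }
      if ("qgc" %in% stages) {
        qgc <- fit_qgc(data, scored$ba, hli,
                       fem_spec(panel = p, exposure = "factors"),
                       bootstrap_reps = config$bootstrap_reps)
        results$qgc[[p]] <- qgc
        fem_p <- fem_rows[[paste(p, "factors")]]
        qgc_rows[[p]] <- cbind(tidy_qgc(qgc, fem_p),
                               psi = qgc$psi, psi_ci_low = qgc$ci_low,
                               psi_ci_high = qgc$ci_high)
      }
    }
    results$fem <- do.call(rbind, fem_rows)
    rownames(results$fem) <- NULL
    artifacts <- c(artifacts,
                   write_stage_csv(results$fem, out_dir,
                                   "fem_results.csv"))
    if (length(qgc_rows)) {
      qgc_df <- do.call(rbind, qgc_rows)
      rownames(qgc_df) <- NULL
      artifacts <- c(artifacts,
                     write_stage_csv(qgc_df, out_dir, "qgc_results.csv"))
    }
  }

  if ("report" %in% stages && !is.null(results$fem)) {
    # Table-2-style effect summary and contribution-bar summary
    tab <- results$fem
    tab$ci <- sprintf("%.2f (%.2f, %.2f)", tab$estimate, tab$ci_low,
                      tab$ci_high)
    artifacts <- c(artifacts,
                   write_stage_csv(
                     tab[, c("panel", "exposure", "term", "ci", "n")],
                     out_dir, "report_effects.csv"))
  }

  manifest <- list(
    seed = if (!is.null(seed)) as.integer(seed) else
      if (!is.null(config$cohort)) config$cohort$seed else NA,
    stages = stages,
    package_version = as.character(utils::packageVersion("orgaging")),
    artifacts = lapply(setNames(nm = unname(artifacts)), function(p) {
      unname(tools::md5sum(p))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  results$artifacts <- c(artifacts, manifest_path)
  invisible(results)
}
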