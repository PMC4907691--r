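#' End-to-end run configuration
#'
#' Bundles everything one simulated study run needs: the task configuration,
#' generating parameters for the two groups, fitting options, analysis
#' subsets, and a master seed from which every stochastic stage derives its
#' own seed.
#'
#' @param task A [task_config()].
#' @param gen_instructed,gen_uninstructed [gen_params()] for the two cohorts;
#'   their `n_subjects` and models define the simulated groups. Seeds inside
#'   are overridden by stage seeds derived from `seed`.
#' @param fit [fit_options()] used for all fits.
#' @param subsets Character vector of analysis subsets for the two-level
#'   models.
#' @param learners_only Restrict fits and analyses to classified learners.
#' @param tr Repetition time for the fMRI design stage.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = task_config(),
                       gen_instructed = gen_params(
                         model = model_params(alpha = 0.061, rho = 0.943)),
                       gen_uninstructed = gen_params(
                         model = model_params(alpha = 0.042,
                                              variant = "feedback")),
                       fit = fit_options(),
                       subsets = "all",
                       learners_only = TRUE,
                       tr = 2,
                       seed = 1L) {
  if (gen_instructed$n_subjects < 1 || gen_uninstructed$n_subjects < 1) {
    stopf("run_config(): both cohorts need n_subjects >= 1.")
  }
  structure(list(task = task, gen_instructed = gen_instructed,
                 gen_uninstructed = gen_uninstructed, fit = fit,
                 subsets = subsets, learners_only = learners_only,
                 tr = tr, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `seed`, `subsets`, `learners_only`, `tr`, and
#' nested `task`, `gen_instructed`, `gen_uninstructed` (whose subkeys are the
#' corresponding constructor arguments; a `model` subkey holds
#' [model_params()] arguments).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build_gen <- function(g, default_variant) {
    if (is.null(g)) return(NULL)
    m <- g$model
    g$model <- if (is.null(m)) NULL else do.call(model_params, m)
    if (is.null(g$model)) g$model <- NULL
    do.call(gen_params, g[!vapply(g, is.null, logical(1))])
  }
  args <- list()
  if (!is.null(y$task)) args$task <- do.call(task_config, y$task)
  if (!is.null(y$gen_instructed)) {
    args$gen_instructed <- build_gen(y$gen_instructed)
  }
  if (!is.null(y$gen_uninstructed)) {
    args$gen_uninstructed <- build_gen(y$gen_uninstructed)
  }
  for (k in c("subsets", "learners_only", "tr", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

# Write a data frame artifact and return a manifest row for it.
stage_output <- function(stage, name, obj, out_dir) {
  row <- tibble(stage = stage, output = name,
                rows = if (is.data.frame(obj)) nrow(obj) else NA_integer_,
                file = NA_character_, md5 = NA_character_)
  if (!is.null(out_dir) && is.data.frame(obj)) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(as.data.frame(obj), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    row$file <- f
    row$md5 <- unname(tools::md5sum(f))
  }
  row
}

#' Run the full simulate-score-fit-analyze-design pipeline
#'
#' Executes every stage in order on synthetic cohorts: trial-order
#' generation, cohort simulation for both groups, amplitude transformation
#' and normalization, learner classification, across- and within-subject
#' model fits with the group comparison of the instructed-reversal
#' parameter, two-level behavioral models, the instructed-reversal window
#' contrast, and construction of the dual-EV fMRI design with its
#' collinearity report. Rerunning with the same configuration reproduces all
#' numeric outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV and hashed into the manifest.
#' @return A list of class `pipeline_result`: all stage results plus a
#'   `manifest` tibble (stage, output, rows, file, md5).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) {
    stopf("`config` must be created with run_config().")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  manifest <- list()
  res <- list(config = config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("Pipeline failed at stage `%s`: %s", stage, conditionMessage(e))
    })
  }

  # 1: task -----------------------------------------------------------------
  res$orders <- run_stage("task", canonical_orders(config$task))
  manifest$task <- bind_rows(
    stage_output("task", "events_order1", as_tibble(res$orders[[1]]), out_dir),
    stage_output("task", "events_order2", as_tibble(res$orders[[2]]), out_dir))

  # 2: cohorts --------------------------------------------------------------
  gi <- config$gen_instructed; gi$seed <- seeds[1]
  gu <- config$gen_uninstructed; gu$seed <- seeds[2]
  res$cohort_instructed <- run_stage("simulate_cohort",
                                     simulate_cohort(res$orders, gi))
  res$cohort_uninstructed <- run_stage("simulate_cohort",
                                       simulate_cohort(res$orders, gu))
  manifest$cohort <- bind_rows(
    stage_output("simulate_cohort", "cohort_instructed",
                 res$cohort_instructed, out_dir),
    stage_output("simulate_cohort", "cohort_uninstructed",
                 res$cohort_uninstructed, out_dir))

  # 3: scoring / normalization ----------------------------------------------
  norm <- function(cohort) transform_normalize(cohort)
  res$scored_instructed <- run_stage("score", norm(res$cohort_instructed))
  res$scored_uninstructed <- run_stage("score", norm(res$cohort_uninstructed))
  manifest$score <- bind_rows(
    stage_output("score", "scored_instructed", res$scored_instructed, out_dir),
    stage_output("score", "scored_uninstructed", res$scored_uninstructed,
                 out_dir))

  # 4: learner classification ------------------------------------------------
  res$learners_instructed <- run_stage(
    "learners", classify_learners(res$scored_instructed, res$orders))
  res$learners_uninstructed <- run_stage(
    "learners", classify_learners(res$scored_uninstructed, res$orders))
  manifest$learners <- bind_rows(
    stage_output("learners", "learners_instructed",
                 res$learners_instructed, out_dir),
    stage_output("learners", "learners_uninstructed",
                 res$learners_uninstructed, out_dir))

  keep <- function(scored, learners) {
    if (!config$learners_only) return(scored)
    ids <- learners$subject[learners$learner]
    if (length(ids) < 2L) return(scored)  # fall back to everyone
    scored[scored$subject %in% ids, ]
  }
  ai <- keep(res$scored_instructed, res$learners_instructed)
  au <- keep(res$scored_uninstructed, res$learners_uninstructed)
  ai$group <- "instructed"
  au$group <- "uninstructed"

  # 5: model fitting ---------------------------------------------------------
  res$fit_instructed <- run_stage(
    "fit", fit_across_subjects(ai, res$orders, "instructed",
                               options = config$fit))
  res$fit_uninstructed <- run_stage(
    "fit", fit_across_subjects(au, res$orders, "feedback",
                               options = config$fit))
  res$within_instructed <- run_stage(
    "fit", fit_within_subjects(ai, res$orders, "instructed",
                               options = config$fit))
  res$within_uninstructed <- run_stage(
    "fit", fit_within_subjects(au, res$orders, "instructed",
                               options = config$fit))
  res$rho_comparison <- run_stage(
    "fit", compare_rho_groups(res$within_instructed, res$within_uninstructed))
  manifest$fit <- bind_rows(
    stage_output("fit", "fit_instructed", tidy(res$fit_instructed), out_dir),
    stage_output("fit", "fit_uninstructed", tidy(res$fit_uninstructed),
                 out_dir),
    stage_output("fit", "within_instructed", res$within_instructed, out_dir),
    stage_output("fit", "within_uninstructed", res$within_uninstructed,
                 out_dir),
    stage_output("fit", "rho_comparison", res$rho_comparison, out_dir))

  # 6: behavioral statistics -------------------------------------------------
  both <- bind_rows(ai, au)
  res$two_level <- run_stage("analyze", purrr::map(
    setNames(config$subsets, config$subsets),
    function(s) fit_two_level(both, res$orders, subset = s)))
  res$reversal_contrast <- run_stage(
    "analyze", instructed_reversal_contrast(ai, res$orders))
  manifest$analyze <- bind_rows(
    purrr::imap(res$two_level, function(tab, s) {
      stage_output("analyze", paste0("two_level_", s), tab, out_dir)
    }) |> bind_rows(),
    stage_output("analyze", "reversal_contrast", res$reversal_contrast,
                 out_dir))

  # 7: fMRI design -----------------------------------------------------------
  res$fmri_design <- run_stage("fmri_design", {
    tr_instr <- simulate_ev_trace(res$orders[[1]], res$fit_instructed$params)
    tr_fb <- simulate_ev_trace(res$orders[[1]], res$fit_uninstructed$params)
    build_fmri_design(res$orders[[1]],
                      list(instructed = tr_instr, feedback = tr_fb),
                      tr = config$tr, orthogonalize = FALSE)
  })
  res$collinearity <- run_stage("fmri_design",
                                collinearity_report(res$fmri_design))
  manifest$fmri <- stage_output("fmri_design", "design_matrix",
                                res$fmri_design, out_dir)

  res$manifest <- bind_rows(manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  stages: %s\n",
              paste(unique(x$manifest$stage), collapse = " -> ")))
  cat(sprintf("  instructed fit: alpha = %.3f, rho = %.3f\n",
              x$fit_instructed$params$alpha, x$fit_instructed$params$rho))
  cat(sprintf("  uninstructed fit: alpha = %.3f\n",
              x$fit_uninstructed$params$alpha))
  cat(sprintf("  rho group comparison: t(%d) = %.2f, p = %.2g\n",
              x$rho_comparison$df, x$rho_comparison$t,
              x$rho_comparison$p_value))
  invisible(x)
}
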