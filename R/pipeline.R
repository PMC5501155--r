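## Pipeline orchestration: a single configuration object with the study's
## default settings, deterministic stage seeding, the end-to-end run
## (thin -> select -> evaluate -> average -> threshold -> habitat/zonal
## accounting), artifact persistence, and the synthetic recovery harness.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its default: thinning buffer
#' radius 564.19 m (circle of area 1 km^2), pseudo-absence exclusion radius
#' 1000 m, contribution cut 1%, correlation cut 0.7, regularization
#' multiplier 1, 10,000 background points, 500 iterations, convergence
#' tolerance 1e-5, 20 replicates at a 75/25 train/test split, 200
#' pseudo-absences, threshold scan step 0.001.
#'
#' @param ... overrides of the defaults listed above; unknown names error.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    thin_radius = 564.19, pa_exclusion_radius = 1000,
    r_cut = 0.7, c_cut = 1.0, rank_from = "current",
    reg_multiplier = 1.0, n_background = 10000, max_iter = 500, tol = 1e-5,
    classes = "auto", hinge_knots = 50, presences_in_background = TRUE,
    reps = 20, train_frac = 0.75, replicate_mode = "split",
    n_pseudo_absences = 200, threshold_step = 0.001,
    connectivity = 8, reserve_role = "reserve",
    seed = 20170705, output_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown config option(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$thin_radius > 0, cfg$pa_exclusion_radius > 0,
            cfg$r_cut > 0, cfg$r_cut <= 1, cfg$c_cut >= 0,
            cfg$train_frac > 0, cfg$train_frac < 1,
            cfg$threshold_step > 0, cfg$threshold_step <= 1,
            cfg$reps >= 1, cfg$n_background >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of [pipeline_config()]'s options; `overrides`
#' (e.g. parsed command-line flags) take precedence over the file.
#'
#' @param path YAML file.
#' @param overrides named list of option overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("'%s' does not hold a configuration mapping", path)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Run the full habitat-modeling pipeline
#'
#' Thins the occurrences, selects variables by stepwise AICc, evaluates the
#' winner with replicated bootstrap, averages the replicate predictions,
#' binarizes at the threshold maximizing TSS of the averaged map (thinned
#' presences vs pseudo-absences), and summarizes habitat area, zones,
#' protection and fragmentation. A single master seed deterministically
#' derives every stage seed, so the same inputs and config reproduce the
#' report exactly.
#'
#' @param stack a [raster_stack()] of candidate variables.
#' @param occurrences an [occurrence_set()] (unthinned).
#' @param zones optional [zone_set()] for zonal/protected summaries.
#' @param config a [pipeline_config()].
#' @return a `run_report` list; if `config$output_dir` is set, every
#'   intermediate artifact is also written there.
#' @export
run_pipeline <- function(stack, occurrences, zones = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(stack, "raster_stack"), inherits(occurrences, "occurrence_set"))
  seed <- config$seed
  out <- config$output_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  persist <- function(f, ...) if (!is.null(out)) f(...)

  occ <- thin_occurrences(occurrences, config$thin_radius,
                          seed = stage_seed(seed, "thin"))
  persist(write_occurrences, occ, file.path(out, "occurrences_thinned.csv"))

  trace <- select_variables(stack, occ,
                            n_background = config$n_background,
                            seed = stage_seed(seed, "background"),
                            r_cut = config$r_cut, c_cut = config$c_cut,
                            rank_from = config$rank_from,
                            classes = config$classes,
                            reg_multiplier = config$reg_multiplier,
                            hinge_knots = config$hinge_knots,
                            max_iter = config$max_iter, tol = config$tol,
                            presences_in_background = config$presences_in_background)
  persist(write_trace, trace, file.path(out, "selection_trace.json"),
          file.path(out, "selection_trace.csv"))
  vars <- winner_vars(trace)
  sstack <- subset_stack(stack, vars)

  pa <- generate_pseudo_absences(stack, occ, n = config$n_pseudo_absences,
                                 exclusion_radius = config$pa_exclusion_radius,
                                 seed = stage_seed(seed, "pseudo_absence"))
  persist(write_occurrences, pa, file.path(out, "pseudo_absences.csv"))

  eval_summary <- bootstrap_evaluate(
    sstack, occ, pa, reps = config$reps, train_frac = config$train_frac,
    seed = stage_seed(seed, "evaluate"),
    n_background = config$n_background, classes = config$classes,
    reg_multiplier = config$reg_multiplier, hinge_knots = config$hinge_knots,
    max_iter = config$max_iter, tol = config$tol,
    presences_in_background = config$presences_in_background,
    threshold_step = config$threshold_step,
    replicate_mode = config$replicate_mode)
  persist(write_evaluation, eval_summary, file.path(out, "evaluation.json"),
          file.path(out, "evaluation.csv"))

  mean_map <- average_replicates(lapply(eval_summary$replicates, `[[`, "prediction"))
  persist(write_ascii_grid, mean_map, file.path(out, "suitability_mean.asc"))

  cl <- point_to_cell(mean_map$spec, occ$records$x, occ$records$y)
  pos_scores <- mean_map$values[cbind(cl$row, cl$col)]
  clpa <- point_to_cell(mean_map$spec, pa$records$x, pa$records$y)
  neg_scores <- mean_map$values[cbind(clpa$row, clpa$col)]
  thr <- maximize_threshold(pos_scores[!is.na(pos_scores)],
                            neg_scores[!is.na(neg_scores)],
                            metric = "tss", step = config$threshold_step)

  habitat <- apply_threshold(mean_map, thr$threshold)
  persist(write_habitat_map, habitat, file.path(out, "habitat_binary.asc"))
  total_km2 <- habitat_area(habitat)
  patches <- patch_stats(habitat, connectivity = config$connectivity)

  zone_table <- NULL; protected_pct <- NULL
  if (!is.null(zones)) {
    zone_table <- zonal_summary(habitat, zones)
    if (any(vapply(zones$zones, `[[`, "", "role") == config$reserve_role) &&
        total_km2 > 0)
      protected_pct <- protected_fraction(habitat, zones, config$reserve_role)
    persist(utils::write.csv, zone_table, file.path(out, "zone_summary.csv"),
            row.names = FALSE)
  }

  m <- eval_summary$means
  report <- structure(list(
    config = config,
    thinning = list(before = nrow(occurrences$records),
                    after = nrow(occ$records)),
    selected_vars = vars,
    selection = write_trace(trace),
    evaluation = m,
    performance = list(train_auc = performance_class("auc", m$train_auc),
                       test_auc = performance_class("auc", m$test_auc),
                       max_kappa = performance_class("kappa", m$max_kappa),
                       max_tss = performance_class("tss", m$max_tss)),
    threshold = thr$threshold,
    threshold_tss = thr$value,
    total_suitable_km2 = total_km2,
    n_patches = patches$n_patches,
    largest_patch_fraction = patches$largest_fraction,
    zone_summary = zone_table,
    protected_pct = protected_pct,
    occurrences = occ, trace = trace, eval_summary = eval_summary,
    mean_map = mean_map, habitat = habitat, patches = patches),
    class = "run_report")
  if (!is.null(out)) {
    slim <- report[c("thinning", "selected_vars", "evaluation", "performance",
                     "threshold", "threshold_tss", "total_suitable_km2",
                     "n_patches", "largest_patch_fraction", "protected_pct")]
    slim$zone_summary <- zone_table
    jsonlite::write_json(slim, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d -> %d occurrences after thinning\n",
              x$thinning$before, x$thinning$after))
  cat(sprintf("  selected: %s\n", paste(x$selected_vars, collapse = ", ")))
  m <- x$evaluation
  cat(sprintf("  train AUC %.3f (%s), test AUC %.3f (%s), kappa %.3f, TSS %.3f\n",
              m$train_auc, x$performance$train_auc, m$test_auc,
              x$performance$test_auc, m$max_kappa, m$max_tss))
  cat(sprintf("  threshold %.3f -> %.1f km2 suitable in %d patches\n",
              x$threshold, x$total_suitable_km2, x$n_patches))
  if (!is.null(x$protected_pct))
    cat(sprintf("  protected fraction: %.2f%%\n", x$protected_pct))
  invisible(x)
}

#' Synthetic recovery harness
#'
#' Runs the selection (and optionally evaluation and response-curve) stages
#' on `n_seeds` independently generated synthetic landscapes and aggregates
#' how often the planted truth is recovered. This is the package's
#' self-validation: with the default landscape, the winner set should
#' contain the informative variables and exclude the redundant duplicate in
#' the large majority of seeds, response-curve peaks should sit near the
#' planted optima, and test AUC should be high.
#'
#' @param n_seeds number of landscapes.
#' @param config a [landscape_config()]; each landscape uses
#'   `config$seed + i`.
#' @param n_background background sample size for all fits.
#' @param eval_seeds,curve_seeds how many of the seeds also run the
#'   bootstrap evaluation / response curves (they dominate run time).
#' @param reps bootstrap replicates for the evaluated seeds.
#' @param n_pseudo_absences,pa_exclusion_radius pseudo-absence settings.
#' @param progress print one line per seed?
#' @return a `recovery_summary`: per-seed [recovery_report()]s plus
#'   aggregate rates (`selection_success_rate`: both informative in the
#'   winner and no redundant duplicate; `informative_recall`;
#'   `median_peak_error_sigma`; `mean_test_auc`).
#' @export
run_recovery <- function(n_seeds = 20, config = landscape_config(),
                         n_background = 2000, eval_seeds = 10,
                         curve_seeds = 10, reps = 20,
                         n_pseudo_absences = 200, pa_exclusion_radius = 1000,
                         progress = FALSE) {
  reports <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + i
    ds <- build_landscape(cfg)
    trace <- select_variables(ds$stack, ds$occurrences,
                              n_background = n_background,
                              seed = stage_seed(cfg$seed, "background"))
    curves <- NULL
    if (i <= curve_seeds) {
      wm <- trace$candidates[[trace$winner]]$model
      informative <- names(ds$manifest)[
        vapply(ds$manifest, `[[`, "", "role") == "informative"]
      avail <- intersect(informative, setdiff(wm$expansion$vars,
                                              wm$expansion$dropped))
      curves <- stats::setNames(lapply(avail, response_curve, model = wm), avail)
    }
    ev <- NULL
    if (i <= eval_seeds) {
      sstack <- subset_stack(ds$stack, winner_vars(trace))
      pa <- generate_pseudo_absences(ds$stack, ds$occurrences,
                                     n = n_pseudo_absences,
                                     exclusion_radius = pa_exclusion_radius,
                                     seed = stage_seed(cfg$seed, "pseudo_absence"))
      ev <- bootstrap_evaluate(sstack, ds$occurrences, pa, reps = reps,
                               seed = stage_seed(cfg$seed, "evaluate"),
                               n_background = n_background)
    }
    reports[[i]] <- recovery_report(ds, trace, curves, ev)
    if (progress)
      cat(sprintf("seed %d: winner {%s} recall %.2f\n", i,
                  paste(reports[[i]]$winner, collapse = ","),
                  reports[[i]]$informative_recall))
  }
  success <- vapply(reports, function(r)
    r$informative_recall == 1 && r$duplicates_in_winner == 0, TRUE)
  peaks <- unlist(lapply(reports, `[[`, "peak_error_sigma"))
  aucs <- vapply(reports, `[[`, 0, "mean_test_auc")
  structure(list(
    reports = reports,
    selection_success_rate = mean(success),
    informative_recall = mean(vapply(reports, `[[`, 0, "informative_recall")),
    median_peak_error_sigma = stats::median(peaks, na.rm = TRUE),
    mean_test_auc = mean(aucs, na.rm = TRUE)),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(paste0("recovery_summary over %d seeds:\n",
                     "  selection success %.0f%%, informative recall %.2f\n",
                     "  median peak error %.2f sigma, mean test AUC %.3f\n"),
              length(x$reports), 100 * x$selection_success_rate,
              x$informative_recall, x$median_peak_error_sigma,
              x$mean_test_auc))
  invisible(x)
}
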