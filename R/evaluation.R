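## Model evaluation: pseudo-absence generation, rank (Mann-Whitney) AUC,
## threshold-dependent confusion metrics (sensitivity, specificity, TSS,
## Cohen's kappa), maximization of kappa/TSS over a threshold grid, verbal
## performance classes, and the replicated 75/25 bootstrap harness.

#' Generate pseudo-absence points
#'
#' Draws `n` cells uniformly without replacement from the unmasked cells
#' whose centers lie at least `exclusion_radius` from every presence, and
#' places a point at each cell center.
#'
#' @param stack a [raster_stack()] defining extent and mask.
#' @param presences an [occurrence_set()] (may be empty: no exclusion).
#' @param n number of pseudo-absences.
#' @param exclusion_radius exclusion buffer around presences (m).
#' @param seed integer seed.
#' @return an [occurrence_set()] of pseudo-absence points.
#' @export
generate_pseudo_absences <- function(stack, presences, n = 200,
                                     exclusion_radius = 1000, seed = 1) {
  mask <- stack_mask(stack)
  cells <- which(mask)
  if (length(cells) == 0) stopf("stack is fully masked")
  rc <- arrayInd(cells, dim(mask))
  ctr <- cell_centers(stack$spec, rc[, 1], rc[, 2])
  rec <- presences$records
  if (nrow(rec) > 0) {
    d2min <- rep(Inf, length(cells))
    for (i in seq_len(nrow(rec)))
      d2min <- pmin(d2min, (ctr$x - rec$x[i])^2 + (ctr$y - rec$y[i])^2)
    eligible <- d2min >= exclusion_radius^2
  } else {
    eligible <- rep(TRUE, length(cells))
  }
  if (!any(eligible))
    stopf("no unmasked area outside the presence exclusion buffers")
  if (sum(eligible) < n)
    stopf("only %d eligible cells for %d pseudo-absences; reduce n",
          sum(eligible), n)
  pick <- with_seed(seed, sort(which(eligible)[sample.int(sum(eligible), n)]))
  occurrence_set(data.frame(id = paste0("pa", seq_len(n)),
                            x = ctr$x[pick], y = ctr$y[pick],
                            source = "pseudo-absence", year = NA_integer_))
}

#' Rank (Mann-Whitney) AUC
#'
#' The probability that a random positive scores above a random negative,
#' ties counted one half: the area under the ROC curve.
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stopf("rank_auc: both score sets must be non-empty")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Confusion-matrix skill metrics
#'
#' Sensitivity is the success rate on presences, specificity on absences;
#' `TSS = sensitivity + specificity - 1`; kappa is chance-corrected overall
#' agreement (`(Po - Pe) / (1 - Pe)`, defined as 0 when `Pe = 1`).
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return list with `sensitivity`, `specificity`, `tss`, `kappa`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  if (min(tp, fn, tn, fp) < 0) stopf("confusion counts must be non-negative")
  if (tp + fn == 0) stopf("no actual presences (tp + fn = 0)")
  if (tn + fp == 0) stopf("no actual absences (tn + fp = 0)")
  n <- tp + fn + tn + fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) 0 else (po - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       kappa = kappa)
}

#' Maximize a threshold-dependent metric
#'
#' Scans thresholds `0, step, ..., 1`; a score at or above the threshold
#' counts as predicted presence. Returns the smallest threshold attaining
#' the metric maximum.
#'
#' @param pos_scores,neg_scores scores in `[0, 1]` of actual presences and
#'   absences.
#' @param metric `"tss"` or `"kappa"`.
#' @param step threshold grid step.
#' @return list with `threshold` and `value`.
#' @export
maximize_threshold <- function(pos_scores, neg_scores,
                               metric = c("tss", "kappa"), step = 0.001) {
  metric <- match.arg(metric)
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stopf("both score sets must be non-empty")
  th <- seq(0, 1, by = step)
  sp <- sort(pos_scores); sn <- sort(neg_scores)
  ## counts of scores >= threshold via binary search on the sorted vectors;
  ## the epsilon guards score-equals-threshold ties against 1-ulp noise in
  ## the grid arithmetic
  eps <- step * 1e-6
  tp <- np - findInterval(th - eps, sp, left.open = TRUE)
  fp <- nn - findInterval(th - eps, sn, left.open = TRUE)
  fn <- np - tp; tn <- nn - fp
  n <- np + nn
  if (metric == "tss") {
    val <- tp / np + tn / nn - 1
  } else {
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    val <- ifelse(abs(1 - pe) < .Machine$double.eps^0.5, 0, (po - pe) / (1 - pe))
  }
  best <- which.max(val)                       # first index: smallest threshold
  list(threshold = th[best], value = val[best])
}

#' Verbal model-performance class
#'
#' Bins AUC, kappa and TSS values into the conventional verbal labels;
#' boundary values are assigned to the higher class.
#'
#' @param statistic `"auc"`, `"kappa"` or `"tss"`.
#' @param value the statistic's value.
#' @return character label.
#' @export
performance_class <- function(statistic = c("auc", "kappa", "tss"), value) {
  statistic <- match.arg(statistic)
  switch(statistic,
    auc = {
      if (value < 0 || value > 1) stopf("AUC out of [0,1]")
      if (value >= 0.9) "excellent"
      else if (value >= 0.8) "good"
      else if (value >= 0.7) "fair"
      else if (value >= 0.6) "poor"
      else "failed"
    },
    kappa = {
      if (value < -1 || value > 1) stopf("kappa out of [-1,1]")
      if (value >= 0.75) "excellent"
      else if (value >= 0.4) "good"
      else "poor"
    },
    tss = {
      if (value < -1 || value > 1) stopf("TSS out of [-1,1]")
      if (value >= 0.8) "good_to_excellent"
      else if (value >= 0.5) "useful"
      else if (value >= 0.2) "poor"
      else "no_skill"
    })
}

#' Replicated bootstrap evaluation of the final model
#'
#' Runs `reps` replicates. Each replicate splits the presences into
#' training and test fractions (train count = `round(train_frac * n)`,
#' without replacement; `replicate_mode = "bootstrap"` instead resamples n
#' presences with replacement and tests on the out-of-bag records), fits the
#' model on the training presences, and scores: training and test AUC
#' against the shared background sample, and maximized kappa and TSS of the
#' test presences against the pseudo-absences. The logistic prediction grid
#' of every replicate is retained for averaging.
#'
#' @param stack a [raster_stack()] already subset to the final variables.
#' @param presences a thinned [occurrence_set()] (>= 4 records).
#' @param pseudo_absences an [occurrence_set()] from
#'   [generate_pseudo_absences()]; generated once and reused across
#'   replicates.
#' @param reps number of replicates.
#' @param train_frac training fraction of presences.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param n_background,classes,reg_multiplier,hinge_knots,max_iter,tol,presences_in_background
#'   model settings (see [maxent()]).
#' @param threshold_step grid step for [maximize_threshold()].
#' @param replicate_mode `"split"` (default) or `"bootstrap"`.
#' @return an `evaluation_summary`: `replicates` (each with AUCs, maximized
#'   kappa/TSS and thresholds, trained model, prediction grid) and `means`.
#' @export
bootstrap_evaluate <- function(stack, presences, pseudo_absences, reps = 20,
                               train_frac = 0.75, seed = 1,
                               n_background = 10000, classes = "auto",
                               reg_multiplier = 1.0, hinge_knots = 50,
                               max_iter = 500, tol = 1e-5,
                               presences_in_background = TRUE,
                               threshold_step = 0.001,
                               replicate_mode = c("split", "bootstrap")) {
  replicate_mode <- match.arg(replicate_mode)
  rec <- presences$records
  n <- nrow(rec)
  if (n < 4) stopf("bootstrap_evaluate: need at least 4 presences")
  kinds <- stack_kinds(stack)
  bg <- sample_background(stack, n_background, seed = stage_seed(seed, "background"))
  pres_vals <- extract_values(stack, presences)[, names(stack$layers), drop = FALSE]
  pa_vals <- extract_values(stack, pseudo_absences)[, names(stack$layers), drop = FALSE]
  grid_cells <- which(stack_mask(stack))
  grid_vals <- stack_values(stack, grid_cells)

  replicates <- vector("list", reps)
  for (i in seq_len(reps)) {
    split <- with_seed(stage_seed(seed, paste0("replicate", i)), {
      if (replicate_mode == "split") {
        tr <- sort(sample.int(n, round(train_frac * n)))
        list(train = tr, test = setdiff(seq_len(n), tr))
      } else {
        tr <- sort(sample.int(n, n, replace = TRUE))
        list(train = tr, test = setdiff(seq_len(n), unique(tr)))
      }
    })
    if (length(split$test) < 1)
      stopf("replicate %d: no test presences after the split", i)
    model <- maxent(pres_vals[split$train, , drop = FALSE], bg$values,
                    kinds = kinds, classes = classes,
                    reg_multiplier = reg_multiplier, hinge_knots = hinge_knots,
                    max_iter = max_iter, tol = tol,
                    presences_in_background = presences_in_background)
    sc_train <- predict(model, pres_vals[split$train, , drop = FALSE])
    sc_test <- predict(model, pres_vals[split$test, , drop = FALSE])
    sc_bg <- predict(model, bg$values)
    sc_pa <- predict(model, pa_vals)
    mk <- maximize_threshold(sc_test, sc_pa, "kappa", step = threshold_step)
    mt <- maximize_threshold(sc_test, sc_pa, "tss", step = threshold_step)
    pred <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
    pred[grid_cells] <- predict(model, grid_vals)
    replicates[[i]] <- list(
      replicate = i,
      train_ids = rec$id[split$train], test_ids = rec$id[split$test],
      train_auc = rank_auc(sc_train, sc_bg),
      test_auc = rank_auc(sc_test, sc_bg),
      max_kappa = mk$value, kappa_threshold = mk$threshold,
      max_tss = mt$value, tss_threshold = mt$threshold,
      model = model,
      prediction = layer(sprintf("suitability_rep%02d", i), pred, stack$spec))
  }
  pull <- function(f) vapply(replicates, `[[`, 0, f)
  structure(list(
    replicates = replicates,
    means = list(train_auc = mean(pull("train_auc")),
                 test_auc = mean(pull("test_auc")),
                 max_kappa = mean(pull("max_kappa")),
                 max_tss = mean(pull("max_tss")),
                 tss_threshold = mean(pull("tss_threshold")))),
    class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  m <- x$means
  cat(sprintf(paste0("evaluation_summary: %d replicates\n",
                     "  training AUC %.3f, test AUC %.3f, max kappa %.3f,",
                     " max TSS %.3f (mean TSS threshold %.3f)\n"),
              length(x$replicates), m$train_auc, m$test_auc,
              m$max_kappa, m$max_tss, m$tss_threshold))
  invisible(x)
}

#' Persist an evaluation summary
#'
#' @param eval_summary an [bootstrap_evaluate()] result.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the per-replicate data frame (summary row appended in
#'   the CSV).
#' @export
write_evaluation <- function(eval_summary, json_path = NULL, csv_path = NULL) {
  df <- do.call(rbind, lapply(eval_summary$replicates, function(r)
    data.frame(replicate = r$replicate, train_auc = r$train_auc,
               test_auc = r$test_auc, max_kappa = r$max_kappa,
               kappa_threshold = r$kappa_threshold, max_tss = r$max_tss,
               tss_threshold = r$tss_threshold)))
  if (!is.null(json_path))
    jsonlite::write_json(list(replicates = df, means = eval_summary$means),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv_path)) {
    m <- eval_summary$means
    out <- rbind(df, data.frame(replicate = NA, train_auc = m$train_auc,
                                test_auc = m$test_auc, max_kappa = m$max_kappa,
                                kappa_threshold = NA, max_tss = m$max_tss,
                                tss_threshold = m$tss_threshold))
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  invisible(df)
}
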