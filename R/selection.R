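## Optimized stepwise variable elimination scored by AICc. Starting from the
## full variable set, each step screens against the t-th highest contributing
## variable: every other variable with contribution < 1% or Pearson |r| > 0.7
## with the screening variable is removed, the model refitted, and AICc
## computed from the landscape-standardized raw likelihood. The candidate
## with the lowest valid AICc wins.

#' Pearson correlation matrix of continuous variables
#'
#' @param values data frame of variable values (normally the background
#'   sample). Non-continuous columns are excluded when `kinds` is given;
#'   constant columns are excluded with a warning.
#' @param kinds optional named kind vector (`"continuous"`/`"categorical"`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(values, kinds = NULL) {
  values <- as.data.frame(values)
  if (nrow(values) < 2) stopf("pearson_matrix: need at least two rows")
  if (!is.null(kinds))
    values <- values[, names(values)[kinds[names(values)] == "continuous"],
                     drop = FALSE]
  keep <- vapply(values, function(x) stats::sd(x, na.rm = TRUE) > 0, TRUE)
  if (any(!keep))
    warnf("constant column(s) excluded from correlation: %s",
          paste(names(values)[!keep], collapse = ", "))
  stats::cor(values[, keep, drop = FALSE], use = "pairwise.complete.obs")
}

#' One variable-elimination screening step
#'
#' Let `v*` be the `rank_t`-th highest contributor of the current model
#' (ties broken by variable name). Every other variable with contribution
#' below `c_cut` percent, or with `|r| > r_cut` against `v*`, is removed;
#' `v*` itself is never removed. Categorical variables bypass the
#' correlation rule and can only fall to the contribution cut.
#'
#' @param contributions named percent contributions of the current model.
#' @param cormat correlation matrix over the continuous variables (e.g.
#'   [pearson_matrix()]).
#' @param rank_t rank of the screening variable (1 = highest contributor).
#' @param r_cut correlation cutoff (default 0.7).
#' @param c_cut contribution cutoff in percent (default 1).
#' @return list with `keep` (retained names), `screen` (the screening
#'   variable) and `removed` (data frame of `var`, `reason`).
#' @export
reduction_step <- function(contributions, cormat, rank_t, r_cut = 0.7,
                           c_cut = 1.0) {
  vars <- names(contributions)
  if (rank_t > length(vars)) stopf("rank_t exceeds the number of variables")
  ord <- order(-contributions, vars)
  v_star <- vars[ord[rank_t]]
  reason <- character(0); out <- character(0)
  for (v in vars) {
    if (v == v_star) next
    if (contributions[[v]] < c_cut) {
      out <- c(out, v); reason <- c(reason, "low_contribution")
    } else if (v %in% rownames(cormat) && v_star %in% rownames(cormat) &&
               abs(cormat[v, v_star]) > r_cut) {
      out <- c(out, v); reason <- c(reason, "high_correlation")
    }
  }
  list(keep = setdiff(vars, out), screen = v_star,
       removed = data.frame(var = out, reason = reason))
}

#' Sample-size-corrected AIC of a fitted model
#'
#' The raw output is renormalized to sum to 1 over all unmasked cells of the
#' study grid; the log-likelihood is the sum of the log standardized raw
#' value at the presence cells; the parameter count k is the number of
#' nonzero coefficients. `AICc = 2k - 2lnL + 2k(k+1)/(n-k-1)`, flagged
#' invalid when `k >= n - 1`.
#'
#' @param model a [maxent()] model.
#' @param presences an [occurrence_set()].
#' @param stack the full study [raster_stack()] (or one subset to the
#'   model's variables).
#' @return list with `aicc`, `lnL`, `k`, `n`, `valid`.
#' @export
compute_aicc <- function(model, presences, stack) {
  cells <- which(stack_mask(stack))
  vals <- stack_values(stack, cells)
  raw <- predict(model, vals[, model$expansion$vars, drop = FALSE],
                 output = "raw")
  p_std <- raw / sum(raw)
  rec <- presences$records
  cl <- point_to_cell(stack$spec, rec$x, rec$y)
  if (any(!cl$inside))
    stopf("presences outside grid: %s", paste(rec$id[!cl$inside], collapse = ", "))
  pcell <- (cl$col - 1L) * stack$spec$n_rows + cl$row
  pos <- match(pcell, cells)
  if (anyNA(pos))
    stopf("presences on masked cells: %s", paste(rec$id[is.na(pos)], collapse = ", "))
  lnL <- sum(log(p_std[pos]))
  k <- sum(model$fit$lambdas != 0)
  n <- nrow(rec)
  valid <- (n - k - 1) > 0
  aicc <- if (valid) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  list(aicc = aicc, lnL = lnL, k = k, n = n, valid = valid)
}

#' Subset a stack to named layers
#' @param stack a [raster_stack()].
#' @param vars layer names to keep.
#' @return a [raster_stack()].
#' @export
subset_stack <- function(stack, vars) {
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing)) stopf("no such layer(s): %s", paste(missing, collapse = ", "))
  raster_stack(stack$layers[vars])
}

#' Stepwise variable selection by AICc
#'
#' Fits the full model, then repeatedly applies [reduction_step()] with rank
#' t at step t (screening against the t-th highest contributor of the
#' current model) and refits, until the rank exceeds the remaining variable
#' count or no later rank removes anything. One shared background sample is
#' used for all candidate fits so AICc differences reflect variables, not
#' sampling. The winner is the candidate with the lowest valid AICc.
#'
#' @param stack a [raster_stack()] of candidate variables.
#' @param occurrences a thinned [occurrence_set()].
#' @param n_background background sample size.
#' @param seed seed for the shared background sample.
#' @param r_cut,c_cut screening cutoffs (correlation, percent contribution).
#' @param rank_from `"current"` ranks contributors in the current model at
#'   each step; `"initial"` freezes the ranking of the full model.
#' @param classes,reg_multiplier,hinge_knots,max_iter,tol,presences_in_background
#'   passed to [maxent()].
#' @return a `selection_trace`: `candidates` (each with `step`, `vars`,
#'   `model`, `contributions`, `cormat`, `aicc`, `removed`), `winner` index,
#'   and the background sample.
#' @export
select_variables <- function(stack, occurrences, n_background = 10000,
                             seed = 1, r_cut = 0.7, c_cut = 1.0,
                             rank_from = c("current", "initial"),
                             classes = "auto", reg_multiplier = 1.0,
                             hinge_knots = 50, max_iter = 500, tol = 1e-5,
                             presences_in_background = TRUE) {
  rank_from <- match.arg(rank_from)
  if (length(stack$layers) < 1) stopf("select_variables: empty stack")
  kinds <- stack_kinds(stack)
  bg <- sample_background(stack, n_background, seed = seed)
  pres_all <- extract_values(stack, occurrences)

  fit_candidate <- function(vars, step, removed) {
    pv <- pres_all[, vars, drop = FALSE]
    bv <- bg$values[, vars, drop = FALSE]
    model <- maxent(pv, bv, kinds = kinds[vars], classes = classes,
                    reg_multiplier = reg_multiplier, hinge_knots = hinge_knots,
                    max_iter = max_iter, tol = tol,
                    presences_in_background = presences_in_background)
    contributions <- variable_contribution(model, pv, bv)
    cont_vars <- vars[kinds[vars] == "continuous"]
    cormat <- if (length(cont_vars) >= 2)
      suppressWarnings(pearson_matrix(bv[, cont_vars, drop = FALSE]))
    else matrix(1, 0, 0)
    aicc <- compute_aicc(model, occurrences, subset_stack(stack, vars))
    list(step = step, vars = vars, model = model,
         contributions = contributions, cormat = cormat, aicc = aicc,
         removed = removed)
  }

  current <- names(stack$layers)
  candidates <- list(fit_candidate(current, 1L,
                                   data.frame(var = character(), reason = character())))
  initial_order <- {
    co <- candidates[[1]]$contributions
    names(co)[order(-co, names(co))]
  }
  rank_t <- 1L
  while (rank_t < length(current) + 1) {
    cand <- candidates[[length(candidates)]]
    contr <- cand$contributions
    if (rank_t > length(contr)) break
    if (rank_from == "initial") {
      ## freeze the full model's ranking, restricted to surviving variables
      surv <- initial_order[initial_order %in% names(contr)]
      if (rank_t > length(surv)) break
      v_star <- surv[rank_t]
      ord_pos <- match(v_star, names(contr)[order(-contr, names(contr))])
      red <- reduction_step(contr, cand$cormat, ord_pos, r_cut, c_cut)
    } else {
      red <- reduction_step(contr, cand$cormat, rank_t, r_cut, c_cut)
    }
    rank_t <- rank_t + 1L
    if (nrow(red$removed) == 0) next          # same model, try the next rank
    current <- red$keep
    candidates[[length(candidates) + 1]] <-
      fit_candidate(current, length(candidates) + 1L, red$removed)
  }

  aiccs <- vapply(candidates, function(cd)
    if (cd$aicc$valid) cd$aicc$aicc else Inf, 0)
  if (all(!is.finite(aiccs)))
    stopf(paste("all candidate models have invalid AICc (too many nonzero",
                "coefficients); use more presences or fewer features"))
  structure(list(candidates = candidates, winner = which.min(aiccs),
                 background = bg,
                 config = list(n_background = n_background, seed = seed,
                               r_cut = r_cut, c_cut = c_cut,
                               rank_from = rank_from)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  for (cd in x$candidates) {
    cat(sprintf("model %d: %d vars, k=%d, AICc=%s%s\n", cd$step,
                length(cd$vars), cd$aicc$k,
                if (cd$aicc$valid) sprintf("%.2f", cd$aicc$aicc) else "invalid",
                if (cd$step == x$winner) "  <- winner" else ""))
  }
  invisible(x)
}

#' Winner variable set of a selection trace
#' @param trace a [select_variables()] result.
#' @return character vector of variable names.
#' @export
winner_vars <- function(trace) trace$candidates[[trace$winner]]$vars

#' Persist a selection trace
#'
#' Writes a JSON document (per-step variable sets, contributions,
#' correlations, AICc) and a CSV summary table.
#'
#' @param trace a [select_variables()] result.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the summary data frame.
#' @export
write_trace <- function(trace, json_path = NULL, csv_path = NULL) {
  summary <- do.call(rbind, lapply(trace$candidates, function(cd) {
    data.frame(step = cd$step, n_vars = length(cd$vars), k = cd$aicc$k,
               lnL = cd$aicc$lnL,
               aicc = if (cd$aicc$valid) cd$aicc$aicc else NA_real_,
               winner = cd$step == trace$winner,
               variables = paste(cd$vars, collapse = ";"),
               removed = paste(cd$removed$var, collapse = ";"))
  }))
  if (!is.null(json_path)) {
    doc <- lapply(trace$candidates, function(cd) list(
      step = cd$step, variables = cd$vars,
      contributions = as.list(cd$contributions),
      correlations = if (nrow(cd$cormat)) as.data.frame(cd$cormat) else NULL,
      aicc = cd$aicc,
      removed = cd$removed))
    jsonlite::write_json(list(candidates = doc, winner = trace$winner),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) utils::write.csv(summary, csv_path, row.names = FALSE)
  invisible(summary)
}
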