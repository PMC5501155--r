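## Maximum-entropy presence-only model. The fitted object is the Gibbs
## distribution over background cells q(x) = exp(sum_j lambda_j f_j(x)) / Z
## that maximizes the L1-penalized log-likelihood of the presences:
##
##   J(lambda) = (1/n) sum_pres eta(x_i) - ln Z - sum_j beta_j |lambda_j|,
##   Z = sum_bg exp(eta),  beta_j = r * s_j / sqrt(n)
##
## with s_j the presence-sample standard deviation of feature j (floored) and
## r the regularization multiplier. J is concave; it is solved by an
## accelerated proximal gradient method (FISTA with backtracking line search
## and adaptive restart), whose soft-thresholding step yields exact zeros in
## lambda. The regularized gain is J + ln m: the penalized likelihood
## improvement over the uniform distribution on the m background cells.

#' Extract layer values at cells of a stack
#'
#' @param stack a [raster_stack()].
#' @param cells integer cell indices (column-major); default all unmasked
#'   cells.
#' @return data frame, one column per layer, attribute `"cells"` holding the
#'   indices.
#' @export
stack_values <- function(stack, cells = NULL) {
  if (is.null(cells)) cells <- which(stack_mask(stack))
  df <- as.data.frame(lapply(stack$layers, function(l) l$values[cells]))
  names(df) <- names(stack$layers)
  attr(df, "cells") <- cells
  df
}

stack_kinds <- function(stack)
  vapply(stack$layers, `[[`, "", "kind")

#' Sample background cells
#'
#' Draws up to `n` distinct unmasked cells uniformly without replacement.
#'
#' @param stack a [raster_stack()].
#' @param n target number of background points (all unmasked cells if fewer).
#' @param seed integer seed.
#' @return a `background_sample`: `cells` (column-major indices), `values`
#'   (data frame of layer values), `coords` (cell-center x/y).
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  mask <- stack_mask(stack)
  avail <- which(mask)
  if (length(avail) == 0) stopf("sample_background: stack is fully masked")
  k <- min(n, length(avail))
  cells <- with_seed(seed, sort(avail[sample.int(length(avail), k)]))
  rc <- arrayInd(cells, dim(mask))
  structure(list(cells = cells,
                 values = stack_values(stack, cells),
                 coords = cell_centers(stack$spec, rc[, 1], rc[, 2])),
            class = "background_sample")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the maximum-entropy model on feature matrices
#'
#' Low-level fitter working directly on presence and background feature
#' rows (each feature in `[0,1]`). Most callers use [maxent()] instead.
#'
#' @param x_pres,x_bg numeric feature matrices (rows = points). `x_bg` is the
#'   normalization set; include the presence rows in it beforehand if they
#'   should contribute to Z.
#' @param reg_multiplier L1 regularization multiplier r; `beta_j = r * s_j /
#'   sqrt(n)` with `s_j` the presence standard deviation of feature j,
#'   floored at 1e-4.
#' @param max_iter iteration cap.
#' @param tol relative objective-change convergence threshold.
#' @param beta optional explicit per-feature penalty vector overriding the
#'   `reg_multiplier` rule.
#' @param init optional starting coefficient vector (default all zero). The
#'   objective is concave, so any start converges to the same optimum value.
#' @return a `maxent_fit`: `lambdas`, `beta`, `log_Z`, `entropy_H`,
#'   `reg_gain`, `converged`, `iterations`.
#' @export
fit_maxent <- function(x_pres, x_bg, reg_multiplier = 1.0, max_iter = 500,
                       tol = 1e-5, beta = NULL, init = NULL) {
  x_pres <- as.matrix(x_pres); x_bg <- as.matrix(x_bg)
  n <- nrow(x_pres); m <- nrow(x_bg); p <- ncol(x_pres)
  if (n < 1) stopf("fit_maxent: need at least one presence")
  if (m < 2) stopf("fit_maxent: need at least two background points")
  a <- colMeans(x_pres)
  if (is.null(beta)) {
    s <- if (n > 1) apply(x_pres, 2, stats::sd) else rep(0, p)
    beta <- reg_multiplier * pmax(s, 1e-4) / sqrt(n)
  }
  beta <- rep_len(beta, p)

  lse_q <- function(eta) {
    mx <- max(eta)
    w <- exp(eta - mx)
    sw <- sum(w)
    list(lse = mx + log(sw), q = w / sw)
  }
  fval <- function(lam) {                       # smooth part to minimize
    lse_q(drop(x_bg %*% lam))$lse - sum(a * lam)
  }
  obj <- function(lam) fval(lam) + sum(beta * abs(lam))

  lam <- if (is.null(init)) numeric(p) else rep_len(init, p)
  yv <- lam; th <- 1
  t_step <- 1
  F_old <- obj(lam)
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    sq <- lse_q(drop(x_bg %*% yv))
    g <- drop(crossprod(x_bg, sq$q)) - a
    f_y <- sq$lse - sum(a * yv)
    repeat {                                    # backtracking line search
      lam_new <- soft_threshold(yv - t_step * g, t_step * beta)
      dlt <- lam_new - yv
      f_new <- fval(lam_new)
      if (f_new <= f_y + sum(g * dlt) + sum(dlt * dlt) / (2 * t_step) + 1e-12)
        break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    yv <- lam_new + ((th - 1) / th_new) * (lam_new - lam)
    F_new <- obj(lam_new)
    if (F_new > F_old) { yv <- lam_new; th_new <- 1 }   # adaptive restart
    lam <- lam_new; th <- th_new
    if (abs(F_new - F_old) < tol * (abs(F_old) + 1e-10)) {
      converged <- TRUE; F_old <- F_new; break
    }
    F_old <- F_new
    t_step <- t_step * 1.25                     # let the step re-grow
  }
  if (!converged) warnf("maxent fit did not converge in %d iterations", max_iter)

  ## Coordinate-wise proximal-Newton polish. Near-collinear hinge columns
  ## make the L1 optimum degenerate: the accelerated gradient path spreads
  ## small weights over many equivalent features. Exact one-dimensional
  ## updates (accepted only when the penalized objective improves) followed
  ## by a zero-cost zeroing pass consolidate such ties onto the sparsest
  ## representation, so the nonzero count reflects model complexity rather
  ## than solver history.
  eta <- drop(x_bg %*% lam)
  obj_at <- function(eta, lam) lse_q(eta)$lse - sum(a * lam) + sum(beta * abs(lam))
  cur <- obj_at(eta, lam)
  for (sweep in seq_len(50)) {
    changed <- FALSE
    w <- lse_q(eta)$q
    ef <- drop(crossprod(x_bg, w))              # E_q[f_j]
    ef2 <- drop(crossprod(x_bg * x_bg, w))      # E_q[f_j^2]
    gv <- ef - a
    hv <- pmax(ef2 - ef^2, 1e-8)
    for (j in seq_len(p)) {
      prop <- soft_threshold(lam[j] - gv[j] / hv[j], beta[j] / hv[j]) - lam[j]
      if (abs(prop) < 1e-12) next
      for (halving in 1:6) {
        lam_new <- lam; lam_new[j] <- lam[j] + prop
        eta_new <- eta + prop * x_bg[, j]
        obj_new <- obj_at(eta_new, lam_new)
        if (obj_new < cur - 1e-12) {
          lam <- lam_new; eta <- eta_new; cur <- obj_new; changed <- TRUE
          break
        }
        prop <- prop / 2
      }
    }
    ## zeroing pass: drop coefficients whose removal costs (numerically)
    ## nothing — the sparsest member of a degenerate optimal set
    for (j in order(abs(lam))) {
      if (lam[j] == 0) next
      lam_new <- lam; lam_new[j] <- 0
      eta_new <- eta - lam[j] * x_bg[, j]
      obj_new <- obj_at(eta_new, lam_new)
      if (obj_new <= cur + 1e-10) {
        lam <- lam_new; eta <- eta_new; cur <- obj_new; changed <- TRUE
      }
    }
    if (!changed) break
  }

  sq <- lse_q(drop(x_bg %*% lam))
  raw <- sq$q
  names(lam) <- colnames(x_pres)
  structure(list(
    lambdas = lam, beta = beta, log_Z = sq$lse,
    entropy_H = -sum(raw * log(raw)),
    reg_gain = sum(a * lam) - sq$lse - sum(beta * abs(lam)) + log(m),
    converged = converged, iterations = it,
    n_presences = n, m_background = m), class = "maxent_fit")
}

#' Fit a maximum-entropy habitat model from variable tables
#'
#' Builds the feature expansion from the background values, evaluates
#' presence and background feature rows, and fits the penalized model.
#'
#' @param pres_values data frame of environmental values at presences.
#' @param bg_values data frame of environmental values at background points
#'   (same columns).
#' @param kinds named `"continuous"`/`"categorical"` per variable.
#' @param classes `"auto"` or explicit feature classes (see
#'   [build_features()]).
#' @param reg_multiplier,max_iter,tol solver settings (see [fit_maxent()]).
#' @param hinge_knots hinge knots per variable.
#' @param presences_in_background add the presence rows to the background for
#'   normalization (the usual convention)?
#' @param expansion optionally reuse a prebuilt [build_features()] expansion.
#' @return a `maxent_model` holding the expansion and the fit.
#' @export
maxent <- function(pres_values, bg_values, kinds = NULL, classes = "auto",
                   reg_multiplier = 1.0, max_iter = 500, tol = 1e-5,
                   hinge_knots = 50, presences_in_background = TRUE,
                   expansion = NULL) {
  pres_values <- as.data.frame(pres_values)
  bg_values <- as.data.frame(bg_values)
  if (is.null(expansion))
    expansion <- build_features(bg_values, kinds = kinds, classes = classes,
                                n_presences = nrow(pres_values),
                                hinge_knots = hinge_knots)
  xp <- feature_matrix(expansion, pres_values)
  xb <- feature_matrix(expansion, bg_values)
  if (presences_in_background) xb <- rbind(xb, xp)
  fit <- fit_maxent(xp, xb, reg_multiplier = reg_multiplier,
                    max_iter = max_iter, tol = tol)
  structure(list(expansion = expansion, fit = fit,
                 settings = list(reg_multiplier = reg_multiplier,
                                 max_iter = max_iter, tol = tol,
                                 hinge_knots = hinge_knots,
                                 presences_in_background = presences_in_background)),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d variables, %d features (%d nonzero), gain %.4f%s\n",
              length(x$expansion$vars), length(x$fit$lambdas),
              sum(x$fit$lambdas != 0), x$fit$reg_gain,
              if (x$fit$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict habitat suitability
#'
#' Raw output is the normalized Gibbs density over the training background
#' (summing to 1 there); logistic output rescales it to a 0-1 suitability
#' index `r*e^H / (1 + r*e^H)` in which a cell with typical presence
#' conditions scores about 0.5. Features are clamped to the training range.
#'
#' @param object a [maxent()] model.
#' @param newdata data frame of variable values, or a [raster_stack()] (then
#'   a suitability [layer()] is returned, masked cells `NA`).
#' @param output `"logistic"` or `"raw"`.
#' @param ... unused.
#' @return numeric vector, or a [layer()] when `newdata` is a stack.
#' @export
predict.maxent_model <- function(object, newdata, output = c("logistic", "raw"),
                                 ...) {
  output <- match.arg(output)
  if (inherits(newdata, "raster_stack")) {
    cells <- which(stack_mask(newdata))
    vals <- stack_values(newdata, cells)
    pr <- predict(object, vals, output = output)
    m <- matrix(NA_real_, newdata$spec$n_rows, newdata$spec$n_cols)
    m[cells] <- pr
    return(layer(paste0("suitability_", output), m, newdata$spec))
  }
  x <- feature_matrix(object$expansion, newdata)
  eta <- drop(x %*% object$fit$lambdas)
  raw <- exp(eta - object$fit$log_Z)
  if (output == "raw") return(raw)
  v <- raw * exp(object$fit$entropy_H)
  v / (1 + v)
}

## refit on a subset of feature columns, reusing precomputed matrices
refit_subset <- function(xp, xb, beta, cols, settings) {
  if (length(cols) == 0) return(NULL)
  fit_maxent(xp[, cols, drop = FALSE], xb[, cols, drop = FALSE],
             max_iter = settings$max_iter, tol = settings$tol,
             beta = beta[cols])
}

#' Percent contribution of each variable
#'
#' Deterministic leave-one-variable-out attribution: each variable's
#' contribution is its drop in regularized gain when all of its features are
#' removed and the model refitted (floored at 0), normalized to sum to 100.
#'
#' @param model a [maxent()] model.
#' @param pres_values,bg_values the tables the model was trained on.
#' @return named numeric vector of percentages summing to 100 (all zeros,
#'   with attribute `all_zero = TRUE`, when no variable changes the gain).
#' @export
variable_contribution <- function(model, pres_values, bg_values) {
  exp_ <- model$expansion
  vars <- setdiff(exp_$vars, exp_$dropped)
  if (length(vars) == 1)
    return(stats::setNames(100, vars))
  xp <- feature_matrix(exp_, as.data.frame(pres_values))
  xb <- feature_matrix(exp_, as.data.frame(bg_values))
  if (model$settings$presences_in_background) xb <- rbind(xb, xp)
  fv <- feature_vars(exp_)
  gain_full <- model$fit$reg_gain
  drops <- vapply(vars, function(v) {
    keep <- which(fv != v)
    f <- refit_subset(xp, xb, model$fit$beta, keep, model$settings)
    max(0, gain_full - f$reg_gain)
  }, 0)
  if (sum(drops) == 0) {
    out <- stats::setNames(rep(0, length(vars)), vars)
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  100 * drops / sum(drops)
}

#' Jackknife AUC of single-variable models
#'
#' Refits the model with each variable alone and scores presences against the
#' background by rank AUC, measuring each variable's standalone
#' discriminative value.
#'
#' @inheritParams variable_contribution
#' @return named numeric vector of AUCs.
#' @export
jackknife_auc <- function(model, pres_values, bg_values) {
  exp_ <- model$expansion
  vars <- setdiff(exp_$vars, exp_$dropped)
  if (length(vars) < 2) stopf("jackknife_auc: need at least two variables")
  xp <- feature_matrix(exp_, as.data.frame(pres_values))
  xb0 <- feature_matrix(exp_, as.data.frame(bg_values))
  xb <- if (model$settings$presences_in_background) rbind(xb0, xp) else xb0
  fv <- feature_vars(exp_)
  vapply(vars, function(v) {
    cols <- which(fv == v)
    f <- refit_subset(xp, xb, model$fit$beta, cols, model$settings)
    if (is.null(f) || all(f$lambdas == 0)) {
      warnf("variable '%s': degenerate single-variable fit, AUC 0.5", v)
      return(0.5)
    }
    eta_p <- drop(xp[, cols, drop = FALSE] %*% f$lambdas)
    eta_b <- drop(xb0[, cols, drop = FALSE] %*% f$lambdas)
    rank_auc(eta_p, eta_b)
  }, 0)
}

#' Response curve of one variable
#'
#' Sweeps the variable across its background range (categorical: its codes)
#' with every other variable held at its background mean (categorical at the
#' modal code) and evaluates logistic suitability.
#'
#' @param model a [maxent()] model.
#' @param variable variable name.
#' @param n_points sweep resolution for continuous variables.
#' @return a `response_curve`: `variable`, `values`, `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  exp_ <- model$expansion
  if (!variable %in% exp_$vars) stopf("unknown variable '%s'", variable)
  sweep_vals <- if (exp_$kinds[[variable]] == "categorical") {
    exp_$levels[[variable]]
  } else {
    rng <- exp_$ranges[[variable]]
    if (is.null(rng)) stopf("variable '%s' was dropped as constant", variable)
    seq(rng[1], rng[2], length.out = n_points)
  }
  nd <- as.data.frame(lapply(exp_$bg_mean, rep, length(sweep_vals)))
  names(nd) <- exp_$vars
  nd[[variable]] <- sweep_vals
  structure(list(variable = variable, values = sweep_vals,
                 suitability = predict(model, nd, output = "logistic")),
            class = "response_curve")
}

## ---- model serialization ---------------------------------------------------

#' Save a fitted model as JSON
#'
#' Writes feature definitions, scaling, coefficients and normalization
#' constants, enabling exact re-prediction with [read_maxent()].
#'
#' @param model a [maxent()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maxent <- function(model, path) {
  doc <- list(
    schema = "maxhab-maxent-1",
    vars = model$expansion$vars,
    kinds = as.list(model$expansion$kinds),
    classes = model$expansion$classes,
    ranges = model$expansion$ranges,
    levels = model$expansion$levels,
    defs = model$expansion$defs,
    bg_mean = as.list(model$expansion$bg_mean),
    dropped = model$expansion$dropped,
    lambdas = as.list(model$fit$lambdas),
    beta = model$fit$beta,
    log_Z = model$fit$log_Z,
    entropy_H = model$fit$entropy_H,
    reg_gain = model$fit$reg_gain,
    converged = model$fit$converged,
    iterations = model$fit$iterations,
    n_presences = model$fit$n_presences,
    m_background = model$fit$m_background,
    settings = model$settings)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [write_maxent()]
#' @param path JSON file.
#' @return a `maxent_model`.
#' @export
read_maxent <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "maxhab-maxent-1"))
    stopf("'%s': unknown model schema", path)
  num <- function(x) as.numeric(unlist(x))
  expansion <- structure(list(
    vars = as.character(unlist(doc$vars)),
    kinds = stats::setNames(as.character(unlist(doc$kinds)), names(doc$kinds)),
    classes = as.character(unlist(doc$classes)),
    ranges = lapply(doc$ranges, num),
    levels = lapply(doc$levels, num),
    defs = lapply(doc$defs, function(d) {
      for (k in c("knot", "code")) if (!is.null(d[[k]])) d[[k]] <- as.numeric(d[[k]])
      d
    }),
    bg_mean = stats::setNames(num(doc$bg_mean), names(doc$bg_mean)),
    dropped = as.character(unlist(doc$dropped))), class = "feature_expansion")
  fit <- structure(list(
    lambdas = stats::setNames(num(doc$lambdas), names(doc$lambdas)),
    beta = num(doc$beta), log_Z = as.numeric(doc$log_Z),
    entropy_H = as.numeric(doc$entropy_H), reg_gain = as.numeric(doc$reg_gain),
    converged = isTRUE(doc$converged), iterations = as.integer(doc$iterations),
    n_presences = as.integer(doc$n_presences),
    m_background = as.integer(doc$m_background)), class = "maxent_fit")
  structure(list(expansion = expansion, fit = fit,
                 settings = lapply(doc$settings, function(x) x)),
            class = "maxent_model")
}
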