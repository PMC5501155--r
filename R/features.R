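## Feature expansion for the maximum-entropy model. Continuous variables are
## clamped to their background range and rescaled to z in [0,1]; features are
## then linear (z), quadratic (z^2), pairwise products (z_a * z_b) and hinge
## ramps max(0, (z - t) / (1 - t)) at background-quantile knots, so every
## feature maps any input to [0,1] after clamping. Categorical variables
## expand to one indicator per class code.

#' Choose feature classes from the presence count
#'
#' The conventional sample-size rule: fewer than 10 presences allows only
#' linear features; 10 adds quadratic; 15 adds hinge; 80 adds product.
#'
#' @param n_presences presence count.
#' @return character vector of feature classes.
#' @export
auto_feature_classes <- function(n_presences) {
  if (n_presences < 10) "linear"
  else if (n_presences < 15) c("linear", "quadratic")
  else if (n_presences < 80) c("linear", "quadratic", "hinge")
  else c("linear", "quadratic", "hinge", "product")
}

#' Build a feature expansion from background values
#'
#' @param bg_values data frame of background values, one column per variable.
#' @param kinds named character vector, `"continuous"` or `"categorical"`
#'   per variable; defaults to all continuous.
#' @param classes `"auto"` (use [auto_feature_classes()] on `n_presences`) or
#'   an explicit subset of `c("linear","quadratic","hinge","product")`.
#' @param n_presences presence count driving the auto rule.
#' @param hinge_knots number of hinge knots per variable, placed at evenly
#'   spaced background quantiles.
#' @return a `feature_expansion`: feature definitions plus the background
#'   scaling (per-variable min/max used for clamping and the `[0,1]`
#'   rescale) and background summaries used by response curves.
#' @export
build_features <- function(bg_values, kinds = NULL, classes = "auto",
                           n_presences = nrow(bg_values), hinge_knots = 50) {
  bg_values <- as.data.frame(bg_values)
  if (nrow(bg_values) == 0) stopf("build_features: empty background table")
  vars <- names(bg_values)
  if (is.null(kinds)) kinds <- stats::setNames(rep("continuous", length(vars)), vars)
  kinds <- kinds[vars]
  if (identical(classes, "auto")) classes <- auto_feature_classes(n_presences)
  stopifnot(all(classes %in% c("linear", "quadratic", "hinge", "product")))

  ranges <- list(); defs <- list(); dropped <- character()
  cont <- vars[kinds == "continuous"]
  for (v in cont) {
    x <- bg_values[[v]]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) {
      dropped <- c(dropped, v); next
    }
    ranges[[v]] <- rng
    z <- (x - rng[1]) / (rng[2] - rng[1])
    if ("linear" %in% classes)
      defs[[length(defs) + 1]] <- list(name = paste0("lin:", v), class = "linear", var = v)
    if ("quadratic" %in% classes)
      defs[[length(defs) + 1]] <- list(name = paste0("quad:", v), class = "quadratic", var = v)
    if ("hinge" %in% classes && hinge_knots > 0) {
      knots <- unname(stats::quantile(z, probs = seq(0, hinge_knots - 1) / hinge_knots,
                                      na.rm = TRUE, type = 7))
      knots <- pmin(knots, 1 - 1e-9)
      for (k in seq_along(knots))
        defs[[length(defs) + 1]] <- list(name = sprintf("hinge:%s:%02d", v, k),
                                         class = "hinge", var = v, knot = knots[k])
    }
  }
  cont_kept <- intersect(cont, names(ranges))
  if ("product" %in% classes && length(cont_kept) >= 2) {
    for (a in seq_len(length(cont_kept) - 1)) for (b in (a + 1):length(cont_kept))
      defs[[length(defs) + 1]] <- list(name = paste0("prod:", cont_kept[a], ":", cont_kept[b]),
                                       class = "product",
                                       var = cont_kept[a], var2 = cont_kept[b])
  }
  levels <- list()
  for (v in vars[kinds == "categorical"]) {
    codes <- sort(unique(bg_values[[v]][!is.na(bg_values[[v]])]))
    if (length(codes) <= 1) { dropped <- c(dropped, v); next }
    levels[[v]] <- codes
    for (cd in codes)
      defs[[length(defs) + 1]] <- list(name = sprintf("cat:%s:%g", v, cd),
                                       class = "category", var = v, code = cd)
  }
  if (length(dropped))
    warnf("constant layer(s) dropped from feature expansion: %s",
          paste(dropped, collapse = ", "))
  if (length(defs) == 0) stopf("no usable features (all layers constant?)")

  ## background summaries for response curves: means of continuous, modal
  ## code of categorical variables
  bg_mean <- vapply(vars, function(v) {
    x <- bg_values[[v]][!is.na(bg_values[[v]])]
    if (kinds[[v]] == "categorical") {
      tab <- table(x); as.numeric(names(tab)[which.max(tab)])
    } else mean(x)
  }, 0)

  structure(list(vars = vars, kinds = kinds, classes = classes,
                 ranges = ranges, levels = levels, defs = defs,
                 bg_mean = bg_mean, dropped = dropped),
            class = "feature_expansion")
}

#' Evaluate the feature matrix
#'
#' Continuous inputs are clamped to the background (training) range before
#' rescaling, so out-of-range projection values never leave `[0,1]`.
#'
#' @param expansion a [build_features()] result.
#' @param values data frame with the expansion's variables as columns.
#' @return numeric matrix, rows = input rows, one column per feature.
#' @export
feature_matrix <- function(expansion, values) {
  values <- as.data.frame(values)
  zcache <- new.env(parent = emptyenv())
  zval <- function(v) {
    if (!is.null(zcache[[v]])) return(zcache[[v]])
    rng <- expansion$ranges[[v]]
    z <- (pmin(pmax(values[[v]], rng[1]), rng[2]) - rng[1]) / (rng[2] - rng[1])
    zcache[[v]] <- z
    z
  }
  cols <- lapply(expansion$defs, function(d) {
    switch(d$class,
      linear    = zval(d$var),
      quadratic = zval(d$var)^2,
      product   = zval(d$var) * zval(d$var2),
      hinge     = pmax(0, (zval(d$var) - d$knot) / (1 - d$knot)),
      category  = as.numeric(values[[d$var]] == d$code))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(expansion$defs, `[[`, "", "name")
  m
}

## variable owning each feature column
feature_vars <- function(expansion)
  vapply(expansion$defs, `[[`, "", "var")
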