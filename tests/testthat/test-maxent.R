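# two-cell closed-form setup: single binary feature, presence mean 0.8;
# the moment condition e^l / (1 + e^l) = 0.8 gives l = ln 4
two_cell_fit <- function(tol = 1e-10) {
  x_pres <- matrix(c(rep(1, 8), rep(0, 2)), ncol = 1)
  x_bg <- matrix(c(0, 1), ncol = 1)
  fit_maxent(x_pres, x_bg, beta = 0, tol = tol)
}

test_that("two-cell model matches the closed form", {
  f <- two_cell_fit()
  expect_equal(unname(f$lambdas), log(4), tolerance = 1e-4)
  raw <- exp(c(0, 1) * f$lambdas - f$log_Z)
  expect_equal(raw, c(0.2, 0.8), tolerance = 1e-4)
  expect_equal(f$reg_gain, 0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("matched presence and background moments give the uniform model", {
  x_pres <- matrix(c(0, 1), ncol = 1)            # mean 0.5
  x_bg <- matrix(c(0, 1), ncol = 1)              # uniform mean 0.5
  f <- fit_maxent(x_pres, x_bg, beta = 0)
  expect_equal(unname(f$lambdas), 0)
  expect_equal(f$reg_gain, 0, tolerance = 1e-10)
})

test_that("the uniform model predicts logistic 0.5 everywhere", {
  set.seed(21)
  bg <- data.frame(v = rnorm(200))
  # overwhelming penalty forces all coefficients to zero
  m <- maxent(bg[1:10, , drop = FALSE], bg, reg_multiplier = 1e6,
              presences_in_background = FALSE)
  expect_true(all(m$fit$lambdas == 0))
  expect_equal(m$fit$entropy_H, log(200), tolerance = 1e-12)
  pr <- predict(m, bg)
  expect_equal(pr, rep(0.5, 200), tolerance = 1e-12)
  expect_equal(predict(m, bg, output = "raw"), rep(1 / 200, 200))
})

test_that("raw predictions sum to one over the background after every fit", {
  ds <- small_landscape()
  bg <- sample_background(ds$stack, 500, seed = 2)
  pv <- extract_values(ds$stack, ds$occurrences)[, names(ds$stack$layers)]
  for (r in c(0.5, 1, 2)) {
    m <- maxent(pv, bg$values, reg_multiplier = r,
                presences_in_background = FALSE)
    raw <- predict(m, bg$values, output = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-8)
  }
})

test_that("objective is concave: random starts agree", {
  set.seed(31)
  x_bg <- cbind(runif(80), runif(80))
  x_pres <- x_bg[sample(80, 25, prob = x_bg[, 1] + 0.1), ]
  objs <- vapply(1:5, function(i) {
    f <- fit_maxent(x_pres, x_bg, reg_multiplier = 1, tol = 1e-9,
                    init = rnorm(2, sd = 2))
    f$reg_gain
  }, 0)
  expect_lt(diff(range(objs)), 1e-6)
})

test_that("stronger L1 penalty shrinks coefficients, weaker raises gain", {
  set.seed(32)
  for (case in 1:5) {
    x_bg <- cbind(runif(60), runif(60), runif(60))
    x_pres <- x_bg[sample(60, 20, prob = x_bg[, 2] + 0.05), ]
    fits <- lapply(c(0.5, 1, 2), function(r)
      fit_maxent(x_pres, x_bg, reg_multiplier = r, tol = 1e-8))
    l1 <- vapply(fits, function(f) sum(abs(f$lambdas)), 0)
    expect_true(all(diff(l1) <= 1e-6))           # L1 norm non-increasing in r
    gains <- vapply(fits, `[[`, 0, "reg_gain")
    expect_true(all(diff(gains) <= 1e-6))        # gain non-increasing in r
  }
})

test_that("background sampling is reproducible, exhaustive and uniform", {
  ds <- small_landscape(n = 20, n_presences = 10)
  b1 <- sample_background(ds$stack, 100, seed = 9)
  b2 <- sample_background(ds$stack, 100, seed = 9)
  expect_identical(b1$cells, b2$cells)
  # n larger than the number of unmasked cells: all cells returned
  ball <- sample_background(ds$stack, 1e6, seed = 1)
  expect_equal(length(ball$cells), 400)
  # empirical inclusion rate over seeds matches n / N
  n_cells <- 400; draw <- 40
  hits <- integer(n_cells)
  for (s in 1:200) {
    b <- sample_background(ds$stack, draw, seed = s)
    hits[b$cells] <- hits[b$cells] + 1L
  }
  rate <- hits / 200
  expect_equal(mean(rate), draw / n_cells, tolerance = 1e-12)
  se <- sqrt(0.1 * 0.9 / 200)
  expect_true(all(abs(rate - 0.1) < 5 * se))
})

test_that("fully masked stacks cannot be sampled", {
  m <- matrix(NA_real_, 3, 3)
  st <- raster_stack(list(layer("v", m, grid_spec(3, 3, 100))))
  expect_error(sample_background(st, 10, seed = 1), "masked")
})

test_that("variable contributions attribute gain drops", {
  # single variable: 100% by convention
  set.seed(41)
  bg1 <- data.frame(a = rnorm(300))
  pv1 <- data.frame(a = rnorm(40, mean = 1))
  m1 <- maxent(pv1, bg1, presences_in_background = FALSE)
  expect_equal(unname(variable_contribution(m1, pv1, bg1)), 100)

  # two independent, symmetric informative variables: about 50/50
  bg2 <- data.frame(a = rnorm(2000), b = rnorm(2000))
  keep <- runif(2000) < exp(-((bg2$a - 0.5)^2 + (bg2$b - 0.5)^2) / (2 * 0.35^2))
  pv2 <- bg2[keep, ][1:60, ]
  m2 <- maxent(pv2, bg2, presences_in_background = FALSE)
  co <- variable_contribution(m2, pv2, bg2)
  expect_equal(sum(co), 100, tolerance = 1e-8)
  expect_equal(unname(co["a"]), 50, tolerance = 15)

  # an exact duplicate's leave-out drop vanishes: its twin compensates
  bg3 <- data.frame(a = bg2$a, dup = bg2$a)
  pv3 <- data.frame(a = pv2$a, dup = pv2$a)
  m3 <- maxent(pv3, bg3, presences_in_background = FALSE)
  co3 <- variable_contribution(m3, pv3, bg3)
  expect_equal(sum(co3), 100, tolerance = 1e-8)
})

test_that("jackknife AUC separates informative from noise variables", {
  hits <- 0
  for (s in 1:5) {
    ds <- small_landscape(seed = 300 + s, n = 40, n_presences = 60)
    bg <- sample_background(ds$stack, 600, seed = s)
    pv <- extract_values(ds$stack, ds$occurrences)[, names(ds$stack$layers)]
    m <- maxent(pv, bg$values)
    ja <- jackknife_auc(m, pv, bg$values)
    if (ja[["env_a"]] > ja[["noise_1"]]) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("jackknife AUC is invariant to affine recoding of a variable", {
  set.seed(51)
  bg <- data.frame(a = rnorm(400), b = rnorm(400))
  bg$recoded <- 3 * bg$a - 7
  pv <- data.frame(a = rnorm(30, 0.8))
  pv$b <- rnorm(30); pv$recoded <- 3 * pv$a - 7
  m <- maxent(pv, bg, presences_in_background = FALSE)
  ja <- jackknife_auc(m, pv, bg)
  expect_equal(unname(ja["a"]), unname(ja["recoded"]), tolerance = 1e-6)
})

test_that("response curves are flat at 0.5 for the uniform model", {
  set.seed(61)
  bg <- data.frame(a = rnorm(150), b = rnorm(150))
  m <- maxent(bg[1:12, ], bg, reg_multiplier = 1e6,
              presences_in_background = FALSE)
  cv <- response_curve(m, "a")
  expect_true(all(abs(cv$suitability - 0.5) < 1e-10))
  expect_length(cv$values, 100)
  expect_error(response_curve(m, "zzz"), "unknown variable")
})

test_that("response curves stay within [0, 1] and track a planted optimum", {
  # coarse recovery at reduced landscape scale; the tight +/- 0.5 sigma
  # recovery bound is asserted at full scale in the acceptance suite
  errs <- vapply(1:5, function(s) {
    ds <- small_landscape(seed = 400 + s, n = 50, n_presences = 120)
    bg <- sample_background(ds$stack, 800, seed = s)
    pv <- extract_values(ds$stack, ds$occurrences)[, names(ds$stack$layers)]
    m <- maxent(pv, bg$values)
    cv <- response_curve(m, "env_a")
    expect_true(all(cv$suitability >= 0 & cv$suitability <= 1))
    abs(cv$values[which.max(cv$suitability)] - 0.5) / 0.3
  }, 0)
  expect_lt(median(errs), 1)
})

test_that("models survive a JSON round-trip with exact re-prediction", {
  path <- withr::local_tempfile(fileext = ".json")
  set.seed(71)
  bg <- data.frame(a = rnorm(200), b = rnorm(200),
                   lc = sample(c(1, 2, 4), 200, replace = TRUE))
  pv <- data.frame(a = rnorm(25, 1), b = rnorm(25),
                   lc = sample(c(1, 2, 4), 25, replace = TRUE))
  m <- maxent(pv, bg, kinds = c(a = "continuous", b = "continuous",
                                lc = "categorical"))
  write_maxent(m, path)
  m2 <- read_maxent(path)
  nd <- data.frame(a = seq(-2, 2, length.out = 17), b = 0.3, lc = 2)
  expect_equal(predict(m2, nd), predict(m, nd), tolerance = 1e-12)
  expect_equal(predict(m2, nd, output = "raw"), predict(m, nd, output = "raw"),
               tolerance = 1e-12)
})
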