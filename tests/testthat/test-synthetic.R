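test_that("gaussian fields are reproducible, standardized and smooth", {
  spec <- grid_spec(40, 40, 250)
  f1 <- gaussian_field(spec, 2500, seed = 7)
  f2 <- gaussian_field(spec, 2500, seed = 7)
  expect_identical(f1$values, f2$values)
  expect_equal(mean(f1$values), 0, tolerance = 1e-6)
  expect_equal(sd(f1$values), 1, tolerance = 1e-6)

  # longer length scale raises lag-1 spatial autocorrelation
  wins <- 0
  for (s in 1:20) {
    smooth <- maxhab:::lag1_autocor(gaussian_field(spec, 2500, seed = s)$values)
    rough <- maxhab:::lag1_autocor(gaussian_field(spec, 250, seed = s)$values)
    if (smooth > rough) wins <- wins + 1
  }
  expect_equal(wins, 20)
  expect_error(gaussian_field(spec, -5, seed = 1), "positive")
})

test_that("planted responses have the stated functional forms", {
  rf <- maxhab:::response_factor
  expect_equal(rf("gaussian", 0.5, list(mu = 0.5, sigma = 0.3)), 1)
  expect_equal(rf("gaussian", 0.8, list(mu = 0.5, sigma = 0.3)),
               exp(-0.09 / (2 * 0.09)))
  expect_equal(rf("saturating", c(100, 5000, 99999), list(d0 = 5000)),
               c(0.02, 1, 1))
  expect_equal(rf("flat", c(1, 2, 3), list()), c(1, 1, 1))
})

test_that("landscape generation is a pure function of its configuration", {
  cfg <- landscape_config(n_cols = 30, n_rows = 30, n_presences = 40,
                          seed = 314)
  d1 <- build_landscape(cfg)
  d2 <- build_landscape(cfg)
  expect_identical(d1$stack$layers$env_a$values, d2$stack$layers$env_a$values)
  expect_identical(d1$truth$values, d2$truth$values)
  expect_identical(d1$occurrences$records, d2$occurrences$records)
  expect_true(all(d1$truth$values >= 0 & d1$truth$values <= 1))
  # manifest records every layer's role
  roles <- vapply(d1$manifest, `[[`, "", "role")
  expect_equal(sum(roles == "informative"), 2)
  expect_equal(sum(roles == "duplicate"), 1)
  expect_equal(sum(roles == "noise"), 3)
  expect_equal(names(d1$manifest), names(d1$stack$layers))
})

test_that("flat-only truth is rejected; flat responses leave truth at one", {
  expect_error(build_landscape(landscape_config(
    n_cols = 10, n_rows = 10, n_presences = 5,
    responses = list(list(name = "a", form = "flat")))), "informative")
  ds <- build_landscape(landscape_config(
    n_cols = 10, n_rows = 10, n_presences = 5,
    responses = list(list(name = "a", form = "flat"),
                     list(name = "b", form = "gaussian", mu = 0, sigma = 1e6)),
    n_duplicates = 0, n_noise = 0, seed = 2))
  expect_true(all(abs(ds$truth$values - 1) < 1e-6))
})

test_that("duplicate layers hit their target correlation", {
  for (r_target in c(0.9, 0.75, -0.6)) {
    ds <- build_landscape(landscape_config(
      n_cols = 40, n_rows = 40, n_presences = 20,
      duplicate_r = r_target, seed = 99))
    got_all <- cor(as.vector(ds$stack$layers$env_a$values),
                   as.vector(ds$stack$layers$dup_env_a_1$values))
    expect_equal(got_all, r_target, tolerance = 1e-10)
    bg <- sample_background(ds$stack, 500, seed = 3)
    got_bg <- cor(bg$values$env_a, bg$values$dup_env_a_1)
    expect_lt(abs(got_bg - r_target), 0.03)
  }
  expect_error(landscape_config(duplicate_r = 1), "inside")
})

test_that("presences are sampled proportional to the truth", {
  spec <- grid_spec(3, 3, 100)
  # all mass on one cell
  m <- matrix(0, 3, 3); m[2, 2] <- 1
  tl <- layer("t", m, spec)
  occ <- sample_presences(tl, 1, seed = 4)
  expect_equal(occ$records$x, 150)
  expect_equal(occ$records$y, 150)
  expect_error(sample_presences(tl, 2, seed = 1), "positive-truth")

  # uniform truth: per-cell frequencies match the uniform rate
  u <- layer("u", matrix(1, 4, 4), grid_spec(4, 4, 100))
  hits <- numeric(16)
  for (s in 1:500) {
    oc <- sample_presences(u, 4, seed = s)
    cl <- maxhab:::point_to_cell(u$spec, oc$records$x, oc$records$y)
    hits[(cl$col - 1) * 4 + cl$row] <- hits[(cl$col - 1) * 4 + cl$row] + 1
  }
  p_hat <- hits / (500 * 4)
  se <- sqrt((1 / 16) * (15 / 16) / (500 * 4))
  expect_true(all(abs(p_hat - 1 / 16) < 5 * se))

  # determinism
  o1 <- sample_presences(u, 4, seed = 10)
  o2 <- sample_presences(u, 4, seed = 10)
  expect_identical(o1$records, o2$records)
})

test_that("presence density tracks the planted truth", {
  ds <- small_landscape(seed = 404, n = 30, n_presences = 60)
  counts <- matrix(0, 30, 30)
  for (s in 1:100) {
    oc <- sample_presences(ds$truth, 60, seed = s)
    cl <- maxhab:::point_to_cell(ds$truth$spec, oc$records$x, oc$records$y)
    idx <- cbind(cl$row, cl$col)
    counts[idx] <- counts[idx] + 1
  }
  rho <- cor(as.vector(counts), as.vector(ds$truth$values),
             method = "spearman")
  expect_gte(rho, 0.5)
})

test_that("the synthetic record-table stand-in thins to its cluster count", {
  for (s in c(1, 7, 42)) {
    occ <- synthetic_s1_occurrences(seed = s)
    expect_equal(nrow(occ$records), 103)
    expect_equal(nrow(thin_occurrences(occ, 564.19, seed = s)$records), 64)
    expect_equal(nrow(thin_occurrences(occ, 1000, seed = s + 1)$records), 64)
  }
})

test_that("synthetic datasets dump to a loadable directory", {
  dir <- withr::local_tempdir()
  ds <- small_landscape(seed = 510, n = 15, n_presences = 10)
  write_landscape(ds, dir)
  grids <- list.files(file.path(dir, "stack"), full.names = TRUE)
  back <- load_stack(grids, names = sub("\\.asc$", "", basename(grids)))
  expect_setequal(names(back$layers), names(ds$stack$layers))
  expect_equal(back$layers$env_a$values, ds$stack$layers$env_a$values,
               tolerance = 1e-9)
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ$records), 10)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(names(man$manifest), names(ds$manifest))
})

test_that("recovery reports count aliased twins and peak errors", {
  ds <- small_landscape(seed = 505, n = 40, n_presences = 70,
                        n_duplicates = 1)
  tr <- select_variables(ds$stack, ds$occurrences, n_background = 500,
                         seed = 6)
  rep <- recovery_report(ds, tr)
  expect_true(rep$informative_recall >= 0 && rep$informative_recall <= 1)
  expect_equal(names(rep$recovered), c("env_a", "env_b"))
  # a duplicate standing alone counts as its source
  fake_trace <- tr
  fake_trace$candidates[[fake_trace$winner]]$vars <- c("dup_env_a_1", "env_b")
  rep2 <- recovery_report(ds, fake_trace)
  expect_equal(unname(rep2$recovered["env_a"]), TRUE)
  expect_equal(rep2$informative_recall, 1)
})
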