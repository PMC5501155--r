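test_that("pseudo-absences respect the exclusion buffer", {
  ds <- small_landscape(n = 40, n_presences = 20)
  pa <- generate_pseudo_absences(ds$stack, ds$occurrences, n = 100,
                                 exclusion_radius = 1000, seed = 4)
  expect_equal(nrow(pa$records), 100)
  d <- outer(pa$records$x, ds$occurrences$records$x, "-")^2 +
       outer(pa$records$y, ds$occurrences$records$y, "-")^2
  expect_true(all(sqrt(d) >= 1000))            # brute-force distance check

  # no presences: no exclusion anywhere
  none <- occurrence_set(data.frame(id = character(), x = numeric(),
                                    y = numeric()))
  pa2 <- generate_pseudo_absences(ds$stack, none, n = 50, seed = 1)
  expect_equal(nrow(pa2$records), 50)

  # determinism
  pa3 <- generate_pseudo_absences(ds$stack, ds$occurrences, n = 100,
                                  exclusion_radius = 1000, seed = 4)
  expect_identical(pa$records$x, pa3$records$x)
})

test_that("pseudo-absence generation fails when no cell is eligible", {
  sp <- grid_spec(4, 4, 100)
  st <- raster_stack(list(layer("v", matrix(1, 4, 4), sp)))
  center <- occurrence_set(data.frame(id = 1, x = 200, y = 200))
  expect_error(generate_pseudo_absences(st, center, n = 5,
                                        exclusion_radius = 5000, seed = 1),
               "no unmasked area")
  expect_error(generate_pseudo_absences(st, center, n = 16,
                                        exclusion_radius = 150, seed = 1),
               "reduce n")
})

test_that("rank AUC counts concordant pairs with half ties", {
  expect_equal(rank_auc(c(0.8, 0.6), c(0.7, 0.2)), 0.75)
  expect_equal(rank_auc(rep(0.4, 5), rep(0.4, 7)), 0.5)
  expect_equal(rank_auc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_error(rank_auc(numeric(0), 1), "non-empty")

  # brute-force pairwise oracle on random score sets
  set.seed(10)
  for (i in 1:20) {
    pos <- round(runif(sample(2:15, 1)), 2)
    neg <- round(runif(sample(2:15, 1)), 2)
    brute <- mean(outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q)))
    expect_equal(rank_auc(pos, neg), brute)
  }
})

test_that("rank AUC is invariant under monotone score transforms", {
  set.seed(11)
  pos <- runif(20); neg <- runif(30)
  a0 <- rank_auc(pos, neg)
  expect_equal(rank_auc(qlogis(pos), qlogis(neg)), a0)
  expect_equal(rank_auc(pos^3, neg^3), a0)
})

test_that("confusion metrics match the textbook formulas", {
  cm <- confusion_metrics(tp = 45, fn = 5, tn = 180, fp = 20)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$tss, 0.8)
  expect_equal(cm$kappa, 0.7191, tolerance = 1e-4)
  perfect <- confusion_metrics(10, 0, 20, 0)
  expect_equal(perfect$tss, 1)
  expect_equal(perfect$kappa, 1)
  expect_error(confusion_metrics(0, 0, 5, 5), "presences")
  expect_error(confusion_metrics(5, 5, 0, 0), "absences")
})

test_that("threshold maximization scans the grid and ties break small", {
  mt <- maximize_threshold(c(0.9, 0.8), c(0.1, 0.2), "tss")
  expect_equal(mt$value, 1.0)
  expect_equal(mt$threshold, 0.201)            # smallest grid value above 0.2
  flat <- maximize_threshold(rep(0.5, 4), rep(0.5, 6), "tss")
  expect_equal(flat$value, 0)

  # exact agreement with an exhaustive unique-score scan when scores sit on
  # the threshold grid; never better than the exhaustive scan otherwise
  set.seed(12)
  for (metric in c("tss", "kappa")) {
    for (i in 1:25) {
      pos <- round(runif(sample(3:20, 1)), 3)
      neg <- round(runif(sample(3:20, 1)), 3)
      got <- maximize_threshold(pos, neg, metric)
      cand <- sort(unique(c(0, pos, neg, 1)))
      vals <- vapply(cand, function(th) {
        tp <- sum(pos >= th); fp <- sum(neg >= th)
        cmx <- confusion_metrics(tp, length(pos) - tp,
                                 length(neg) - fp, fp)
        cmx[[metric]]
      }, 0)
      expect_equal(got$value, max(vals), tolerance = 1e-12)
      cont_pos <- runif(10); cont_neg <- runif(10)
      gc <- maximize_threshold(cont_pos, cont_neg, metric)
      cc <- sort(unique(c(0, cont_pos, cont_neg)))
      best <- max(vapply(cc, function(th) {
        tp <- sum(cont_pos >= th); fp <- sum(cont_neg >= th)
        confusion_metrics(tp, 10 - tp, 10 - fp, fp)[[metric]]
      }, 0))
      expect_lte(gc$value, best + 1e-12)
    }
  }
})

test_that("performance classes follow the published bins", {
  expect_equal(performance_class("auc", 0.966), "excellent")
  expect_equal(performance_class("auc", 0.85), "good")
  expect_equal(performance_class("auc", 0.75), "fair")
  expect_equal(performance_class("auc", 0.65), "poor")
  expect_equal(performance_class("auc", 0.55), "failed")
  expect_equal(performance_class("auc", 0.9), "excellent")  # boundary up
  expect_equal(performance_class("kappa", 0.813), "excellent")
  expect_equal(performance_class("kappa", 0.5), "good")
  expect_equal(performance_class("kappa", 0.2), "poor")
  expect_equal(performance_class("tss", 0.882), "good_to_excellent")
  expect_equal(performance_class("tss", 0.6), "useful")
  expect_error(performance_class("auc", 1.2), "out of")
})

test_that("TSS of a random classifier is centered on zero", {
  set.seed(13)
  scores <- runif(120)
  labels <- rep(c(TRUE, FALSE), c(40, 80))
  tss <- vapply(1:1000, function(i) {
    lab <- sample(labels)
    th <- 0.5
    tp <- sum(scores >= th & lab); fn <- sum(scores < th & lab)
    tn <- sum(scores < th & !lab); fp <- sum(scores >= th & !lab)
    tp / (tp + fn) + tn / (tn + fp) - 1
  }, 0)
  expect_lt(abs(mean(tss)), 0.02)
})

test_that("bootstrap evaluation produces consistent replicate bookkeeping", {
  ds <- small_landscape(seed = 202, n = 40, n_presences = 64)
  pa <- generate_pseudo_absences(ds$stack, ds$occurrences, n = 80, seed = 5)
  ev <- bootstrap_evaluate(ds$stack, ds$occurrences, pa, reps = 6,
                           seed = 99, n_background = 400)
  expect_length(ev$replicates, 6)
  # n = 64 at 75/25: 48 train, 16 test
  expect_equal(lengths(lapply(ev$replicates, `[[`, "train_ids")),
               rep(48, 6))
  expect_equal(lengths(lapply(ev$replicates, `[[`, "test_ids")),
               rep(16, 6))
  # summary means equal recomputed means of the stored replicates
  expect_identical(ev$means$test_auc,
                   mean(vapply(ev$replicates, `[[`, 0, "test_auc")))
  expect_identical(ev$means$max_tss,
                   mean(vapply(ev$replicates, `[[`, 0, "max_tss")))
  expect_true(all(vapply(ev$replicates, `[[`, 0, "tss_threshold") >= 0))
  expect_true(all(vapply(ev$replicates, `[[`, 0, "max_tss") <= 1))
  # prediction grids retained per replicate
  expect_s3_class(ev$replicates[[1]]$prediction, "hab_layer")
  expect_error(bootstrap_evaluate(ds$stack,
                                  occurrence_set(ds$occurrences$records[1:3, ]),
                                  pa, reps = 2, seed = 1,
                                  n_background = 100),
               "at least 4")
})

test_that("evaluation reports persist to JSON and CSV", {
  dir <- withr::local_tempdir()
  ds <- small_landscape(seed = 203, n = 30, n_presences = 24)
  pa <- generate_pseudo_absences(ds$stack, ds$occurrences, n = 40, seed = 5)
  ev <- bootstrap_evaluate(ds$stack, ds$occurrences, pa, reps = 3,
                           seed = 1, n_background = 200)
  write_evaluation(ev, file.path(dir, "e.json"), file.path(dir, "e.csv"))
  back <- utils::read.csv(file.path(dir, "e.csv"))
  expect_equal(nrow(back), 4)                  # 3 replicates + summary row
  expect_equal(back$test_auc[4], ev$means$test_auc)
})
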