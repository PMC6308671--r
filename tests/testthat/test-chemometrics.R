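# Autoscaling, SIMPLS PLS-DA, Gaussian-PDF calibration, probabilities,
# LV selection and cross-validated performance.

test_that("autoscaler standardizes with n-1 sd and training statistics", {
  tab <- spectrum_table(matrix(c(1, 3, 10, 20), 2), c(500, 600),
                        c("a", "b"))
  sc <- fit_scaler(tab)
  z <- apply_scaler(sc, tab)
  expect_equal(unname(z$values[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(z$values))), 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)), c(1, 1))
  # new data transformed with training statistics, not its own
  tab2 <- spectrum_table(matrix(c(3, 3, 20, 20), 2), c(500, 600),
                         c("c", "d"))
  z2 <- apply_scaler(sc, tab2)
  expect_equal(unname(z2$values[, 1]), c(1, 1) / sqrt(2))
})

test_that("constant columns are clamped with a warning and map to zero", {
  tab <- spectrum_table(matrix(c(5, 5, 5, 1, 2, 3), 3), c(500, 600),
                        c("a", "b", "c"))
  expect_warning(sc <- fit_scaler(tab), "constant")
  z <- apply_scaler(sc, tab)
  expect_equal(unname(z$values[, 1]), c(0, 0, 0))
})

test_that("PLS-DA with a perfectly collinear predictor reproduces the labels", {
  label <- rep(c("healthy", "bruised"), each = 10)
  y <- ifelse(label == "healthy", 1, -1)
  tab <- spectrum_table(matrix(3 * y + 1, ncol = 1), 700,
                        sprintf("s%02d", 1:20), label)
  m <- fit_plsda(tab, 1)
  expect_equal(predict_scores(m, tab), y, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(2)
  n <- 30; p <- 4
  label <- rep(c("healthy", "bruised"), each = n / 2)
  X <- matrix(rnorm(n * p), n)
  tab <- spectrum_table(X, seq(500, 800, length.out = p),
                        sprintf("s%02d", 1:n), label)
  m <- fit_plsda(tab, p, autoscale = FALSE)
  ols <- lm(ifelse(label == "healthy", 1, -1) ~ X)
  expect_equal(unname(m$coef), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("PLS-DA is invariant to training-row permutation", {
  tab <- separable_table(seed = 3, n = 40, p = 6, delta = 2)
  set.seed(9); perm <- sample(40)
  tabp <- spectrum_table(tab$values[perm, ], tab$wavelengths,
                         tab$sample_id[perm], tab$label[perm])
  expect_equal(fit_plsda(tab, 3)$coef, fit_plsda(tabp, 3)$coef,
               tolerance = 1e-10)
})

test_that("fit_plsda validates inputs", {
  tab <- separable_table(seed = 1, n = 20, p = 5)
  single <- spectrum_table(tab$values, tab$wavelengths, tab$sample_id,
                           rep("healthy", 20))
  expect_error(fit_plsda(single, 2), "single class")
  expect_error(fit_plsda(tab, 0), "n_lv")
  expect_error(fit_plsda(tab, 25), "n_lv")
  m <- fit_plsda(tab, 2)
  other <- spectrum_table(tab$values, tab$wavelengths + 1, tab$sample_id)
  expect_error(predict_scores(m, other), "grid")
})

test_that("select_lv respects bounds, ties and determinism", {
  tab <- separable_table(seed = 4, n = 50, p = 6, delta = 3)
  expect_equal(select_lv(tab, max_lv = 1, folds = 5, seed = 1), 1)
  expect_identical(select_lv(tab, 5, folds = 5, seed = 7),
                   select_lv(tab, 5, folds = 5, seed = 7))
  tiny <- separable_table(seed = 1, n = 8, p = 3)
  expect_error(select_lv(tiny, 2, folds = 10), "folds")
})

test_that("select_lv finds a single informative direction", {
  # one strong latent direction + pure noise: 1 LV should win usually
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80; p <- 12
    label <- rep(c("healthy", "bruised"), each = n / 2)
    strength <- ifelse(label == "healthy", 2, -2)
    X <- outer(strength, rep(1, p)) + matrix(rnorm(n * p, 0, 2), n)
    tab <- spectrum_table(X, seq(500, 900, length.out = p),
                          sprintf("s%02d", 1:n), label)
    if (select_lv(tab, 5, folds = 10, seed = seed) == 1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("PDF calibration: symmetric case, numeric-root oracle, 0.5 at cutoff", {
  pdf <- calibrate_pdf(c(0.8, 1.2, -0.8, -1.2),
                       c("healthy", "healthy", "bruised", "bruised"))
  expect_equal(pdf$mu_h, 1); expect_equal(pdf$mu_b, -1)
  expect_equal(pdf$cutoff, 0, tolerance = 1e-12)

  # unequal sds: compare against a numeric root-finder oracle
  g <- gaussian_class_pdf(1, 1, -1, 2)
  oracle <- uniroot(function(y) dnorm(y, 1, 1) - dnorm(y, -1, 2),
                    c(-1, 1), tol = 1e-14)$root
  expect_equal(g$cutoff, oracle, tolerance = 1e-9)
  expect_equal(pdf_posterior(g, g$cutoff), 0.5, tolerance = 1e-12)

  expect_error(calibrate_pdf(c(1, -1), c("healthy", "bruised")), ">= 2")
  expect_warning(calibrate_pdf(c(1, 1, -1, -1.0000001),
                               c("healthy", "healthy", "bruised", "bruised")),
                 "clamped")
})

test_that("posteriors normalize, respect the cutoff and are monotone", {
  tab <- separable_table(seed = 5, n = 40, p = 6, delta = 4)
  m <- fit_plsda(tab, 2)
  pdf <- calibrate_pdf(predict_scores(m, tab), tab$label)
  pr <- predict_proba(m, pdf, tab)
  expect_equal(pr$p_healthy + pr$p_bruised, rep(1, 40), tolerance = 1e-15)
  expect_identical(pr$label,
                   ifelse(pr$score > pdf$cutoff, "healthy", "bruised"))
  # equal-sd symmetric pdf: tie at the cutoff goes to bruised
  g <- gaussian_class_pdf(1, 1, -1, 1)
  out <- hsifuse:::proba_from_scores(0, g, "x")
  expect_equal(out$p_healthy, 0.5)
  expect_identical(out$label, "bruised")
  # monotone in y between the class means
  ys <- seq(-1, 1, length.out = 50)
  expect_true(all(diff(pdf_posterior(g, ys)) > 0))
})

test_that("cross-validated performance: separable data and permutation null", {
  spec <- classifier_spec("plsda", n_lv = 2, folds = 5)
  tab <- separable_table(seed = 6, n = 60, p = 6, delta = 6)
  perf <- crossval_perf(spec, tab, folds = 5, seed = 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_identical(perf$alpha_h, perf$specificity)
  expect_identical(perf$alpha_b, perf$sensitivity)

  set.seed(99)
  n <- 200
  null_tab <- spectrum_table(matrix(rnorm(n * 6), n),
                             seq(500, 900, length.out = 6),
                             sprintf("s%03d", 1:n),
                             sample(rep(c("healthy", "bruised"), n / 2)))
  perf0 <- crossval_perf(spec, null_tab, folds = 5, seed = 2)
  # binomial 99.9% band around chance at n=200
  expect_lt(abs(perf0$accuracy - 0.5), 3.3 * sqrt(0.25 / n))
})

test_that("RBF classifier separates blobs and is deterministic", {
  tab <- separable_table(seed = 7, n = 50, p = 4, delta = 5)
  clf <- rbf_classifier(tab, c_grid = c(1, 10), g_grid = c(0.01, 0.1),
                        folds = 5, seed = 3)
  expect_gte(clf$cv_accuracy, 0.95)
  pr <- clf_predict(clf, tab)
  expect_gte(mean(pr$label == tab$label), 0.95)
  expect_equal(pr$p_healthy + pr$p_bruised, rep(1, 50), tolerance = 1e-12)
  # one-point grid returns that point
  clf1 <- rbf_classifier(tab, c_grid = 2, g_grid = 0.05, folds = 5)
  expect_equal(c(clf1$c, clf1$g), c(2, 0.05))
  # same seed, same choice
  clf2 <- rbf_classifier(tab, c_grid = c(1, 10), g_grid = c(0.01, 0.1),
                         folds = 5, seed = 3)
  expect_equal(c(clf$c, clf$g), c(clf2$c, clf2$g))
  expect_error(rbf_classifier(tab, c_grid = numeric(0)), "empty")
})

test_that("parameter recovery: strong effect gives >= 0.95 CV accuracy", {
  d <- tiny_spectra(seed = 21, n = 120, bands = 30,
                    effect_size = 0.2, noise_sd_pb = 0.005,
                    noise_sd_lctf = 0.005, calyx_fraction = 0,
                    bio_sd = 0.01, scatter_sd = 0.02)
  perf <- crossval_perf(classifier_spec("plsda", n_lv = 5, folds = 10),
                        d$pb, folds = 10, seed = 5)
  expect_gte(perf$accuracy, 0.95)
})

test_that("classifier JSON round trip reproduces predictions exactly", {
  tab <- separable_table(seed = 11, n = 40, p = 6, delta = 3)
  clf <- clf_fit(classifier_spec("plsda", n_lv = 2, folds = 5), tab)
  path <- file.path(tempdir(), "clf.json")
  write_classifier_json(clf, path)
  back <- read_classifier_json(path)
  p1 <- clf_predict(clf, tab); p2 <- clf_predict(back, tab)
  expect_equal(p2$p_healthy, p1$p_healthy, tolerance = 1e-12)
  expect_identical(p2$label, p1$label)
  writeLines('{"format":"other"}', path)
  expect_error(read_classifier_json(path), "format")
})
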