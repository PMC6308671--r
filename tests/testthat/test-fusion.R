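# Data-, feature- and decision-level fusion.

test_that("data-level fusion autoscales and concatenates 102 + 139 = 241", {
  d <- generate_mean_spectra(synth_config(n_healthy = 6, n_bruised = 6,
                                          seed = 4))
  fused <- fuse_data_level(d$pb, d$lctf)
  expect_equal(ncol(fused$values), 241)
  expect_lt(max(abs(colMeans(fused$values))), 1e-10)
  expect_equal(unname(apply(fused$values, 2, sd)), rep(1, 241),
               tolerance = 1e-10)
  expect_identical(fused$instrument[c(1, 241)], c("PB", "LCTF"))
  expect_match(colnames(fused$values)[1], "^PB:")
  expect_match(colnames(fused$values)[241], "^LCTF:")
})

test_that("data-level fusion rejects misalignment and same-instrument input", {
  d <- tiny_spectra(seed = 4, n = 8, bands = 6)
  shuffled <- d$lctf
  perm <- c(2:8, 1)
  shuffled$values <- shuffled$values[perm, ]
  shuffled$sample_id <- shuffled$sample_id[perm]
  expect_error(fuse_data_level(d$pb, shuffled), "sample ids")
  expect_error(fuse_data_level(d$pb, d$pb), "distinct instruments")
})

test_that("prediction tables are scaled with the training scalers", {
  d <- tiny_spectra(seed = 5, n = 20, bands = 8)
  p <- tiny_spectra(seed = 6, n = 10, bands = 8)
  ftr <- fuse_data_level(d$pb, d$lctf)
  fte <- fuse_data_level(p$pb, p$lctf, scalers = attr(ftr, "scalers"))
  # applying training stats to new data: means not exactly 0
  expect_gt(max(abs(colMeans(fte$values))), 1e-6)
  sc <- attr(ftr, "scalers")[[1]]
  expect_equal(unname(fte$values[1, 1]),
               unname((p$pb$values[1, 1] - sc$mean[1]) / sc$sd[1]))
})

test_that("feature-level separate fusion: 17 + 17 = 34, dedup, empty error", {
  d <- tiny_spectra(seed = 7, n = 12, bands = 40)
  fused <- fuse_feature_separate(1:17, 21:37, d$pb, d$lctf)
  expect_equal(ncol(fused$values), 34)
  dedup <- fuse_feature_separate(c(1, 1, 2), c(3, 4), d$pb, d$lctf)
  expect_equal(ncol(dedup$values), 4)
  expect_error(fuse_feature_separate(integer(0), 1:3, d$pb, d$lctf),
               "empty")
})

test_that("feature-level joint fusion selects from both namespaces", {
  s <- sparse_tables(60, n = 120, p = 15, k = 4, delta = 1.5)
  fused <- fuse_data_level(s$pb, s$lctf)
  fj <- fuse_feature_joint(fused, n_iter = 120, seed = 2, folds = 5,
                           max_n = 10)
  ins <- fj$table$instrument
  expect_true(all(c("PB", "LCTF") %in% ins))
  # most chosen bands should be informative ones
  chosen <- fj$selection$subset
  info <- c(s$info_pb, s$info_lctf + 15)
  expect_gte(mean(chosen %in% info), 0.5)
  # max_n = 1 -> a single fused band
  fj1 <- fuse_feature_joint(fused, n_iter = 40, seed = 2, folds = 5,
                            max_n = 1)
  expect_equal(ncol(fj1$table$values), 1)
})

test_that("weighted-majority-vote weights follow the class accuracies", {
  pA <- classifier_performance(sensitivity = 0.8, specificity = 0.9)
  pB <- classifier_performance(sensitivity = 0.8, specificity = 0.6)
  w <- wmv_weights(pA, pB)
  expect_equal(unname(w$w_h), c(0.6, 0.4))
  expect_equal(unname(w$w_b), c(0.5, 0.5))
  expect_equal(sum(w$w_h), 1); expect_equal(sum(w$w_b), 1)
  sym <- wmv_weights(pA, pA)
  expect_equal(unname(sym$w_h), c(0.5, 0.5))
  z <- classifier_performance(0, 0)
  expect_error(wmv_weights(z, z), "zero accuracy")
})

prob_row <- function(id, p_h) {
  out <- data.frame(sample_id = id, p_healthy = p_h, p_bruised = 1 - p_h,
                    score = p_h, label = ifelse(p_h > 0.5, "healthy",
                                                "bruised"),
                    stringsAsFactors = FALSE)
  class(out) <- c("prob_output", class(out))
  out
}

test_that("weighted majority vote matches hand arithmetic", {
  w <- structure(list(w_h = c(A = 0.6, B = 0.4), w_b = c(A = 0.5, B = 0.5)),
                 class = "fusion_weights")
  res <- weighted_majority_vote(w, prob_row("x", 0.9), prob_row("x", 0.2))
  expect_equal(res$score_h, 0.6 * 0.9 + 0.4 * 0.2)  # 0.62
  expect_equal(res$score_b, 0.5 * 0.1 + 0.5 * 0.8)  # 0.45
  expect_identical(res$label, "healthy")

  sure <- weighted_majority_vote(w, prob_row("x", 1), prob_row("x", 1))
  expect_equal(sure$score_h, 1); expect_equal(sure$score_b, 0)
  expect_identical(sure$label, "healthy")

  # equal weights and complementary probabilities: tie -> bruised
  weq <- structure(list(w_h = c(A = 0.5, B = 0.5),
                        w_b = c(A = 0.5, B = 0.5)),
                   class = "fusion_weights")
  tie <- weighted_majority_vote(weq, prob_row("x", 0.7), prob_row("x", 0.3))
  expect_equal(tie$score_h, tie$score_b)
  expect_identical(tie$label, "bruised")

  bad <- prob_row("x", 0.9); bad$p_bruised <- 0.3
  expect_error(weighted_majority_vote(w, bad, prob_row("x", 0.2)),
               "sum to 1")
})

test_that("Bayesian fusion: certainty, uninformative sensors, enumeration oracle", {
  one <- classifier_performance(1, 1)
  res <- bayes_fuse(one, one, prob_row("x", 1), prob_row("x", 1))
  expect_equal(res$score_h, 1)
  expect_identical(res$label, "healthy")

  half <- classifier_performance(0.5, 0.5)
  res2 <- bayes_fuse(half, half, prob_row("x", 0.83), prob_row("x", 0.21))
  expect_equal(res2$score_h, 0.5, tolerance = 1e-12)

  # brute-force 4-term enumeration for the quoted parameter set
  pa <- classifier_performance(0.86, 0.90)
  pb <- classifier_performance(0.88, 0.89)
  res3 <- bayes_fuse(pa, pb, prob_row("x", 0.7), prob_row("x", 0.4))
  enum <- function(spec1, sens1, spec2, sens2, pa_h, pb_h, state) {
    pd <- function(dec, st, spc, sns) {
      if (st == "h") { if (dec == "h") spc else 1 - spc }
      else { if (dec == "b") sns else 1 - sns }
    }
    tot <- 0
    for (d1 in c("h", "b")) for (d2 in c("h", "b")) {
      tot <- tot + pd(d1, state, spec1, sens1) *
        (if (d1 == "h") pa_h else 1 - pa_h) *
        pd(d2, state, spec2, sens2) *
        (if (d2 == "h") pb_h else 1 - pb_h)
    }
    tot
  }
  lh <- enum(0.90, 0.86, 0.89, 0.88, 0.7, 0.4, "h")
  lb <- enum(0.90, 0.86, 0.89, 0.88, 0.7, 0.4, "b")
  expect_equal(res3$score_h, lh / (lh + lb), tolerance = 1e-12)
})

test_that("fuzzy templates average class profiles and score similarity", {
  dp <- array(0, c(3, 2, 2),
              dimnames = list(c("a", "b", "c"), c("A", "B"),
                              c("healthy", "bruised")))
  dp[1, , ] <- c(0.9, 0.8, 0.1, 0.2)   # healthy sample P
  dp[2, , ] <- c(0.7, 0.6, 0.3, 0.4)   # healthy sample Q
  dp[3, , ] <- c(0.1, 0.2, 0.9, 0.8)   # bruised sample
  ft <- fuzzy_template_fit(dp, c("healthy", "healthy", "bruised"))
  expect_equal(ft$healthy, (dp[1, , ] + dp[2, , ]) / 2)
  expect_equal(ft$bruised, dp[3, , ])  # single sample: template equals it
  expect_error(fuzzy_template_fit(dp[1:2, , , drop = FALSE],
                                  c("healthy", "healthy")), "bruised")

  # exact template match scores 1
  res <- fuzzy_template_predict(ft, dp[3, , , drop = FALSE])
  expect_equal(res$score_b, 1)
  expect_identical(res$label, "bruised")

  # all-ones vs all-zeros: similarity 0
  ft0 <- structure(list(healthy = matrix(1, 2, 2),
                        bruised = matrix(0.5, 2, 2)),
                   class = "fuzzy_templates")
  dp0 <- array(0, c(1, 2, 2))
  expect_equal(fuzzy_template_predict(ft0, dp0)$score_h, 0)

  # hand arithmetic: mu_h = 1 - (1/4) * 4 * 0.04 = 0.96
  fth <- structure(list(healthy = matrix(c(0.9, 0.8, 0.1, 0.2), 2),
                        bruised = matrix(c(0.1, 0.2, 0.9, 0.8), 2)),
                   class = "fuzzy_templates")
  dph <- array(c(0.7, 0.6, 0.3, 0.4), c(1, 2, 2))
  expect_equal(fuzzy_template_predict(fth, dph)$score_h, 0.96)

  expect_error(fuzzy_template_predict(ft, array(0, c(1, 3, 2))),
               "shape")
})

test_that("decision profiles stack the two outputs row-normalized", {
  pA <- random_prob_output(5, 1); pB <- random_prob_output(5, 2)
  dp <- decision_profiles(pA, pB)
  expect_equal(dim(dp), c(5, 2, 2))
  expect_equal(unname(dp[, "A", "healthy"] + dp[, "A", "bruised"]),
               rep(1, 5))
  expect_equal(dp[, "B", "bruised"], pB$p_bruised, ignore_attr = TRUE)
})

test_that("all rules honour unanimous base decisions under equal priors", {
  set.seed(77)
  for (rep in 1:20) {
    p_h <- runif(1)
    agree_h <- p_h > 0.5
    # both classifiers share the hard label, equal performances
    pA <- prob_row("x", p_h)
    pB <- prob_row("x", if (agree_h) runif(1, 0.55, 1) else runif(1, 0, 0.45))
    perf <- classifier_performance(0.85, 0.85)
    expected <- if (agree_h) "healthy" else "bruised"
    expect_identical(weighted_majority_vote(wmv_weights(perf, perf),
                                            pA, pB)$label, expected)
    expect_identical(bayes_fuse(perf, perf, pA, pB)$label, expected)
    # fuzzy: templates from clean unanimous training profiles
    dp_tr <- array(c(0.9, 0.1, 0.9, 0.1, 0.1, 0.9, 0.1, 0.9), c(2, 2, 2))
    ft <- fuzzy_template_fit(dp_tr, c("healthy", "bruised"))
    expect_identical(fuzzy_template_predict(ft, decision_profiles(pA, pB))$label,
                     expected)
  }
})

test_that("fuzzy soft labels stay within [0, 1] for random profiles", {
  set.seed(13)
  dp_tr <- decision_profiles(random_prob_output(30, 4),
                             random_prob_output(30, 5))
  ft <- fuzzy_template_fit(dp_tr, sample(rep(c("healthy", "bruised"), 15)))
  dp_te <- decision_profiles(random_prob_output(50, 6),
                             random_prob_output(50, 7))
  res <- fuzzy_template_predict(ft, dp_te)
  expect_true(all(res$score_h >= 0 & res$score_h <= 1))
  expect_true(all(res$score_b >= 0 & res$score_b <= 1))
})

test_that("bayes posteriors always normalize", {
  set.seed(14)
  pA <- random_prob_output(40, 8); pB <- random_prob_output(40, 9)
  perfA <- classifier_performance(runif(1, 0.6, 1), runif(1, 0.6, 1))
  perfB <- classifier_performance(runif(1, 0.6, 1), runif(1, 0.6, 1))
  res <- bayes_fuse(perfA, perfB, pA, pB)
  expect_equal(res$score_h + res$score_b, rep(1, 40), tolerance = 1e-12)
})
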