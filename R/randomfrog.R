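# Random frog wavelength selection: an iterative stochastic subset
# search in the spirit of reversible-jump MCMC. A candidate subset is
# proposed by growing or shrinking the current one guided by PLS-DA
# coefficient magnitudes, and accepted with a probability driven by its
# cross-validated classification accuracy. The per-wavelength selection
# probability is the fraction of iterations whose retained subset
# contains that wavelength.

# sample() without the scalar-x surprise
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

# column scale helpers on bare matrices (hot path: no container overhead)
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  pmax(sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1)), SD_FLOOR)
}

# CV accuracy of a PLS-DA model restricted to `subset` (column indices).
# `train$values` is expected to be autoscaled already (done once per
# selection run; fold models are centred inside SIMPLS, so only the
# scale statistics are shared across folds).
frog_cv_accuracy <- function(train, subset, folds, seed) {
  X <- train$values[, sort(subset), drop = FALSE]
  labels <- train$label
  y <- label_to_code(labels)
  fold <- stratified_folds(labels, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    n_lv <- max(1L, min(10L, ncol(X), nrow(Xtr) - 2L))
    path <- simpls(Xtr, y[tr], n_lv)
    b <- path$coef[, ncol(path$coef)]
    icpt <- path$y_mean - sum(path$x_mean * b)
    sc_tr <- drop(Xtr %*% b) + icpt
    pdf <- suppressWarnings(calibrate_pdf(sc_tr, labels[tr]))
    pred_h <- drop(X[!tr, , drop = FALSE] %*% b) + icpt > pdf$cutoff
    correct <- correct + sum(pred_h == (labels[!tr] == "healthy"))
  }
  correct / length(y)
}

# CV misclassification error of a PLS-DA model on `subset` (prescaled
# table), with the latent-variable count chosen by the same CV: the
# coefficient path gives every LV's out-of-fold error at no extra cost,
# and the best LV's pooled error is returned. Keeps small and large
# subsets comparable (no forced near-full-rank fits on small subsets).
subset_cv_error <- function(train, subset, folds, seed) {
  X <- train$values[, sort(subset), drop = FALSE]
  labels <- train$label
  y <- label_to_code(labels)
  fold <- stratified_folds(labels, folds, seed)
  lv_max <- max(1L, min(10L, ncol(X)))
  wrong <- numeric(lv_max)
  for (f in seq_len(folds)) {
    tr <- fold != f
    path <- simpls(X[tr, , drop = FALSE], y[tr], lv_max)
    for (lv in seq_len(path$ncomp)) {
      b <- path$coef[, lv]
      icpt <- path$y_mean - sum(path$x_mean * b)
      sc_tr <- drop(X[tr, , drop = FALSE] %*% b) + icpt
      pdf <- suppressWarnings(calibrate_pdf(sc_tr, labels[tr]))
      pred_h <- drop(X[!tr, , drop = FALSE] %*% b) + icpt > pdf$cutoff
      wrong[lv] <- wrong[lv] + sum(pred_h != (labels[!tr] == "healthy"))
    }
    if (path$ncomp < lv_max) {
      wrong[(path$ncomp + 1L):lv_max] <- Inf
    }
  }
  min(wrong) / length(y)
}

# autoscale a table's matrix once, in place, for a selection run
prescale_table <- function(train) {
  mu <- colMeans(train$values)
  sdv <- col_sds(train$values)
  train$values <- sweep(sweep(train$values, 2, mu), 2, sdv, "/")
  train
}

# |coefficient| of a PLS-DA fit on the given (prescaled) columns, named
# by column index; magnitudes comparable across wavelengths.
frog_coef_weight <- function(train, cols) {
  cols <- sort(unique(cols))
  X <- train$values[, cols, drop = FALSE]
  n_lv <- max(1L, min(10L, ncol(X), nrow(X) - 2L))
  path <- simpls(X, label_to_code(train$label), n_lv)
  w <- abs(path$coef[, ncol(path$coef)])
  names(w) <- as.character(cols)
  w
}

#' Random-frog selection probabilities
#'
#' Runs `n_iter` iterations of the random-frog chain on a labeled
#' spectrum table and returns the per-wavelength selection probability
#' (fraction of iterations whose retained subset contains the
#' wavelength). Candidate subsets are proposed by resizing the current
#' subset to `round(N(Q, 0.3 Q))` clamped to `[1, p]`: shrinking drops
#' the lowest-|coefficient| members, growing adds outside wavelengths
#' drawn with probability proportional to their |coefficient| in a model
#' fit on the union of the subset and a random candidate pool (3x the
#' needed count). Candidate and current subset are scored by k-fold CV
#' accuracy under a fresh fold split each iteration (a paired
#' comparison); the candidate replaces the current subset with
#' probability 1 if `a_new >= a_cur`, else `eta * a_new / a_cur`.
#'
#' @param train labeled [spectrum_table()].
#' @param n_iter number of iterations (>= 1; default 1000).
#' @param q0 initial subset size (default `max(2, round(p / 10))`).
#' @param seed chain seed.
#' @param folds CV folds for the acceptance performance (default 10).
#' @param eta acceptance damping when the candidate is worse (default 0.1).
#' @param burn_in iterations discarded before counting membership
#'   (default 0: all iterations count).
#' @return a `frog_probs` object: numeric `probability` per wavelength,
#'   `counts`, `n_iter_used`, and the table's band names.
#' @export
random_frog <- function(train, n_iter = 1000, q0 = NULL, seed = 1,
                        folds = 10, eta = 0.1, burn_in = 0) {
  stopifnot(inherits(train, "spectrum_table"))
  if (is.null(train$label)) stop("random_frog: labeled table required")
  if (n_iter < 1L) stop("random_frog: n_iter must be >= 1")
  p <- ncol(train$values)
  q0 <- q0 %||% min(p, max(2L, round(p / 10)))
  if (q0 < 1L || q0 > p) stop("random_frog: q0 out of [1, p]")
  stopifnot(burn_in >= 0, burn_in < n_iter)

  train <- prescale_table(train)
  set.seed(derive_seed(seed, 11L))
  counts <- numeric(p)
  if (p == 1L) {
    return(structure(list(probability = stats::setNames(1, colnames(train$values)),
                          counts = stats::setNames(n_iter, colnames(train$values)),
                          n_iter_used = n_iter,
                          bands = colnames(train$values)),
                     class = "frog_probs"))
  }

  subset <- sort(sample.int(p, q0))
  for (it in seq_len(n_iter)) {
    Q <- length(subset)
    q_new <- round(stats::rnorm(1, Q, 0.3 * Q))
    q_new <- max(1L, min(p, q_new))
    cand <- subset
    if (q_new < Q) {
      w <- frog_coef_weight(train, subset)  # ordered like sort(subset)
      cand <- subset[order(w, decreasing = TRUE)[seq_len(q_new)]]
    } else if (q_new > Q) {
      outside <- setdiff(seq_len(p), subset)
      need <- q_new - Q
      pool_n <- min(length(outside), 3L * need)
      pool <- resample(outside, pool_n)
      w <- frog_coef_weight(train, c(subset, pool))
      w_pool <- w[as.character(pool)] + 1e-12
      add <- if (need >= pool_n) pool else
        resample(pool, need, prob = w_pool)
      cand <- c(subset, add)
    }
    cand <- sort(cand)
    if (!identical(cand, subset)) {
      # fresh CV split per iteration, shared by both subsets: a paired
      # comparison that keeps the chain mixing on uninformative data
      it_seed <- derive_seed(seed, 12L + it)
      perf_new <- frog_cv_accuracy(train, cand, folds, it_seed)
      perf_cur <- frog_cv_accuracy(train, subset, folds, it_seed)
      accept <- perf_new >= perf_cur ||
        stats::runif(1) < eta * perf_new / max(perf_cur, 1e-12)
      if (accept) subset <- cand
    }
    if (it > burn_in) counts[subset] <- counts[subset] + 1
  }
  used <- n_iter - burn_in
  probability <- counts / used
  names(probability) <- names(counts) <- colnames(train$values)
  structure(list(probability = probability, counts = counts,
                 n_iter_used = used, bands = colnames(train$values)),
            class = "frog_probs")
}

#' Size the selected subset by a CV-error curve
#'
#' Ranks wavelengths by descending selection probability and fits PLS-DA
#' on the top-1, top-2, ..., top-`min(max_n, p)` subsets, computing the
#' k-fold CV misclassification error of each. Returns the subset at the
#' curve minimum; ties break to the smallest subset.
#'
#' @param probabilities a `frog_probs` object (or named numeric vector of
#'   selection probabilities matching the table's columns).
#' @param train the labeled [spectrum_table()] the probabilities refer to.
#' @param max_n largest subset size to evaluate (default 80).
#' @param folds,seed cross-validation controls.
#' @param repeats number of repeated CV fold splits averaged per subset
#'   size (default 3); the latent-variable count of each subset model is
#'   itself chosen by the same CV.
#' @return a `selection_result`: `probability`, `ranking` (column
#'   indices, descending importance), `subset` (chosen column indices),
#'   `wavelengths` (chosen bands, nm), `bands` (chosen band names),
#'   `cv_error` curve, `k` chosen size.
#' @export
choose_n_features <- function(probabilities, train, max_n = 80,
                              folds = 10, seed = 1, repeats = 3) {
  stopifnot(inherits(train, "spectrum_table"), max_n >= 1L)
  if (nrow(train$values) < folds) stop("choose_n_features: fewer samples than folds")
  prob <- if (inherits(probabilities, "frog_probs")) {
    probabilities$probability
  } else probabilities
  p <- ncol(train$values)
  stopifnot(length(prob) == p)
  ranking <- order(prob, decreasing = TRUE)  # ties -> lower wavelength first
  train <- prescale_table(train)
  k_max <- min(max_n, p)
  cv_err <- numeric(k_max)
  for (k in seq_len(k_max)) {
    errs <- vapply(seq_len(repeats), function(r) {
      subset_cv_error(train, ranking[seq_len(k)], folds,
                      derive_seed(seed, 13L + r))
    }, numeric(1))
    cv_err[k] <- mean(errs)
  }
  k_best <- which.min(cv_err)  # ties -> smallest k
  subset <- sort(ranking[seq_len(k_best)])
  structure(list(probability = prob, ranking = ranking, subset = subset,
                 wavelengths = train$wavelengths[subset],
                 bands = colnames(train$values)[subset],
                 cv_error = cv_err, k = k_best),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d wavelengths selected\n",
              x$k, length(x$probability)))
  cat("  following", x$k, "wavelengths:",
      paste(formatC(x$wavelengths, format = "f", digits = 1),
            collapse = ", "), "nm\n")
  invisible(x)
}

#' Write a selection result as CSV
#'
#' Writes `<path>_selection.csv` (band, wavelength, probability, rank,
#' chosen) and `<path>_cv_curve.csv` (n_features, cv_error).
#'
#' @param sel a `selection_result`.
#' @param train the table it was computed on.
#' @param path output path stem.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(sel, train, path) {
  stopifnot(inherits(sel, "selection_result"))
  rank_of <- match(seq_along(sel$probability), sel$ranking)
  utils::write.csv(
    data.frame(band = colnames(train$values),
               wavelength = train$wavelengths,
               probability = sel$probability,
               rank = rank_of,
               chosen = seq_along(sel$probability) %in% sel$subset),
    paste0(path, "_selection.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(n_features = seq_along(sel$cv_error),
               cv_error = sel$cv_error),
    paste0(path, "_cv_curve.csv"), row.names = FALSE)
  invisible(path)
}
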