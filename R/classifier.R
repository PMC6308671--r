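# A uniform probabilistic-classifier contract: every classifier is
# described by a classifier_spec, fitted with clf_fit() and produces a
# prob_output via clf_predict(). PLS-DA is the reference implementation;
# an RBF kernel machine fills the non-linear slot.

#' Describe a probabilistic classifier
#'
#' @param type `"plsda"` or `"rbf"`.
#' @param n_lv for PLS-DA: latent-variable count, or `"auto"` to choose by
#'   10-fold cross-validation.
#' @param c_grid,g_grid for RBF: penalty / kernel-width grids for the CV
#'   grid search (defaults `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`).
#' @param folds,seed cross-validation folds and seed used by `"auto"`
#'   selection and grid search.
#' @param autoscale standardize columns before fitting (default `TRUE`).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(type = c("plsda", "rbf"), n_lv = "auto",
                            c_grid = 2^seq(-5, 15, 2),
                            g_grid = 2^seq(-15, 3, 2),
                            folds = 10, seed = 1, autoscale = TRUE) {
  type <- match.arg(type)
  structure(list(type = type, n_lv = n_lv, c_grid = c_grid, g_grid = g_grid,
                 folds = folds, seed = seed, autoscale = autoscale),
            class = "classifier_spec")
}

#' Fit a classifier from its spec
#'
#' @param spec a [classifier_spec()].
#' @param train a labeled [spectrum_table()].
#' @return a fitted classifier (with Gaussian-PDF probability
#'   calibration attached).
#' @export
clf_fit <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$type == "plsda") {
    n_lv <- spec$n_lv
    if (identical(n_lv, "auto")) {
      n_lv <- select_lv(train,
                        max_lv = min(10L, nrow(train$values) - 1L,
                                     ncol(train$values)),
                        folds = spec$folds, seed = spec$seed,
                        autoscale = spec$autoscale)
    }
    model <- fit_plsda(train, n_lv, autoscale = spec$autoscale)
    pdf <- calibrate_pdf(predict_scores(model, train), train$label)
    structure(list(spec = spec, model = model, pdf = pdf),
              class = "plsda_classifier")
  } else {
    rbf_classifier(train, c_grid = spec$c_grid, g_grid = spec$g_grid,
                   folds = spec$folds, seed = spec$seed,
                   autoscale = spec$autoscale)
  }
}

#' Predict class probabilities with a fitted classifier
#'
#' @param clf a fitted classifier from [clf_fit()].
#' @param table a [spectrum_table()].
#' @return a `prob_output` data frame.
#' @export
clf_predict <- function(clf, table) UseMethod("clf_predict")

#' @export
clf_predict.plsda_classifier <- function(clf, table) {
  predict_proba(clf$model, clf$pdf, table)
}

#' @export
clf_predict.rbf_classifier <- function(clf, table) {
  stopifnot(identical(colnames(table$values), clf$bands))
  X <- table$values
  if (!is.null(clf$scaler)) X <- apply_scaler(clf$scaler, table)$values
  K <- rbf_kernel(X, clf$X_train, clf$g)
  y <- drop(K %*% clf$alpha) + clf$intercept
  proba_from_scores(y, clf$pdf, table$sample_id)
}

rbf_kernel <- function(A, B, g) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-g * pmax(d2, 0))
}

# Kernel ridge on +/-1 codes for one (c, g); lambda = 1/c so larger
# penalty parameter c means a harder fit, as in the usual SVM convention.
krr_fit <- function(X, y, c_pen, g) {
  K <- rbf_kernel(X, X, g)
  alpha <- solve(K + diag(1 / c_pen, nrow(X)), y - mean(y))
  list(alpha = alpha, intercept = mean(y), g = g)
}

#' RBF kernel classifier with grid-searched hyperparameters
#'
#' Fills the non-linear classifier slot of the pipeline with a radial
#' basis function kernel machine: kernel ridge regression on the +1/-1
#' class codes (penalty `c`, kernel width `g`), calibrated to
#' probabilities with the same Gaussian class-density scheme as PLS-DA.
#' `(c, g)` are chosen by stratified k-fold cross-validation accuracy
#' over the grid; ties break to smaller `c`, then smaller `g`.
#'
#' @param train labeled [spectrum_table()].
#' @param c_grid,g_grid positive penalty and kernel-width candidates
#'   (non-empty).
#' @param folds,seed cross-validation controls.
#' @param autoscale standardize columns first (default `TRUE`).
#' @return an `rbf_classifier`.
#' @export
rbf_classifier <- function(train, c_grid = 2^seq(-5, 15, 2),
                           g_grid = 2^seq(-15, 3, 2),
                           folds = 10, seed = 1, autoscale = TRUE) {
  stopifnot(inherits(train, "spectrum_table"))
  if (length(c_grid) == 0L || length(g_grid) == 0L) {
    stop("rbf_classifier: empty hyperparameter grid")
  }
  stopifnot(all(c_grid > 0), all(g_grid > 0))
  if (is.null(train$label)) stop("rbf_classifier: labeled training set required")
  scaler <- NULL
  Xfull <- train$values
  if (autoscale) {
    scaler <- suppressWarnings(fit_scaler(train))
    Xfull <- apply_scaler(scaler, train)$values
  }
  y <- label_to_code(train$label)
  grid <- expand.grid(g = sort(g_grid), c = sort(c_grid))[, c("c", "g")]
  grid <- grid[order(grid$c, grid$g), ]
  best <- NULL; best_acc <- -Inf
  fold <- stratified_folds(train$label, folds, seed)
  for (i in seq_len(nrow(grid))) {
    cp <- grid$c[i]; g <- grid$g[i]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- krr_fit(Xfull[tr, , drop = FALSE], y[tr], cp, g)
      K <- rbf_kernel(Xfull[!tr, , drop = FALSE], Xfull[tr, , drop = FALSE], g)
      pred <- drop(K %*% fit$alpha) + fit$intercept
      correct <- correct + sum((pred > 0) == (y[!tr] > 0))
    }
    acc <- correct / length(y)
    if (acc > best_acc) { best_acc <- acc; best <- c(cp, g) }
    # ties keep the earlier (smaller c, then smaller g) candidate
  }
  fit <- krr_fit(Xfull, y, best[1], best[2])
  scores <- drop(rbf_kernel(Xfull, Xfull, best[2]) %*% fit$alpha) + fit$intercept
  pdf <- calibrate_pdf(scores, train$label)
  structure(list(X_train = Xfull, alpha = fit$alpha,
                 intercept = fit$intercept, c = best[1], g = best[2],
                 cv_accuracy = best_acc, scaler = scaler, pdf = pdf,
                 bands = colnames(train$values)),
            class = "rbf_classifier")
}

#' Cross-validated class-conditional performance
#'
#' Pools out-of-fold predictions from a stratified k-fold
#' cross-validation of `spec` on `train` and reports sensitivity (bruised
#' recall), specificity (healthy recall), per-class accuracies
#' (`alpha_h` = specificity, `alpha_b` = sensitivity) and overall
#' accuracy. These cross-validation rates are the classifier-behaviour
#' priors consumed by the decision-level fusion rules.
#'
#' @param spec a [classifier_spec()].
#' @param train labeled [spectrum_table()].
#' @param folds,seed cross-validation controls.
#' @return a `classifier_performance` list.
#' @export
crossval_perf <- function(spec, train, folds = 10, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  n <- nrow(train$values)
  if (n < folds) stop("crossval_perf: fewer samples than folds")
  fold <- stratified_folds(train$label, folds, seed)
  pred <- character(n)
  for (f in seq_len(folds)) {
    tr <- st_rows(train, fold != f)
    if (length(unique(tr$label)) < 2L) {
      stop("crossval_perf: a training fold lost one class entirely")
    }
    clf <- clf_fit(spec, tr)
    pred[fold == f] <- clf_predict(clf, st_rows(train, fold == f))$label
  }
  rep <- score_predictions(pred, train$label)
  structure(list(sensitivity = rep$sensitivity,
                 specificity = rep$specificity,
                 accuracy = rep$accuracy,
                 alpha_h = rep$specificity, alpha_b = rep$sensitivity,
                 folds = folds, seed = seed),
            class = "classifier_performance")
}

#' Construct a classifier performance object directly
#'
#' Mainly for tests and for feeding externally measured sensitivities /
#' specificities into the decision-fusion rules.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return a `classifier_performance`.
#' @export
classifier_performance <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 accuracy = NA_real_, alpha_h = specificity,
                 alpha_b = sensitivity, folds = NA, seed = NA),
            class = "classifier_performance")
}

#' Serialize / restore a fitted PLS-DA classifier as versioned JSON
#'
#' Writes coefficients, intercept, scaler statistics, Gaussian-PDF
#' parameters and band names to a JSON document (format version 1);
#' `read_classifier_json` reconstructs a classifier whose predictions
#' are identical to the original's.
#'
#' @param clf a fitted `plsda_classifier` from [clf_fit()].
#' @param path JSON file path.
#' @return `write_classifier_json`: `path`, invisibly;
#'   `read_classifier_json`: a `plsda_classifier`.
#' @export
write_classifier_json <- function(clf, path) {
  stopifnot(inherits(clf, "plsda_classifier"))
  doc <- list(
    format = "hsifuse-classifier", version = 1L, type = "plsda",
    n_lv = clf$model$n_lv,
    coef = unname(clf$model$coef), intercept = clf$model$intercept,
    bands = clf$model$bands,
    scaler = if (!is.null(clf$model$scaler)) {
      list(mean = unname(clf$model$scaler$mean),
           sd = unname(clf$model$scaler$sd))
    },
    pdf = list(mu_h = clf$pdf$mu_h, sd_h = clf$pdf$sd_h,
               mu_b = clf$pdf$mu_b, sd_b = clf$pdf$sd_b),
    seed = clf$spec$seed, folds = clf$spec$folds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hsifuse-classifier") || doc$version != 1L) {
    stop("read_classifier_json: unrecognized document format/version")
  }
  scaler <- NULL
  if (!is.null(doc$scaler)) {
    scaler <- structure(list(mean = stats::setNames(doc$scaler$mean,
                                                    doc$bands),
                             sd = stats::setNames(doc$scaler$sd, doc$bands),
                             bands = doc$bands),
                        class = "scaler")
  }
  model <- structure(list(coef = doc$coef, intercept = doc$intercept,
                          n_lv = doc$n_lv, scaler = scaler,
                          bands = doc$bands),
                     class = "plsda_model")
  pdf <- gaussian_class_pdf(doc$pdf$mu_h, doc$pdf$sd_h,
                            doc$pdf$mu_b, doc$pdf$sd_b)
  structure(list(spec = classifier_spec("plsda", n_lv = doc$n_lv,
                                        folds = doc$folds %||% 10,
                                        seed = doc$seed %||% 1),
                 model = model, pdf = pdf),
            class = "plsda_classifier")
}
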