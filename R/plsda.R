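# Probability-calibrated PLS-DA. Class membership (healthy = +1,
# bruised = -1) is regressed on the spectra by SIMPLS partial least
# squares; the real-valued prediction y is turned into class
# probabilities by fitting one Gaussian density to the training scores of
# each class and applying Bayes' rule with equal priors. The cut-off y*
# is the point between the class means where the two densities are equal,
# i.e. where both posteriors are 0.5.

label_to_code <- function(label) ifelse(label == "healthy", 1, -1)

# SIMPLS for a single response (de Jong 1993). X and y are centred
# internally; returns coefficients on the original scale for each number
# of components 1..ncomp (matrix p x ncomp).
simpls <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  S <- crossprod(Xc, yc)                      # p x 1
  R <- matrix(0, p, ncomp); TT <- matrix(0, n, ncomp)
  V <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t * t))
    if (nt < 1e-10) break
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)                    # loadings
    v <- pv
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    nv <- sqrt(sum(v * v))
    if (nv < 1e-10) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; V[, a] <- v
    q[a] <- sum(t * yc)
    a_done <- a
  }
  if (a_done == 0L) stop("simpls: degenerate predictor matrix")
  coefs <- matrix(0, p, a_done)
  for (a in seq_len(a_done)) {
    coefs[, a] <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  }
  list(coef = coefs, x_mean = xm, y_mean = ym, ncomp = a_done)
}

#' Fit a PLS-DA model
#'
#' Regresses the +1/-1 class code on the (optionally autoscaled) spectra
#' with `n_lv` SIMPLS latent variables. The fit is deterministic and
#' invariant to row permutation.
#'
#' @param train a labeled [spectrum_table()].
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @param autoscale standardize columns with training statistics first
#'   (default `TRUE`).
#' @return a `plsda_model` with fields `coef`, `intercept`, `n_lv`,
#'   `scaler` (or `NULL`), `bands`.
#' @export
fit_plsda <- function(train, n_lv, autoscale = TRUE) {
  stopifnot(inherits(train, "spectrum_table"))
  if (is.null(train$label)) stop("fit_plsda: training table must be labeled")
  if (length(unique(train$label)) < 2L) {
    stop("fit_plsda: training set contains a single class")
  }
  n <- nrow(train$values); p <- ncol(train$values)
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop("fit_plsda: n_lv out of range [1, min(n-1, p)]")
  }
  scaler <- NULL
  X <- train$values
  if (autoscale) {
    scaler <- suppressWarnings(fit_scaler(train))
    X <- apply_scaler(scaler, train)$values
  }
  y <- label_to_code(train$label)
  fit <- simpls(X, y, n_lv)
  b <- fit$coef[, ncol(fit$coef)]
  structure(list(coef = b,
                 intercept = fit$y_mean - sum(fit$x_mean * b),
                 n_lv = fit$ncomp, scaler = scaler,
                 bands = colnames(train$values)),
            class = "plsda_model")
}

#' Predict PLS-DA scores
#'
#' @param model a `plsda_model`.
#' @param table a [spectrum_table()] on the model's band grid.
#' @return numeric vector of real-valued scores y (ideally near +1 for
#'   healthy, -1 for bruised).
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "plsda_model"), inherits(table, "spectrum_table"))
  if (!identical(colnames(table$values), model$bands)) {
    stop("predict_scores: wavelength grid does not match the model")
  }
  X <- table$values
  if (!is.null(model$scaler)) X <- apply_scaler(model$scaler, table)$values
  drop(X %*% model$coef) + model$intercept
}

#' Choose the number of latent variables by cross-validation
#'
#' Evaluates `1..max_lv` latent variables by stratified k-fold
#' cross-validation misclassification error (hard labels from the
#' Gaussian-PDF cut-off) and returns the count with minimum error; ties
#' break to the fewest latent variables.
#'
#' @param train labeled [spectrum_table()].
#' @param max_lv largest count to consider (>= 1).
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param autoscale passed to [fit_plsda()].
#' @return the selected latent-variable count.
#' @export
select_lv <- function(train, max_lv, folds = 10, seed = 1, autoscale = TRUE) {
  stopifnot(max_lv >= 1L)
  n <- nrow(train$values)
  if (n < folds) stop("select_lv: fewer samples than folds")
  fold <- stratified_folds(train$label, folds, seed)
  max_lv <- min(max_lv, ncol(train$values))
  err <- numeric(max_lv)
  for (f in seq_len(folds)) {
    tr <- st_rows(train, fold != f)
    te <- st_rows(train, fold == f)
    k_max <- min(max_lv, nrow(tr$values) - 1L)
    X <- tr$values; Xte <- te$values
    if (autoscale) {
      sc <- suppressWarnings(fit_scaler(tr))
      X <- apply_scaler(sc, tr)$values
      Xte <- apply_scaler(sc, te)$values
    }
    # one simpls call yields the whole coefficient path 1..k_max
    path <- simpls(X, label_to_code(tr$label), k_max)
    k_max <- path$ncomp
    fold_err <- numeric(k_max)
    for (k in seq_len(k_max)) {
      b <- path$coef[, k]
      icpt <- path$y_mean - sum(path$x_mean * b)
      pdf <- suppressWarnings(calibrate_pdf(drop(X %*% b) + icpt, tr$label))
      pred <- ifelse(drop(Xte %*% b) + icpt > pdf$cutoff,
                     "healthy", "bruised")
      fold_err[k] <- sum(pred != te$label)
    }
    err[seq_len(k_max)] <- err[seq_len(k_max)] + fold_err
    if (k_max < max_lv) {
      # sizes unreachable in this fold inherit the deepest model's error
      err[(k_max + 1L):max_lv] <- err[(k_max + 1L):max_lv] + fold_err[k_max]
    }
  }
  which.min(err)  # ties -> smallest
}

#' Fit the Gaussian class densities and cut-off
#'
#' Estimates one Gaussian per class from the training scores and locates
#' the cut-off y*: the intersection of the two densities lying between
#' the class means, where both posteriors (equal priors) are exactly 0.5.
#'
#' @param scores real-valued training scores.
#' @param labels matching labels (`"healthy"`/`"bruised"`, both present,
#'   each with >= 2 samples).
#' @param sd_floor lower clamp for the class sds (default `1e-6`).
#' @return a `gaussian_class_pdf` with `mu_h`, `sd_h`, `mu_b`, `sd_b`,
#'   `cutoff`.
#' @export
calibrate_pdf <- function(scores, labels, sd_floor = 1e-6) {
  stopifnot(length(scores) == length(labels))
  h <- scores[labels == "healthy"]; b <- scores[labels == "bruised"]
  if (length(h) < 2L || length(b) < 2L) {
    stop("calibrate_pdf: each class needs >= 2 samples")
  }
  mu_h <- mean(h); mu_b <- mean(b)
  sd_h <- stats::sd(h); sd_b <- stats::sd(b)
  if (sd_h < sd_floor || sd_b < sd_floor) {
    warning("calibrate_pdf: class sd clamped to floor")
    sd_h <- max(sd_h, sd_floor); sd_b <- max(sd_b, sd_floor)
  }
  gaussian_class_pdf(mu_h, sd_h, mu_b, sd_b)
}

#' Construct Gaussian class densities from known parameters
#'
#' Builds the two-class score-density object directly from means and
#' standard deviations (as [calibrate_pdf()] does from training scores)
#' and locates the cut-off between the class means.
#'
#' @param mu_h,sd_h,mu_b,sd_b class means and sds of the score
#'   distribution (`sd > 0`; healthy scores are the larger by the +1/-1
#'   coding).
#' @return a `gaussian_class_pdf` with the `cutoff` y*.
#' @export
gaussian_class_pdf <- function(mu_h, sd_h, mu_b, sd_b) {
  stopifnot(sd_h > 0, sd_b > 0)
  structure(list(mu_h = mu_h, sd_h = sd_h, mu_b = mu_b, sd_b = sd_b,
                 cutoff = pdf_cutoff(mu_h, sd_h, mu_b, sd_b)),
            class = "gaussian_class_pdf")
}

#' Posterior healthy-class probability at given scores
#'
#' `p(h|y) = p(y|h) / (p(y|h) + p(y|b))` under equal priors; the bruised
#' posterior is its complement.
#'
#' @param pdf a `gaussian_class_pdf`.
#' @param y numeric scores.
#' @return numeric vector of healthy posteriors.
#' @export
pdf_posterior <- function(pdf, y) {
  lh <- stats::dnorm(y, pdf$mu_h, pdf$sd_h)
  lb <- stats::dnorm(y, pdf$mu_b, pdf$sd_b)
  denom <- lh + lb
  ifelse(denom > 0, lh / denom, as.numeric(y > pdf$cutoff))
}

# Root of p(y|h) = p(y|b) between the class means. Equal sds give the
# midpoint; unequal sds give a quadratic with two real roots, exactly one
# of which lies between the means.
pdf_cutoff <- function(mu_h, sd_h, mu_b, sd_b) {
  if (abs(sd_h - sd_b) < 1e-12) {
    return((mu_h + mu_b) / 2)
  }
  a <- 1 / sd_b^2 - 1 / sd_h^2
  b <- 2 * (mu_h / sd_h^2 - mu_b / sd_b^2)
  cc <- mu_b^2 / sd_b^2 - mu_h^2 / sd_h^2 - 2 * log(sd_h / sd_b)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) disc <- 0
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(mu_h, mu_b); hi <- max(mu_h, mu_b)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside) == 0L) {
    # degenerate overlap: fall back to the root closest to the midpoint
    inside <- roots[which.min(abs(roots - (lo + hi) / 2))]
  }
  inside[1L]
}

#' Class probabilities from PLS-DA scores
#'
#' Applies Bayes' rule with equal priors to the two Gaussian class
#' densities: `p(h|y) = p(y|h) / (p(y|h) + p(y|b))`. Hard labels follow
#' the cut-off (healthy iff `y > y*`); the tie at `y = y*` goes to
#' bruised, the detection-positive class.
#'
#' @param model a `plsda_model`.
#' @param pdf a `gaussian_class_pdf`.
#' @param table a [spectrum_table()] on the model's band grid.
#' @return a `prob_output` data frame: `sample_id`, `p_healthy`,
#'   `p_bruised`, `score`, `label`.
#' @export
predict_proba <- function(model, pdf, table) {
  y <- predict_scores(model, table)
  proba_from_scores(y, pdf, table$sample_id)
}

proba_from_scores <- function(y, pdf, sample_id) {
  # far in the tails both densities underflow; pdf_posterior then decides
  # by the cut-off side
  p_h <- pdf_posterior(pdf, y)
  out <- data.frame(sample_id = sample_id, p_healthy = p_h,
                    p_bruised = 1 - p_h, score = y,
                    label = ifelse(y > pdf$cutoff, "healthy", "bruised"),
                    stringsAsFactors = FALSE)
  class(out) <- c("prob_output", class(out))
  out
}
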