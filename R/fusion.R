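# Fusion of the two instruments at three levels:
#   data level     - autoscale each instrument's table, concatenate columns;
#   feature level  - concatenate random-frog-selected wavelengths (chosen
#                    separately per instrument, or jointly on the fused
#                    matrix);
#   decision level - combine the two classifiers' probabilistic outputs by
#                    weighted majority vote, Bayesian combination of
#                    sensitivities/specificities, or fuzzy templates.

#' Data-level fusion: autoscale and concatenate
#'
#' Each table is autoscaled on its own rows (training statistics), then
#' the columns are concatenated A-then-B with instrument-namespaced
#' column names. To transform a prediction set with the training
#' statistics, pass the scalers stored on the fused training table.
#'
#' @param tableA,tableB [spectrum_table()]s with identical sample ids in
#'   identical order and distinct instrument tags.
#' @param scalers optional list of two fitted scalers (from a previous
#'   `fuse_data_level` call, attribute `"scalers"`); default: fit on the
#'   given tables.
#' @return the fused `spectrum_table` with a `"scalers"` attribute.
#' @export
fuse_data_level <- function(tableA, tableB, scalers = NULL) {
  stopifnot(inherits(tableA, "spectrum_table"),
            inherits(tableB, "spectrum_table"))
  if (!identical(tableA$sample_id, tableB$sample_id)) {
    stop("fuse_data_level: sample ids must match in the same order")
  }
  insA <- unique(tableA$instrument); insB <- unique(tableB$instrument)
  if (length(intersect(insA, insB)) > 0L) {
    stop("fuse_data_level: tables must come from distinct instruments")
  }
  if (is.null(scalers)) {
    scalers <- list(suppressWarnings(fit_scaler(tableA)),
                    suppressWarnings(fit_scaler(tableB)))
  }
  A <- apply_scaler(scalers[[1]], tableA)
  B <- apply_scaler(scalers[[2]], tableB)
  fused <- spectrum_table(cbind(A$values, B$values),
                          c(A$wavelengths, B$wavelengths),
                          A$sample_id,
                          label = tableA$label %||% tableB$label,
                          instrument = c(A$instrument, B$instrument))
  attr(fused, "scalers") <- scalers
  fused
}

#' Feature-level fusion with separately selected wavelengths
#'
#' Subsets each instrument's table to its own selected wavelengths and
#' concatenates (instrument-namespaced, duplicates within an instrument
#' deduplicated).
#'
#' @param selA,selB `selection_result`s computed on `tableA` / `tableB`.
#' @param tableA,tableB the corresponding [spectrum_table()]s.
#' @return the fused `spectrum_table` of selected columns (autoscaled per
#'   instrument, as in [fuse_data_level()]), with a `"scalers"` attribute.
#' @param scalers optional scalers from the training call.
#' @export
fuse_feature_separate <- function(selA, selB, tableA, tableB,
                                  scalers = NULL) {
  subA <- unique(if (inherits(selA, "selection_result")) selA$subset else selA)
  subB <- unique(if (inherits(selB, "selection_result")) selB$subset else selB)
  if (length(subA) == 0L || length(subB) == 0L) {
    stop("fuse_feature_separate: empty selection")
  }
  fuse_data_level(st_cols(tableA, sort(subA)), st_cols(tableB, sort(subB)),
                  scalers = scalers)
}

#' Feature-level fusion with jointly selected wavelengths
#'
#' Runs random frog plus CV-curve subset sizing on an already fused
#' (data-level) table and keeps the selected columns, which may mix both
#' instruments' bands.
#'
#' @param fused a fused [spectrum_table()] from [fuse_data_level()].
#' @param n_iter,q0,seed,folds,eta random-frog controls (see
#'   [random_frog()]).
#' @param max_n largest subset size for [choose_n_features()].
#' @return a list: `table` (selected-column `spectrum_table`), `selection`
#'   (the `selection_result`).
#' @export
fuse_feature_joint <- function(fused, n_iter = 1000, q0 = NULL, seed = 1,
                               folds = 10, eta = 0.1, max_n = 80) {
  stopifnot(inherits(fused, "spectrum_table"))
  fp <- random_frog(fused, n_iter = n_iter, q0 = q0, seed = seed,
                    folds = folds, eta = eta)
  sel <- choose_n_features(fp, fused, max_n = max_n, folds = folds,
                           seed = seed)
  list(table = st_cols(fused, sel$subset), selection = sel)
}

#' Weighted-majority-vote weights from class accuracies
#'
#' `w^l(i) = alpha^l(i) / (alpha^A(i) + alpha^B(i))` for each class, so
#' the weights of the two classifiers sum to 1 per class.
#'
#' @param perfA,perfB `classifier_performance` objects (cross-validation
#'   per-class accuracies).
#' @return a `fusion_weights` list: `w_h = c(A, B)`, `w_b = c(A, B)`.
#' @export
wmv_weights <- function(perfA, perfB) {
  ah <- c(perfA$alpha_h, perfB$alpha_h)
  ab <- c(perfA$alpha_b, perfB$alpha_b)
  if (sum(ah) <= 0 || sum(ab) <= 0) {
    stop("wmv_weights: both classifiers have zero accuracy for a class")
  }
  structure(list(w_h = stats::setNames(ah / sum(ah), c("A", "B")),
                 w_b = stats::setNames(ab / sum(ab), c("A", "B"))),
            class = "fusion_weights")
}

check_prob_output <- function(prob, who) {
  stopifnot(is.data.frame(prob))
  if (any(abs(prob$p_healthy + prob$p_bruised - 1) > 1e-6)) {
    stop(sprintf("%s: probability rows must sum to 1", who))
  }
}

check_aligned <- function(probA, probB, who) {
  if (!identical(probA$sample_id, probB$sample_id)) {
    stop(sprintf("%s: sample ids of the two outputs must align", who))
  }
}

fusion_result <- function(sample_id, score_h, score_b, probA, probB) {
  label <- ifelse(score_h > score_b, "healthy", "bruised")  # tie -> bruised
  out <- data.frame(sample_id = sample_id, score_h = score_h,
                    score_b = score_b, label_A = probA$label,
                    label_B = probB$label, label = label,
                    agreed = probA$label == probB$label,
                    stringsAsFactors = FALSE)
  class(out) <- c("fusion_result", class(out))
  out
}

#' Weighted majority vote decision fusion
#'
#' Combines the two classifiers' class probabilities into class scores
#' `S(i, x) = w^A(i) p^A(i, x) + w^B(i) p^B(i, x)`; the fused label is
#' the class with the highest score (tie to bruised).
#'
#' @param w a `fusion_weights` from [wmv_weights()].
#' @param probA,probB aligned `prob_output`s of the two classifiers.
#' @return a `fusion_result` data frame.
#' @export
weighted_majority_vote <- function(w, probA, probB) {
  stopifnot(inherits(w, "fusion_weights"))
  check_prob_output(probA, "weighted_majority_vote")
  check_prob_output(probB, "weighted_majority_vote")
  check_aligned(probA, probB, "weighted_majority_vote")
  S_h <- w$w_h["A"] * probA$p_healthy + w$w_h["B"] * probB$p_healthy
  S_b <- w$w_b["A"] * probA$p_bruised + w$w_b["B"] * probB$p_bruised
  fusion_result(probA$sample_id, S_h, S_b, probA, probB)
}

#' Bayesian decision fusion from classifier behaviour priors
#'
#' Treats the two classifiers as independent sensors whose behaviour is
#' summarised by their cross-validation sensitivity and specificity:
#' `P(healthy decision | healthy sample) = specificity`,
#' `P(bruised decision | bruised sample) = sensitivity`. For each sample
#' the likelihood of the pair of soft classifier outputs given each true
#' state is the sum over the four joint decision combinations, weighted
#' by the per-sample probability outputs; the posterior over the two
#' states (equal priors by default) gives the fused label (tie to
#' bruised).
#'
#' @param perfA,perfB `classifier_performance`s (CV sensitivities and
#'   specificities in `[0, 1]`).
#' @param probA,probB aligned `prob_output`s.
#' @param priors prior `c(healthy, bruised)` (default `c(0.5, 0.5)`).
#' @return a `fusion_result` with `score_h`/`score_b` the posteriors.
#' @export
bayes_fuse <- function(perfA, perfB, probA, probB, priors = c(0.5, 0.5)) {
  stopifnot(perfA$sensitivity >= 0, perfA$sensitivity <= 1,
            perfA$specificity >= 0, perfA$specificity <= 1,
            perfB$sensitivity >= 0, perfB$sensitivity <= 1,
            perfB$specificity >= 0, perfB$specificity <= 1)
  check_prob_output(probA, "bayes_fuse")
  check_prob_output(probB, "bayes_fuse")
  check_aligned(probA, probB, "bayes_fuse")
  # P(decision | state) per classifier: rows = decision (h, b),
  # cols = state (healthy, bruised)
  condA <- matrix(c(perfA$specificity, 1 - perfA$specificity,
                    1 - perfA$sensitivity, perfA$sensitivity), 2,
                  dimnames = list(c("dec_h", "dec_b"), c("healthy", "bruised")))
  condB <- matrix(c(perfB$specificity, 1 - perfB$specificity,
                    1 - perfB$sensitivity, perfB$sensitivity), 2,
                  dimnames = list(c("dec_h", "dec_b"), c("healthy", "bruised")))
  lik_state <- function(state) {
    # 4-term sum over joint decisions, factorised per independent sensor
    (condA["dec_h", state] * probA$p_healthy +
       condA["dec_b", state] * probA$p_bruised) *
      (condB["dec_h", state] * probB$p_healthy +
         condB["dec_b", state] * probB$p_bruised)
  }
  L_h <- lik_state("healthy"); L_b <- lik_state("bruised")
  denom <- priors[1] * L_h + priors[2] * L_b
  if (any(denom <= 0)) stop("bayes_fuse: degenerate likelihoods (both zero)")
  post_h <- priors[1] * L_h / denom
  fusion_result(probA$sample_id, post_h, 1 - post_h, probA, probB)
}

#' Stack two classifiers' outputs into decision profiles
#'
#' @param probA,probB aligned `prob_output`s.
#' @return an n x 2 x 2 array: samples x classifiers (A, B) x classes
#'   (healthy, bruised); each classifier row sums to 1.
#' @export
decision_profiles <- function(probA, probB) {
  check_prob_output(probA, "decision_profiles")
  check_prob_output(probB, "decision_profiles")
  check_aligned(probA, probB, "decision_profiles")
  n <- nrow(probA)
  dp <- array(NA_real_, c(n, 2, 2),
              dimnames = list(probA$sample_id, c("A", "B"), CLASS_LEVELS))
  dp[, "A", "healthy"] <- probA$p_healthy
  dp[, "A", "bruised"] <- probA$p_bruised
  dp[, "B", "healthy"] <- probB$p_healthy
  dp[, "B", "bruised"] <- probB$p_bruised
  dp
}

#' Fit fuzzy templates
#'
#' The template of class i is the elementwise mean of the decision
#' profiles of the training samples labeled i.
#'
#' @param dp an n x L x c decision-profile array from
#'   [decision_profiles()].
#' @param labels training labels, both classes present.
#' @return a `fuzzy_templates` list of one L x c matrix per class.
#' @export
fuzzy_template_fit <- function(dp, labels) {
  stopifnot(length(dim(dp)) == 3L, dim(dp)[1] == length(labels))
  templates <- list()
  for (cl in CLASS_LEVELS) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) {
      stop(sprintf("fuzzy_template_fit: no training sample of class '%s'", cl))
    }
    templates[[cl]] <- apply(dp[idx, , , drop = FALSE], c(2, 3), mean)
  }
  structure(templates, class = "fuzzy_templates")
}

#' Fuzzy-template decision fusion
#'
#' Soft class label `mu^i(x) = 1 - mean((F_i - DP(x))^2)` (mean over the
#' L x c entries); the fused label is the class with the largest soft
#' label (tie to bruised).
#'
#' @param templates a `fuzzy_templates` from [fuzzy_template_fit()].
#' @param dp an n x L x c decision-profile array of the samples to fuse.
#' @param probA,probB optional aligned `prob_output`s used only to report
#'   the base labels / agreement; if omitted, hard labels are derived
#'   from the profiles.
#' @return a `fusion_result` with `score_h`/`score_b` the soft labels.
#' @export
fuzzy_template_predict <- function(templates, dp, probA = NULL, probB = NULL) {
  stopifnot(inherits(templates, "fuzzy_templates"), length(dim(dp)) == 3L)
  Lc <- dim(dp)[2] * dim(dp)[3]
  if (!identical(dim(templates[["healthy"]]), dim(dp)[2:3])) {
    stop("fuzzy_template_predict: template / profile shape mismatch")
  }
  mu <- sapply(CLASS_LEVELS, function(cl) {
    diffs <- sweep(dp, c(2, 3), templates[[cl]])
    1 - apply(diffs^2, 1, sum) / Lc
  })
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1,
                                     dimnames = list(NULL, CLASS_LEVELS))
  ids <- dimnames(dp)[[1]] %||% as.character(seq_len(dim(dp)[1]))
  if (is.null(probA)) {
    probA <- data.frame(sample_id = ids,
                        label = label_from_prob(dp[, 1, 1]))
  }
  if (is.null(probB)) {
    probB <- data.frame(sample_id = ids,
                        label = label_from_prob(dp[, 2, 1]))
  }
  fusion_result(ids, mu[, "healthy"], mu[, "bruised"], probA, probB)
}

#' Write a fusion result as CSV
#'
#' @param result a `fusion_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fusion_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
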