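# End-to-end orchestration: a flat key = value run configuration, a
# seeded pipeline that simulates (or loads) the two instruments' tables,
# trains calibrated classifiers, selects wavelengths, fuses at the
# requested level and writes every artifact plus a manifest. Identical
# configs produce byte-identical outputs.

#' Default run configuration
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `seed`; calibration/prediction sample counts
#'   (`n_healthy`, `n_bruised`, `n_healthy_pred`, `n_bruised_pred`);
#'   generator knobs (`rho`, `effect_size`, `noise_sd`, `scatter_sd`,
#'   `bands_pb`, `bands_lctf` = band counts of the two grids);
#'   `classifier` (`"plsda"` or `"rbf"`); `folds`; feature selection
#'   (`frog_iter`, `max_features`); `level` (`"data"`,
#'   `"feature-separate"`, `"feature-joint"`, `"decision"`) and
#'   `decision_rule` (`"wmv"`, `"bayes"`, `"fuzzy"`, `"all"`).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1, n_healthy = 120, n_bruised = 120,
              n_healthy_pred = 80, n_bruised_pred = 96,
              rho = 0.5, effect_size = 0.12, noise_sd = 0.01,
              scatter_sd = 0.05, bands_pb = 102, bands_lctf = 139,
              classifier = "plsda", folds = 10,
              frog_iter = 1000, max_features = 80,
              level = "decision", decision_rule = "all")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("run_config: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$folds >= 2,
            cfg$level %in% c("data", "feature-separate", "feature-joint",
                             "decision"),
            cfg$decision_rule %in% c("wmv", "bayes", "fuzzy", "all"),
            cfg$classifier %in% c("plsda", "rbf"))
  structure(cfg, class = "run_config")
}

#' Read / write a flat key = value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Numeric-looking values are converted.
#'
#' @param path config file path.
#' @param config a `run_config` (for writing).
#' @return `read_run_config`: a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("read_run_config: malformed line: ", lines[bad][1])
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}

synth_from_run_config <- function(config, n_h, n_b, seed) {
  synth_config(n_healthy = n_h, n_bruised = n_b, seed = seed,
               band_grid_pb = seq(480, 960, length.out = config$bands_pb),
               band_grid_lctf = seq(965, 1655,
                                    length.out = config$bands_lctf),
               effect_size = config$effect_size,
               noise_sd_pb = config$noise_sd,
               noise_sd_lctf = config$noise_sd,
               scatter_sd = config$scatter_sd, rho = config$rho)
}

#' Run the full fusion pipeline
#'
#' Simulates calibration and prediction sets for the two instruments,
#' trains the configured classifier per instrument, selects wavelengths
#' when the fusion level needs them, fuses at the configured level,
#' evaluates on the prediction set, and writes all artifacts (spectra,
#' selections, per-model metrics, fused results, manifest) into
#' `out_dir`. Rerunning the same config into a fresh directory produces
#' byte-identical files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly. Metrics are also returned as the
#'   attribute `"metrics"`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    cal_cfg <- synth_from_run_config(config, config$n_healthy,
                                     config$n_bruised,
                                     derive_seed(config$seed, 100L))
    pred_cfg <- synth_from_run_config(config, config$n_healthy_pred,
                                      config$n_bruised_pred,
                                      derive_seed(config$seed, 200L))
    cal <- generate_mean_spectra(cal_cfg)
    pred <- generate_mean_spectra(pred_cfg)
    pred$truth$sample_id <- sub("^S", "P", pred$truth$sample_id)
    for (ins in c("pb", "lctf")) {
      pred[[ins]]$sample_id <- sub("^S", "P", pred[[ins]]$sample_id)
      rownames(pred[[ins]]$values) <- pred[[ins]]$sample_id
    }
    write_spectrum_csv(cal$pb, file.path(out_dir, "cal_pb.csv"))
    write_spectrum_csv(cal$lctf, file.path(out_dir, "cal_lctf.csv"))
    write_spectrum_csv(pred$pb, file.path(out_dir, "pred_pb.csv"))
    write_spectrum_csv(pred$lctf, file.path(out_dir, "pred_lctf.csv"))
    utils::write.csv(cal$truth, file.path(out_dir, "cal_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(pred$truth, file.path(out_dir, "pred_truth.csv"),
                     row.names = FALSE)

    spec <- classifier_spec(config$classifier, folds = config$folds,
                            seed = derive_seed(config$seed, 300L))
    truth_pred <- pred$truth$label
    metrics <- list()
    files <- c("cal_pb.csv", "cal_lctf.csv", "pred_pb.csv",
               "pred_lctf.csv", "cal_truth.csv", "pred_truth.csv")

    stage <- "train-single"
    clfA <- clf_fit(spec, cal$pb)
    clfB <- clf_fit(spec, cal$lctf)
    probA_pred <- clf_predict(clfA, pred$pb)
    probB_pred <- clf_predict(clfB, pred$lctf)
    metrics$single_pb <- score_predictions(probA_pred$label, truth_pred)
    metrics$single_lctf <- score_predictions(probB_pred$label, truth_pred)

    run_on <- function(train_tab, pred_tab, name) {
      clf <- clf_fit(spec, train_tab)
      prob <- clf_predict(clf, pred_tab)
      rep <- score_predictions(prob$label, truth_pred)
      write_report(rep, file.path(out_dir, paste0("metrics_", name)),
                   roc = roc_auc(prob$p_bruised, truth_pred)$roc)
      files <<- c(files, paste0("metrics_", name, c(".json", ".csv",
                                                    "_roc.csv")))
      metrics[[name]] <<- rep
      prob
    }

    frog_seed <- derive_seed(config$seed, 400L)
    if (config$level == "data") {
      stage <- "fuse-data"
      fused_cal <- fuse_data_level(cal$pb, cal$lctf)
      fused_pred <- fuse_data_level(pred$pb, pred$lctf,
                                    scalers = attr(fused_cal, "scalers"))
      run_on(fused_cal, fused_pred, "data_level")
    } else if (config$level == "feature-joint") {
      stage <- "select-joint"
      fused_cal <- fuse_data_level(cal$pb, cal$lctf)
      fused_pred <- fuse_data_level(pred$pb, pred$lctf,
                                    scalers = attr(fused_cal, "scalers"))
      fj <- fuse_feature_joint(fused_cal, n_iter = config$frog_iter,
                               seed = frog_seed, folds = config$folds,
                               max_n = config$max_features)
      write_selection_csv(fj$selection, fused_cal,
                          file.path(out_dir, "joint"))
      files <- c(files, "joint_selection.csv", "joint_cv_curve.csv")
      message("following ", fj$selection$k, " wavelengths: ",
              paste(fj$selection$bands, collapse = ", "))
      run_on(fj$table, st_cols(fused_pred, fj$selection$subset),
             "feature_joint")
    } else if (config$level %in% c("feature-separate", "decision")) {
      stage <- "select-separate"
      fpA <- random_frog(cal$pb, n_iter = config$frog_iter,
                         seed = frog_seed, folds = config$folds)
      selA <- choose_n_features(fpA, cal$pb, max_n = config$max_features,
                                folds = config$folds, seed = frog_seed)
      fpB <- random_frog(cal$lctf, n_iter = config$frog_iter,
                         seed = derive_seed(config$seed, 401L),
                         folds = config$folds)
      selB <- choose_n_features(fpB, cal$lctf,
                                max_n = config$max_features,
                                folds = config$folds, seed = frog_seed)
      write_selection_csv(selA, cal$pb, file.path(out_dir, "pb"))
      write_selection_csv(selB, cal$lctf, file.path(out_dir, "lctf"))
      files <- c(files, paste0(rep(c("pb", "lctf"), each = 2),
                               c("_selection.csv", "_cv_curve.csv")))
      for (s in list(selA, selB)) {
        message("following ", s$k, " wavelengths: ",
                paste(s$bands, collapse = ", "))
      }
      if (config$level == "feature-separate") {
        stage <- "fuse-feature-separate"
        fused_cal <- fuse_feature_separate(selA, selB, cal$pb, cal$lctf)
        fused_pred <- fuse_feature_separate(selA, selB, pred$pb,
                                            pred$lctf,
                                            scalers = attr(fused_cal,
                                                           "scalers"))
        run_on(fused_cal, fused_pred, "feature_separate")
      } else {
        stage <- "fuse-decision"
        calA <- st_cols(cal$pb, selA$subset)
        calB <- st_cols(cal$lctf, selB$subset)
        clfA <- clf_fit(spec, calA)
        clfB <- clf_fit(spec, calB)
        perfA <- crossval_perf(spec, calA, folds = config$folds,
                               seed = derive_seed(config$seed, 500L))
        perfB <- crossval_perf(spec, calB, folds = config$folds,
                               seed = derive_seed(config$seed, 501L))
        pA <- clf_predict(clfA, st_cols(pred$pb, selA$subset))
        pB <- clf_predict(clfB, st_cols(pred$lctf, selB$subset))
        rules <- if (config$decision_rule == "all") {
          c("wmv", "bayes", "fuzzy")
        } else config$decision_rule
        dp_train <- decision_profiles(clf_predict(clfA, calA),
                                      clf_predict(clfB, calB))
        templates <- fuzzy_template_fit(dp_train, calA$label)
        for (rule in rules) {
          fr <- switch(rule,
            wmv = weighted_majority_vote(wmv_weights(perfA, perfB), pA, pB),
            bayes = bayes_fuse(perfA, perfB, pA, pB),
            fuzzy = fuzzy_template_predict(templates,
                                           decision_profiles(pA, pB),
                                           pA, pB))
          write_fusion_csv(fr, file.path(out_dir,
                                         paste0("fusion_", rule, ".csv")))
          rep <- score_predictions(fr$label, truth_pred)
          part <- agreement_partition(fr$label_A, fr$label_B, fr$label,
                                      truth_pred)
          write_report(c(unclass(rep), part),
                       file.path(out_dir, paste0("metrics_", rule)))
          files <- c(files, paste0("fusion_", rule, ".csv"),
                     paste0("metrics_", rule, c(".json", ".csv")))
          metrics[[paste0("decision_", rule)]] <- rep
        }
      }
    }

    stage <- "report"
    write_report(metrics$single_pb, file.path(out_dir, "metrics_single_pb"))
    write_report(metrics$single_lctf,
                 file.path(out_dir, "metrics_single_lctf"))
    files <- c(files, paste0("metrics_single_", rep(c("pb", "lctf"),
                                                    each = 2),
                             c(".json", ".csv")))
    manifest <- list(package = "hsifuse",
                     version = as.character(utils::packageVersion("hsifuse")),
                     config = unclass(config),
                     seeds = list(master = config$seed,
                                  calibration = derive_seed(config$seed, 100L),
                                  prediction = derive_seed(config$seed, 200L),
                                  classifier = derive_seed(config$seed, 300L),
                                  featsel = derive_seed(config$seed, 400L)),
                     files = sort(unique(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    metrics
  }, error = function(e) {
    stop(sprintf("run_pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(structure(out_dir, metrics = result))
}
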