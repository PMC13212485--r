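VARIANTS <- c("gb", "hgb", "gbef", "hgef", "ghef_w", "ghef_d")

#' Model-variant specification
#'
#' The six model variants of the framework: the two plain base learners
#' (`gb`, `hgb`), their metaheuristic-tuned counterparts (`gbef`, `hgef`),
#' and the two fused ensembles of the tuned learners — simplex-weighted
#' averaging (`ghef_w`) and Dempster-Shafer evidence combination
#' (`ghef_d`).
#'
#' @param variant One of `"gb"`, `"hgb"`, `"gbef"`, `"hgef"`, `"ghef_w"`,
#'   `"ghef_d"`.
#' @param profile Optimizer scale: `"desk"` (population 15, 50 iterations)
#'   or `"paper"` (population 30, 200 iterations).
#' @param k CV folds used for tuning objectives and validation RMSE,
#'   default 5.
#' @param frame_bins Bins of the evidence frame (`ghef_d`), default 20.
#' @param member_configs Optional list of fixed [learner_config()]s (one
#'   per member); when given, tuning is skipped — used to freeze
#'   hyperparameters across bootstrap replicates.
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(variant = VARIANTS, profile = c("desk", "paper"),
                         k = 5, frame_bins = 20, member_configs = NULL) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  structure(list(variant = variant, profile = profile, k = k,
                 frame_bins = frame_bins, member_configs = member_configs),
            class = "variant_spec")
}

variant_members <- function(variant) {
  switch(variant,
         gb = "gb", hgb = "hgb", gbef = "gb", hgef = "hgb",
         ghef_w = c("gb", "hgb"), ghef_d = c("gb", "hgb"))
}

variant_tuned <- function(variant) !variant %in% c("gb", "hgb")

as_variant_spec <- function(model_spec) {
  if (inherits(model_spec, "variant_spec")) return(model_spec)
  if (inherits(model_spec, "learner_config")) {
    return(variant_spec(model_spec$kind, member_configs = list(model_spec)))
  }
  if (is.character(model_spec) && model_spec %in% VARIANTS) {
    return(variant_spec(model_spec))
  }
  stop_ghef("cannot interpret model_spec")
}

# freeze tuned member configurations into the spec (bootstrap replicates)
freeze_spec <- function(spec, fit) {
  spec$member_configs <- fit$configs
  spec
}

tuning_eefo <- function(profile, seed) {
  bounds <- matrix(c(0, 0, 0, 1, 1, 1), 3, 2)
  init <- matrix(0.5, 1, 3)
  if (profile == "paper") eefo_config(bounds, seed = seed, init = init)
  else eefo_desk_profile(bounds, seed = seed, init = init)
}

weight_eefo <- function(profile, m, seed) {
  bounds <- cbind(rep(0, m), rep(1, m))
  init <- rbind(diag(m), matrix(1 / m, 1, m))
  if (profile == "paper") eefo_config(bounds, seed = seed, init = init)
  else eefo_desk_profile(bounds, seed = seed, init = init)
}

#' Fit a model variant on a training set
#'
#' Single variants fit one learner (reference configuration, or
#' metaheuristic-tuned for `gbef`/`hgef`). Ensemble variants fit both tuned
#' learners, compute out-of-fold validation predictions on the training
#' set, and from those fit either simplex weights (`ghef_w`) or per-member
#' reliabilities, bandwidths and the evidence frame (`ghef_d`). When
#' `member_configs` is fixed in the spec, tuning is skipped and, if `oob`
#' records are supplied (bootstrap replicates), the out-of-bag records
#' replace the CV out-of-fold predictions for weight/reliability fitting.
#'
#' @param spec A [variant_spec()].
#' @param train Training [solubility_dataset()].
#' @param seed Integer seed.
#' @param oob Optional held-out [solubility_dataset()] for weight fitting.
#' @return A `fitted_variant`.
#' @export
fit_variant <- function(spec, train, seed = 1, oob = NULL) {
  spec <- as_variant_spec(spec)
  train <- solubility_dataset(train)
  kinds <- variant_members(spec$variant)
  fixed <- !is.null(spec$member_configs)

  configs <- list(); models <- list(); tuning <- list()
  for (mi in seq_along(kinds)) {
    kind <- kinds[mi]
    if (fixed) {
      cfg <- spec$member_configs[[mi]]
      configs[[mi]] <- cfg
      models[[mi]] <- train_learner(cfg, train)
    } else if (variant_tuned(spec$variant)) {
      tuned <- tune_learner(kind, train, k = spec$k,
                            eefo = tuning_eefo(spec$profile,
                                               derive_seed(seed, "tune", kind)),
                            seed = seed)
      configs[[mi]] <- tuned$config
      models[[mi]] <- tuned$model
      tuning[[kind]] <- tuned$result
    } else {
      cfg <- reference_config(kind, seed = derive_seed(seed, "fit", kind))
      configs[[mi]] <- cfg
      models[[mi]] <- train_learner(cfg, train)
    }
  }

  fit <- list(variant = spec$variant, spec = spec, configs = configs,
              models = models, tuning = tuning, seed = seed)

  if (spec$variant %in% c("ghef_w", "ghef_d")) {
    if (!is.null(oob)) {
      V <- vapply(models, predict_learner, numeric(nrow(oob)), records = oob)
      yv <- target_vector(oob)
    } else {
      held <- oof_predictions(configs, train, spec$k, seed)
      V <- held$V
      yv <- held$y
    }
    V <- matrix(V, ncol = length(models))
    val_rmse <- apply(V, 2, function(p) rmse(yv, p))
    fit$val_rmse <- val_rmse
    if (spec$variant == "ghef_w") {
      fit$weights <- fit_weights(V, yv,
                                 eefo = weight_eefo(spec$profile, ncol(V),
                                                    derive_seed(seed, "weights")))
    } else {
      y_train <- target_vector(train)
      fit$reliabilities <- reliability_from_rmse(val_rmse, stats::sd(y_train))
      fit$bandwidths <- pmax(val_rmse, 1e-6)
      fit$frame <- dst_frame(y_train, k = spec$frame_bins)
    }
  }
  class(fit) <- "fitted_variant"
  fit
}

# out-of-fold predictions of each member config on the training set
oof_predictions <- function(configs, train, k, seed) {
  folds <- kfold_indices(nrow(train), k, derive_seed(seed, "oof"))
  V <- matrix(NA_real_, nrow(train), length(configs))
  for (fold in seq_len(k)) {
    hold <- folds == fold
    sub <- solubility_dataset(train[!hold, , drop = FALSE])
    heldout <- solubility_dataset(train[hold, , drop = FALSE])
    for (mi in seq_along(configs)) {
      m <- train_learner(configs[[mi]], sub)
      V[hold, mi] <- predict_learner(m, heldout)
    }
  }
  list(V = V, y = target_vector(train))
}

#' Predict with a fitted variant
#'
#' @param fit A `fitted_variant` from [fit_variant()].
#' @param records [solubility_dataset()] to predict.
#' @return Numeric prediction vector, (g/L) x 10.
#' @export
predict_variant <- function(fit, records) {
  stopifnot(inherits(fit, "fitted_variant"))
  records <- solubility_dataset(records)
  P <- vapply(fit$models, predict_learner, numeric(nrow(records)),
              records = records)
  P <- matrix(P, ncol = length(fit$models))
  switch(fit$variant,
         ghef_w = weighted_predict(fit$weights, P),
         ghef_d = dst_predict(fit$models, fit$reliabilities, fit$bandwidths,
                              fit$frame, records)$prediction,
         P[, 1])
}

#' Run configuration for the end-to-end pipeline
#'
#' @param data A [solubility_dataset()], a CSV path, or a
#'   [generator_config()] (default: the standard synthetic design).
#' @param variant Model variant, see [variant_spec()].
#' @param split_fraction Test fraction, default 0.2 (stratified by
#'   compound).
#' @param k CV folds, default 5.
#' @param profile `"desk"` or `"paper"` optimizer scale.
#' @param bootstrap `NULL`, or a [bootstrap_config()] to add prediction
#'   intervals on the test set.
#' @param seed Master seed: every random stage derives its own stream.
#' @param out_dir Optional directory for persisted artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(data = generator_config(), variant = "ghef_w",
                       split_fraction = 0.2, k = 5,
                       profile = c("desk", "paper"), bootstrap = NULL,
                       seed = 1, out_dir = NULL) {
  profile <- match.arg(profile)
  stopifnot(variant %in% VARIANTS)
  structure(list(data = data, variant = variant,
                 split_fraction = split_fraction, k = k, profile = profile,
                 bootstrap = bootstrap, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_data <- function(data, seed) {
  if (inherits(data, "solubility_dataset")) return(data)
  if (inherits(data, "generator_config")) return(generate_dataset(data))
  if (is.character(data)) return(read_dataset(data))
  if (is.data.frame(data)) return(solubility_dataset(data))
  stop_ghef("cannot interpret the data source")
}

#' Run the end-to-end pipeline for one variant
#'
#' Load or generate the data, split train/test (stratified by compound),
#' fit the requested variant (tuning where the variant calls for it),
#' evaluate the five statistics on train and test, optionally compute
#' bootstrap prediction intervals on the test set, and return a run
#' report. Every random stage derives its seed from the master seed, so a
#' report is exactly reproducible from (config, seed, data).
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `variant`, `seed`, `metrics` (train/test
#'   [metrics_report()]s), `fit`, `split`, optional `intervals` and
#'   `calibration`, `elapsed` (seconds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dataset <- resolve_data(config$data, config$seed)
  split <- split_train_test(dataset, config$split_fraction,
                            seed = derive_seed(config$seed, "split"))
  spec <- variant_spec(config$variant, profile = config$profile, k = config$k)
  fit <- fit_variant(spec, split$train, seed = derive_seed(config$seed, "fit"))
  metrics <- list(
    train = metrics_report(target_vector(split$train),
                           predict_variant(fit, split$train)),
    test = metrics_report(target_vector(split$test),
                          predict_variant(fit, split$test)))
  report <- list(variant = config$variant, seed = config$seed,
                 profile = config$profile, metrics = metrics, fit = fit,
                 split = split)
  if (!is.null(config$bootstrap)) {
    bcfg <- config$bootstrap
    bcfg$seed <- derive_seed(config$seed, "bootstrap")
    spec_frozen <- freeze_spec(spec, fit)
    report$intervals <- bootstrap_pi(spec_frozen, split$train, split$test, bcfg)
    report$calibration <- calibration_report(report$intervals,
                                             target_vector(split$test))
  }
  report$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) persist_report(report, config)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> variant=%s seed=%d (%.1fs)\n",
              x$variant, x$seed, x$elapsed))
  cat(sprintf("  train: RMSE %.4f  R2 %.4f  MAPE %.2f%%\n",
              x$metrics$train$rmse, x$metrics$train$r_squared,
              x$metrics$train$mape))
  cat(sprintf("  test:  RMSE %.4f  R2 %.4f  MAPE %.2f%%\n",
              x$metrics$test$rmse, x$metrics$test$r_squared,
              x$metrics$test$mape))
  if (!is.null(x$calibration)) {
    cat(sprintf("  PI coverage %.3f, mean width %.4f (B=%d)\n",
                x$calibration$coverage, x$calibration$mean_width,
                x$intervals$replicates[1]))
  }
  invisible(x)
}

persist_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    variant = report$variant, seed = report$seed, profile = report$profile,
    metrics = lapply(report$metrics, unclass),
    member_configs = lapply(report$fit$configs, unclass),
    weights = as.numeric(report$fit$weights),
    reliabilities = report$fit$reliabilities,
    elapsed_seconds = report$elapsed)
  jsonlite::write_json(summary, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$intervals)) {
    utils::write.csv(as.data.frame(report$intervals),
                     file.path(config$out_dir, "intervals.csv"),
                     row.names = FALSE)
  }
  for (kind in names(report$fit$tuning)) {
    trajectory_table(report$fit$tuning[[kind]],
                     file.path(config$out_dir,
                               sprintf("convergence_%s.csv", kind)))
  }
  invisible(config$out_dir)
}

#' Compare model variants on a shared split
#'
#' Fits each variant on the same train/test partition (same master seed)
#' and tabulates the five statistics, sorted by test RMSE.
#'
#' @param variants Character vector of variant names (default all six).
#' @param data Data source as in [run_config()].
#' @param split_fraction,k,profile,seed As in [run_config()].
#' @return data.frame with one row per variant: train and test RMSE, R2,
#'   MAPE, FGE, sorted by test RMSE.
#' @export
compare_variants <- function(variants = VARIANTS, data = generator_config(),
                             split_fraction = 0.2, k = 5, profile = "desk",
                             seed = 1) {
  dataset <- resolve_data(data, seed)
  split <- split_train_test(dataset, split_fraction,
                            seed = derive_seed(seed, "split"))
  rows <- lapply(variants, function(v) {
    spec <- variant_spec(v, profile = profile, k = k)
    fit <- fit_variant(spec, split$train, seed = derive_seed(seed, "fit"))
    tr <- metrics_report(target_vector(split$train),
                         predict_variant(fit, split$train))
    te <- metrics_report(target_vector(split$test),
                         predict_variant(fit, split$test))
    data.frame(variant = v,
               train_rmse = tr$rmse, train_r2 = tr$r_squared,
               train_mape = tr$mape, train_fge = tr$fge,
               test_rmse = te$rmse, test_r2 = te$r_squared,
               test_mape = te$mape, test_fge = te$fge)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$test_rmse), , drop = FALSE]
}
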