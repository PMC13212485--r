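#' Bootstrap configuration
#'
#' @param replicates Number of bootstrap replicates B (>= 2); 1000 at full
#'   study scale, 200 in the desk profile.
#' @param level Central interval probability, default 0.95.
#' @param seed Integer master seed; one RNG stream is derived per replicate
#'   so B can grow without changing earlier replicates.
#' @param refit_hyperparameters Re-run the metaheuristic tuning inside each
#'   replicate (expensive; default FALSE, hyperparameters are frozen from
#'   the initial fit).
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(replicates = 1000, level = 0.95, seed = 1,
                             refit_hyperparameters = FALSE) {
  if (replicates < 2) stop_ghef("need at least 2 bootstrap replicates")
  stopifnot(level > 0, level < 1)
  structure(list(replicates = as.integer(replicates), level = level,
                 seed = as.integer(seed),
                 refit_hyperparameters = isTRUE(refit_hyperparameters)),
            class = "bootstrap_config")
}

#' Resample a dataset with replacement
#'
#' Same size as the input; deterministic given `seed`.
#'
#' @param dataset A [solubility_dataset()].
#' @param seed Integer seed.
#' @return A [solubility_dataset()] of the same size.
#' @export
bootstrap_resample <- function(dataset, seed = 1) {
  dataset <- solubility_dataset(dataset)
  n <- nrow(dataset)
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  solubility_dataset(dataset[idx, , drop = FALSE],
                     provenance = "bootstrap resample")
}

#' Bootstrapped percentile prediction intervals
#'
#' Retrains the model on `B` with-replacement resamples of `train`, predicts
#' every target record with each replicate, and reports per record the mean
#' replicate prediction and the empirical percentile bounds at
#' `(1 - level)/2` and `1 - (1 - level)/2` (linear interpolation between
#' order statistics, [stats::quantile()] type 7). Hyperparameters are
#' frozen from an initial fit on the full training set unless
#' `config$refit_hyperparameters` is set. Deterministic given the config
#' seed.
#'
#' @param model_spec A [variant_spec()], a [learner_config()], or a
#'   `"gb"`/`"hgb"` kind string.
#' @param train Training [solubility_dataset()] with solubility values.
#' @param targets [solubility_dataset()] of records to predict (solubility
#'   optional).
#' @param config A [bootstrap_config()].
#' @return An `interval_table` data.frame: the target features plus
#'   `prediction`, `lower`, `upper`, `replicates`, `extrapolated` (feature
#'   outside the training hull); replicate predictions in attribute `draws`.
#' @export
bootstrap_pi <- function(model_spec, train, targets, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  train <- solubility_dataset(train)
  targets <- solubility_dataset(targets)
  spec <- as_variant_spec(model_spec)
  if (!config$refit_hyperparameters) {
    fit0 <- fit_variant(spec, train, seed = derive_seed(config$seed, "freeze"))
    spec <- freeze_spec(spec, fit0)
  }
  B <- config$replicates
  draws <- matrix(NA_real_, B, nrow(targets))
  for (b in seq_len(B)) {
    rep_seed <- derive_seed(config$seed, "replicate", b)
    resample <- bootstrap_resample(train, derive_seed(rep_seed, "resample"))
    fit <- fit_variant(spec, resample, seed = rep_seed, oob = train_oob(train, resample))
    draws[b, ] <- predict_variant(fit, targets)
  }
  alpha <- (1 - config$level) / 2
  lower <- apply(draws, 2, stats::quantile, probs = alpha, type = 7)
  upper <- apply(draws, 2, stats::quantile, probs = 1 - alpha, type = 7)
  hull_lo <- apply(feature_matrix(train), 2, min)
  hull_hi <- apply(feature_matrix(train), 2, max)
  Xt <- feature_matrix(targets)
  extrapolated <- apply(Xt, 1, function(x) any(x < hull_lo | x > hull_hi))
  out <- cbind(as.data.frame(targets)[, c("compound", FEATURE_COLS)],
               data.frame(prediction = colMeans(draws), lower = lower,
                          upper = upper, replicates = B,
                          extrapolated = extrapolated))
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  attr(out, "level") <- config$level
  class(out) <- c("interval_table", "data.frame")
  out
}

# rows of `train` absent from the resample, for out-of-bag weight fitting
train_oob <- function(train, resample) {
  key <- function(d) apply(as.data.frame(d)[, c(FEATURE_COLS, "solubility")],
                           1, paste, collapse = "\r")
  oob <- !(key(train) %in% key(resample))
  if (sum(oob) < 2) return(NULL)
  solubility_dataset(train[oob, , drop = FALSE], provenance = "oob")
}

#' Coverage and width calibration of an interval table
#'
#' @param intervals An `interval_table` from [bootstrap_pi()] (or any
#'   data.frame with `lower`/`upper` columns).
#' @param y_true Observed solubility values, same length.
#' @return List: `coverage` (proportion of truths inside their closed
#'   intervals), `mean_width`, `n`.
#' @export
calibration_report <- function(intervals, y_true) {
  cov <- pi_coverage(y_true, intervals$lower, intervals$upper)
  list(coverage = cov, mean_width = mean(intervals$upper - intervals$lower),
       n = length(y_true))
}
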