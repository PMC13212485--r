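check_pair <- function(y, yhat) {
  if (length(y) == 0) stop_ghef("empty vectors")
  if (length(y) != length(yhat)) stop_ghef("length mismatch (%d vs %d)",
                                           length(y), length(yhat))
}

#' Root mean squared error
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return sqrt(mean((y - yhat)^2)).
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the observed mean as baseline; can be
#' negative when the model underperforms the mean predictor.
#'
#' @inheritParams rmse
#' @return Scalar <= 1.
#' @export
r_squared <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 2) stop_ghef("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop_ghef("observed values are constant: R-squared undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' `(100/n) * sum(|(y - yhat) / y|)`. A zero observed value is a hard
#' error: with near-zero solubilities the statistic explodes, so refusing
#' is safer than silently fudging the denominator.
#'
#' @inheritParams rmse
#' @return Percent.
#' @export
mape <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y == 0)) stop_ghef("observed values contain 0: MAPE undefined (division hazard)")
  100 * mean(abs((y - yhat) / y))
}

#' Fractional error
#'
#' `(1/n) * sum(|y - yhat| / |y|)`; identically MAPE / 100.
#'
#' @inheritParams rmse
#' @return Dimensionless.
#' @export
fge <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y == 0)) stop_ghef("observed values contain 0: FGE undefined (division hazard)")
  mean(abs(y - yhat) / abs(y))
}

#' Prediction-interval coverage probability
#'
#' Fraction of observed values inside their closed intervals `[L_i, U_i]`
#' (boundary counts as covered).
#'
#' @param y Observed values.
#' @param lower,upper Interval bounds, element-wise `lower <= upper`.
#' @return Proportion in [0, 1].
#' @export
pi_coverage <- function(y, lower, upper) {
  check_pair(y, lower)
  check_pair(y, upper)
  if (any(lower > upper)) stop_ghef("crossed interval bounds (lower > upper)")
  mean(y >= lower & y <= upper)
}

#' Full metrics report
#'
#' @inheritParams rmse
#' @param lower,upper Optional interval bounds for coverage.
#' @return List of class `metrics_report`: rmse, r_squared, mape, fge,
#'   pi_coverage (NA without bounds), n.
#' @export
metrics_report <- function(y, yhat, lower = NULL, upper = NULL) {
  cov <- if (!is.null(lower) && !is.null(upper)) pi_coverage(y, lower, upper) else NA_real_
  structure(list(rmse = rmse(y, yhat), r_squared = r_squared(y, yhat),
                 mape = mape(y, yhat), fge = fge(y, yhat),
                 pi_coverage = cov, n = length(y)),
            class = "metrics_report")
}

#' k-fold assignment
#'
#' Random permutation chunked into k folds whose sizes differ by at most
#' one (the first `n %% k` folds get the extra record). Deterministic given
#' `seed`.
#'
#' @param n Number of records.
#' @param k Number of folds, 2 <= k <= n.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..k, one per index.
#' @export
kfold_indices <- function(n, k, seed = 1) {
  if (k < 2) stop_ghef("need k >= 2 folds")
  if (n < k) stop_ghef("n must be at least k")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  labels <- rep(seq_len(k), times = sizes)
  perm <- with_seed(derive_seed(seed, "kfold"), sample.int(n))
  folds <- integer(n)
  folds[perm] <- labels
  folds
}

#' k-fold cross-validation of a learner configuration
#'
#' Trains on k-1 folds, evaluates the held-out fold, for each fold; fold
#' partition derives from `seed`.
#'
#' @param config A [learner_config()] (or `"gb"`/`"hgb"` for the reference
#'   configuration of that kind).
#' @param dataset [solubility_dataset()] with solubility values.
#' @param k Number of folds, default 5.
#' @param seed Integer seed.
#' @return List of class `cv_result`: `folds` (data.frame of per-fold
#'   metrics), `mean`, `sd` (across folds, per metric).
#' @export
cross_validate <- function(config, dataset, k = 5, seed = 1) {
  if (is.character(config)) config <- reference_config(config, seed = seed)
  dataset <- solubility_dataset(dataset)
  folds <- kfold_indices(nrow(dataset), k, seed)
  rows <- lapply(seq_len(k), function(fold) {
    hold <- folds == fold
    model <- train_learner(config, dataset[!hold, , drop = FALSE])
    held <- solubility_dataset(dataset[hold, , drop = FALSE])
    y <- target_vector(held)
    yhat <- predict_learner(model, held)
    # R-squared needs >= 2 non-constant held-out values (undefined for LOO folds)
    r2 <- if (length(y) >= 2 && stats::sd(y) > 0) r_squared(y, yhat) else NA_real_
    data.frame(fold = fold, n = sum(hold), rmse = rmse(y, yhat),
               r_squared = r2,
               mape = if (any(y == 0)) NA_real_ else mape(y, yhat),
               fge = if (any(y == 0)) NA_real_ else fge(y, yhat))
  })
  tab <- do.call(rbind, rows)
  metric_cols <- c("rmse", "r_squared", "mape", "fge")
  structure(list(folds = tab,
                 mean = colMeans(tab[metric_cols], na.rm = TRUE),
                 sd = apply(tab[metric_cols], 2, stats::sd, na.rm = TRUE),
                 k = k, seed = seed),
            class = "cv_result")
}

#' Kruskal-Wallis rank test
#'
#' Wrapper over [stats::kruskal.test()] (rank-based H with tie correction,
#' chi-square p-value on g - 1 degrees of freedom). The degenerate case of
#' all values identical, where the tie correction annihilates the
#' denominator, returns H = 0 with `degenerate = TRUE` by convention.
#'
#' @param values Numeric response (e.g. solubility).
#' @param groups Group labels (e.g. a feature's design levels).
#' @return List of class `kw_result`: `h`, `p_value`, `df`, `groups`,
#'   `ties_corrected`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_ghef("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop_ghef("every group must be nonempty")
  if (length(unique(values)) == 1) {
    return(structure(list(h = 0, p_value = 1, df = nlevels(groups) - 1L,
                          groups = nlevels(groups), ties_corrected = TRUE,
                          degenerate = TRUE),
                     class = "kw_result"))
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(h = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter), groups = nlevels(groups),
                 ties_corrected = anyDuplicated(values) > 0,
                 degenerate = FALSE),
            class = "kw_result")
}

#' Kruskal-Wallis screening of all four features
#'
#' Convenience wrapper: groups solubility by each feature's design levels
#' (temperature and pressure levels; compound identity for molecular weight
#' and melting point, which are constant within a compound).
#'
#' @param dataset A [solubility_dataset()] with solubility values.
#' @return data.frame with one row per feature: h, p_value, groups.
#' @export
feature_screening <- function(dataset) {
  dataset <- solubility_dataset(dataset)
  y <- target_vector(dataset)
  rows <- lapply(FEATURE_COLS, function(feat) {
    kw <- kruskal_wallis(y, dataset[[feat]])
    data.frame(feature = feat, h = kw$h, p_value = kw$p_value,
               groups = kw$groups)
  })
  do.call(rbind, rows)
}

#' Local linear-surrogate attribution for one record
#'
#' Perturbs the record with per-feature Gaussian noise (scale = the
#' background population SD of each feature), weights the perturbations by
#' an exponential kernel on standardized distance (default width
#' `0.75 * sqrt(4)`), and fits a weighted least-squares linear surrogate on
#' standardized features. The attribution of a feature is its surrogate
#' coefficient on the standardized scale, i.e. raw slope x feature SD, in
#' solubility units. Zero-variance background features get attribution 0
#' with a flag. Deterministic given `seed`.
#'
#' @param model Either a `trained_learner` or a function mapping a
#'   [solubility_dataset()] to predictions.
#' @param record One-row [solubility_dataset()] (or coercible data.frame).
#' @param background [solubility_dataset()] supplying feature scales.
#' @param n_samples Number of perturbations, default 1000.
#' @param kernel_width Kernel width on the standardized scale,
#'   default `0.75 * sqrt(4)`.
#' @param seed Integer seed.
#' @return List of class `attribution`: `scores` (named length-4 vector),
#'   `intercept`, `r_squared` (surrogate fit quality), `zero_variance`
#'   (named logical flags).
#' @export
local_attribution <- function(model, record, background, n_samples = 1000,
                              kernel_width = 0.75 * sqrt(4), seed = 1) {
  background <- solubility_dataset(background)
  record <- solubility_dataset(as.data.frame(record))
  if (nrow(record) != 1) stop_ghef("record must be a single row")
  predict_fn <- if (inherits(model, "trained_learner")) {
    function(ds) predict_learner(model, ds)
  } else model
  x0 <- as.numeric(feature_matrix(record)[1, ])
  scales <- apply(feature_matrix(background), 2, pop_sd)
  zero_var <- scales == 0
  names(zero_var) <- FEATURE_COLS
  Z <- with_seed(derive_seed(seed, "lime"), {
    matrix(stats::rnorm(n_samples * 4), n_samples, 4)
  })
  Z[, zero_var] <- 0
  X <- sweep(sweep(Z, 2, scales, `*`), 2, x0, `+`)
  perturbed <- data.frame(compound = record$compound,
                          temperature = X[, 1], pressure = X[, 2],
                          molecular_weight = X[, 3], melting_point = X[, 4])
  # temperatures/pressures must stay positive for the schema; reflect if needed
  perturbed$temperature <- abs(perturbed$temperature)
  perturbed$pressure <- abs(perturbed$pressure)
  perturbed$molecular_weight <- pmax(abs(perturbed$molecular_weight), 1e-6)
  yhat <- predict_fn(solubility_dataset(perturbed))
  d <- sqrt(rowSums(Z^2))
  w <- exp(-d^2 / kernel_width^2)
  active <- !zero_var
  fit <- stats::lm.wfit(cbind(1, Z[, active, drop = FALSE]), yhat, w)
  coefs <- numeric(4)
  names(coefs) <- FEATURE_COLS
  coefs[active] <- fit$coefficients[-1]
  fitted <- cbind(1, Z[, active, drop = FALSE]) %*% fit$coefficients
  ybar <- sum(w * yhat) / sum(w)
  ss_tot <- sum(w * (yhat - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * (yhat - fitted)^2) / ss_tot else NA_real_
  structure(list(scores = coefs, intercept = fit$coefficients[1],
                 r_squared = r2, zero_variance = zero_var,
                 kernel_width = kernel_width),
            class = "attribution")
}
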