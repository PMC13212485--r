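#' Default hyperparameter search space for a base learner
#'
#' Three tuned hyperparameters: learning rate, maximum tree depth, and the
#' number of boosting iterations. Depth upper bounds are the published
#' search-space bounds of the two learners (74 for the classic variant, 139
#' for the histogram variant); the learning-rate interval [0.01, 0.3] and
#' estimator interval [50, 300] contain the published tuned optima (0.05,
#' 0.145, 147) with headroom.
#'
#' @param kind `"gb"` (classic gradient boosting) or `"hgb"`
#'   (histogram-binned gradient boosting).
#' @return A `hyperparameter_space` list of [low, high] intervals.
#' @export
default_space <- function(kind = c("gb", "hgb")) {
  kind <- match.arg(kind)
  structure(list(
    kind = kind,
    learning_rate = c(0.01, 0.3),
    max_depth = c(2L, if (kind == "gb") 74L else 139L),
    n_estimators = c(50L, 300L)
  ), class = "hyperparameter_space")
}

#' Decode a continuous optimizer position into a learner configuration
#'
#' Each coordinate in [0,1] is clipped, then mapped affinely onto its
#' interval; integer dimensions are rounded half-up. This is the bridge
#' between the continuous metaheuristic search space and the discrete
#' hyperparameters.
#'
#' @param space A `hyperparameter_space` from [default_space()].
#' @param position Numeric vector of length 3:
#'   (learning_rate, max_depth, n_estimators) coordinates.
#' @param seed Seed recorded in the configuration (training determinism).
#' @return A `learner_config` list.
#' @export
decode_position <- function(space, position, seed = 1) {
  stopifnot(inherits(space, "hyperparameter_space"))
  if (length(position) != 3) stop_ghef("position must have length 3")
  p <- pmin(pmax(as.numeric(position), 0), 1)
  affine <- function(iv, x) iv[1] + x * (iv[2] - iv[1])
  learner_config(
    kind = space$kind,
    learning_rate = affine(space$learning_rate, p[1]),
    max_depth = as.integer(round_half_up(affine(as.numeric(space$max_depth), p[2]))),
    n_estimators = as.integer(round_half_up(affine(as.numeric(space$n_estimators), p[3]))),
    seed = seed)
}

#' Learner configuration
#'
#' @param kind `"gb"` or `"hgb"`.
#' @param learning_rate Shrinkage in (0, 1].
#' @param max_depth Maximum tree depth (>= 1).
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param seed Integer seed.
#' @return A `learner_config` list.
#' @export
learner_config <- function(kind = c("gb", "hgb"), learning_rate = 0.1,
                           max_depth = 3L, n_estimators = 100L, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            max_depth >= 1, n_estimators >= 1)
  structure(list(kind = kind, learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed)),
            class = "learner_config")
}

#' Reference member configurations
#'
#' Fixed (non-tuned) configurations used for the plain single-model
#' variants: the published tuned learning rates (0.05 classic, 0.145
#' histogram) and estimator count (147 for the classic learner; 150 for the
#' histogram learner, whose tuned count was not published), with a moderate
#' depth of 3 (classic) / 6 (histogram).
#'
#' @param kind `"gb"` or `"hgb"`.
#' @param seed Integer seed.
#' @return A [learner_config()].
#' @export
reference_config <- function(kind = c("gb", "hgb"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "gb") {
    learner_config("gb", learning_rate = 0.05, max_depth = 3L,
                   n_estimators = 147L, seed = seed)
  } else {
    learner_config("hgb", learning_rate = 0.145, max_depth = 6L,
                   n_estimators = 150L, seed = seed)
  }
}

#' Train a gradient-boosted base learner
#'
#' Both variants are fitted with xgboost under squared-error loss on the
#' fixed feature tuple (temperature, pressure, molecular_weight,
#' melting_point): the classic variant uses exact greedy splits, the
#' histogram variant binned splits (256 bins). Training is single-threaded
#' and seeded, so refitting with identical config and data reproduces
#' identical predictions.
#'
#' @param config A [learner_config()].
#' @param train A [solubility_dataset()] with solubility values, n >= 5.
#' @return A `trained_learner` (config, fitted booster, feature order).
#' @export
train_learner <- function(config, train) {
  stopifnot(inherits(config, "learner_config"))
  train <- solubility_dataset(train)
  if (nrow(train) < 5) stop_ghef("need at least 5 training records")
  X <- feature_matrix(train)
  y <- target_vector(train)
  params <- list(
    objective = "reg:squarederror",
    eta = config$learning_rate,
    max_depth = config$max_depth,
    tree_method = if (config$kind == "gb") "exact" else "hist",
    max_bin = 256,
    lambda = 0, alpha = 0,
    nthread = 1,
    seed = config$seed)
  if (config$kind == "gb") params$max_bin <- NULL
  booster <- with_seed(config$seed, {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = config$n_estimators, verbose = 0)
  })
  structure(list(config = config, booster = booster,
                 feature_order = FEATURE_COLS),
            class = "trained_learner")
}

#' Predict solubility with a trained base learner
#'
#' Raw model output in (g/L) x 10, order-preserving, one value per record.
#' No clipping is applied by default: boosted trees can legitimately emit
#' small negative values for near-zero solubilities, and silently clamping
#' would bias error statistics. Set `clip_negative = TRUE` to floor
#' deployment predictions at zero.
#'
#' @param model A `trained_learner`.
#' @param records A [solubility_dataset()] (solubility may be absent).
#' @param clip_negative Clamp predictions at 0 (default FALSE).
#' @return Numeric vector of predictions.
#' @export
predict_learner <- function(model, records, clip_negative = FALSE) {
  stopifnot(inherits(model, "trained_learner"))
  if (is.data.frame(records) && nrow(records) == 0) return(numeric(0))
  records <- solubility_dataset(records)
  X <- feature_matrix(records)[, model$feature_order, drop = FALSE]
  pred <- predict(model$booster, xgboost::xgb.DMatrix(X))
  if (clip_negative) pred <- pmax(pred, 0)
  as.numeric(pred)
}
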