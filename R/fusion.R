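#' Fit simplex weights for a weighted-average ensemble
#'
#' Minimizes the RMSE of the weighted prediction against `y` over the
#' probability simplex. The metaheuristic searches `[0,1]^M` and each
#' position is repaired onto the simplex by normalization; the M unit
#' vectors and the uniform vector are seeded into the initial population,
#' so the fitted ensemble is never worse on the fitting set than its best
#' single member.
#'
#' @param prediction_matrix n x M matrix, one column per base learner.
#' @param y Length-n target vector.
#' @param eefo Optional [eefo_config()]; defaults to the desk profile on
#'   `[0,1]^M` with the unit vectors seeded.
#' @param seed Seed used when `eefo` is NULL.
#' @return A `weight_vector`: non-negative weights summing to one, with the
#'   achieved RMSE as attribute `rmse`.
#' @export
fit_weights <- function(prediction_matrix, y, eefo = NULL, seed = 1) {
  P <- as.matrix(prediction_matrix)
  M <- ncol(P)
  if (M < 2) stop_ghef("need at least 2 base learners")
  if (length(y) == 0) stop_ghef("empty fitting set")
  if (nrow(P) != length(y)) stop_ghef("prediction matrix and y disagree on n")
  normalize <- function(x) {
    x <- pmax(x, 0)
    s <- sum(x)
    if (s <= 0) rep(1 / M, M) else x / s
  }
  if (is.null(eefo)) {
    init <- rbind(diag(M), matrix(1 / M, 1, M))
    eefo <- eefo_desk_profile(bounds = cbind(rep(0, M), rep(1, M)),
                              seed = derive_seed(seed, "weights"), init = init)
  }
  objective <- function(x) rmse(y, drop(P %*% normalize(x)))
  res <- eefo_optimize(objective, eefo)
  w <- normalize(res$best_position)
  structure(w, class = "weight_vector", rmse = objective(res$best_position))
}

#' Weighted-average fused prediction
#'
#' @param weights A `weight_vector` (or any non-negative vector summing
#'   to 1 within 1e-8).
#' @param prediction_matrix n x M matrix of member predictions.
#' @return Length-n fused prediction vector.
#' @export
weighted_predict <- function(weights, prediction_matrix) {
  P <- as.matrix(prediction_matrix)
  w <- as.numeric(weights)
  if (ncol(P) != length(w)) stop_ghef("weight/prediction dimension mismatch")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop_ghef("weights must be non-negative and sum to 1")
  }
  drop(P %*% w)
}

#' Map validation RMSE to a source reliability
#'
#' `r = 1 / (1 + rmse / y_scale)`, capped at 0.999 so the ignorance mass of
#' the discounted evidence never vanishes. Dimensionless, monotone
#' decreasing in RMSE: more accurate learners contribute stronger evidence.
#'
#' @param validation_rmse Non-negative per-learner RMSE(s).
#' @param y_scale Positive scale of the targets (SD of training solubility).
#' @return Reliabilities in (0, 0.999].
#' @export
reliability_from_rmse <- function(validation_rmse, y_scale) {
  if (any(validation_rmse < 0)) stop_ghef("rmse must be non-negative")
  if (!is.numeric(y_scale) || y_scale <= 0) stop_ghef("y_scale must be positive")
  pmin(1 / (1 + validation_rmse / y_scale), 0.999)
}

#' Discretization frame over the solubility axis
#'
#' K equal-width bins spanning the training target range padded by 5% of
#' the range on each side, plus the ignorance set (the whole frame).
#'
#' @param y Training solubility values (used for the span), or `NULL` when
#'   `edges` is given.
#' @param k Number of bins (>= 2), default 20.
#' @param edges Explicit strictly increasing bin edges (overrides `y`/`k`).
#' @return A `dst_frame` with elements `edges` (length K+1), `centers`, `k`.
#' @export
dst_frame <- function(y = NULL, k = 20, edges = NULL) {
  if (is.null(edges)) {
    stopifnot(!is.null(y), k >= 2)
    rng <- range(y)
    pad <- 0.05 * diff(rng)
    if (pad == 0) pad <- max(abs(rng[1]), 1) * 0.05
    edges <- seq(rng[1] - pad, rng[2] + pad, length.out = k + 1)
  }
  edges <- as.numeric(edges)
  if (length(edges) < 3 || any(diff(edges) <= 0)) {
    stop_ghef("edges must be strictly increasing with at least 2 bins")
  }
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 k = length(edges) - 1L),
            class = "dst_frame")
}

#' Build a reliability-discounted mass function from one model prediction
#'
#' Evidence is a Gaussian centered at the prediction with the model's
#' validation RMSE as bandwidth, integrated over each bin and renormalized
#' over the frame; the singleton masses get the reliability `r` and the
#' ignorance set the remaining `1 - r`. If the frame does not cover
#' `prediction +/- 4 * bandwidth` the mass is flagged as truncated.
#'
#' @param prediction Point prediction, (g/L) x 10.
#' @param bandwidth Positive Gaussian SD (validation RMSE of the model).
#' @param reliability Discount factor in [0, 1).
#' @param frame A [dst_frame()].
#' @return A `mass_function`: `frame`, `m` (length K), `m_theta`,
#'   `truncated` flag.
#' @export
build_mass_function <- function(prediction, bandwidth, reliability, frame) {
  stopifnot(inherits(frame, "dst_frame"))
  if (bandwidth <= 0) stop_ghef("bandwidth must be positive")
  if (reliability < 0 || reliability >= 1) stop_ghef("reliability must be in [0, 1)")
  edges <- frame$edges
  cdf <- stats::pnorm(edges, mean = prediction, sd = bandwidth)
  p <- diff(cdf)
  total <- sum(p)
  if (total <= 0) {
    # prediction far outside the frame: put the evidence on the nearest bin
    p <- numeric(frame$k)
    p[if (prediction <= edges[1]) 1 else frame$k] <- 1
    total <- 1
  }
  truncated <- (prediction - 4 * bandwidth < edges[1]) ||
    (prediction + 4 * bandwidth > edges[length(edges)])
  mass_function(frame, reliability * p / total, 1 - reliability,
                truncated = truncated)
}

mass_function <- function(frame, m, m_theta, truncated = FALSE) {
  stopifnot(inherits(frame, "dst_frame"), length(m) == frame$k)
  if (any(m < -1e-12) || m_theta < -1e-12) stop_ghef("masses must be non-negative")
  s <- sum(m) + m_theta
  if (abs(s - 1) > 1e-9) stop_ghef("masses must sum to 1 (got %.12f)", s)
  structure(list(frame = frame, m = pmax(m, 0), m_theta = max(m_theta, 0),
                 truncated = truncated),
            class = "mass_function")
}

#' Vacuous mass function (total ignorance)
#'
#' @param frame A [dst_frame()].
#' @return A `mass_function` with all mass on the ignorance set.
#' @export
vacuous_mass <- function(frame) {
  mass_function(frame, numeric(frame$k), 1)
}

#' Combine two mass functions by Dempster's rule
#'
#' For the singleton-plus-ignorance structure used here the rule is closed:
#' conflict `K = sum_{i != j} m1(b_i) m2(b_j)`, combined singleton mass
#' `m(b_k) = (m1_k m2_k + m1_k m2_Theta + m1_Theta m2_k) / (1 - K)` and
#' `m(Theta) = m1_Theta m2_Theta / (1 - K)`. Total conflict (K ~ 1) is an
#' explicit error.
#'
#' @param m1,m2 `mass_function`s over the same frame.
#' @return Combined `mass_function` with attribute `conflict`.
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  if (!isTRUE(all.equal(m1$frame$edges, m2$frame$edges))) {
    stop_ghef("mass functions live on different frames")
  }
  s1 <- sum(m1$m); s2 <- sum(m2$m)
  agree <- sum(m1$m * m2$m)
  conflict <- s1 * s2 - agree
  if (conflict >= 1 - 1e-12) stop_ghef("total conflict between sources (K = %.12f)", conflict)
  norm <- 1 - conflict
  m <- (m1$m * m2$m + m1$m * m2$m_theta + m1$m_theta * m2$m) / norm
  m_theta <- m1$m_theta * m2$m_theta / norm
  out <- mass_function(m1$frame, m, m_theta,
                       truncated = m1$truncated || m2$truncated)
  attr(out, "conflict") <- conflict
  out
}

#' Belief and plausibility of a solubility interval
#'
#' Belief sums the masses of bins fully inside `[a, b]`; plausibility sums
#' the masses of bins intersecting it, plus the ignorance mass whenever the
#' interval intersects the frame at all.
#'
#' @param mass A `mass_function`.
#' @param interval Numeric `c(a, b)` with a <= b.
#' @return Named vector `c(belief =, plausibility =)`.
#' @export
bel_pl <- function(mass, interval) {
  stopifnot(inherits(mass, "mass_function"), length(interval) == 2)
  a <- interval[1]; b <- interval[2]
  if (a > b) stop_ghef("interval must satisfy a <= b")
  lo <- mass$frame$edges[-length(mass$frame$edges)]
  hi <- mass$frame$edges[-1]
  inside <- lo >= a & hi <= b
  intersects <- hi > a & lo < b
  bel <- sum(mass$m[inside])
  if (all(inside)) bel <- bel + mass$m_theta  # Theta itself lies inside [a, b]
  pl <- sum(mass$m[intersects]) +
    if (b > mass$frame$edges[1] && a < mass$frame$edges[length(mass$frame$edges)]) {
      mass$m_theta
    } else 0
  c(belief = bel, plausibility = pl)
}

#' Pignistic point estimate of a mass function
#'
#' The ignorance mass is split uniformly over the K bins
#' (`BetP(b_k) = m(b_k) + m(Theta)/K`) and the estimate is the
#' BetP-weighted mean of the bin centers; it always lies inside the frame.
#'
#' @param mass A `mass_function`.
#' @return Point estimate in (g/L) x 10.
#' @export
pignistic_predict <- function(mass) {
  stopifnot(inherits(mass, "mass_function"))
  betp <- mass$m + mass$m_theta / mass$frame$k
  sum(betp * mass$frame$centers)
}

#' Evidence-fused prediction from several trained learners
#'
#' Per record, each model contributes a reliability-discounted Gaussian
#' mass function ([build_mass_function()]) with its validation RMSE as
#' bandwidth; the masses are folded with Dempster's rule and the pignistic
#' transform extracts the fused point value. The reported conflict is
#' `1 - prod(1 - K_step)` over the sequential combinations.
#'
#' @param models List of `trained_learner`s (>= 2).
#' @param reliabilities Per-model reliabilities from
#'   [reliability_from_rmse()].
#' @param bandwidths Per-model positive bandwidths (validation RMSEs).
#' @param frame A [dst_frame()].
#' @param records [solubility_dataset()] to predict.
#' @return A data.frame (class `fused_prediction`): `prediction`,
#'   `conflict`, `belief` and `plausibility` of the central 95% evidence
#'   interval, `truncated`; the per-record combined masses are in
#'   attribute `masses`.
#' @export
dst_predict <- function(models, reliabilities, bandwidths, frame, records) {
  stopifnot(length(models) >= 2,
            length(reliabilities) == length(models),
            length(bandwidths) == length(models))
  preds <- lapply(models, predict_learner, records = records)
  n <- length(preds[[1]])
  out <- data.frame(prediction = numeric(n), conflict = numeric(n),
                    belief = numeric(n), plausibility = numeric(n),
                    truncated = logical(n))
  masses <- vector("list", n)
  for (idx in seq_len(n)) {
    combined <- NULL
    keep <- 1
    for (mi in seq_along(models)) {
      m <- build_mass_function(preds[[mi]][idx], bandwidths[mi],
                               reliabilities[mi], frame)
      if (is.null(combined)) {
        combined <- m
      } else {
        combined <- tryCatch(dempster_combine(combined, m),
                             error = function(e) {
                               stop_ghef("record %d: %s", idx, conditionMessage(e))
                             })
        keep <- keep * (1 - attr(combined, "conflict"))
      }
    }
    est <- pignistic_predict(combined)
    # central 95% evidence interval around the estimate
    half <- 1.96 * min(bandwidths)
    bp <- bel_pl(combined, c(est - half, est + half))
    out$prediction[idx] <- est
    out$conflict[idx] <- 1 - keep
    out$belief[idx] <- bp["belief"]
    out$plausibility[idx] <- bp["plausibility"]
    out$truncated[idx] <- combined$truncated
    masses[[idx]] <- combined
  }
  attr(out, "masses") <- masses
  class(out) <- c("fused_prediction", "data.frame")
  out
}
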