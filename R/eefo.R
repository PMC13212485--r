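#' Electric Eel Foraging Optimization configuration
#'
#' Settings for the population metaheuristic used throughout the package
#' for hyperparameter tuning and ensemble-weight fitting. Defaults are the
#' published run settings: population 30, at most 200 iterations, early
#' stop after 20 consecutive iterations without improvement.
#'
#' @param bounds Two-column matrix (low, high) with one row per dimension,
#'   or a list of c(low, high) pairs.
#' @param population_size Number of candidate solutions (>= 2), default 30.
#' @param max_iterations Maximum optimization cycles, default 200.
#' @param patience Iterations without improvement before stopping, default 20.
#' @param improvement_tol Absolute fitness improvement that resets the
#'   patience counter, default 1e-8.
#' @param seed Integer seed.
#' @param init Optional matrix of positions (rows) seeded into the initial
#'   population, e.g. known incumbents such as a space midpoint or the unit
#'   weight vectors.
#' @return An `eefo_config` list.
#' @export
eefo_config <- function(bounds, population_size = 30, max_iterations = 200,
                        patience = 20, improvement_tol = 1e-8, seed = 1,
                        init = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (any(bounds[, 1] >= bounds[, 2])) stop_ghef("each bound must satisfy low < high")
  stopifnot(population_size >= 2, max_iterations >= 1, patience >= 1,
            improvement_tol >= 0)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = nrow(bounds))
    init <- clip_bounds(init, bounds)
  }
  structure(list(bounds = bounds, population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 improvement_tol = improvement_tol, seed = as.integer(seed),
                 init = init),
            class = "eefo_config")
}

#' Desk-scale optimizer profile
#'
#' A reduced profile (population 15, 50 iterations) for interactive and
#' test use; [eefo_config()] defaults are the full published profile.
#'
#' @inheritParams eefo_config
#' @return An `eefo_config`.
#' @export
eefo_desk_profile <- function(bounds, seed = 1, init = NULL) {
  eefo_config(bounds, population_size = 15, max_iterations = 50,
              patience = 20, seed = seed, init = init)
}

clip_bounds <- function(X, bounds) {
  X <- matrix(X, ncol = nrow(bounds))
  for (d in seq_len(nrow(bounds))) {
    X[, d] <- pmin(pmax(X[, d], bounds[d, 1]), bounds[d, 2])
  }
  X
}

#' Energy factor schedule
#'
#' `E = 4 * draw * (1 - t / max_iterations)` with `draw ~ U(0,1)`. E > 1
#' triggers an exploration (interacting) move, E <= 1 an exploitation move;
#' the factor decays with iteration so the population shifts from global
#' exploration to local exploitation. The constant 4 sets the initial
#' exploration probability to 3/4.
#'
#' @param t Iteration index, 0-based, 0 <= t < max_iterations.
#' @param config An [eefo_config()].
#' @param draw A uniform(0,1) variate.
#' @return Dimensionless energy factor E >= 0.
#' @export
energy_factor <- function(t, config, draw) {
  stopifnot(t >= 0, t < config$max_iterations)
  4 * draw * (1 - t / config$max_iterations)
}

#' Propose a candidate position for one eel
#'
#' Exploration (E > 1): interacting move toward/beyond a random reference
#' `v = ref + alpha * (ref - x)` with `alpha ~ N(0,1)` and the reference a
#' 50/50 mix of a random peer and a random point in the bounds.
#' Exploitation (E <= 1): one of resting (local perturbation with radius
#' proportional to `(1 - t/T_max)` times the box size), hunting
#' (`x_best + r * (x_best - x)`), or migrating (`x + r * (x_best - x_peer)`),
#' chosen uniformly. The candidate is clipped into the bounds.
#'
#' @param state List with elements `positions` (matrix), `best` (vector),
#'   `t` (0-based iteration), `max_iterations`.
#' @param i Index of the moving eel.
#' @param E Energy factor from [energy_factor()].
#' @param bounds Bounds matrix.
#' @return Candidate position vector within bounds.
#' @export
propose_candidate <- function(state, i, E, bounds) {
  X <- state$positions
  x <- X[i, ]
  dim_n <- ncol(X)
  span <- bounds[, 2] - bounds[, 1]
  if (E > 1) {
    ref <- if (stats::runif(1) < 0.5) {
      j <- sample.int(nrow(X), 1)
      X[j, ]
    } else {
      bounds[, 1] + stats::runif(dim_n) * span
    }
    v <- ref + stats::rnorm(1) * (ref - x)
  } else {
    move <- sample.int(3, 1)
    if (move == 1) { # resting
      radius <- 0.1 * (1 - state$t / state$max_iterations) * span
      v <- x + stats::runif(dim_n, -1, 1) * radius
    } else if (move == 2) { # hunting
      v <- state$best + stats::runif(1) * (state$best - x)
    } else { # migrating
      j <- sample.int(nrow(X), 1)
      v <- x + stats::runif(1) * (state$best - X[j, ])
    }
  }
  drop(clip_bounds(matrix(v, nrow = 1), bounds))
}

#' Greedy selection between incumbent and candidate
#'
#' Minimization: the incumbent is kept when its fitness is less than or
#' equal to the candidate's (ties keep the incumbent). Non-finite candidate
#' fitness is treated as +Inf, i.e. rejected, never an error.
#'
#' @param x Incumbent position.
#' @param fx Incumbent fitness.
#' @param v Candidate position.
#' @param fv Candidate fitness.
#' @return List (position, fitness, accepted).
#' @export
greedy_select <- function(x, fx, v, fv) {
  if (!is.finite(fv)) fv <- Inf
  if (fx <= fv) list(position = x, fitness = fx, accepted = FALSE)
  else list(position = v, fitness = fv, accepted = TRUE)
}

#' Bound-constrained minimization by Electric Eel Foraging Optimization
#'
#' Population search with the energy-factor schedule of [energy_factor()],
#' the movement operators of [propose_candidate()] and greedy replacement
#' per eel ([greedy_select()]). The best-so-far fitness trajectory is
#' monotone non-increasing by construction. Stops early when the best
#' fitness fails to improve by more than `improvement_tol` for `patience`
#' consecutive iterations. Fully deterministic given the config seed.
#'
#' @param objective Function mapping a position vector to a scalar;
#'   non-finite values are treated as +Inf.
#' @param config An [eefo_config()].
#' @return An `eefo_result`: `best_position`, `best_fitness`, `trajectory`
#'   (per-iteration best fitness), `iterations_run`, `converged_early`,
#'   `evaluations`.
#' @export
eefo_optimize <- function(objective, config) {
  stopifnot(inherits(config, "eefo_config"))
  bounds <- config$bounds
  dim_n <- nrow(bounds)
  pop <- config$population_size
  evals <- 0L
  f <- function(x) {
    evals <<- evals + 1L
    val <- tryCatch(objective(x), error = function(e) Inf)
    if (length(val) != 1 || !is.finite(val)) Inf else as.numeric(val)
  }
  with_seed(config$seed, {
    X <- matrix(stats::runif(pop * dim_n), pop, dim_n)
    X <- sweep(sweep(X, 2, bounds[, 2] - bounds[, 1], `*`), 2, bounds[, 1], `+`)
    if (!is.null(config$init)) {
      k <- min(nrow(config$init), pop)
      X[seq_len(k), ] <- config$init[seq_len(k), , drop = FALSE]
    }
    fit <- apply(X, 1, f)
    best_i <- which.min(fit)
    best_x <- X[best_i, ]
    best_f <- fit[best_i]
    trajectory <- numeric(0)
    stall <- 0L
    iters <- 0L
    converged <- FALSE
    for (t in seq_len(config$max_iterations) - 1L) {
      state <- list(positions = X, best = best_x, t = t,
                    max_iterations = config$max_iterations)
      for (i in seq_len(pop)) {
        E <- energy_factor(t, config, stats::runif(1))
        v <- propose_candidate(state, i, E, bounds)
        sel <- greedy_select(X[i, ], fit[i], v, f(v))
        X[i, ] <- sel$position
        fit[i] <- sel$fitness
        state$positions <- X
      }
      iters <- iters + 1L
      new_best <- min(fit)
      if (best_f - new_best > config$improvement_tol) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (new_best < best_f) {
        best_i <- which.min(fit)
        best_x <- X[best_i, ]
        best_f <- new_best
      }
      trajectory <- c(trajectory, best_f)
      if (stall >= config$patience) {
        converged <- TRUE
        break
      }
    }
    structure(list(best_position = best_x, best_fitness = best_f,
                   trajectory = trajectory, iterations_run = iters,
                   converged_early = converged, evaluations = evals),
              class = "eefo_result")
  })
}

#' @export
print.eefo_result <- function(x, ...) {
  cat(sprintf("<eefo_result> best fitness %.6g after %d iteration(s)%s, %d evaluations\n",
              x$best_fitness, x$iterations_run,
              if (x$converged_early) " (early stop)" else "", x$evaluations))
  invisible(x)
}

#' Export a convergence trajectory as a data.frame
#'
#' @param result An `eefo_result`.
#' @param path Optional CSV path (columns iteration, best_fitness).
#' @return data.frame, invisibly when written.
#' @export
trajectory_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "eefo_result"))
  df <- data.frame(iteration = seq_along(result$trajectory),
                   best_fitness = result$trajectory)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Tune a base learner's hyperparameters by EEFO
#'
#' Minimizes the mean k-fold cross-validation RMSE of the decoded learner
#' configuration over the unit cube mapped onto [default_space()]. Folds are
#' fixed once per tuning run. The space midpoint is seeded into the initial
#' population, so the tuned configuration is never worse (on the tuning
#' folds) than the midpoint incumbent. The best configuration is refit on
#' all of `train`.
#'
#' @param kind `"gb"` or `"hgb"`.
#' @param train Training [solubility_dataset()].
#' @param k Number of CV folds (default 5).
#' @param eefo An [eefo_config()] on `[0,1]^3` bounds; if `NULL`, the full
#'   default profile is used.
#' @param seed Integer seed (folds and learner seeds derive from it).
#' @return List: `config` (tuned [learner_config()]), `model` (refit
#'   `trained_learner`), `cv_rmse` (tuned objective value), `result`
#'   (`eefo_result`).
#' @export
tune_learner <- function(kind, train, k = 5, eefo = NULL, seed = 1) {
  train <- solubility_dataset(train)
  space <- default_space(kind)
  if (is.null(eefo)) {
    eefo <- eefo_config(bounds = matrix(c(0, 0, 0, 1, 1, 1), 3, 2),
                        seed = derive_seed(seed, "tune", kind),
                        init = matrix(0.5, 1, 3))
  }
  folds <- kfold_indices(nrow(train), k, derive_seed(seed, "folds", kind))
  objective <- function(position) {
    cfg <- decode_position(space, position, seed = derive_seed(seed, "fit", kind))
    cv_rmse_for_config(cfg, train, folds)
  }
  res <- eefo_optimize(objective, eefo)
  config <- decode_position(space, res$best_position,
                            seed = derive_seed(seed, "fit", kind))
  list(config = config, model = train_learner(config, train),
       cv_rmse = res$best_fitness, result = res)
}

# mean held-out RMSE of one config across fixed folds
cv_rmse_for_config <- function(config, train, folds) {
  errs <- vapply(seq_len(max(folds)), function(fold) {
    hold <- folds == fold
    model <- train_learner(config, train[!hold, , drop = FALSE])
    rmse(target_vector(solubility_dataset(train[hold, , drop = FALSE])),
         predict_learner(model, train[hold, , drop = FALSE]))
  }, numeric(1))
  mean(errs)
}
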