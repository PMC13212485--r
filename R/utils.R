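#' @keywords internal
"_PACKAGE"

# Feature columns in canonical order; every model consumes them in this order.
FEATURE_COLS <- c("temperature", "pressure", "molecular_weight", "melting_point")
ALL_COLS <- c("compound", FEATURE_COLS, "solubility")

#' Derive a reproducible child seed from a master seed
#'
#' Folds the master seed and any number of integer or character tags into a
#' single non-negative integer below 2^31 - 1 via a polynomial hash. Used so
#' that every random stage (generator stream, fold shuffle, bootstrap
#' replicate, optimizer run) owns an independent, replayable seed.
#'
#' @param seed Integer master seed.
#' @param ... Integer or character tags naming the stage.
#' @return A single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|")) else as.numeric(tag)
    for (v in codes) {
      h <- (h * 31 + (v %% m) + 17) %% m
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# population standard deviation (divide by n, not n-1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stop_ghef <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
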