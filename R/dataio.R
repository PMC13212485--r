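#' Construct a solubility dataset
#'
#' A `solubility_dataset` is a data.frame with one row per equilibrium
#' solubility measurement in supercritical CO2 and the fixed schema
#' `compound` (label, optional), `temperature` (K), `pressure` (MPa),
#' `molecular_weight` (g/mol), `melting_point` (degrees C) and `solubility`
#' ((g/L) x 10, optional for prediction-only records). Solubility keeps the
#' (g/L) x 10 working unit throughout the package; no conversion is applied.
#'
#' @param df A data.frame carrying the schema columns.
#' @param provenance Free-text tag recording where the records came from.
#' @return A `solubility_dataset` (data.frame subclass).
#' @export
solubility_dataset <- function(df, provenance = "user") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(FEATURE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop_ghef("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"compound" %in% names(df)) df$compound <- NA_character_
  if (!"solubility" %in% names(df)) df$solubility <- NA_real_
  df <- df[, ALL_COLS]
  df$compound <- as.character(df$compound)
  for (col in c(FEATURE_COLS, "solubility")) {
    if (!is.numeric(df[[col]])) stop_ghef("column '%s' must be numeric", col)
  }
  if (nrow(df) < 1) stop_ghef("dataset must contain at least one record")
  for (col in FEATURE_COLS) {
    if (anyNA(df[[col]])) stop_ghef("column '%s' contains missing values", col)
  }
  if (any(df$temperature <= 0)) stop_ghef("temperature must be positive (kelvin)")
  if (any(df$pressure <= 0)) stop_ghef("pressure must be positive (MPa)")
  if (any(df$molecular_weight <= 0)) stop_ghef("molecular_weight must be positive")
  sol <- df$solubility
  if (any(!is.na(sol) & sol < 0)) stop_ghef("solubility must be non-negative when present")
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("solubility_dataset", "data.frame"))
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("<solubility_dataset> %d records, %d compound(s) [%s]\n",
              nrow(x), length(unique(x$compound)),
              attr(x, "provenance") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a solubility dataset from CSV
#'
#' Comma-delimited, "." decimal separator, UTF-8, header row required. The
#' `compound` column is optional; the four feature columns and `solubility`
#' must be present (solubility cells may be empty for prediction-only rows).
#'
#' @param path Path to a CSV file.
#' @return A [solubility_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_ghef("file not found: %s", path)
  if (file.size(path) == 0) stop_ghef("empty file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) stop_ghef("no data rows in %s", path)
  missing_cols <- setdiff(c(FEATURE_COLS, "solubility"), names(df))
  if (length(missing_cols) > 0) {
    stop_ghef("%s: missing required column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  }
  for (col in c(FEATURE_COLS, "solubility")) {
    raw <- df[[col]]
    if (is.logical(raw) && all(is.na(raw))) {
      df[[col]] <- as.numeric(raw)   # fully empty column (prediction-only)
    } else if (is.character(raw)) {
      conv <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & nzchar(trimws(raw)) & is.na(conv))
      if (length(bad) > 0) {
        stop_ghef("%s: non-numeric value '%s' in column '%s', row %d",
                  path, raw[bad[1]], col, bad[1])
      }
      df[[col]] <- conv
    }
  }
  solubility_dataset(df, provenance = path)
}

#' Write a solubility dataset to CSV
#'
#' Canonical column order (compound, temperature, pressure, molecular_weight,
#' melting_point, solubility) at full double precision; missing solubility is
#' written as an empty cell.
#'
#' @param dataset A [solubility_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dataset <- solubility_dataset(dataset)
  out <- as.data.frame(dataset)[, ALL_COLS]
  for (col in c(FEATURE_COLS, "solubility")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ghef("cannot write to %s", path)
  invisible(path)
}

#' Per-compound design summary statistics
#'
#' For each compound and each variable reports min, max, arithmetic mean and
#' POPULATION standard deviation (divide by n). The default `mode = "level"`
#' summarizes the distinct design levels of each variable, which is how
#' factorial solubility designs are conventionally tabulated: four equally
#' spaced temperature levels 308-338 K have mean 323 and population SD
#' sqrt(125) = 11.1803 regardless of how many replicate records share each
#' level. `mode = "record"` summarizes raw per-record values instead.
#'
#' @param dataset A [solubility_dataset()].
#' @param mode `"level"` (default) or `"record"`.
#' @return A data.frame with columns compound, variable, min, max, mean, sd,
#'   n (count of levels or records), of class `solubility_summary`.
#' @export
summarize_dataset <- function(dataset, mode = c("level", "record")) {
  dataset <- solubility_dataset(dataset)
  mode <- match.arg(mode)
  vars <- c(FEATURE_COLS, "solubility")
  res <- list()
  for (cmp in unique(dataset$compound)) {
    sub <- dataset[dataset$compound %in% cmp | (is.na(cmp) & is.na(dataset$compound)), ]
    for (v in vars) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      if (mode == "level") x <- sort(unique(x))
      res[[length(res) + 1]] <- data.frame(
        compound = cmp, variable = v,
        min = min(x), max = max(x), mean = mean(x), sd = pop_sd(x),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("solubility_summary", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Serialize a summary table to JSON keyed by compound then variable
#'
#' @param summary A `solubility_summary` from [summarize_dataset()].
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "solubility_summary"))
  by_cmp <- split(summary, summary$compound)
  obj <- lapply(by_cmp, function(s) {
    by_var <- split(s, s$variable)
    lapply(by_var, function(r) list(min = r$min, max = r$max,
                                    mean = r$mean, sd = r$sd, n = r$n))
  })
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Split a dataset into train and test partitions
#'
#' Samples `round(n * fraction)` test records without replacement,
#' stratified by compound when compound labels are present (per-compound
#' quotas by largest remainder so the total matches the unstratified count).
#' Deterministic given `seed`.
#'
#' @param dataset A [solubility_dataset()].
#' @param fraction Test proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train`, `test` (both datasets), `test_idx`
#'   (row indices of the test set in the input), `seed`, `fraction`.
#' @export
split_train_test <- function(dataset, fraction = 0.2, seed = 1) {
  dataset <- solubility_dataset(dataset)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop_ghef("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(dataset)
  n_test <- round_half_up(n * fraction)
  if (n_test < 1) stop_ghef("fraction too small: no test records (n * fraction < 0.5)")
  if (n_test >= n) stop_ghef("fraction too large: no training records left")

  groups <- dataset$compound
  if (all(is.na(groups))) groups <- rep("all", n)
  idx_by_grp <- split(seq_len(n), groups)
  raw <- vapply(idx_by_grp, length, integer(1)) * fraction
  quota <- floor(raw)
  rem <- n_test - sum(quota)
  if (rem > 0) {
    order_frac <- order(raw - quota, decreasing = TRUE)
    quota[order_frac[seq_len(rem)]] <- quota[order_frac[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_frac <- order(raw - quota, decreasing = FALSE)
    take <- order_frac[quota[order_frac] > 0][seq_len(-rem)]
    quota[take] <- quota[take] - 1
  }
  test_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(seq_along(idx_by_grp), function(g) {
      ids <- idx_by_grp[[g]]
      if (quota[g] == 0) return(integer(0))
      ids[sample.int(length(ids), quota[g])]
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  list(train = solubility_dataset(dataset[-test_idx, , drop = FALSE],
                                  provenance = "train split"),
       test = solubility_dataset(dataset[test_idx, , drop = FALSE],
                                 provenance = "test split"),
       test_idx = test_idx, seed = seed, fraction = fraction)
}

# feature matrix in the fixed canonical order
feature_matrix <- function(dataset) {
  as.matrix(as.data.frame(dataset)[, FEATURE_COLS])
}

# targets; errors if any are missing (training path)
target_vector <- function(dataset) {
  y <- dataset$solubility
  if (anyNA(y)) stop_ghef("dataset contains records without solubility values")
  y
}
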