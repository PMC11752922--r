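# Feature schema, cohort validation, CSV I/O, and preprocessing
# (IQR outlier rule, standardization, test/fold splitting).

#' Default sepsis feature schema
#'
#' Returns the 17-column schema used throughout the package: 10 clinical
#' features (age, sex, BMI, lactate, AF, SBP, DBP, MBP, P/F ratio, GCS),
#' 6 SOFA-related features (VASO, MV, UR, Plt, Bil, Cr), and the regression
#' target ICU_LOS in days. Sex, AF, VASO and MV are binary (1 = yes/male);
#' GCS is an integer score on 3--15.
#'
#' The BMI unit is recorded as "kg/cm^2" to match the source table verbatim;
#' the conventional unit is kg/m^2.
#'
#' @return A tibble of class `los_schema` with columns `name`, `kind`
#'   (`"numeric"`, `"integer"` or `"binary"`), `unit` and `role`
#'   (`"clinical"`, `"sofa"` or `"target"`).
#' @examples
#' sepsis_schema()
#' @export
sepsis_schema <- function() {
  entries <- tibble::tribble(
    ~name,      ~kind,     ~unit,        ~role,
    "age",      "numeric", "years",      "clinical",
    "sex",      "binary",  "male=1",     "clinical",
    "BMI",      "numeric", "kg/cm^2",    "clinical",
    "lactate",  "numeric", "mmol/L",     "clinical",
    "AF",       "binary",  "yes=1",      "clinical",
    "SBP",      "numeric", "mmHg",       "clinical",
    "DBP",      "numeric", "mmHg",       "clinical",
    "MBP",      "numeric", "mmHg",       "clinical",
    "PF",       "numeric", "-",          "clinical",
    "GCS",      "integer", "-",          "clinical",
    "VASO",     "binary",  "yes=1",      "sofa",
    "MV",       "binary",  "yes=1",      "sofa",
    "UR",       "numeric", "cm^3",       "sofa",
    "Plt",      "numeric", "x10^3/uL",   "sofa",
    "Bil",      "numeric", "mg/dl",      "sofa",
    "Cr",       "numeric", "mg/dl",      "sofa",
    "ICU_LOS",  "numeric", "days",       "target"
  )
  structure(entries, class = c("los_schema", class(entries)))
}

#' Names of the model input features of a schema
#'
#' @param schema A `los_schema`.
#' @return Character vector of the non-target feature names, in schema order.
#' @export
feature_names <- function(schema = sepsis_schema()) {
  schema$name[schema$role != "target"]
}

#' Name of the target column of a schema
#' @param schema A `los_schema`.
#' @return The target column name (a string).
#' @export
target_name <- function(schema = sepsis_schema()) {
  schema$name[schema$role == "target"]
}

binary_names <- function(schema = sepsis_schema()) {
  schema$name[schema$kind == "binary"]
}

# Text labels accepted for binary columns in CSV input.
.binary_one  <- c("1", "yes", "y", "true", "male", "m")
.binary_zero <- c("0", "no", "n", "false", "female", "f")

coerce_binary <- function(x, column) {
  xs <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(xs))
  out[xs %in% .binary_one] <- 1
  out[xs %in% .binary_zero] <- 0
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("column '%s', row %d: value '%s' is not a recognised binary label",
                 column, bad[1], as.character(x)[bad[1]]), call. = FALSE)
  }
  out
}

#' Validate a cohort against a schema
#'
#' Checks column presence, reorders columns to schema order, coerces binary
#' text labels (yes/no, male/female) to 1/0, and enforces the cohort
#' invariants: no missing cells, binary columns in \{0, 1\}, integer columns
#' whole-valued, and a strictly positive target.
#'
#' @param data A data frame.
#' @param schema A `los_schema` (default [sepsis_schema()]).
#' @return The validated cohort as a tibble, columns in schema order.
#' @export
validate_cohort <- function(data, schema = sepsis_schema()) {
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[schema$name]
  for (i in seq_len(nrow(schema))) {
    nm   <- schema$name[i]
    kind <- schema$kind[i]
    col  <- data[[nm]]
    if (kind == "binary") {
      col <- if (is.numeric(col)) as.numeric(col) else coerce_binary(col, nm)
      if (anyNA(col)) {
        stop(sprintf("column '%s', row %d: missing value",
                     nm, which(is.na(col))[1]), call. = FALSE)
      }
      bad <- which(!(col %in% c(0, 1)))
      if (length(bad) > 0) {
        stop(sprintf("column '%s', row %d: binary value must be 0 or 1 (got %s)",
                     nm, bad[1], col[bad[1]]), call. = FALSE)
      }
    } else {
      if (!is.numeric(col)) {
        suppressWarnings(num <- as.numeric(col))
        bad <- which(is.na(num) & !is.na(col))
        if (length(bad) > 0) {
          stop(sprintf("column '%s', row %d: unparseable value '%s'",
                       nm, bad[1], as.character(col)[bad[1]]), call. = FALSE)
        }
        col <- num
      }
      if (anyNA(col)) {
        stop(sprintf("column '%s', row %d: missing value",
                     nm, which(is.na(col))[1]), call. = FALSE)
      }
      if (kind == "integer") {
        bad <- which(abs(col - round(col)) > 1e-8)
        if (length(bad) > 0) {
          stop(sprintf("column '%s', row %d: expected a whole number (got %s)",
                       nm, bad[1], col[bad[1]]), call. = FALSE)
        }
        col <- round(col)
      }
      if (schema$role[i] == "target") {
        bad <- which(col <= 0)
        if (length(bad) > 0) {
          stop(sprintf("column '%s', row %d: target must be > 0 days (got %s)",
                       nm, bad[1], col[bad[1]]), call. = FALSE)
        }
      }
    }
    data[[nm]] <- col
  }
  data
}

#' Read a cohort from CSV
#'
#' @param path Path to a CSV file with a header row containing all schema
#'   columns (any order). Binary columns may use yes/no or male/female labels.
#' @param schema A `los_schema`.
#' @return A validated cohort tibble in schema order.
#' @export
read_cohort <- function(path, schema = sepsis_schema()) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  validate_cohort(data, schema)
}

#' Write a cohort to CSV
#'
#' Doubles are written with shortest round-trip precision, so
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param data A validated cohort.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Tukey fences for outlier detection
#'
#' Computes `(Q1 - m*IQR, Q3 + m*IQR)` with quartiles obtained by linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param values Numeric vector with at least 4 values.
#' @param multiplier Fence multiplier `m` (default 1.5).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' iqr_bounds(1:8) # c(-2.5, 11.5)
#' @export
iqr_bounds <- function(values, multiplier = 1.5) {
  if (length(values) < 4) {
    stop("iqr_bounds() needs at least 4 values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - multiplier * iqr, upper = q[2] + multiplier * iqr)
}

#' Remove length-of-stay outliers by the IQR rule
#'
#' Drops rows whose target lies strictly below `Q1 - m*IQR` or strictly above
#' `Q3 + m*IQR`, where the quartiles are those of the target column itself.
#' Applied to the full cohort before any splitting, mirroring study-level
#' exclusion at dataset construction.
#'
#' @param data A validated cohort.
#' @param schema A `los_schema`.
#' @param multiplier Fence multiplier (default 1.5).
#' @return A list with elements `cohort` (filtered tibble) and `report`
#'   (a `los_preprocess_report` recording the bounds and `n_excluded`).
#' @export
filter_outliers <- function(data, schema = sepsis_schema(), multiplier = 1.5) {
  tgt <- target_name(schema)
  y <- data[[tgt]]
  b <- iqr_bounds(y, multiplier)
  keep <- y >= b["lower"] & y <= b["upper"]
  report <- structure(
    list(lower_bound = unname(b["lower"]), upper_bound = unname(b["upper"]),
         n_excluded = sum(!keep), multiplier = multiplier,
         standardizer = NULL),
    class = "los_preprocess_report")
  list(cohort = data[keep, , drop = FALSE], report = report)
}

#' @export
print.los_preprocess_report <- function(x, ...) {
  cat(sprintf("<los_preprocess_report> target bounds [%.4g, %.4g] days, %d row(s) excluded\n",
              x$lower_bound, x$upper_bound, x$n_excluded))
  if (!is.null(x$standardizer)) {
    cat(sprintf("  standardizer fitted on %d column(s)\n", nrow(x$standardizer)))
  }
  invisible(x)
}

#' Fit a column standardizer
#'
#' Stores per-column mean and sample standard deviation (n - 1 denominator)
#' for the z-score transform `Z = (X - mean) / sd`. Binary columns and the
#' target are never standardized.
#'
#' @param data A validated cohort (typically the training rows only).
#' @param schema A `los_schema`.
#' @param columns Columns to standardize; defaults to all numeric/integer
#'   non-target columns of the schema.
#' @return A tibble of class `los_standardizer` with columns
#'   `column`, `mean`, `sd`.
#' @export
fit_standardizer <- function(data, schema = sepsis_schema(),
                             columns = NULL) {
  if (is.null(columns)) {
    columns <- schema$name[schema$kind %in% c("numeric", "integer") &
                             schema$role != "target"]
  }
  disallowed <- intersect(columns, c(binary_names(schema), target_name(schema)))
  if (length(disallowed) > 0) {
    stop(sprintf("refusing to standardize binary/target column(s): %s",
                 paste(disallowed, collapse = ", ")), call. = FALSE)
  }
  stats_tbl <- purrr::map_dfr(columns, function(nm) {
    x <- data[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("column '%s' has zero variance; cannot standardize", nm),
           call. = FALSE)
    }
    tibble::tibble(column = nm, mean = mean(x), sd = s)
  })
  structure(stats_tbl, class = c("los_standardizer", class(stats_tbl)))
}

#' Apply a fitted standardizer
#'
#' @param data A cohort containing every column in the standardizer.
#' @param standardizer A `los_standardizer` from [fit_standardizer()].
#' @return The cohort with the stored columns z-scored; other columns
#'   untouched. Applying twice re-centers (the transform is not idempotent).
#' @export
apply_standardizer <- function(data, standardizer) {
  missing_cols <- setdiff(standardizer$column, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("standardizer column(s) absent from cohort: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(standardizer))) {
    nm <- standardizer$column[i]
    data[[nm]] <- (data[[nm]] - standardizer$mean[i]) / standardizer$sd[i]
  }
  data
}

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a test/fold split plan
#'
#' Holds out `round(n * test_fraction)` rows for testing, then partitions the
#' remaining rows into `k` folds of near-equal size (sizes differ by at most
#' one). Uniformly random, without stratification, and fully determined by
#' `seed`.
#'
#' @param n Number of rows (or a data frame, in which case its row count).
#' @param test_fraction Fraction held out for the common test set (default 0.2).
#' @param k Number of folds on the remaining pool (default 4).
#' @param seed Integer seed.
#' @return A `los_split`: list with `test_indices`, `folds` (list of k index
#'   vectors), `n`, and `seed`.
#' @export
make_split <- function(n, test_fraction = 0.2, k = 4, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < k + 1) {
    stop(sprintf("need at least k + 1 = %d rows to split; got %d", k + 1, n),
         call. = FALSE)
  }
  n_test <- round(n * test_fraction)
  if (n - n_test < k) {
    stop("training pool smaller than the number of folds", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n))
  test_indices <- sort(idx[seq_len(n_test)])
  pool <- idx[-seq_len(n_test)]
  assignment <- rep(seq_len(k), length.out = length(pool))
  folds <- lapply(seq_len(k), function(f) sort(pool[assignment == f]))
  structure(list(test_indices = test_indices, folds = folds,
                 n = n, k = k, test_fraction = test_fraction, seed = seed),
            class = "los_split")
}

#' @export
print.los_split <- function(x, ...) {
  cat(sprintf("<los_split> n=%d: %d test rows, %d folds of sizes %s (seed %d)\n",
              x$n, length(x$test_indices), x$k,
              paste(vapply(x$folds, length, 1L), collapse = "/"), x$seed))
  invisible(x)
}

#' Serialize a split plan or preprocessing report to JSON
#'
#' @param x A `los_split` or `los_preprocess_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read back a split plan written by [write_plan()]
#' @param path JSON path.
#' @return A `los_split`.
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- if (is.matrix(x$folds)) {
    # equal-size folds simplify to a matrix with one fold per row
    lapply(asplit(x$folds, 1), as.integer)
  } else {
    lapply(x$folds, as.integer)
  }
  x$test_indices <- as.integer(x$test_indices)
  structure(x, class = "los_split")
}
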