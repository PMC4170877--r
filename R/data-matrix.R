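#' Feature matrices as tibbles
#'
#' Throughout pcboot an object-by-variable matrix travels as a tibble whose
#' first column holds the object identifiers (character) and whose remaining
#' columns are numeric variables. `read_feature_matrix()` /
#' `write_feature_matrix()` move such tables to and from CSV (first column =
#' row id, header row = variable names, decimal point, UTF-8).
#'
#' @param path Path to a CSV file.
#' @param data A feature-matrix tibble (id column first).
#' @return `read_feature_matrix()` returns a tibble with a character
#'   `object_id`-style first column; `write_feature_matrix()` returns `path`
#'   invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_feature_matrix(synth_feature_matrix(n_subjects = 3, seed = 1), tf)
#' read_feature_matrix(tf)
#' @export
read_feature_matrix <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out[[1]] <- as.character(out[[1]])
  check_feature_matrix(out)
  out
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(data, path) {
  check_feature_matrix(data)
  readr::write_csv(data, path)
  invisible(path)
}

# split a feature tibble into ids + numeric matrix; shared input validation
check_feature_matrix <- function(data, min_rows = 1L) {
  if (!is.data.frame(data) || ncol(data) < 2) {
    abort("`data` must be a data frame with an id column plus >= 1 numeric variable.")
  }
  vals <- data[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric variable column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(vals)) {
    abort("Missing values are not supported; impute or drop rows first.")
  }
  if (nrow(data) < min_rows) {
    abort(sprintf("At least %d rows are required.", min_rows))
  }
  invisible(data)
}

fm_ids <- function(data) as.character(data[[1]])

fm_matrix <- function(data) {
  x <- as.matrix(data[-1])
  rownames(x) <- fm_ids(data)
  storage.mode(x) <- "double"
  x
}

fm_rebuild <- function(data, x) {
  out <- tibble::as_tibble(as.data.frame(x))
  out <- tibble::add_column(out, ..id.. = fm_ids(data), .before = 1)
  names(out) <- names(data)
  out
}

#' Standardize the variable columns of a feature matrix
#'
#' Centers every variable to mean zero and scales it to unit sample standard
#' deviation (n - 1 denominator, matching the correlation-matrix convention
#' used by [fit_pca()]). The means and SDs actually used are attached as
#' attributes `col_means` / `col_sds` so supplementary observations can be
#' standardized on the same scale.
#'
#' @param data Feature-matrix tibble (first column id, rest numeric).
#' @return A tibble of the same shape with standardized variables and
#'   attributes `col_means`, `col_sds`, `standardized = TRUE`.
#' @details A constant column cannot be standardized and raises an error
#'   naming the column. Standardization is idempotent up to floating point:
#'   re-standardizing returns the input within 1e-10.
#' @examples
#' standardize_features(tibble::tibble(id = c("a", "b", "c"), v = c(1, 2, 3)))
#' @export
standardize_features <- function(data) {
  check_feature_matrix(data, min_rows = 2L)
  x <- fm_matrix(data)
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  if (any(sds < .Machine$double.eps * 100)) {
    abort(paste0(
      "Constant column(s) cannot be standardized: ",
      paste(colnames(x)[sds < .Machine$double.eps * 100], collapse = ", ")
    ))
  }
  out <- fm_rebuild(data, sweep(sweep(x, 2, mu), 2, sds, "/"))
  attr(out, "col_means") <- mu
  attr(out, "col_sds") <- sds
  attr(out, "standardized") <- TRUE
  out
}

is_standardized <- function(data, tol = 1e-8) {
  x <- fm_matrix(data)
  all(abs(colMeans(x)) < tol) && all(abs(apply(x, 2, sd) - 1) < tol)
}
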