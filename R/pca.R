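#' Fit a correlation-matrix PCA by singular value decomposition
#'
#' Standardizes the variables (unless the input already carries the
#' `standardized` attribute from [standardize_features()]) and decomposes the
#' resulting matrix as `X = U D V'`. The columns of `V` are the loadings, the
#' scores are `Z = X V = U D`, and the eigenvalues of the correlation matrix
#' are `d^2 / (n - 1)`, so for standardized input they sum to the number of
#' variables `p`.
#'
#' The sign of each loading column is arbitrary in an SVD; here it is fixed
#' deterministically so that the largest-magnitude entry of every column is
#' positive (first such entry on ties). Eigenvalue ties leave the
#' corresponding axes non-identifiable; the order returned by [base::svd()]
#' is kept.
#'
#' @param data Feature-matrix tibble (first column id, rest numeric), raw or
#'   already standardized.
#' @return An object of class `pb_pca`: a list with `loadings` (p x p),
#'   `singular_values`, `eigenvalues`, `scores` (n x p matrix), `explained`
#'   (per-rank percent of variance), `row_ids`, `col_names`, `n`, `p`, and
#'   the `col_means` / `col_sds` of the source data.
#' @seealso [tidy.pb_pca()], [glance.pb_pca()], [autoplot.pb_pca()],
#'   [project_supplementary()], [explained_variance()]
#' @examples
#' fit <- fit_pca(synth_feature_matrix(seed = 1))
#' glance(fit)
#' @export
fit_pca <- function(data) {
  check_feature_matrix(data, min_rows = 2L)
  if (isTRUE(attr(data, "standardized"))) {
    xs <- data
  } else {
    xs <- standardize_features(data)
  }
  x <- fm_matrix(xs)
  n <- nrow(x)
  p <- ncol(x)
  if (n > p) {
    dec <- svd(x, nu = 0)
    v0 <- dec$v
    d <- dec$d
  } else {
    # fewer objects than variables: complete the basis from the Gram matrix
    e <- eigen(crossprod(x), symmetric = TRUE)
    v0 <- e$vectors
    d <- sqrt(pmax(e$values, 0))
  }
  flip <- vapply(seq_len(p), function(j) {
    v <- v0[, j]
    sign_of <- v[which.max(abs(v))]
    if (sign_of < 0) -1 else 1
  }, numeric(1))
  v <- sweep(v0, 2, flip, "*")
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(p)))
  scores <- x %*% v
  eig <- d^2 / (n - 1)
  structure(
    list(
      loadings = v,
      singular_values = d,
      eigenvalues = eig,
      scores = scores,
      explained = 100 * eig / sum(eig),
      row_ids = rownames(x),
      col_names = colnames(x),
      n = n,
      p = p,
      col_means = attr(xs, "col_means"),
      col_sds = attr(xs, "col_sds")
    ),
    class = "pb_pca"
  )
}

#' @export
print.pb_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d objects x %d variables\n", x$n, x$p))
  cat("Eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  cat(sprintf(
    "First two components explain %.1f%% of the variance\n",
    explained_variance(x$eigenvalues, min(2, x$p))
  ))
  invisible(x)
}

#' Cumulative percent of variance explained by the leading components
#'
#' @param eigenvalues Nonnegative eigenvalues of the correlation matrix, in
#'   decreasing order (not all zero).
#' @param m Number of leading components, `1 <= m <= length(eigenvalues)`.
#' @return Percent in `[0, 100]`; equals 100 at `m = p`.
#' @examples
#' explained_variance(c(8.42, 0.74, rep(0.84 / 8, 8)), 2) # 91.6
#' @export
explained_variance <- function(eigenvalues, m) {
  if (!is.numeric(eigenvalues) || any(eigenvalues < -1e-12) || sum(eigenvalues) <= 0) {
    abort("`eigenvalues` must be nonnegative and not all zero.")
  }
  if (length(m) != 1 || m < 1 || m > length(eigenvalues) || m != round(m)) {
    abort(sprintf("`m` must be an integer in [1, %d].", length(eigenvalues)))
  }
  100 * sum(eigenvalues[seq_len(m)]) / sum(eigenvalues)
}

#' Project supplementary observations onto a fitted loading basis
#'
#' Supplementary points are new (or resampled) observations dropped into an
#' existing component space: they are multiplied by the first `m` loading
#' columns of the fitted model and do not alter the basis. This is the core
#' of the partial bootstrap, which avoids Procrustes alignment of replicate
#' axes altogether.
#'
#' @param fit A [fit_pca()] model.
#' @param newdata Feature-matrix tibble or numeric matrix with the model's
#'   variables (same count and, if named, same order).
#' @param m Number of components to project onto (default all).
#' @param standardized If `TRUE` (default) `newdata` is taken as already
#'   standardized; if `FALSE` it is standardized with the training sample's
#'   means and SDs before projection.
#' @return A tibble of scores `PC1..PCm`, preceded by the id column when
#'   `newdata` carried one.
#' @export
project_supplementary <- function(fit, newdata, m = fit$p, standardized = TRUE) {
  stopifnot(inherits(fit, "pb_pca"))
  if (length(m) != 1 || m < 1 || m > fit$p) {
    abort(sprintf("`m` must be in [1, %d].", fit$p))
  }
  ids <- NULL
  if (is.data.frame(newdata)) {
    check_feature_matrix(newdata)
    ids <- fm_ids(newdata)
    x <- fm_matrix(newdata)
  } else {
    x <- rbind(newdata)
  }
  if (ncol(x) != fit$p) {
    abort(sprintf("`newdata` has %d variables; the model expects %d.", ncol(x), fit$p))
  }
  if (!standardized) {
    x <- sweep(sweep(x, 2, fit$col_means), 2, fit$col_sds, "/")
  }
  z <- x %*% fit$loadings[, seq_len(m), drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(z))
  if (!is.null(ids)) out <- tibble::add_column(out, object_id = ids, .before = 1)
  out
}

#' Tidy methods for pb_pca fits
#'
#' `tidy()` returns, per the `matrix` argument, the scores (long or wide),
#' the loadings in long form, or the eigenvalue table; `glance()` returns a
#' one-row model summary.
#'
#' @param x A [fit_pca()] object.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pb_pca <- function(x, matrix = "scores", ...) {
  matrix <- match.arg(matrix, c("scores", "loadings", "eigenvalues"))
  if (matrix == "scores") {
    out <- tibble::as_tibble(as.data.frame(x$scores))
    names(out) <- paste0("PC", seq_len(x$p))
    return(tibble::add_column(out, object_id = x$row_ids, .before = 1))
  }
  if (matrix == "loadings") {
    lo <- x$loadings
    return(tibble::tibble(
      variable = rep(rownames(lo), times = ncol(lo)),
      component = rep(colnames(lo), each = nrow(lo)),
      loading = as.vector(lo)
    ))
  }
  tibble::tibble(
    rank = seq_len(x$p),
    eigenvalue = x$eigenvalues,
    percent = x$explained,
    cumulative = cumsum(x$explained)
  )
}

#' @rdname tidy.pb_pca
#' @export
glance.pb_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    p = x$p,
    eigenvalue_1 = x$eigenvalues[1],
    eigenvalue_2 = if (x$p >= 2) x$eigenvalues[2] else NA_real_,
    explained_2 = explained_variance(x$eigenvalues, min(2, x$p))
  )
}

#' Principal-plane score plot
#'
#' @param object A [fit_pca()] model.
#' @param dims Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_pca <- function(object, dims = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  xcol <- paste0("PC", dims[1])
  ycol <- paste0("PC", dims[2])
  ggplot2::ggplot(sc, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$object_id), size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", dims[1], object$explained[dims[1]]),
      y = sprintf("PC%d (%.1f%%)", dims[2], object$explained[dims[2]]),
      title = "Principal plane"
    ) +
    ggplot2::theme_minimal()
}

#' Export a fitted PCA as JSON
#'
#' Fixed field names: `n`, `p`, `variables`, `row_ids`, `eigenvalues`,
#' `loadings` (p x p, column per component), and `explained_variance`
#' (table with `rank`, `eigenvalue`, `percent`, `cumulative`).
#'
#' @param fit A [fit_pca()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(fit, path) {
  stopifnot(inherits(fit, "pb_pca"))
  payload <- list(
    n = fit$n,
    p = fit$p,
    variables = fit$col_names,
    row_ids = fit$row_ids,
    eigenvalues = fit$eigenvalues,
    loadings = as.data.frame(fit$loadings),
    explained_variance = tidy(fit, "eigenvalues")
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}
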