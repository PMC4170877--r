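#' Build a deterministic row-resampling plan
#'
#' Draws `R` bootstrap index vectors of length `n` (rows sampled with
#' replacement). Replicate `r` is generated from its own derived seed
#' `seed + r`, so any single replicate can be regenerated in isolation and
#' the plan as a whole is reproducible from `seed`.
#'
#' @param n Number of objects (rows) in the training matrix, `n >= 2`.
#' @param R Number of bootstrap replicates, `R >= 1`.
#' @param seed Integer master seed.
#' @return An object of class `resample_plan`: list with `n`, `R`, `seed`
#'   and `idx`, an `R x n` integer matrix of row indices. The occurrence
#'   counts of the original rows over all replicates sum to `n * R`, so the
#'   mean per-object count is exactly `R`.
#' @examples
#' plan <- resample_plan(48, 10, seed = 1)
#' mean(tidy(plan)$count) # exactly 10
#' @export
resample_plan <- function(n, R, seed) {
  if (length(n) != 1 || n < 2 || n != round(n)) abort("`n` must be an integer >= 2.")
  if (length(R) != 1 || R < 1 || R != round(R)) abort("`R` must be an integer >= 1.")
  idx <- t(vapply(seq_len(R), function(r) replicate_indices(n, seed, r), integer(n)))
  structure(list(n = as.integer(n), R = as.integer(R), seed = as.integer(seed),
                 idx = idx),
            class = "resample_plan")
}

# the r-th replicate's indices, regenerable independently of the others
replicate_indices <- function(n, seed, r) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) + r) %% .Machine$integer.max)
  sample.int(n, n, replace = TRUE)
}

#' @export
print.resample_plan <- function(x, ...) {
  cat(sprintf("Resample plan: n = %d, R = %d, seed = %d (%d indices drawn)\n",
              x$n, x$R, x$seed, x$n * x$R))
  invisible(x)
}

#' @describeIn resample_plan per-object occurrence counts over all replicates.
#' @param x A `resample_plan`.
#' @param ... Unused.
#' @export
tidy.resample_plan <- function(x, ...) {
  tibble::tibble(row = seq_len(x$n), count = tabulate(x$idx, nbins = x$n))
}

# standardize a replicate matrix by its own column moments; NULL if degenerate
standardize_replicate <- function(xr) {
  mu <- colMeans(xr)
  sds <- apply(xr, 2, sd)
  if (any(sds < .Machine$double.eps * 100)) return(NULL)
  sweep(sweep(xr, 2, mu), 2, sds, "/")
}

#' Partial-bootstrap cloud of replicate scores
#'
#' For each bootstrap replicate the resampled raw rows are re-standardized
#' with their own column means/SDs (set `standardize = "original"` to reuse
#' the training sample's moments instead) and projected as supplementary
#' points onto the first `m` loading columns of the original fit. Stacking
#' all replicates yields `n * R` points in the original component space,
#' tagged by the object they replicate — one cloud per object, with no
#' Procrustes alignment needed because the basis never changes.
#'
#' Replicates in which some column becomes constant cannot be standardized;
#' they are dropped with a warning listing their ids and the cloud records
#' the reduced effective `R` (attribute `R_effective`).
#'
#' @param data The raw (unstandardized) training feature matrix the model
#'   was fitted from.
#' @param fit The [fit_pca()] model of `data`.
#' @param plan A [resample_plan()] with `n = nrow(data)`.
#' @param m Number of leading components to keep (default 2, the plotting
#'   plane).
#' @param standardize `"own"` (default) or `"original"` replicate scaling.
#' @return A tibble of class `bootstrap_cloud` with columns `object_id`,
#'   `replicate`, `PC1..PCm` and attributes `n`, `R`, `R_effective`, `m`,
#'   `dropped`.
#' @export
bootstrap_scores <- function(data, fit, plan, m = 2L,
                             standardize = c("own", "original")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(fit, "pb_pca"), inherits(plan, "resample_plan"))
  check_feature_matrix(data)
  x <- fm_matrix(data)
  if (nrow(x) != plan$n) abort("`plan` was built for a different number of rows.")
  if (m < 1 || m > fit$p) abort(sprintf("`m` must be in [1, %d].", fit$p))
  ids <- fm_ids(data)
  v <- fit$loadings[, seq_len(m), drop = FALSE]
  pieces <- vector("list", plan$R)
  dropped <- integer(0)
  for (r in seq_len(plan$R)) {
    take <- plan$idx[r, ]
    xs <- if (standardize == "own") {
      standardize_replicate(x[take, , drop = FALSE])
    } else {
      sweep(sweep(x[take, , drop = FALSE], 2, fit$col_means), 2, fit$col_sds, "/")
    }
    if (is.null(xs)) {
      dropped <- c(dropped, r)
      next
    }
    z <- xs %*% v
    pieces[[r]] <- tibble::tibble(object_id = ids[take], replicate = r,
                                  as.data.frame(z))
  }
  if (length(dropped)) {
    warn(paste0("Dropped degenerate replicate(s): ", paste(dropped, collapse = ", ")))
    pieces <- pieces[-dropped]
  }
  out <- dplyr::bind_rows(pieces)
  names(out)[-(1:2)] <- paste0("PC", seq_len(m))
  structure(out,
            class = c("bootstrap_cloud", class(tibble::tibble())),
            n = plan$n, R = plan$R, R_effective = plan$R - length(dropped),
            m = as.integer(m), dropped = dropped)
}

#' Replicate eigenvalue sets from the partial bootstrap
#'
#' Each resampled matrix is re-standardized and decomposed on its own; row
#' `r` of the result holds the eigenvalues of replicate `r`'s correlation
#' matrix (`d^2 / (n - 1)`) in decreasing order, so every row sums to `p`.
#' Degenerate replicates are dropped as in [bootstrap_scores()].
#'
#' @inheritParams bootstrap_scores
#' @return An object of class `pb_eigen`: list with `values`
#'   (`R_effective x p` matrix), `n`, `p`, `R`, `R_effective`, `dropped`.
#' @seealso [eigenvalue_bands()], [nonoverlap_dimension()]
#' @export
bootstrap_eigenvalues <- function(data, plan) {
  stopifnot(inherits(plan, "resample_plan"))
  check_feature_matrix(data)
  x <- fm_matrix(data)
  if (nrow(x) != plan$n) abort("`plan` was built for a different number of rows.")
  n <- nrow(x)
  p <- ncol(x)
  rows <- vector("list", plan$R)
  dropped <- integer(0)
  for (r in seq_len(plan$R)) {
    xs <- standardize_replicate(x[plan$idx[r, ], , drop = FALSE])
    if (is.null(xs)) {
      dropped <- c(dropped, r)
      next
    }
    d <- svd(xs, nu = 0, nv = 0)$d
    ev <- sort(d^2 / (n - 1), decreasing = TRUE)
    rows[[r]] <- c(ev, rep(0, p - length(ev))) # rank-deficient when n <= p
  }
  if (length(dropped)) {
    warn(paste0("Dropped degenerate replicate(s): ", paste(dropped, collapse = ", ")))
    rows <- rows[-dropped]
  }
  structure(list(values = do.call(rbind, rows), n = n, p = p, R = plan$R,
                 R_effective = plan$R - length(dropped), dropped = dropped),
            class = "pb_eigen")
}

#' @export
print.pb_eigen <- function(x, ...) {
  cat(sprintf("Bootstrap eigenvalues: %d replicates x %d ranks\n",
              x$R_effective, x$p))
  print(eigenvalue_bands(x))
  invisible(x)
}

#' @describeIn bootstrap_eigenvalues replicate eigenvalues in long form
#'   (`replicate`, `rank`, `eigenvalue`).
#' @param x A `pb_eigen` object.
#' @param ... Unused.
#' @export
tidy.pb_eigen <- function(x, ...) {
  tibble::tibble(
    replicate = rep(seq_len(nrow(x$values)), times = x$p),
    rank = rep(seq_len(x$p), each = nrow(x$values)),
    eigenvalue = as.vector(x$values)
  )
}

#' Percentile confidence bands for replicate eigenvalues
#'
#' @param x A [bootstrap_eigenvalues()] result.
#' @param alpha Two-sided tail mass in `[0, 1)`; `alpha = 0` gives the
#'   min/max (100% interval) bands used by the non-overlap criterion.
#' @return A tibble with `rank`, `lo`, `hi`.
#' @export
eigenvalue_bands <- function(x, alpha = 0) {
  stopifnot(inherits(x, "pb_eigen"))
  ci <- apply(x$values, 2, percentile_ci, alpha = alpha)
  tibble::tibble(rank = seq_len(x$p), lo = ci["lo", ], hi = ci["hi", ])
}

#' Percentile bootstrap confidence interval
#'
#' Order-statistic convention (1-based): with `R` sorted values the lower
#' bound is element `max(1, ceiling(R * alpha / 2))` and the upper bound is
#' element `R - ceiling(R * alpha / 2) + 1`; `alpha = 0` returns the full
#' range. For `R = 1000`, `alpha = 0.05` this selects the 25th and 976th
#' elements.
#'
#' @param values Numeric vector of at least 2 bootstrap statistics.
#' @param alpha Two-sided tail mass in `[0, 1)`.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' percentile_ci(1:1000, alpha = 0.05) # 25, 976
#' @export
percentile_ci <- function(values, alpha = 0) {
  if (length(values) < 2) abort("Need at least 2 values for a percentile interval.")
  if (length(alpha) != 1 || alpha < 0 || alpha >= 1) abort("`alpha` must be in [0, 1).")
  s <- sort(values)
  R <- length(s)
  k <- ceiling(R * alpha / 2)
  c(lo = s[max(1L, k)], hi = s[R - k + ifelse(k == 0, 0, 1)])
}
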