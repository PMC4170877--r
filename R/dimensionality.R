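#' Number of nontrivial axes from bootstrap eigenvalue bands
#'
#' Applies the non-overlap criterion to replicate eigenvalue bands: rank `k`
#' is *separated* from rank `k + 1` when the smallest replicate eigenvalue
#' of rank `k` exceeds the largest of rank `k + 1` (with `alpha = 0` bands,
#' i.e. min/max over replicates; percentile bands at a user `alpha` may be
#' used instead). Writing `g_k = min(sigma_k*) - max(sigma_{k+1}*)`:
#'
#' * `n_separated` — the number of leading consecutive ranks with `g_k > 0`;
#'   this is the number of axes that stand clear of the next one and is what
#'   a planted-factor recovery experiment should compare against.
#' * `m_star` — the retention count under the criterion's own convention,
#'   `n_separated + 1`: a dimensionality `m` is admissible when gaps
#'   `1..m-1` are all positive, and `m_star` is the largest admissible `m`
#'   (at least 1, even when no rank pair separates).
#'
#' The two differ by exactly one; both are reported so the off-by-one in
#' the retention convention is never silent.
#'
#' @param bands A [bootstrap_eigenvalues()] result.
#' @param alpha Band level passed to [eigenvalue_bands()] (default 0, the
#'   100% min/max bands of the criterion as stated).
#' @param fit Optional [fit_pca()] model; adds the scree eigenvalues and the
#'   percent of variance explained at `m_star`.
#' @return Object of class `dim_report`: `m_star`, `n_separated`,
#'   `gap_table` (tibble `rank`, `lo`, `hi`, `gap_to_next`), `alpha`,
#'   `scree_eigenvalues`, `explained_at_m`.
#' @export
nonoverlap_dimension <- function(bands, alpha = 0, fit = NULL) {
  stopifnot(inherits(bands, "pb_eigen"))
  if (bands$R_effective < 2) abort("Need at least 2 replicates.")
  bt <- eigenvalue_bands(bands, alpha = alpha)
  p <- nrow(bt)
  gaps <- c(bt$lo[-p] - bt$hi[-1], NA_real_)
  lead <- 0L
  for (k in seq_len(p - 1)) {
    if (gaps[k] > 0) lead <- lead + 1L else break
  }
  m_star <- min(lead + 1L, p)
  structure(
    list(
      m_star = m_star,
      n_separated = lead,
      gap_table = tibble::add_column(bt, gap_to_next = gaps),
      alpha = alpha,
      scree_eigenvalues = if (!is.null(fit)) fit$eigenvalues else NULL,
      explained_at_m = if (!is.null(fit)) explained_variance(fit$eigenvalues, m_star) else NA_real_
    ),
    class = "dim_report"
  )
}

#' @export
print.dim_report <- function(x, ...) {
  cat(sprintf(
    "Non-overlap criterion (alpha = %g bands): %d leading separated rank(s); m* = %d\n",
    x$alpha, x$n_separated, x$m_star
  ))
  if (!is.na(x$explained_at_m)) {
    cat(sprintf("Variance explained by the first %d axes: %.1f%%\n",
                x$m_star, x$explained_at_m))
  }
  print(x$gap_table)
  invisible(x)
}

#' @describeIn nonoverlap_dimension the per-rank band/gap table.
#' @param x A `dim_report`.
#' @param ... Unused.
#' @export
tidy.dim_report <- function(x, ...) x$gap_table

#' Scree table with a second-difference elbow heuristic
#'
#' Tabulates eigenvalues against rank with marginal and cumulative percent
#' of variance. The optional elbow flag marks the rank `k` maximising the
#' second difference `lambda_k - 2 lambda_{k+1} + lambda_{k+2}` — a
#' heuristic reading of the scree plot, not a test; no elbow is flagged
#' when the profile is flat.
#'
#' @param fit A [fit_pca()] model.
#' @return Tibble `rank`, `eigenvalue`, `percent`, `cumulative`, `elbow`.
#' @export
scree_table <- function(fit) {
  stopifnot(inherits(fit, "pb_pca"))
  out <- tidy(fit, "eigenvalues")
  elbow <- rep(FALSE, fit$p)
  if (fit$p >= 3) {
    ev <- fit$eigenvalues
    d2 <- ev[seq_len(fit$p - 2)] - 2 * ev[seq_len(fit$p - 2) + 1] + ev[seq_len(fit$p - 2) + 2]
    if (max(d2) > 1e-8) elbow[which.max(d2)] <- TRUE
  }
  tibble::add_column(out, elbow = elbow)
}

#' Histogram of replicate eigenvalues per rank
#'
#' @param object A [bootstrap_eigenvalues()] result.
#' @param ranks Ranks to display (default first three).
#' @param fit Optional [fit_pca()] model whose eigenvalues are marked as
#'   dashed reference lines.
#' @param ... Unused.
#' @return A ggplot, faceted by rank.
#' @export
autoplot.pb_eigen <- function(object, ranks = 1:3, fit = NULL, ...) {
  ranks <- ranks[ranks <= object$p]
  long <- dplyr::filter(tidy(object), .data$rank %in% ranks)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$eigenvalue)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~rank, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Replicate eigenvalue", y = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    ref <- tibble::tibble(rank = ranks, eigenvalue = fit$eigenvalues[ranks])
    p <- p + ggplot2::geom_vline(
      data = ref, ggplot2::aes(xintercept = .data$eigenvalue), linetype = 2
    )
  }
  p
}
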