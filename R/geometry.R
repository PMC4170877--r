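#' Convex hull of a 2-D point cloud
#'
#' Returns the minimal convex vertex set in counter-clockwise order, with no
#' three consecutive collinear vertices. Fewer than three distinct points,
#' or a collinear cloud, yield a degenerate "polygon" (the distinct extreme
#' points) flagged with attribute `degenerate = TRUE`.
#'
#' @param points Two-column numeric matrix or data frame of (x, y) points.
#' @return Two-column matrix of hull vertices (columns `x`, `y`), attribute
#'   `degenerate`.
#' @export
convex_hull <- function(points) {
  pts <- as_xy(points)
  if (nrow(pts) < 1) abort("Need at least one point.")
  pts <- unique(pts)
  if (nrow(pts) >= 3) {
    h <- grDevices::chull(pts) # clockwise
    v <- pts[rev(h), , drop = FALSE] # counter-clockwise
    if (nrow(v) >= 3 && abs(polygon_signed_area(v)) > 1e-12) {
      attr(v, "degenerate") <- FALSE
      return(v)
    }
    pts <- v
  }
  attr(pts, "degenerate") <- TRUE
  pts
}

as_xy <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[vapply(points, is.numeric, logical(1))])
  if (!is.matrix(points) || ncol(points) != 2 || !is.numeric(points)) {
    abort("`points` must be a two-column numeric matrix or data frame.")
  }
  colnames(points) <- c("x", "y")
  unname_rows(points)
}

unname_rows <- function(m) {
  rownames(m) <- NULL
  m
}

# shoelace formula with sign: positive for counter-clockwise winding
polygon_signed_area <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' Half the absolute sum of the consecutive 2x2 cross products of the vertex
#' coordinates. Taking the absolute value makes the result independent of
#' winding direction and of which vertex starts the list.
#'
#' @param vertices Ordered polygon vertices (two-column matrix or data
#'   frame), either winding.
#' @return Area in square units (`>= 0`).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))) # 1
#' @export
polygon_area <- function(vertices) {
  v <- as_xy(vertices)
  if (nrow(v) < 3) abort("A polygon needs at least 3 vertices.")
  abs(polygon_signed_area(v))
}

#' Polygon centroid (signed-area weighted)
#'
#' The standard centroid of a simple polygon,
#' `xc = 1/(6S) * sum (x_{i} + x_{i+1}) (x_i y_{i+1} - x_{i+1} y_i)` and
#' symmetrically for `yc`, with `S` the signed shoelace area. For a convex
#' polygon the centroid lies strictly inside. Near-zero-area (collinear)
#' polygons fall back to the arithmetic mean of the vertices, flagged with
#' attribute `degenerate = TRUE`.
#'
#' @inheritParams polygon_area
#' @return Named numeric vector `c(x, y)`.
#' @export
polygon_centroid <- function(vertices) {
  v <- as_xy(vertices)
  if (nrow(v) < 3) abort("A polygon needs at least 3 vertices.")
  s <- polygon_signed_area(v)
  if (abs(s) < 1e-12) {
    out <- c(x = mean(v[, 1]), y = mean(v[, 2]))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  out <- c(x = sum((x + xn) * cross) / (6 * s), y = sum((y + yn) * cross) / (6 * s))
  attr(out, "degenerate") <- FALSE
  out
}

#' Trim a point cloud before hulling
#'
#' With `alpha = 0` the cloud is returned untouched (the 100% hull).
#' Otherwise `method = "peel"` performs convex-hull peeling: whole hull
#' layers are deleted while doing so leaves at least `ceiling((1 - alpha) *
#' M)` points, then, within the last layer, the vertices farthest from the
#' current centroid are removed one at a time until exactly that target
#' remains. `method = "mahalanobis"` instead keeps the `ceiling((1 - alpha)
#' * M)` points of smallest Mahalanobis distance from the cloud mean.
#'
#' @param points Two-column numeric matrix or data frame.
#' @param alpha Trim level in `[0, 1)`.
#' @param method `"peel"` (default) or `"mahalanobis"`.
#' @return The retained points, same two-column form; at least
#'   `ceiling((1 - alpha) * M)` rows.
#' @export
trim_cloud <- function(points, alpha = 0, method = c("peel", "mahalanobis")) {
  method <- match.arg(method)
  pts <- as_xy(points)
  if (length(alpha) != 1 || alpha < 0 || alpha >= 1) abort("`alpha` must be in [0, 1).")
  if (alpha == 0) return(pts)
  target <- ceiling((1 - alpha) * nrow(pts))
  if (method == "mahalanobis") {
    mu <- colMeans(pts)
    cv <- stats::cov(pts)
    d2 <- tryCatch(stats::mahalanobis(pts, mu, cv),
                   error = function(e) rowSums(sweep(pts, 2, mu)^2))
    return(pts[order(d2)[seq_len(target)], , drop = FALSE])
  }
  while (nrow(pts) > target) {
    h <- grDevices::chull(pts)
    if (nrow(pts) - length(h) >= target) {
      pts <- pts[-h, , drop = FALSE]
    } else {
      # partial last layer: drop the hull vertices farthest from the centroid
      excess <- nrow(pts) - target
      mu <- colMeans(pts)
      d2 <- rowSums(sweep(pts[h, , drop = FALSE], 2, mu)^2)
      pts <- pts[-h[order(-d2)[seq_len(excess)]], , drop = FALSE]
    }
  }
  pts
}

#' Test points against a convex polygon
#'
#' @param points Two-column matrix of query points.
#' @param vertices Convex polygon vertices in counter-clockwise order.
#' @param tol Boundary tolerance.
#' @return Logical vector: inside or on the boundary.
#' @export
points_in_hull <- function(points, vertices, tol = 1e-9) {
  pts <- as_xy(points)
  v <- as_xy(vertices)
  inside <- rep(TRUE, nrow(pts))
  l <- nrow(v)
  for (i in seq_len(l)) {
    a <- v[i, ]
    b <- v[if (i == l) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cross >= -tol)
  }
  inside
}

# Sutherland-Hodgman: clip subject polygon by each edge of a convex CCW clip
# polygon; returns a (possibly empty) vertex matrix
clip_convex <- function(subject, clip, tol = 1e-12) {
  out <- subject
  l <- nrow(clip)
  for (i in seq_len(l)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == l) 1 else i + 1, ]
    input <- out
    out <- matrix(numeric(0), ncol = 2)
    ni <- nrow(input)
    side <- (b[1] - a[1]) * (input[, 2] - a[2]) - (b[2] - a[2]) * (input[, 1] - a[1])
    for (j in seq_len(ni)) {
      k <- if (j == ni) 1 else j + 1
      p <- input[j, ]
      q <- input[k, ]
      if (side[j] >= -tol) {
        out <- rbind(out, p)
        if (side[k] < -tol) out <- rbind(out, edge_intersect(p, q, a, b))
      } else if (side[k] >= -tol) {
        out <- rbind(out, edge_intersect(p, q, a, b))
      }
    }
  }
  unname_rows(out)
}

edge_intersect <- function(p, q, a, b) {
  d1 <- q - p
  d2 <- b - a
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
  p + t * d1
}

#' Overlap between two convex confidence polygons
#'
#' Overlap of polygons in the principal plane suggests objects with similar
#' (statistically indistinguishable) score coordinates. The intersection of
#' two convex polygons is computed by Sutherland-Hodgman clipping; the flag
#' is `TRUE` when the interiors intersect or the boundaries touch.
#'
#' @param a,b Vertex matrices (as from [convex_hull()]) or single rows of a
#'   [confidence_polygons()] table.
#' @param tol Geometric tolerance for touching boundaries.
#' @return List with `overlap` (logical) and `area` (intersection area,
#'   `<= min(area(a), area(b))`).
#' @export
polygons_overlap <- function(a, b, tol = 1e-9) {
  va <- polygon_vertices_of(a)
  vb <- polygon_vertices_of(b)
  if (nrow(va) < 3 || nrow(vb) < 3) {
    # degenerate: test the point set against the other shape, area 0
    hit <- if (nrow(va) >= 3) {
      any(points_in_hull(vb, va, tol))
    } else if (nrow(vb) >= 3) {
      any(points_in_hull(va, vb, tol))
    } else {
      any(apply(va, 1, function(p) any(sqrt(rowSums(sweep(vb, 2, p)^2)) <= tol)))
    }
    return(list(overlap = hit, area = 0))
  }
  inter <- clip_convex(va, vb)
  if (nrow(inter) == 0) {
    return(list(overlap = FALSE, area = 0))
  }
  area <- if (nrow(inter) >= 3) abs(polygon_signed_area(inter)) else 0
  list(overlap = area > 0 || nrow(inter) >= 1, area = area)
}

polygon_vertices_of <- function(x) {
  if (is.data.frame(x) && "vertices" %in% names(x)) {
    if (nrow(x) != 1) abort("Pass a single polygon row.")
    return(as_xy(x$vertices[[1]]))
  }
  as_xy(x)
}

#' Confidence polygons around each object's replicate cloud
#'
#' Splits a [bootstrap_scores()] cloud by object, optionally trims each
#' cloud ([trim_cloud()]), and summarises it by its convex hull: the hull
#' area measures the sampling variability of that object's score
#' coordinates, and the signed-area centroid is the bootstrap estimate of
#' the score itself (the validation set used downstream).
#'
#' @param cloud A `bootstrap_cloud` tibble, or any tibble with an
#'   `object_id` column and the two score columns named in `dims`.
#' @param alpha Trim level in `[0, 1)` (`0` = hull of all points).
#' @param dims Names of the two score columns spanning the plane.
#' @param method Trimming method, see [trim_cloud()].
#' @return A tibble of class `confidence_polygons`: `object_id`, `alpha`,
#'   `n_points`, `n_vertices`, `area`, `centroid_x`, `centroid_y`,
#'   `degenerate`, and a `vertices` list-column of CCW vertex matrices.
#' @export
confidence_polygons <- function(cloud, alpha = 0, dims = c("PC1", "PC2"),
                                method = "peel") {
  if (!all(c("object_id", dims) %in% names(cloud))) {
    abort(paste0("`cloud` must contain columns object_id, ", paste(dims, collapse = ", ")))
  }
  split_ids <- unique(cloud$object_id)
  rows <- purrr::map(split_ids, function(id) {
    pts <- as_xy(cloud[cloud$object_id == id, dims])
    kept <- trim_cloud(pts, alpha = alpha, method = method)
    hull <- convex_hull(kept)
    degen <- isTRUE(attr(hull, "degenerate"))
    if (degen) {
      area <- 0
      cen <- colMeans(hull)
    } else {
      area <- polygon_area(hull)
      cen <- polygon_centroid(hull)
    }
    tibble::tibble(
      object_id = id, alpha = alpha, n_points = nrow(kept),
      n_vertices = nrow(hull), area = area,
      centroid_x = cen[[1]], centroid_y = cen[[2]],
      degenerate = degen, vertices = list(hull)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("confidence_polygons", class(tibble::tibble()))
  attr(out, "dims") <- dims
  out
}

#' Bootstrap centroids as a feature matrix
#'
#' @param polygons A [confidence_polygons()] table.
#' @return Tibble `object_id`, `centroid_x`, `centroid_y` usable as input to
#'   [average_linkage()].
#' @export
polygon_centroids <- function(polygons) {
  dplyr::select(tibble::as_tibble(polygons), "object_id", "centroid_x", "centroid_y")
}

#' Plot confidence polygons on the principal plane
#'
#' @param object A [confidence_polygons()] table.
#' @param scores Optional tibble of original scores (`object_id` + the same
#'   two dims) to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confidence_polygons <- function(object, scores = NULL, ...) {
  dims <- attr(object, "dims") %||% c("PC1", "PC2")
  hulls <- tidyr::unnest(
    dplyr::mutate(
      tibble::as_tibble(object),
      vertices = purrr::map(.data$vertices, ~ tibble::as_tibble(as.data.frame(.x)))
    ),
    "vertices"
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = hulls,
      ggplot2::aes(.data$x, .data$y, group = .data$object_id),
      fill = NA, colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      ggplot2::aes(.data$centroid_x, .data$centroid_y),
      colour = "red", size = 1
    ) +
    ggplot2::labs(x = dims[1], y = dims[2],
                  title = sprintf("Confidence polygons (alpha = %g)", object$alpha[1])) +
    ggplot2::theme_minimal()
  if (!is.null(scores)) {
    p <- p + ggplot2::geom_text(
      data = scores,
      ggplot2::aes(.data[[dims[1]]], .data[[dims[2]]], label = .data$object_id),
      size = 2.5
    )
  }
  p
}
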