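# Shared fixtures and independent oracles used across the suite.

# random feature matrix (iid Gaussian unless a factor loading is given)
rand_fm <- function(n, p, seed, factor_loading = 0) {
  set.seed(seed)
  f <- rnorm(n)
  x <- matrix(rnorm(n * p), n, p) + factor_loading * f
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- paste0("v", seq_len(p))
  tibble::add_column(out, object_id = sprintf("o%02d", seq_len(n)), .before = 1)
}

# random convex polygon: hull of q random points (>= 3 vertices)
rand_convex_polygon <- function(q = 12) {
  repeat {
    pts <- cbind(runif(q, -2, 2), runif(q, -1, 3))
    h <- pcboot::convex_hull(pts)
    if (!isTRUE(attr(h, "degenerate"))) return(h)
  }
}

# Monte-Carlo area: hit fraction over the bounding box
mc_area <- function(vertices, n_samples = 1e6) {
  lo <- apply(vertices, 2, min)
  hi <- apply(vertices, 2, max)
  pts <- cbind(runif(n_samples, lo[1], hi[1]), runif(n_samples, lo[2], hi[2]))
  inside <- pcboot::points_in_hull(pts, vertices)
  box <- prod(hi - lo)
  p_hat <- mean(inside)
  list(area = p_hat * box, se = sqrt(p_hat * (1 - p_hat) / n_samples) * box)
}

# fan-triangulation centroid: area-weighted centroids of triangles from v1
fan_centroid <- function(vertices) {
  v1 <- vertices[1, ]
  acc <- c(0, 0)
  total <- 0
  for (i in 2:(nrow(vertices) - 1)) {
    a <- v1
    b <- vertices[i, ]
    cc <- vertices[i + 1, ]
    s <- ((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
    acc <- acc + s * (a + b + cc) / 3
    total <- total + s
  }
  acc / total
}

# brute-force UPGMA: recompute every inter-cluster average distance from the
# raw point distances at each step; returns merges as sorted member sets
upgma_oracle <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(rownames(d))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, j, i)
      }
    }
    i <- best[3]
    j <- best[2]
    merges[[length(merges) + 1]] <- list(
      members = sort(c(sort(clusters[[j]]), sort(clusters[[i]]))),
      height = best[1]
    )
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  merges
}

# pair-enumeration Rand index over all object pairs
rand_oracle <- function(a, b) {
  ids <- names(a)
  agree <- 0
  total <- 0
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      same_a <- unname(a[ids[i]] == a[ids[j]])
      same_b <- unname(b[ids[i]] == b[ids[j]])
      agree <- agree + (same_a == same_b)
      total <- total + 1
    }
  }
  agree / total
}

# unit-amplitude sinusoid epochs
sine_epochs <- function(freq, fs = 400, L = 400, E = 10) {
  t <- seq_len(L) / fs
  m <- matrix(rep(sin(2 * pi * freq * t), E), nrow = E, byrow = TRUE)
  m <- m - rowMeans(m)
  structure(list(epochs = m, fs = fs, n_rejected = 0L, qualifies = TRUE),
            class = "epoch_set")
}
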