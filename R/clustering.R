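#' Average-linkage (UPGMA) clustering of score coordinates
#'
#' Euclidean distances between the objects' score (or centroid) coordinates
#' are clustered agglomeratively with average linkage: the distance between
#' two clusters is the mean of all pairwise inter-point distances, which
#' makes the merge heights nondecreasing. Used to compare the partition of
#' the original PC scores with the partition of the bootstrap polygon
#' centroids.
#'
#' @param data Tibble whose first column is the object id and whose
#'   remaining numeric columns are the coordinates (typically the two
#'   retained score dimensions, or `centroid_x`/`centroid_y`).
#' @return Object of class `pb_dendro`: list with `hc` (the
#'   [stats::hclust()] tree), `labels`, and `merges` — a list of
#'   `(a, b, height)` member-set triples in merge order.
#' @seealso [cut_tree()], [suggest_cut()], [compare_partitions()],
#'   [as_newick()]
#' @export
average_linkage <- function(data) {
  check_feature_matrix(data, min_rows = 2L)
  x <- fm_matrix(data)
  hc <- hclust(dist(x), method = "average")
  structure(list(hc = hc, labels = rownames(x), merges = hclust_merges(hc)),
            class = "pb_dendro")
}

# expand an hclust merge matrix into member-label sets per merge step
hclust_merges <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  side <- function(v, i) {
    if (hc$merge[i, v] < 0) hc$labels[-hc$merge[i, v]] else members[[hc$merge[i, v]]]
  }
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- side(1, i)
    b <- side(2, i)
    members[[i]] <- c(a, b)
    out[[i]] <- list(a = sort(a), b = sort(b), height = hc$height[i])
  }
  out
}

#' @export
print.pb_dendro <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram of %d objects; merge heights %.4g .. %.4g\n",
              length(x$labels), min(x$hc$height), max(x$hc$height)))
  invisible(x)
}

#' @export
plot.pb_dendro <- function(x, ...) plot(x$hc, ...)

#' @describeIn average_linkage merge table (`step`, `height`, `size`,
#'   member sets as list-columns).
#' @param x A `pb_dendro`.
#' @param ... Unused.
#' @export
tidy.pb_dendro <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$merges),
    height = vapply(x$merges, `[[`, numeric(1), "height"),
    size = vapply(x$merges, function(m) length(m$a) + length(m$b), integer(1)),
    members_a = purrr::map(x$merges, "a"),
    members_b = purrr::map(x$merges, "b")
  )
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected components of the merges performed at or
#' below `height`: cutting below the first merge returns all singletons and
#' cutting above the last returns one cluster.
#'
#' @param dendro A [average_linkage()] tree.
#' @param height Cut height, `>= 0`.
#' @return Tibble `object_id`, `cluster` (integer labels in leaf order of
#'   first appearance).
#' @export
cut_tree <- function(dendro, height) {
  stopifnot(inherits(dendro, "pb_dendro"))
  if (length(height) != 1 || height < 0) abort("`height` must be a single value >= 0.")
  cl <- cutree(dendro$hc, h = height)
  tibble::tibble(object_id = names(cl), cluster = as.integer(cl))
}

#' Pair-counting agreement between two partitions
#'
#' Counts object pairs placed together/apart in each partition: the Rand
#' index is the fraction of pairs on which the partitions agree (1 for
#' identical partitions) and the Hubert-Arabie adjusted Rand corrects for
#' chance. A cluster cross-table is returned alongside.
#'
#' @param a,b Partitions over the same objects: tibbles with `object_id`
#'   and `cluster` columns (as from [cut_tree()]) or named vectors.
#' @return List with `rand`, `adjusted_rand`, `table` (cross-tabulation),
#'   `n_objects`.
#' @export
compare_partitions <- function(a, b) {
  pa <- as_partition(a)
  pb <- as_partition(b)
  if (!setequal(names(pa), names(pb))) abort("Partitions are over different object sets.")
  pb <- pb[names(pa)]
  q <- length(pa)
  if (q < 2) abort("Need at least 2 objects.")
  tab <- table(pa, pb)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  total <- choose(q, 2)
  rand <- (total + 2 * nij - ai - bj) / total
  expected <- ai * bj / total
  denom <- (ai + bj) / 2 - expected
  ari <- if (abs(denom) < 1e-12) 1 else (nij - expected) / denom
  list(rand = rand, adjusted_rand = ari, table = tab, n_objects = q)
}

as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("object_id", "cluster") %in% names(x))) {
      abort("A partition tibble needs `object_id` and `cluster` columns.")
    }
    return(setNames(x$cluster, x$object_id))
  }
  if (is.null(names(x))) abort("A partition vector must be named by object id.")
  x
}

#' Heuristic cut height: midpoint of the largest merge-height gap
#'
#' Scans the (nondecreasing) merge heights and returns the midpoint of the
#' largest gap between consecutive merges — the earliest such gap on ties.
#' A reading aid for choosing a cut by inspection, not an inferential rule.
#'
#' @param dendro A [average_linkage()] tree with at least 3 leaves.
#' @return A single cut height.
#' @export
suggest_cut <- function(dendro) {
  stopifnot(inherits(dendro, "pb_dendro"))
  h <- dendro$hc$height
  if (length(h) < 2) abort("Need at least 3 leaves to locate a gap.")
  gaps <- diff(h)
  i <- which.max(gaps) # which.max takes the earliest on ties
  (h[i] + h[i + 1]) / 2
}

#' Serialise a dendrogram to Newick
#'
#' Branch lengths are height differences between a node's merge height and
#' its children's (leaves sit at height 0), so leaf depths equal merge
#' heights and the tree is ultrametric.
#'
#' @param dendro A [average_linkage()] tree.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
as_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "pb_dendro"))
  hc <- dendro$hc
  node <- function(i, parent_height) {
    if (i < 0) {
      sprintf("%s:%.10g", hc$labels[-i], parent_height)
    } else {
      sprintf("(%s,%s):%.10g",
              node(hc$merge[i, 1], hc$height[i]),
              node(hc$merge[i, 2], hc$height[i]),
              parent_height - hc$height[i])
    }
  }
  root <- nrow(hc$merge)
  s <- sprintf("(%s,%s);",
               node(hc$merge[root, 1], hc$height[root]),
               node(hc$merge[root, 2], hc$height[root]))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
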