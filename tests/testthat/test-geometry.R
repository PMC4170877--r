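test_that("convex hulls keep extreme points only, counter-clockwise", {
  sq <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4) # the interior point is excluded
  expect_false(attr(h, "degenerate"))
  expect_equal(polygon_area(h), 1)

  tri <- cbind(c(0, 2, 1), c(0, 0, 3))
  expect_equal(nrow(convex_hull(tri)), 3)

  set.seed(41)
  pts <- cbind(rnorm(200), rnorm(200))
  h <- convex_hull(pts)
  expect_true(all(points_in_hull(pts, h))) # independent half-plane test per edge
  # consistent winding: positive shoelace sum means counter-clockwise
  x <- h[, 1]; y <- h[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)

  coll <- cbind(1:5, 2 * (1:5))
  expect_true(attr(convex_hull(coll), "degenerate"))
  expect_error(convex_hull(matrix(numeric(0), ncol = 2)), "at least one")
})

test_that("shoelace area matches closed forms and is winding/rotation invariant", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(cbind(c(0, 4, 0), c(0, 0, 3))), 6)
  expect_equal(polygon_area(sq[4:1, ]), 1) # reversed winding
  expect_equal(polygon_area(sq[c(3, 4, 1, 2), ]), 1) # cyclic rotation
  expect_error(polygon_area(sq[1:2, ]), "3 vertices")
})

test_that("area and centroid agree with Monte-Carlo and fan-triangulation oracles", {
  set.seed(42)
  for (i in 1:5) {
    poly <- rand_convex_polygon(10)
    a <- polygon_area(poly)
    mc <- mc_area(poly, 2e5)
    expect_lt(abs(a - mc$area), 3 * mc$se)
    expect_equal(unname(polygon_centroid(poly))[1:2], unname(fan_centroid(poly)),
                 tolerance = 1e-9)
  }
})

test_that("centroids satisfy symmetry, the triangle identity, and interiority", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(unname(polygon_centroid(sq))[1:2], c(0.5, 0.5), tolerance = 1e-12)
  set.seed(43)
  tri <- cbind(rnorm(3), rnorm(3))
  expect_equal(unname(polygon_centroid(tri))[1:2], unname(colMeans(tri)),
               tolerance = 1e-12)
  poly <- rand_convex_polygon(8)
  cen <- polygon_centroid(poly)
  expect_true(points_in_hull(rbind(c(cen[1], cen[2])), poly, tol = -1e-9))
  # degenerate fallback: collinear "polygon" -> vertex mean, flagged
  flat <- cbind(c(0, 1, 2), c(0, 1, 2))
  cen_flat <- polygon_centroid(flat)
  expect_true(attr(cen_flat, "degenerate"))
  expect_equal(unname(cen_flat)[1:2], c(1, 1))
})

test_that("area/centroid transform correctly under translation, rotation, scaling", {
  set.seed(44)
  poly <- rand_convex_polygon(9)
  a <- polygon_area(poly)
  cen <- unname(polygon_centroid(poly))[1:2]
  shift <- sweep(poly, 2, c(3, -7), "+")
  expect_equal(polygon_area(shift), a, tolerance = 1e-9)
  expect_equal(unname(polygon_centroid(shift))[1:2], cen + c(3, -7), tolerance = 1e-9)
  th <- 0.7
  rot <- poly %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(polygon_area(rot), a, tolerance = 1e-9)
  expect_equal(polygon_area(poly * 3), 9 * a, tolerance = 1e-9)
  expect_equal(unname(polygon_centroid(poly * 3))[1:2], 3 * cen, tolerance = 1e-9)
})

test_that("trimming keeps the contract count and shrinks outlier-driven hulls", {
  set.seed(45)
  pts <- cbind(rnorm(100), rnorm(100))
  t0 <- trim_cloud(pts, 0) # alpha = 0 is the identity on the point set
  expect_equal(unname(t0), unname(pts))
  expect_gte(nrow(trim_cloud(pts, 0.10)), 90)
  with_outliers <- rbind(pts, cbind(runif(5, 8, 12), runif(5, 8, 12)))
  a0 <- polygon_area(convex_hull(with_outliers))
  a10 <- polygon_area(convex_hull(trim_cloud(with_outliers, 0.10)))
  expect_lt(a10, a0)
  # mahalanobis route obeys the same count contract
  expect_identical(nrow(trim_cloud(pts, 0.25, method = "mahalanobis")), 75L)
  expect_error(trim_cloud(pts, 1), "alpha")
})

test_that("polygon overlap is symmetric with analytic intersection areas", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  self <- polygons_overlap(sq, sq)
  expect_true(self$overlap)
  expect_equal(self$area, 1, tolerance = 1e-9)

  far <- sweep(sq, 2, c(10, 10), "+")
  expect_false(polygons_overlap(sq, far)$overlap)
  expect_equal(polygons_overlap(sq, far)$area, 0)

  off <- sweep(sq, 2, c(0.5, 0.5), "+")
  expect_equal(polygons_overlap(sq, off)$area, 0.25, tolerance = 1e-9)
  expect_equal(polygons_overlap(off, sq)$area, 0.25, tolerance = 1e-9)

  # touching edges: overlap flagged, zero area
  touch <- sweep(sq, 2, c(1, 0), "+")
  got <- polygons_overlap(sq, touch)
  expect_true(got$overlap)
  expect_equal(got$area, 0, tolerance = 1e-9)

  # intersection area never exceeds the smaller polygon
  set.seed(46)
  for (i in 1:10) {
    a <- rand_convex_polygon(8)
    b <- sweep(rand_convex_polygon(8), 2, runif(2, -1, 1), "+")
    got <- polygons_overlap(a, b)
    expect_lte(got$area, min(polygon_area(a), polygon_area(b)) + 1e-9)
    expect_equal(got$area, polygons_overlap(b, a)$area, tolerance = 1e-9)
  }

  # degenerate input: a segment crossing a square overlaps with area 0
  seg <- cbind(c(-1, 2), c(0.5, 0.5))
  got <- polygons_overlap(seg, sq)
  expect_equal(got$area, 0)
})

test_that("confidence polygons summarise each object's cloud", {
  set.seed(47)
  cloud <- tibble::tibble(
    object_id = rep(c("a", "b"), each = 50),
    replicate = rep(1:50, 2),
    PC1 = rnorm(100, mean = rep(c(0, 5), each = 50)),
    PC2 = rnorm(100)
  )
  po <- confidence_polygons(cloud)
  expect_equal(nrow(po), 2)
  expect_equal(po$n_points, c(50L, 50L))
  for (i in 1:2) {
    own <- cloud[cloud$object_id == po$object_id[i], c("PC1", "PC2")]
    expect_true(all(points_in_hull(as.matrix(own), po$vertices[[i]])))
    expect_equal(po$area[i], polygon_area(po$vertices[[i]]))
    cen <- polygon_centroid(po$vertices[[i]])
    expect_equal(c(po$centroid_x[i], po$centroid_y[i]), unname(cen)[1:2])
  }
  expect_true(all(confidence_polygons(cloud, alpha = 0.1)$area <= po$area))
  expect_s3_class(autoplot(po), "ggplot")
})
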