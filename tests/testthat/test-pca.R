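test_that("standardization centers and scales with the n-1 denominator", {
  d <- tibble::tibble(id = c("a", "b", "c"), v = c(1, 2, 3))
  s <- standardize_features(d)
  expect_equal(s$v, c(-1, 0, 1)) # sample SD of (1,2,3) is exactly 1

  g <- rand_fm(50, 4, seed = 1)
  gs <- standardize_features(g)
  x <- as.matrix(gs[-1])
  expect_lt(max(abs(colMeans(x))), 1e-10)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-10)

  # idempotent: re-standardizing a standardized table changes nothing
  gs2 <- standardize_features(gs)
  expect_lt(max(abs(as.matrix(gs2[-1]) - x)), 1e-10)
})

test_that("constant and missing columns are rejected by name", {
  d <- tibble::tibble(id = c("a", "b", "c"), ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(standardize_features(d), "flat")
  d$flat <- c(1, NA, 2)
  expect_error(standardize_features(d), "[Mm]issing")
})

test_that("SVD fit satisfies the PCA identities on random matrices", {
  for (seed in 1:5) {
    fm <- rand_fm(30, 5, seed = seed)
    fit <- fit_pca(fm)
    v <- fit$loadings
    expect_lt(max(abs(crossprod(v) - diag(5))), 1e-8)
    # scores computed as X V must equal U D elementwise
    xs <- as.matrix(standardize_features(fm)[-1])
    ud <- svd(xs)$u %*% diag(svd(xs)$d)
    expect_lt(max(abs(abs(fit$scores) - abs(ud))), 1e-8)
    expect_lt(abs(sum(fit$eigenvalues) - 5), 1e-6)
    # full-rank reconstruction
    expect_lt(max(abs(xs - fit$scores %*% t(v))), 1e-8)
    # eigenvalues nonincreasing
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  }
})

test_that("a duplicated column collapses the two-variable fit to one axis", {
  set.seed(3)
  fm <- tibble::tibble(object_id = sprintf("o%d", 1:20), a = rnorm(20))
  fm$b <- fm$a
  fit <- fit_pca(fm)
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-8)
  # appending a duplicate never raises the rank
  fm3 <- rand_fm(20, 3, seed = 4)
  fm3$v4 <- fm3$v1
  rank_of <- function(f) sum(fit_pca(f)$eigenvalues > 1e-10)
  expect_equal(rank_of(fm3), rank_of(fm3[1:4]))
})

test_that("loading signs are fixed deterministically", {
  fm <- rand_fm(25, 4, seed = 9)
  f1 <- fit_pca(fm)
  f2 <- fit_pca(fm[sample(nrow(fm)), ])
  for (j in 1:4) {
    v <- f1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(abs(f1$loadings), abs(f2$loadings), tolerance = 1e-8)
})

test_that("explained variance matches the printed two-axis figure and its identities", {
  ev <- c(8.42, 0.74, rep((10 - 9.16) / 8, 8))
  expect_equal(round(explained_variance(ev, 2), 1), 91.6)
  expect_equal(explained_variance(rep(2.5, 4), 1), 25)
  expect_equal(explained_variance(ev, 10), 100)
  # invariant to uniform rescaling, nondecreasing in m
  expect_equal(explained_variance(ev * 7, 2), explained_variance(ev, 2))
  profile <- vapply(1:10, explained_variance, numeric(1), eigenvalues = ev)
  expect_true(all(diff(profile) >= 0))
  expect_error(explained_variance(ev, 0))
  expect_error(explained_variance(ev, 11))
})

test_that("supplementary projection reproduces training scores and brute-force products", {
  fm <- rand_fm(12, 5, seed = 11)
  fit <- fit_pca(fm)
  xs <- standardize_features(fm)
  z <- project_supplementary(fit, xs, m = 5)
  expect_equal(as.matrix(z[-1]), unname(fit$scores), ignore_attr = TRUE, tolerance = 1e-10)

  expect_equal(unlist(project_supplementary(fit, rep(0, 5), m = 3)),
               c(PC1 = 0, PC2 = 0, PC3 = 0))

  set.seed(12)
  row <- rnorm(5)
  got <- unlist(project_supplementary(fit, row, m = 4))
  manual <- vapply(1:4, function(j) sum(row * fit$loadings[, j]), numeric(1))
  expect_equal(unname(got), manual, tolerance = 1e-10)

  expect_error(project_supplementary(fit, rnorm(4)), "variables")
  # unstandardized input goes through the training moments
  z2 <- project_supplementary(fit, fm, standardized = FALSE)
  expect_equal(as.matrix(z2[-1]), unname(fit$scores), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("tidiers, scree table and JSON export expose the fit coherently", {
  fm <- rand_fm(20, 4, seed = 21)
  fit <- fit_pca(fm)
  expect_equal(dim(tidy(fit, "loadings")), c(16L, 3L))
  eig <- tidy(fit, "eigenvalues")
  expect_equal(eig$cumulative[4], 100)
  expect_equal(glance(fit)$n, 20)

  st <- scree_table(fit)
  expect_named(st, c("rank", "eigenvalue", "percent", "cumulative", "elbow"))
  expect_lte(sum(st$elbow), 1L)
  # a dominant-factor spectrum (~8.5, then a flat tail) puts the elbow at rank 1
  st1 <- scree_table(fit_pca(synth_feature_matrix(seed = 5)))
  expect_true(st1$elbow[1])

  tf <- tempfile(fileext = ".json")
  write_pca_json(fit, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$eigenvalues, unname(fit$eigenvalues), tolerance = 1e-12)
  expect_equal(back$explained_variance$cumulative[4], 100, tolerance = 1e-12)
})
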