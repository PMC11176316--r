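test_that("covariance_eigen decomposes the column covariance", {
  set.seed(31)
  # independent unit-variance columns at large T: eigenvalues near 1
  big <- roi_timeseries(matrix(rnorm(4000 * 4), 4000), "big")
  eig <- covariance_eigen(big)
  expect_true(all(abs(eig$values - 1) < 3 / sqrt(4000)))
  expect_lt(max(abs(crossprod(eig$vectors) - diag(4))), 1e-8)
  expect_true(all(diff(eig$values) <= 1e-12))

  # duplicated ROI columns: rank deficiency, smallest eigenvalue 0
  base <- matrix(rnorm(30 * 2), 30)
  dup <- roi_timeseries(cbind(base, base[, 1]), "dup")
  expect_lt(min(covariance_eigen(dup)$values), 1e-8)

  # reconstruction oracle
  x <- roi_timeseries(matrix(rnorm(50 * 5), 50), "x")
  e <- covariance_eigen(x)
  recomposed <- e$vectors %*% (e$values * t(e$vectors))
  expect_lt(max(abs(recomposed - cov(x$values))), 1e-8)

  flat <- roi_timeseries(matrix(1, 5, 3), "flat")
  expect_error(covariance_eigen(flat), "degenerate")
})

test_that("eros_weights normalizes, aggregates and renormalizes", {
  e1 <- random_eigstruct(2); e1$values <- c(3, 1)
  expect_equal(eros_weights(list(e1))$omega, c(0.75, 0.25))

  e2 <- random_eigstruct(2); e2$values <- c(1, 3)
  expect_equal(eros_weights(list(e1, e2))$omega, c(0.5, 0.5))

  set.seed(41)
  eigs <- lapply(1:7, function(i) random_eigstruct(5, paste0("s", i)))
  for (agg in c("mean", "max", "min")) {
    w <- eros_weights(eigs, aggregate = agg)
    expect_equal(sum(w$omega), 1, tolerance = 1e-10)
    expect_true(all(w$omega >= 0))
  }
  expect_error(eros_weights(list()), "empty")
})

test_that("eros similarity/distance match their definitions and bounds", {
  set.seed(42)
  a <- random_eigstruct(6, "a")
  w <- uniform_weights(6)
  expect_equal(eros_similarity(a, a, w), 1, tolerance = 1e-12)
  expect_equal(eros_distance(a, a, w), 0, tolerance = 1e-6)

  # pairwise-orthogonal eigenvector sets: similarity 0, distance sqrt(2)
  b <- a
  b$vectors <- a$vectors[, c(2, 1, 4, 3, 6, 5)]
  expect_equal(eros_similarity(a, b, w), 0, tolerance = 1e-12)
  expect_equal(eros_distance(a, b, w), sqrt(2))

  mismatch <- random_eigstruct(4, "m")
  expect_error(eros_similarity(a, mismatch, w), "mismatch")
})

test_that("eros_distance agrees with the direct-summation oracle on random pairs", {
  set.seed(43)
  for (trial in 1:40) {
    n <- sample(2:20, 1)
    a <- random_eigstruct(n, "a")
    b <- random_eigstruct(n, "b")
    w <- eros_weights(list(a, b))
    d <- eros_distance(a, b, w)
    expect_equal(d, eros_distance_oracle(a, b, w), tolerance = 1e-10)
    expect_equal(d, eros_distance(b, a, w), tolerance = 1e-12)
    expect_gte(d, 0)
    expect_lte(d, sqrt(2) + 1e-12)
    s <- eros_similarity(a, b, w)
    expect_gte(s, 0)
    expect_lte(s, 1 + 1e-12)
  }
})

test_that("spca_similarity sums squared cosines over leading pivots", {
  set.seed(44)
  a <- random_eigstruct(5, "a")
  expect_equal(spca_similarity(a, a, 5), 5, tolerance = 1e-10)
  expect_equal(spca_similarity(a, a, 1), 1, tolerance = 1e-10)
  b <- random_eigstruct(5, "b")
  z <- 2
  brute <- 0
  for (i in 1:z) for (j in 1:z) {
    brute <- brute + sum(a$vectors[, i] * b$vectors[, j])^2
  }
  expect_equal(spca_similarity(a, b, z), brute, tolerance = 1e-10)
  expect_error(spca_similarity(a, b, 6), "must not exceed")
})

test_that("knn_eros ranks by distance with lexicographic tie-break", {
  ds <- tiny_cohort(n_per_class = 4, seed = 55)
  eigs <- lapply(ds$series, covariance_eigen)
  w <- eros_weights(eigs)

  # an exact copy of the query ranks first with distance 0
  copy <- ds
  copy$series$clone_of_pat_001 <- roi_timeseries(
    ds$series$pat_001$values, "clone_of_pat_001")
  copy$phenotypes <- phenotype_table(rbind(
    as.data.frame(copy$phenotypes),
    data.frame(subject_id = "clone_of_pat_001", label = 1L, site_id = "site1",
               is_synthetic = FALSE)
  ))
  nn <- knn_eros("pat_001", copy, w, k = 2)
  expect_identical(nn[1], "clone_of_pat_001")

  # k = pool size returns the whole pool
  nn_all <- knn_eros("pat_001", ds, w, k = 3)
  expect_setequal(nn_all, c("pat_002", "pat_003", "pat_004"))

  expect_error(knn_eros("pat_001", ds, w, k = 4), "smaller than k")
})

test_that("knn_eros matches the exhaustive all-pairs oracle", {
  ds <- tiny_cohort(n_per_class = 6, n_rois = 5, seed = 56)
  eigs <- lapply(ds$series, covariance_eigen)
  w <- eros_weights(eigs)
  for (query in ds$phenotypes$subject_id) {
    q_label <- ds$phenotypes$label[ds$phenotypes$subject_id == query]
    pool <- setdiff(ds$phenotypes$subject_id[ds$phenotypes$label == q_label],
                    query)
    d <- vapply(pool, function(id) {
      eros_distance_oracle(eigs[[query]], eigs[[id]], w)
    }, numeric(1))
    oracle <- pool[order(d, pool)][1:3]
    expect_identical(knn_eros(query, ds, w, k = 3, eigs = eigs), oracle)
  }
})

test_that("interpolate is the stated convex combination", {
  expect_equal(interpolate(c(0, 0), c(2, 4), 0.5), c(1, 2))
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(interpolate(x, y, 0), x)
  expect_equal(interpolate(x, y, 1), y)
  expect_error(interpolate(x, y[1:3], 0.5), "lengths")
  expect_error(interpolate(x, y, 1.2), "phi")
})

test_that("augment grows the cohort by gamma with hull and proportion contracts", {
  ds <- compute_features(tiny_cohort(n_per_class = 10, n_rois = 6, seed = 57))
  m <- nrow(ds$phenotypes)
  for (gamma in c(1L, 3L)) {
    aug <- augment(ds, augmentation_config(k = 3, gamma = gamma, seed = 9))
    expect_equal(nrow(aug$phenotypes), gamma * m)
    expect_equal(sum(aug$phenotypes$is_synthetic), (gamma - 1L) * m)
    # per-class proportions preserved
    expect_equal(mean(aug$phenotypes$label), mean(ds$phenotypes$label))
  }
  aug1 <- augment(ds, augmentation_config(k = 3, gamma = 1L, seed = 9))
  expect_identical(aug1, ds)

  aug <- augment(ds, augmentation_config(k = 3, gamma = 2L, seed = 9))
  expect_equal(nrow(aug$provenance), m)
  for (r in seq_len(nrow(aug$provenance))) {
    pr <- aug$provenance[r, ]
    v <- aug$features[pr$synthetic_id, ]
    src_label <- ds$phenotypes$label[ds$phenotypes$subject_id == pr$source_id]
    nb_label <- ds$phenotypes$label[ds$phenotypes$subject_id == pr$neighbor_id]
    expect_equal(aug$phenotypes$label[
      aug$phenotypes$subject_id == pr$synthetic_id], src_label)
    expect_equal(nb_label, src_label)   # same-class neighbour pool
    # convexity oracle: synthetic vector inside the componentwise hull of
    # its source and chosen neighbour
    lo <- pmin(ds$features[pr$source_id, ], ds$features[pr$neighbor_id, ])
    hi <- pmax(ds$features[pr$source_id, ], ds$features[pr$neighbor_id, ])
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  }

  # determinism under seed, divergence across seeds
  aug2 <- augment(ds, augmentation_config(k = 3, gamma = 2L, seed = 9))
  expect_identical(aug, aug2)
  aug3 <- augment(ds, augmentation_config(k = 3, gamma = 2L, seed = 10))
  expect_false(identical(aug$features, aug3$features))

  expect_error(augment(tiny_cohort(n_per_class = 3, seed = 57),
                       augmentation_config(k = 3, gamma = 2)),
               "features")
  small <- compute_features(tiny_cohort(n_per_class = 3, seed = 57))
  expect_error(augment(small, augmentation_config(k = 3, gamma = 2)),
               "pool too small")
})
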