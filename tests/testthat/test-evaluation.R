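pheno_of <- function(n, n_sites = 1, labels = rep(c(0L, 1L), length.out = n)) {
  phenotype_table(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    label = labels,
    site_id = paste0("site", rep_len(seq_len(n_sites), n))
  ))
}

test_that("make_folds partitions the cohort under each scheme", {
  plan <- make_folds(pheno_of(20), "nested_kfold", n_outer = 10, seed = 2)
  expect_length(plan$folds, 10L)
  sizes <- vapply(plan$folds, function(f) length(f$test_ids), integer(1))
  expect_true(all(sizes == 2L))
  all_test <- unlist(lapply(plan$folds, `[[`, "test_ids"))
  expect_setequal(all_test, pheno_of(20)$subject_id)
  for (f in plan$folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_length(intersect(f$validation_ids, f$test_ids), 0L)
    expect_length(intersect(f$train_ids, f$validation_ids), 0L)
    expect_gt(length(f$validation_ids), 0L)  # nested: inner split present
  }

  loo <- make_folds(pheno_of(7), "loocv")
  expect_length(loo$folds, 7L)
  expect_true(all(vapply(loo$folds, function(f) length(f$test_ids), integer(1)) == 1L))

  pheno_sites <- phenotype_table(data.frame(
    subject_id = sprintf("s%02d", 1:15),
    label = rep(c(0L, 1L), length.out = 15),
    site_id = rep(c("A", "B", "C"), times = c(4, 5, 6))
  ))
  loso <- make_folds(pheno_sites, "leave_one_site_out")
  expect_equal(sort(vapply(loso$folds, function(f) length(f$test_ids), integer(1))),
               c(4L, 5L, 6L))
  for (f in loso$folds) {
    test_sites <- pheno_sites$site_id[match(f$test_ids, pheno_sites$subject_id)]
    expect_length(unique(test_sites), 1L)
  }

  expect_error(make_folds(pheno_of(5), "nested_kfold", n_outer = 10), "fewer")
  expect_error(make_folds(pheno_of(6, n_sites = 1), "leave_one_site_out"),
               "2 sites")
})

test_that("compute_metrics reproduces the worked example and handles edge cases", {
  met <- compute_metrics(c(1L, 1L, 0L, 0L), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(met$accuracy, 0.5)
  expect_equal(met$precision, 0.5)
  expect_equal(met$recall, 0.5)
  expect_equal(met$auc, 0.75)

  perfect <- compute_metrics(c(1L, 0L, 1L, 0L), c(0.9, 0.1, 0.8, 0.2))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "auc")]) == 1))

  expect_error(compute_metrics(c(1L, 1L), c(0.2, 0.9)), "single class")

  none_pos <- compute_metrics(c(1L, 0L), c(0.1, 0.05))
  expect_false(none_pos$precision_defined)
  expect_equal(none_pos$precision, 0)
})

test_that("metric suite agrees with the confusion-table oracle on random vectors", {
  set.seed(81)
  for (trial in 1:200) {
    n <- sample(4:30, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 2)   # rounding makes ties plausible
    got <- compute_metrics(y, p)
    want <- metrics_oracle(y, p)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
  }
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  set.seed(82)
  y <- sample(0:1, 40, replace = TRUE)
  y[1:2] <- c(0L, 1L)
  p <- runif(40)
  a0 <- compute_metrics(y, p)$auc
  expect_equal(compute_metrics(y, p^3)$auc, a0)
  expect_equal(compute_metrics(y, plogis(5 * p - 2))$auc, a0)
})

test_that("compare_models implements the paired two-sided t-test", {
  a <- c(0.7, 0.8, 0.75, 0.9, 0.85)
  same <- compare_models(a, a)
  expect_equal(same$t, 0)
  expect_false(same$significant)
  expect_identical(same$flag, "zero_variance")

  set.seed(83)
  b <- a + 0.1 + rnorm(5, sd = 0.01)
  res <- compare_models(b, a, alpha = 0.01)
  d <- b - a
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_ref), df = 4), tolerance = 1e-12)
  expect_true(res$significant)

  swapped <- compare_models(a, b)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  expect_error(compare_models(a, a[1:3]), "equal fold counts")
})

fast_pipeline <- function(seed = 1) {
  pipeline_config(
    dae = dae_config(input_dim = 15, bottleneck_dim = 6, max_epochs = 3,
                     learning_rate = 1e-2, seed = 1),
    cnn = cnn_config(input_length = 6, conv_specs = list(c(3L, 4L)),
                     pool_after = integer(0), bn_conv = 1L, fc_width = 4,
                     learning_rate = 1e-2, max_epochs = 3, batch_size = 8,
                     seed = 1),
    augmentation = augmentation_config(k = 2, gamma = 2, seed = 1),
    seed = seed
  )
}

test_that("run_protocol is deterministic and writes coherent reports", {
  ds <- tiny_cohort(n_per_class = 8, n_rois = 6, seed = 91)
  plan <- make_folds(ds$phenotypes, "nested_kfold", n_outer = 4, seed = 3)
  r1 <- run_protocol(ds, plan, fast_pipeline())
  r2 <- run_protocol(ds, plan, fast_pipeline())
  expect_identical(r1$folds, r2$folds)
  expect_equal(nrow(r1$folds), 4L)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  vals <- unlist(r1$folds[metric_cols])
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_equal(r1$aggregate$mean$accuracy, mean(r1$folds$accuracy))
})

test_that("the leakage guard trips on a corrupted fold plan", {
  ds <- tiny_cohort(n_per_class = 6, n_rois = 6, seed = 92)
  plan <- make_folds(ds$phenotypes, "nested_kfold", n_outer = 3, seed = 3)
  # deliberately corrupt: a test subject also appears in the train set
  plan$folds[[1]]$train_ids <- c(plan$folds[[1]]$train_ids,
                                 plan$folds[[1]]$test_ids[1])
  expect_error(run_protocol(ds, plan, fast_pipeline()), "leakage guard")
})
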