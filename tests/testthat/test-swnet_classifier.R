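fresh_encoder <- function(d_in, d_out, seed = 1) {
  withr::with_seed(seed, structure(
    list(W = matrix(rnorm(d_in * d_out, sd = 0.1), d_in), b = rnorm(d_out),
         activation = "relu", scale = NULL),
    class = "encoder_weights"
  ))
}

tiny_cnn_cfg <- function(...) {
  defaults <- list(input_length = 16, conv_specs = list(c(3L, 4L), c(3L, 8L)),
                   pool_after = c(1L, 2L), bn_conv = c(1L, 2L), fc_width = 8,
                   learning_rate = 1e-2, max_epochs = 15,
                   early_stop_patience = 5, batch_size = 8, seed = 3)
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

test_that("full-scale output shapes reproduce the architecture table", {
  shapes <- compute_output_shapes(cnn_config())
  conv_pool <- shapes[grepl("^(Conv|MaxPooling)", shapes$layer), ]
  expect_equal(conv_pool$length,
               c(1994L, 997L, 993L, 496L, 494L, 492L, 246L, 244L, 242L, 240L, 120L))
  expect_equal(conv_pool$channels,
               c(16L, 16L, 32L, 32L, 64L, 128L, 128L, 256L, 512L, 1024L, 1024L))
  expect_equal(shapes$length[shapes$layer == "Fully connected"], 256L)
  expect_equal(shapes$length[shapes$layer == "Sigmoid"], 1L)
})

test_that("shape arithmetic follows the conv/pool recurrences on random configs", {
  set.seed(61)
  for (trial in 1:20) {
    n_conv <- sample(1:4, 1)
    kernels <- sample(c(1L, 3L, 5L, 7L), n_conv, replace = TRUE)
    filters <- sample(c(2L, 4L, 8L), n_conv, replace = TRUE)
    pool <- which(runif(n_conv) < 0.5)
    len0 <- sample(40:120, 1)
    cfg <- try(cnn_config(input_length = len0,
                          conv_specs = Map(c, kernels, filters),
                          pool_after = pool, bn_conv = integer(0),
                          fc_width = 4), silent = TRUE)
    # step-by-step oracle
    len <- len0
    expected <- integer(0)
    ok <- TRUE
    for (i in seq_len(n_conv)) {
      len <- len - kernels[i] + 1L
      if (len <= 0L) { ok <- FALSE; break }
      expected <- c(expected, len)
      if (i %in% pool) {
        len <- len %/% 2L
        if (len <= 0L) { ok <- FALSE; break }
        expected <- c(expected, len)
      }
    }
    if (!ok) {
      expect_error(compute_output_shapes(cfg), "nonpositive")
    } else {
      shapes <- compute_output_shapes(cfg)
      got <- shapes$length[grepl("^(Conv|MaxPooling)", shapes$layer)]
      expect_equal(got, expected)
    }
  }
})

test_that("kernel size 1 preserves length", {
  cfg <- cnn_config(input_length = 50, conv_specs = list(c(1L, 4L)),
                    pool_after = integer(0), bn_conv = integer(0), fc_width = 4)
  shapes <- compute_output_shapes(cfg)
  expect_equal(shapes$length[shapes$layer == "Conv 0"], 50L)
})

test_that("conv parameter count matches the closed form", {
  expect_equal(conv_parameter_count(cnn_config()),
               7 * 1 * 16 + 16 + 5 * 16 * 32 + 32 + 3 * 32 * 64 + 64 +
                 3 * 64 * 128 + 128 + 3 * 128 * 256 + 256 +
                 3 * 256 * 512 + 512 + 3 * 512 * 1024 + 1024)
  cfg <- tiny_cnn_cfg()
  model <- build_swnet(fresh_encoder(30, 16), cfg)
  got <- sum(vapply(grep("^conv", names(model$params), value = TRUE),
                    function(nm) length(model$params[[nm]]), numeric(1)))
  expect_equal(got, conv_parameter_count(cfg))
})

test_that("build_swnet enforces the shared-weight contract and seeded init", {
  enc <- fresh_encoder(30, 16)
  m1 <- build_swnet(enc, tiny_cnn_cfg())
  expect_identical(m1$encoder$W, enc$W)
  expect_identical(m1$encoder$b, enc$b)
  expect_identical(m1$params$enc_W, enc$W)

  m2 <- build_swnet(enc, tiny_cnn_cfg())
  expect_identical(m1$params, m2$params)
  m3 <- build_swnet(enc, tiny_cnn_cfg(seed = 99))
  expect_false(identical(m1$params$conv1_W, m3$params$conv1_W))

  expect_error(build_swnet(fresh_encoder(30, 12), tiny_cnn_cfg()),
               "bottleneck")
})

blob_data <- function(n = 60, d = 30, seed = 71) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * d), n)
    x[y == 1L, 1:10] <- x[y == 1L, 1:10] + 2.5
    list(x = x, y = y)
  })
}

test_that("zero learning rate leaves parameters untouched", {
  dat <- blob_data()
  model <- build_swnet(fresh_encoder(30, 16), tiny_cnn_cfg(learning_rate = 0))
  fit <- train_joint(model, dat$x, dat$y)
  expect_identical(fit$model$params, model$params)
})

test_that("joint training separates linear blobs and updates the encoder", {
  dat <- blob_data()
  cfg <- tiny_cnn_cfg(max_epochs = 50)
  model <- build_swnet(fresh_encoder(30, 16), cfg)
  fit <- train_joint(model, dat$x, dat$y, val_features = dat$x,
                     val_labels = dat$y, config = cfg)
  prob <- predict_proba(fit$model, dat$x)
  expect_gte(mean(classify(prob) == dat$y), 0.95)
  # descent contract on the log endpoints
  expect_lte(tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  # encoder diverged from its initialization: weight sharing is trainable
  expect_false(identical(fit$model$params$enc_W, model$params$enc_W))
  expect_gt(max(abs(fit$model$params$enc_W - model$params$enc_W)), 0)

  expect_error(train_joint(model, dat$x, rep(1L, nrow(dat$x))), "both classes")
})

test_that("training is deterministic under the config seed", {
  dat <- blob_data(n = 24)
  cfg <- tiny_cnn_cfg(max_epochs = 4)
  f1 <- train_joint(build_swnet(fresh_encoder(30, 16), cfg), dat$x, dat$y,
                    config = cfg)
  f2 <- train_joint(build_swnet(fresh_encoder(30, 16), cfg), dat$x, dat$y,
                    config = cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$log, f2$log)
})

test_that("predict_proba is a deterministic probability, batch-consistent", {
  dat <- blob_data(n = 24)
  model <- build_swnet(fresh_encoder(30, 16), tiny_cnn_cfg())
  set.seed(5)
  x <- matrix(rnorm(6 * 30), 6)
  p <- predict_proba(model, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_proba(model, x))
  for (i in 1:6) expect_equal(p[i], predict_proba(model, x[i, ]))
  expect_error(predict_proba(model, rnorm(10)), "expects")
})

test_that("dropout is stochastic in training mode only", {
  model <- build_swnet(fresh_encoder(30, 16), tiny_cnn_cfg(dropout_rate = 0.5))
  x <- matrix(rnorm(4 * 30), 4)
  set.seed(1)
  p1 <- swnet:::swnet_forward(model, x, train = TRUE)$prob
  p2 <- swnet:::swnet_forward(model, x, train = TRUE)$prob
  expect_false(identical(p1, p2))
  e1 <- swnet:::swnet_forward(model, x, train = FALSE)$prob
  e2 <- swnet:::swnet_forward(model, x, train = FALSE)$prob
  expect_identical(e1, e2)
})

test_that("classify thresholds with ties going positive", {
  expect_identical(classify(0.7), 1L)
  expect_identical(classify(0.5), 1L)
  expect_identical(classify(0.49), 0L)
  expect_identical(classify(c(0.2, 0.8), threshold = 0.5), c(0L, 1L))
  expect_error(classify(0.5, threshold = 1.5), "threshold")
})
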