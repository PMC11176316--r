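#' 1-D CNN configuration
#'
#' Describes the supervised network: a stack of valid (no padding, stride 1)
#' 1-D convolutions with rectified-linear activations, batch normalization
#' on a configurable subset of the conv layers (by design absent from the
#' middle three at full scale), max pooling (window 2, floor division) after
#' selected conv layers, then a fully-connected layer, dropout, and a
#' single sigmoid output unit giving P(patient). Trained with the Adam
#' optimizer on binary cross-entropy.
#'
#' The defaults are the full-scale architecture for a 2000-length input:
#' conv (kernel, filters) pairs (7,16), (5,32), (3,64), (3,128), (3,256),
#' (3,512), (3,1024); pooling after conv layers 1, 2, 4 and 7 (1-based);
#' batch norm on conv layers 1, 2, 6 and 7; fully-connected width 256;
#' dropout 0.3; learning rate 1e-4; 200 epochs with patience 20.
#'
#' @param input_length length of the (single-channel) input sequence — the
#'   encoder bottleneck width in the shared-weight assembly.
#' @param conv_specs list of `c(kernel, filters)` pairs, in order.
#' @param pool_after 1-based indices of conv layers followed by max pooling.
#' @param bn_conv 1-based indices of conv layers with batch normalization.
#' @param fc_width width of the fully-connected layer.
#' @param dropout_rate dropout probability after the fully-connected layer.
#' @param learning_rate Adam learning rate.
#' @param max_epochs,early_stop_patience,batch_size training budget.
#' @param seed integer seed for initialization and minibatch order.
#' @return a `cnn_config`.
#' @export
cnn_config <- function(input_length = 2000L,
                       conv_specs = list(c(7L, 16L), c(5L, 32L), c(3L, 64L),
                                         c(3L, 128L), c(3L, 256L),
                                         c(3L, 512L), c(3L, 1024L)),
                       pool_after = c(1L, 2L, 4L, 7L),
                       bn_conv = c(1L, 2L, 6L, 7L),
                       fc_width = 256L, dropout_rate = 0.3,
                       learning_rate = 1e-4, max_epochs = 200L,
                       early_stop_patience = 20L, batch_size = 16L,
                       seed = 1L) {
  stopifnot(input_length >= 1L, length(conv_specs) >= 1L,
            all(pool_after %in% seq_along(conv_specs)),
            all(bn_conv %in% seq_along(conv_specs)),
            fc_width >= 1L, dropout_rate >= 0, dropout_rate < 1,
            learning_rate >= 0, max_epochs >= 0L,
            early_stop_patience >= 1L, batch_size >= 1L)
  structure(
    list(input_length = as.integer(input_length),
         conv_specs = lapply(conv_specs, as.integer),
         pool_after = as.integer(pool_after),
         bn_conv = as.integer(bn_conv),
         fc_width = as.integer(fc_width), dropout_rate = dropout_rate,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Miniature CNN configuration for desk-scale experiments
#'
#' Same design pattern as the full architecture — valid convolutions,
#' floor-halving max pooling, batch norm at the outer conv layers but not
#' the middle, dropout before a sigmoid head — shrunk so that a 64-length
#' bottleneck survives the stack. (The full seven-conv stack needs an input
#' of at least 78, so a faithful bottleneck-64 miniature necessarily uses a
#' shorter stack.) The learning rate is raised to 1e-3, the usual Adam
#' magnitude for a network this small with a short epoch budget.
#'
#' @param input_length bottleneck width (default 64).
#' @param seed integer seed.
#' @param ... overrides passed on to [cnn_config()].
#' @return a `cnn_config`.
#' @export
cnn_config_miniature <- function(input_length = 64L, seed = 1L, ...) {
  defaults <- list(
    input_length = input_length,
    conv_specs = list(c(7L, 8L), c(5L, 16L), c(3L, 32L)),
    pool_after = c(1L, 2L, 3L),
    bn_conv = c(1L, 3L),
    fc_width = 32L, dropout_rate = 0.3,
    learning_rate = 1e-3, max_epochs = 60L, early_stop_patience = 10L,
    batch_size = 16L, seed = seed
  )
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

#' Per-layer output shapes of a CNN configuration
#'
#' Applies the valid-convolution recurrence `L_out = L_in - kernel + 1` and
#' floor-halving pooling `L_out = floor(L_in / 2)` through the stack.
#'
#' @param config a [cnn_config()].
#' @return data.frame with columns `layer`, `length`, `channels`, covering
#'   input, every conv/pool layer, the fully-connected layer and the sigmoid
#'   head.
#' @export
compute_output_shapes <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  len <- config$input_length
  ch <- 1L
  rows <- list(data.frame(layer = "Input", length = len, channels = ch))
  for (i in seq_along(config$conv_specs)) {
    spec <- config$conv_specs[[i]]
    len <- len - spec[1L] + 1L
    ch <- spec[2L]
    if (len <= 0L) {
      stop(sprintf("layer 'Conv %d' has nonpositive output length %d", i - 1L, len),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("Conv %d", i - 1L), length = len, channels = ch)
    if (i %in% config$pool_after) {
      len <- len %/% 2L
      if (len <= 0L) {
        stop(sprintf("layer 'MaxPooling after Conv %d' has nonpositive output length",
                     i - 1L), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(layer = sprintf("MaxPooling %d", match(i, config$pool_after) - 1L),
                   length = len, channels = ch)
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "Fully connected", length = config$fc_width, channels = 1L)
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "Sigmoid", length = 1L, channels = 1L)
  do.call(rbind, rows)
}

#' Number of trainable parameters in the conv stack
#'
#' `sum(kernel * in_channels * out_channels + out_channels)` over the conv
#' specs (batch-norm and dense parameters excluded).
#'
#' @param config a [cnn_config()].
#' @return integer parameter count.
#' @export
conv_parameter_count <- function(config) {
  in_ch <- 1L
  total <- 0L
  for (spec in config$conv_specs) {
    total <- total + spec[1L] * in_ch * spec[2L] + spec[2L]
    in_ch <- spec[2L]
  }
  total
}

refresh_encoder <- function(model) {
  model$encoder <- structure(
    list(W = model$params$enc_W, b = model$params$enc_b,
         activation = model$encoder_meta$activation,
         scale = model$encoder_meta$scale),
    class = "encoder_weights"
  )
  model
}

#' Assemble the shared-weight model
#'
#' Prepends the pretrained dense encoder to the CNN: the encoder's weights
#' are copied into the assembled model (numerically identical at build
#' time — the shared-weight contract) and every remaining parameter is
#' freshly initialized from `config$seed`. During joint training both the
#' encoder stage and the CNN receive gradient updates.
#'
#' @param enc an `encoder_weights` from [train_dae()]; its bottleneck width
#'   must equal `config$input_length`.
#' @param config a [cnn_config()].
#' @return a `swnet_model`.
#' @export
build_swnet <- function(enc, config) {
  stopifnot(inherits(enc, "encoder_weights"), inherits(config, "cnn_config"))
  if (ncol(enc$W) != config$input_length) {
    stop(sprintf("encoder bottleneck %d != cnn input_length %d",
                 ncol(enc$W), config$input_length), call. = FALSE)
  }
  shapes <- compute_output_shapes(config)   # validates all lengths
  withr::with_seed(config$seed, {
    params <- list(enc_W = enc$W, enc_b = enc$b)
    bn_state <- list()
    in_ch <- 1L
    for (i in seq_along(config$conv_specs)) {
      spec <- config$conv_specs[[i]]
      params[[sprintf("conv%d_W", i)]] <-
        he_init(spec[1L] * in_ch, spec[2L], fan_in = spec[1L] * in_ch)
      params[[sprintf("conv%d_b", i)]] <- numeric(spec[2L])
      if (i %in% config$bn_conv) {
        params[[sprintf("bn%d_gamma", i)]] <- rep(1, spec[2L])
        params[[sprintf("bn%d_beta", i)]] <- numeric(spec[2L])
        bn_state[[sprintf("bn%d", i)]] <-
          list(mean = numeric(spec[2L]), var = rep(1, spec[2L]))
      }
      in_ch <- spec[2L]
    }
    conv_rows <- grepl("^(Conv|MaxPooling)", shapes$layer)
    last <- shapes[max(which(conv_rows)), ]
    flat_dim <- last$length * last$channels
    params$fc_W <- he_init(flat_dim, config$fc_width)
    params$fc_b <- numeric(config$fc_width)
    params$out_W <- he_init(config$fc_width, 1L)
    params$out_b <- 0
    model <- structure(
      list(params = params, bn_state = bn_state,
           encoder_meta = list(activation = enc$activation, scale = enc$scale),
           config = config, trained = FALSE),
      class = "swnet_model"
    )
    refresh_encoder(model)
  })
}

#' @export
print.swnet_model <- function(x, ...) {
  cat(sprintf(
    "<swnet_model> encoder %d -> %d, %d conv layers, fc %d, %s\n",
    nrow(x$params$enc_W), ncol(x$params$enc_W),
    length(x$config$conv_specs), x$config$fc_width,
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# full forward pass; train = TRUE uses batch statistics, draws dropout masks
# from the current RNG stream, and (when update_bn) refreshes running stats
swnet_forward <- function(model, x, train = FALSE, update_bn = train) {
  p <- model$params
  cfg <- model$config
  cache <- list(x = x)
  if (!is.null(model$encoder_meta$scale)) {
    sc <- model$encoder_meta$scale
    x <- sweep(sweep(x, 2L, sc$mu, "-"), 2L, sc$sd, "/")
    cache$x <- x
  }
  h <- activation_fwd(sweep(x %*% p$enc_W, 2L, p$enc_b, "+"),
                      model$encoder_meta$activation)
  cache$enc_h <- h
  a <- array(h, dim = c(nrow(h), ncol(h), 1L))
  cache$blocks <- list()
  bn_state <- model$bn_state
  for (i in seq_along(cfg$conv_specs)) {
    blk <- list(x_dim = dim(a), kernel = cfg$conv_specs[[i]][1L])
    cv <- conv1d_fwd(a, p[[sprintf("conv%d_W", i)]], p[[sprintf("conv%d_b", i)]])
    blk$m <- cv$m
    a <- cv$y
    if (i %in% cfg$bn_conv) {
      key <- sprintf("bn%d", i)
      bn <- bn_fwd(a, p[[sprintf("bn%d_gamma", i)]], p[[sprintf("bn%d_beta", i)]],
                   bn_state[[key]], train = train)
      a <- bn$y
      blk$bn <- bn[c("xhat", "inv_sd")]
      if (update_bn) bn_state[[key]] <- bn$running
    }
    relu_out <- pmax(a, 0)
    blk$relu_out <- relu_out
    a <- relu_out
    if (i %in% cfg$pool_after) {
      mp <- maxpool2_fwd(a)
      a <- mp$y
      blk$pool <- mp[c("take_first", "l_in")]
    }
    cache$blocks[[i]] <- blk
  }
  cache$conv_out_dim <- dim(a)
  flat <- matrix(a, nrow = dim(a)[1L])
  cache$flat <- flat
  fc <- pmax(sweep(flat %*% p$fc_W, 2L, p$fc_b, "+"), 0)
  cache$fc <- fc
  fc_drop <- fc
  if (train && cfg$dropout_rate > 0) {
    mask <- matrix(
      stats::rbinom(length(fc), 1L, 1 - cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(fc), ncol(fc)
    )
    fc_drop <- fc * mask
    cache$drop_mask <- mask
  }
  cache$fc_drop <- fc_drop
  z <- sweep(fc_drop %*% p$out_W, 2L, p$out_b, "+")
  prob <- sigmoid(z)
  list(prob = drop(prob), cache = cache, bn_state = bn_state)
}

# gradients of BCE loss wrt every parameter; dz = (p - y) / N
swnet_backward <- function(model, cache, prob, y) {
  p <- model$params
  cfg <- model$config
  n <- length(y)
  grads <- list()
  dz <- matrix((prob - y) / n, ncol = 1L)
  grads$out_W <- crossprod(cache$fc_drop, dz)
  grads$out_b <- sum(dz)
  dfc_drop <- tcrossprod(dz, p$out_W)
  if (!is.null(cache$drop_mask)) dfc_drop <- dfc_drop * cache$drop_mask
  dfc <- dfc_drop * (cache$fc > 0)
  grads$fc_W <- crossprod(cache$flat, dfc)
  grads$fc_b <- colSums(dfc)
  da <- array(tcrossprod(dfc, p$fc_W), dim = cache$conv_out_dim)
  for (i in rev(seq_along(cfg$conv_specs))) {
    blk <- cache$blocks[[i]]
    if (!is.null(blk$pool)) {
      da <- maxpool2_bwd(da, blk$pool$take_first, blk$pool$l_in)
    }
    da <- da * (blk$relu_out > 0)
    if (!is.null(blk$bn)) {
      bb <- bn_bwd(da, blk$bn$xhat, blk$bn$inv_sd,
                   p[[sprintf("bn%d_gamma", i)]])
      grads[[sprintf("bn%d_gamma", i)]] <- bb$dgamma
      grads[[sprintf("bn%d_beta", i)]] <- bb$dbeta
      da <- bb$dx
    }
    cb <- conv1d_bwd(da, blk$m, p[[sprintf("conv%d_W", i)]],
                     blk$x_dim, blk$kernel)
    grads[[sprintf("conv%d_W", i)]] <- cb$dw
    grads[[sprintf("conv%d_b", i)]] <- cb$db
    da <- cb$dx
  }
  dh <- matrix(da, nrow = dim(da)[1L])
  dh <- activation_bwd(dh, cache$enc_h, model$encoder_meta$activation)
  grads$enc_W <- crossprod(cache$x, dh)
  grads$enc_b <- colSums(dh)
  grads
}

#' Jointly train the shared-weight model
#'
#' Minimizes binary cross-entropy with Adam; both the encoder stage and the
#' CNN parameters are updated. Early stopping monitors the validation loss
#' (an internal stratified 10% split is carved out when no validation set is
#' supplied) with the configured patience, restoring the best-validation
#' weights.
#'
#' @param model a `swnet_model` from [build_swnet()].
#' @param features numeric matrix, subjects x encoder input dim.
#' @param labels binary vector (patient = 1, control = 0).
#' @param val_features,val_labels optional held-out set driving early
#'   stopping.
#' @param config optional [cnn_config()] overriding `model$config` for this
#'   training run.
#' @return list with the trained `model` and `log` (per-epoch train loss,
#'   validation loss and validation accuracy).
#' @export
train_joint <- function(model, features, labels, val_features = NULL,
                        val_labels = NULL, config = NULL) {
  stopifnot(inherits(model, "swnet_model"), is.matrix(features),
            nrow(features) == length(labels))
  cfg <- if (is.null(config)) model$config else config
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (any(!is.finite(features))) stop("features must be finite", call. = FALSE)
  withr::with_seed(cfg$seed + 1L, {
    if (is.null(val_features)) {
      idx1 <- which(labels == 1L)
      idx0 <- which(labels == 0L)
      take <- c(idx1[seq_len(max(1L, floor(0.1 * length(idx1))))],
                idx0[seq_len(max(1L, floor(0.1 * length(idx0))))])
      val_features <- features[take, , drop = FALSE]
      val_labels <- labels[take]
      features <- features[-take, , drop = FALSE]
      labels <- labels[-take]
    }
    opt <- list(t = 0L, m = list(), v = list())
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_acc = numeric())
    best <- list(loss = Inf, params = model$params,
                 bn_state = model$bn_state, epoch = 0L)
    for (epoch in seq_len(cfg$max_epochs)) {
      batches <- minibatches(nrow(features), cfg$batch_size)
      epoch_loss <- 0
      for (idx in batches) {
        xb <- features[idx, , drop = FALSE]
        yb <- labels[idx]
        fw <- swnet_forward(model, xb, train = TRUE)
        model$bn_state <- fw$bn_state
        loss <- bce_loss(fw$prob, yb)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        grads <- swnet_backward(model, fw$cache, fw$prob, yb)
        step <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- step$params
        opt <- step$state
      }
      train_loss <- epoch_loss / nrow(features)
      val_fw <- swnet_forward(model, val_features, train = FALSE)
      val_loss <- bce_loss(val_fw$prob, val_labels)
      val_acc <- mean(as.integer(val_fw$prob >= 0.5) == val_labels)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params,
                     bn_state = model$bn_state, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$early_stop_patience) {
        break
      }
    }
    if (cfg$max_epochs > 0L && nrow(log) > 0L && cfg$learning_rate > 0) {
      model$params <- best$params
      model$bn_state <- best$bn_state
    }
    model$trained <- TRUE
    model <- refresh_encoder(model)
    list(model = model, log = log)
  })
}

#' Predict P(patient) for feature vectors
#'
#' Evaluation mode: dropout disabled, batch norm uses running statistics, so
#' repeated calls are bit-identical.
#'
#' @param model a `swnet_model`.
#' @param x numeric vector of encoder-input length, or a matrix of rows.
#' @return probability in `[0, 1]` (vector for matrix input).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "swnet_model"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(model$params$enc_W)) {
    stop(sprintf("input has %d features, model expects %d",
                 ncol(x), nrow(model$params$enc_W)), call. = FALSE)
  }
  pr <- swnet_forward(model, x, train = FALSE)$prob
  if (vec) pr[[1L]] else pr
}

#' Threshold a probability into a class label
#'
#' Ties at the threshold classify as positive (patient).
#'
#' @param prob probability in `[0, 1]` (vectorized).
#' @param threshold decision threshold in `[0, 1]`.
#' @return integer label(s) in `{0, 1}`.
#' @export
classify <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  as.integer(prob >= threshold)
}
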