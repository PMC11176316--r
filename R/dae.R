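#' Denoising autoencoder configuration
#'
#' A single-hidden-layer autoencoder: dense encoder (input -> bottleneck)
#' with a nonlinear activation, mirrored untied linear decoder
#' (bottleneck -> input). Training corrupts each input with additive
#' Gaussian noise (redrawn every epoch) and minimizes the mean squared error
#' between the CLEAN input and the reconstruction of the NOISED input, by
#' stochastic gradient descent with momentum. A fraction of subjects is held
#' out internally to drive early stopping.
#'
#' Defaults mirror the full-scale setting (19,900 input features, 2,000
#' bottleneck units, noise sd 0.1, SGD momentum 0.9, learning rate 1e-4,
#' 200 epochs, patience 20); all dims are configurable so desk-scale tests
#' can run miniatures.
#'
#' @param input_dim number of input features.
#' @param bottleneck_dim bottleneck width, `< input_dim`.
#' @param noise_sigma sd of the additive Gaussian corruption (>= 0).
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param max_epochs maximum training epochs (0 returns the initialization).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; the best-validation weights are restored.
#' @param batch_size minibatch size.
#' @param activation bottleneck activation.
#' @param standardize if `TRUE`, features are z-scored (statistics learned
#'   on the training portion) before entering the network and the scaling is
#'   stored in the encoder.
#' @param val_fraction fraction of subjects held out for early stopping.
#' @param seed integer seed for initialization, shuffling and noise.
#' @return a `dae_config`.
#' @export
dae_config <- function(input_dim = 19900L, bottleneck_dim = 2000L,
                       noise_sigma = 0.1, learning_rate = 1e-4,
                       momentum = 0.9, max_epochs = 200L,
                       early_stop_patience = 20L, batch_size = 16L,
                       activation = c("relu", "sigmoid", "identity"),
                       standardize = FALSE, val_fraction = 0.1, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(bottleneck_dim < input_dim, bottleneck_dim >= 1L,
            noise_sigma >= 0, learning_rate > 0,
            momentum >= 0, momentum < 1, max_epochs >= 0L,
            early_stop_patience >= 1L, batch_size >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(
    list(input_dim = as.integer(input_dim),
         bottleneck_dim = as.integer(bottleneck_dim),
         noise_sigma = noise_sigma, learning_rate = learning_rate,
         momentum = momentum, max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size), activation = activation,
         standardize = standardize, val_fraction = val_fraction,
         seed = as.integer(seed)),
    class = "dae_config"
  )
}

#' Corrupt a feature vector with additive Gaussian noise
#'
#' `x' = x + e` with `e ~ N(0, sigma^2)` i.i.d. per component. The noise is
#' generated as `sigma * rnorm(...)`, so the random stream is consumed
#' identically for every `sigma`, and `sigma = 0` returns `x` exactly.
#'
#' @param x numeric vector or matrix.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer; when given the draw is a deterministic
#'   function of it, otherwise the current RNG stream is used.
#' @return corrupted copy of `x`.
#' @export
add_gaussian_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  draw <- function() x + sigma * stats::rnorm(length(x))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

dae_forward <- function(x, params, activation) {
  h <- activation_fwd(sweep(x %*% params$W1, 2L, params$b1, "+"), activation)
  r <- sweep(h %*% params$W2, 2L, params$b2, "+")
  list(h = h, r = r)
}

#' Train the denoising autoencoder
#'
#' @param features numeric matrix, subjects x `input_dim`.
#' @param config a [dae_config()].
#' @return list with `encoder` (class `encoder_weights`: `W`, `b`,
#'   `activation`, optional `scale`), `decoder` (`W`, `b`) and `log`, a
#'   data.frame of per-epoch training and validation reconstruction loss.
#' @export
train_dae <- function(features, config) {
  stopifnot(is.matrix(features), inherits(config, "dae_config"))
  if (ncol(features) != config$input_dim) {
    stop(sprintf("feature dim %d != configured input_dim %d",
                 ncol(features), config$input_dim), call. = FALSE)
  }
  if (nrow(features) < 2L) stop("need at least 2 subjects", call. = FALSE)
  withr::with_seed(config$seed, {
    n <- nrow(features)
    n_val <- max(1L, floor(config$val_fraction * n))
    if (n - n_val < 1L) stop("too few subjects for a validation split", call. = FALSE)
    val_idx <- sample.int(n, n_val)
    x_train <- features[-val_idx, , drop = FALSE]
    x_val <- features[val_idx, , drop = FALSE]
    scale <- NULL
    if (config$standardize) {
      mu <- colMeans(x_train)
      sdv <- apply(x_train, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      scale <- list(mu = mu, sd = sdv)
      x_train <- sweep(sweep(x_train, 2L, mu, "-"), 2L, sdv, "/")
      x_val <- sweep(sweep(x_val, 2L, mu, "-"), 2L, sdv, "/")
    }
    params <- list(
      W1 = he_init(config$input_dim, config$bottleneck_dim),
      b1 = numeric(config$bottleneck_dim),
      W2 = he_init(config$bottleneck_dim, config$input_dim,
                   fan_in = config$bottleneck_dim),
      b2 = numeric(config$input_dim)
    )
    opt <- list(v = list())
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    best <- list(loss = Inf, params = params, epoch = 0L)
    for (epoch in seq_len(config$max_epochs)) {
      noisy <- x_train + config$noise_sigma * stats::rnorm(length(x_train))
      batches <- minibatches(nrow(x_train), config$batch_size)
      epoch_loss <- 0
      for (idx in batches) {
        xb_clean <- x_train[idx, , drop = FALSE]
        xb_noisy <- noisy[idx, , drop = FALSE]
        fw <- dae_forward(xb_noisy, params, config$activation)
        resid <- fw$r - xb_clean
        epoch_loss <- epoch_loss + sum(resid^2)
        dr <- 2 * resid / length(resid)
        grads <- list(
          W2 = crossprod(fw$h, dr), b2 = colSums(dr)
        )
        dh <- activation_bwd(tcrossprod(dr, params$W2), fw$h, config$activation)
        grads$W1 <- crossprod(xb_noisy, dh)
        grads$b1 <- colSums(dh)
        step <- sgd_momentum_step(params, grads, opt,
                                  config$learning_rate, config$momentum)
        params <- step$params
        opt <- step$state
      }
      train_loss <- epoch_loss / length(x_train)
      # validation monitored on clean inputs: deterministic criterion
      val_resid <- dae_forward(x_val, params, config$activation)$r - x_val
      val_loss <- mean(val_resid^2)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop("non-finite reconstruction loss at epoch ", epoch, call. = FALSE)
      }
      log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= config$early_stop_patience) {
        break
      }
    }
    if (config$max_epochs > 0L && nrow(log) > 0L) params <- best$params
    encoder <- structure(
      list(W = params$W1, b = params$b1, activation = config$activation,
           scale = scale),
      class = "encoder_weights"
    )
    list(encoder = encoder,
         decoder = list(W = params$W2, b = params$b2),
         log = log)
  })
}

#' Encode feature vectors through a trained encoder
#'
#' @param x numeric vector of length `input_dim`, or a matrix with that many
#'   columns (rows encoded independently).
#' @param enc an `encoder_weights` from [train_dae()].
#' @return bottleneck activations: a vector, or a matrix for matrix input.
#' @export
encode <- function(x, enc) {
  stopifnot(inherits(enc, "encoder_weights"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(enc$W)) {
    stop(sprintf("input has %d features, encoder expects %d",
                 ncol(x), nrow(enc$W)), call. = FALSE)
  }
  if (!is.null(enc$scale)) {
    x <- sweep(sweep(x, 2L, enc$scale$mu, "-"), 2L, enc$scale$sd, "/")
  }
  h <- activation_fwd(sweep(x %*% enc$W, 2L, enc$b, "+"), enc$activation)
  if (vec) drop(h) else h
}
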