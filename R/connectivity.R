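#' Pearson functional-connectivity matrix
#'
#' Entry (u, v) is the Pearson correlation between the time courses of ROIs
#' u and v. The result is symmetric with unit diagonal and all entries in
#' `[-1, 1]`.
#'
#' @param ts a [roi_timeseries()].
#' @param strict if `TRUE` (default) a zero-variance ROI is an error naming
#'   the offending column; if `FALSE` its coefficients are set to 0 with a
#'   warning.
#' @return an `fc_matrix`: list with `subject_id` and the `n x n` `values`.
#' @export
pearson_fc <- function(ts, strict = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  zero <- which(sds == 0)
  if (length(zero) > 0L) {
    if (strict) {
      stop(sprintf("zero-variance ROI column(s): %s (subject '%s')",
                   paste(zero, collapse = ", "), ts$subject_id), call. = FALSE)
    }
    warning("zero-variance ROI column(s) ", paste(zero, collapse = ", "),
            ": coefficients set to 0", call. = FALSE)
  }
  keep <- sds > 0
  m <- matrix(0, ncol(x), ncol(x))
  m[keep, keep] <- stats::cor(x[, keep, drop = FALSE])
  diag(m) <- 1
  m <- pmin(pmax((m + t(m)) / 2, -1), 1)
  structure(list(subject_id = ts$subject_id, values = m), class = "fc_matrix")
}

#' Flatten the strict upper triangle of an FC matrix
#'
#' Ordering is row-major over the strict upper triangle: pair (i, j) with
#' `i < j`, i ascending then j — the convention every module of this package
#' shares. For an atlas of `n` ROIs the result has length `n (n - 1) / 2`.
#'
#' @param fc an `fc_matrix` from [pearson_fc()], or a plain symmetric matrix.
#' @param tol symmetry tolerance; asymmetry beyond it is an error.
#' @return numeric vector of length `n (n - 1) / 2`, with a `subject_id`
#'   attribute when available.
#' @export
vectorize_upper <- function(fc, tol = 1e-8) {
  if (inherits(fc, "fc_matrix")) {
    m <- fc$values
    id <- fc$subject_id
  } else {
    m <- fc
    id <- NULL
  }
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  # t(m)[lower.tri] walks the upper triangle row-major (i ascending, then j)
  v <- t(m)[lower.tri(m)]
  if (!is.null(id)) attr(v, "subject_id") <- id
  v
}

#' Rebuild a symmetric unit-diagonal matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] on symmetric unit-diagonal matrices.
#'
#' @param v vector of length `n (n - 1) / 2`.
#' @param n number of ROIs.
#' @return `n x n` symmetric matrix with unit diagonal.
#' @export
unvectorize_upper <- function(v, n) {
  if (length(v) != n * (n - 1L) / 2L) {
    stop("length(v) must be n(n-1)/2", call. = FALSE)
  }
  m <- diag(n)
  ij <- upper_pairs(n)
  m[ij] <- v
  m[ij[, 2:1, drop = FALSE]] <- v
  m
}

#' Feature matrix of a dataset
#'
#' Computes (or returns cached) upper-triangle FC features for every
#' non-synthetic subject and stores them in the dataset.
#'
#' @param dataset a [swnet_dataset()].
#' @param strict passed to [pearson_fc()].
#' @return the dataset with a populated `features` matrix
#'   (subjects x `n(n-1)/2`), rownames = subject ids.
#' @export
compute_features <- function(dataset, strict = TRUE) {
  stopifnot(inherits(dataset, "swnet_dataset"))
  if (!is.null(dataset$features)) return(dataset)
  feats <- t(vapply(
    dataset$series,
    function(ts) vectorize_upper(pearson_fc(ts, strict = strict)),
    numeric(ncol(dataset$series[[1L]]$values) *
              (ncol(dataset$series[[1L]]$values) - 1L) / 2L)
  ))
  rownames(feats) <- names(dataset$series)
  dataset$features <- feats
  dataset
}

# deterministic linear ranking score for RFE: L2-regularized least-squares
# separator fitted in the dual (cheap when features outnumber subjects),
# coefficients taken on standardized features
rfe_linear_weights <- function(x, y, lambda = 1e-2) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  yc <- ifelse(y == 1L, 1, -1)
  n <- nrow(xs)
  k <- tcrossprod(xs)                       # n x n gram matrix
  alpha <- solve(k + lambda * diag(n), yc)
  drop(crossprod(xs, alpha))
}

#' Recursive feature elimination with a linear ranking model
#'
#' Iteratively fits a linear separator, ranks features by absolute
#' standardized coefficient, and removes the lowest-ranked `step` features
#' per round until `target_count` remain. Deterministic; the `seed` is kept
#' for interface stability but the ranking itself involves no randomness.
#'
#' @param features numeric matrix, subjects x S.
#' @param labels binary vector (patient = 1, control = 0).
#' @param target_count number of features to keep (`< S`).
#' @param step_frac fraction of remaining features removed per round
#'   (at least one per round); default 2%.
#' @param seed integer, recorded in the result.
#' @return a `feature_selection`: list with sorted `selected_indices`
#'   (1-based positions into the original columns), `target_count`,
#'   `ranking_seed`.
#' @export
rfe_select <- function(features, labels, target_count, step_frac = 0.02,
                       seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  s <- ncol(features)
  if (target_count >= s) stop("target_count must be < number of features", call. = FALSE)
  if (target_count < 1L) stop("target_count must be >= 1", call. = FALSE)
  surviving <- seq_len(s)
  while (length(surviving) > target_count) {
    w <- rfe_linear_weights(features[, surviving, drop = FALSE], labels)
    step <- max(1L, ceiling(step_frac * length(surviving)))
    step <- min(step, length(surviving) - target_count)
    # drop the `step` smallest |coefficients|; ties broken by column order
    drop_local <- order(abs(w), surviving)[seq_len(step)]
    surviving <- surviving[-drop_local]
  }
  structure(
    list(selected_indices = sort(surviving),
         target_count = as.integer(target_count),
         ranking_seed = as.integer(seed)),
    class = "feature_selection"
  )
}
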