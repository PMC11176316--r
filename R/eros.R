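#' Eigenstructure of a subject's ROI covariance
#'
#' Computes the column covariance of the series (an `n x n` matrix) and its
#' eigendecomposition via singular value decomposition, giving orthonormal
#' eigenvectors and nonnegative eigenvalues in descending order. This is the
#' representation the EROS similarity compares.
#'
#' @param ts a [roi_timeseries()].
#' @return an `eigen_structure`: list with `subject_id`, `vectors`
#'   (`n x n`, orthonormal columns), `values` (length `n`, descending).
#' @export
covariance_eigen <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  cv <- stats::cov(x)
  if (all(cv == 0)) {
    stop(sprintf("degenerate (constant) series for subject '%s'",
                 ts$subject_id), call. = FALSE)
  }
  sv <- svd(cv)
  structure(
    list(subject_id = ts$subject_id, vectors = sv$u, values = sv$d),
    class = "eigen_structure"
  )
}

#' Dataset-level EROS weights from covariance spectra
#'
#' Each subject's eigenvalues are normalized to sum to one; the normalized
#' spectra are then aggregated componentwise across subjects (mean by
#' default) and renormalized, yielding a nonnegative weight vector `omega`
#' with `sum(omega) == 1`.
#'
#' @param eigs nonempty list of `eigen_structure`s with consistent `n`.
#' @param aggregate componentwise aggregation across subjects.
#' @return an `eros_weights`: list with `omega`.
#' @export
eros_weights <- function(eigs, aggregate = c("mean", "max", "min")) {
  aggregate <- match.arg(aggregate)
  if (length(eigs) == 0L) stop("empty eigenstructure list", call. = FALSE)
  n <- length(eigs[[1L]]$values)
  spectra <- vapply(eigs, function(e) {
    stopifnot(length(e$values) == n)
    e$values / sum(e$values)
  }, numeric(n))
  spectra <- matrix(spectra, nrow = n)
  agg <- switch(aggregate,
    mean = rowMeans(spectra),
    max = apply(spectra, 1L, max),
    min = apply(spectra, 1L, min)
  )
  structure(list(omega = agg / sum(agg)), class = "eros_weights")
}

#' EROS similarity between two multivariate time series
#'
#' The extended Frobenius norm similarity: the weighted sum of absolute
#' cosines between paired covariance eigenvectors,
#' `sum_i omega_i * |<a_i, b_i>|`, which lies in `[0, 1]` because the
#' weights sum to one. The absolute value also absorbs the arbitrary sign of
#' eigenvectors, so no sign canonicalization is needed.
#'
#' @param a,b `eigen_structure`s with matching `n`.
#' @param w an [eros_weights()].
#' @return similarity in `[0, 1]`.
#' @export
eros_similarity <- function(a, b, w) {
  va <- a$vectors
  vb <- b$vectors
  if (!identical(dim(va), dim(vb)) || length(w$omega) != ncol(va)) {
    stop("dimension mismatch between eigenstructures and weights", call. = FALSE)
  }
  sum(w$omega * abs(colSums(va * vb)))
}

#' EROS distance
#'
#' `sqrt(2 - 2 * similarity)`, in `[0, sqrt(2)]`. Tiny negative radicands
#' from roundoff (>= -1e-10) are clamped to zero; anything more negative
#' signals broken weights and is an error.
#'
#' @inheritParams eros_similarity
#' @return distance in `[0, sqrt(2)]`.
#' @export
eros_distance <- function(a, b, w) {
  rad <- 2 - 2 * eros_similarity(a, b, w)
  if (rad < -1e-10) {
    stop("negative radicand in EROS distance: weights are invalid", call. = FALSE)
  }
  sqrt(max(rad, 0))
}

#' PCA similarity over the leading principal components
#'
#' Sum of squared cosines of the angles between the first `z` principal
#' directions of each series: `sum_{i,j <= z} cos^2(theta_ij)`. Provided as
#' an optional similarity; the default neighbour search uses
#' [eros_distance()].
#'
#' @inheritParams eros_similarity
#' @param z number of leading components, `z <= n`.
#' @return nonnegative similarity (equals `z`'s row sums of 1, i.e. `n` when
#'   `a == b` and `z == n`).
#' @export
spca_similarity <- function(a, b, z) {
  n <- ncol(a$vectors)
  if (z > n) stop("z must not exceed the number of components", call. = FALSE)
  cosines <- crossprod(a$vectors[, seq_len(z), drop = FALSE],
                       b$vectors[, seq_len(z), drop = FALSE])
  sum(cosines^2)
}

#' K nearest neighbours under the EROS distance
#'
#' Ranks the eligible pool (every other subject, restricted to the query's
#' class when `same_class_only`) by ascending [eros_distance()] to the query
#' and returns the `k` closest ids. Ties are broken by lexicographic
#' subject id.
#'
#' @param query_id subject id present in `dataset`.
#' @param dataset a [swnet_dataset()].
#' @param w an [eros_weights()].
#' @param k number of neighbours.
#' @param same_class_only restrict the pool to the query's class (default).
#' @param eigs optional named list of precomputed `eigen_structure`s keyed
#'   by subject id (computed on the fly otherwise).
#' @return character vector of `k` subject ids, nearest first.
#' @export
knn_eros <- function(query_id, dataset, w, k, same_class_only = TRUE,
                     eigs = NULL) {
  pheno <- dataset$phenotypes
  if (!query_id %in% pheno$subject_id) {
    stop("unknown subject: ", query_id, call. = FALSE)
  }
  pool <- pheno$subject_id[pheno$subject_id != query_id &
                             !pheno$is_synthetic]
  if (same_class_only) {
    q_label <- pheno$label[pheno$subject_id == query_id]
    pool <- intersect(pool, pheno$subject_id[pheno$label == q_label])
  }
  if (length(pool) < k) {
    stop(sprintf("pool of %d eligible subjects is smaller than k = %d",
                 length(pool), k), call. = FALSE)
  }
  if (is.null(eigs)) {
    eigs <- lapply(dataset$series[c(query_id, pool)], covariance_eigen)
  }
  d <- vapply(pool, function(id) eros_distance(eigs[[query_id]], eigs[[id]], w),
              numeric(1))
  pool[order(d, pool)][seq_len(k)]
}

#' SMOTE-style linear interpolation of feature vectors
#'
#' `x + phi * (x_neighbor - x)` componentwise, `phi` in `[0, 1]`, so the
#' result lies on the segment between the two vectors.
#'
#' @param x,x_neighbor numeric vectors of equal length.
#' @param phi interpolation threshold in `[0, 1]`.
#' @return interpolated vector of the same length.
#' @export
interpolate <- function(x, x_neighbor, phi) {
  if (length(x) != length(x_neighbor)) {
    stop("feature vectors have different lengths", call. = FALSE)
  }
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]", call. = FALSE)
  x + phi * (x_neighbor - x)
}

#' Configuration of the EROS nearest-neighbour augmentation
#'
#' @param k number of nearest neighbours to sample from (default 5).
#' @param gamma augmentation factor: the dataset grows to `gamma` times its
#'   original size (`gamma = 1` leaves it unchanged; default 2).
#' @param phi_range interval within `[0, 1]` the interpolation threshold is
#'   drawn from uniformly.
#' @param same_class_only restrict neighbour pools to the source's class
#'   (default; synthetic samples inherit the source's label, so cross-class
#'   interpolation would corrupt labels).
#' @param seed integer driving neighbour choice and `phi` draws.
#' @return an `augmentation_config`.
#' @export
augmentation_config <- function(k = 5L, gamma = 2L, phi_range = c(0, 1),
                                same_class_only = TRUE, seed = 1L) {
  stopifnot(k >= 1L, gamma >= 1L, length(phi_range) == 2L,
            phi_range[1L] >= 0, phi_range[2L] <= 1,
            phi_range[1L] <= phi_range[2L])
  structure(
    list(k = as.integer(k), gamma = as.integer(gamma), phi_range = phi_range,
         same_class_only = isTRUE(same_class_only), seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' Grow a dataset by EROS-guided SMOTE-style interpolation
#'
#' For each source subject, in turn, until the dataset reaches `gamma` times
#' its original size: find the source's `k` nearest same-class neighbours by
#' EROS distance over the raw time series, pick one uniformly at random,
#' draw `phi ~ Uniform(phi_range)`, and add the interpolated feature vector
#' as a new synthetic subject inheriting the source's label and site.
#' EROS weights are computed once from the input set. Deterministic given
#' `config$seed`; per-class proportions are preserved exactly when class
#' sizes are equal (and to within rounding otherwise, since sources cycle in
#' phenotype order).
#'
#' @param dataset a [swnet_dataset()] with `features` present (see
#'   [compute_features()]).
#' @param config an [augmentation_config()].
#' @return the augmented [swnet_dataset()]; synthetic subjects are tagged
#'   with ids `<source>_syn<i>` and `is_synthetic = TRUE`, and a
#'   `provenance` data.frame records each synthetic sample's source,
#'   chosen neighbour and `phi`.
#' @export
augment <- function(dataset, config) {
  stopifnot(inherits(dataset, "swnet_dataset"),
            inherits(config, "augmentation_config"))
  if (is.null(dataset$features)) {
    stop("dataset has no features; run compute_features() first", call. = FALSE)
  }
  if (config$gamma == 1L) return(dataset)
  pheno <- dataset$phenotypes
  if (any(pheno$is_synthetic)) {
    stop("dataset already contains synthetic subjects", call. = FALSE)
  }
  for (lab in c(0L, 1L)) {
    if (sum(pheno$label == lab) < config$k + 1L) {
      stop(sprintf("class %d pool too small for k = %d neighbours",
                   lab, config$k), call. = FALSE)
    }
  }
  eigs <- lapply(dataset$series, covariance_eigen)
  w <- eros_weights(eigs)
  m <- nrow(pheno)
  n_new <- (config$gamma - 1L) * m
  sources <- rep_len(pheno$subject_id, n_new)
  withr::with_seed(config$seed, {
    new_rows <- vector("list", n_new)
    new_feats <- matrix(NA_real_, n_new, ncol(dataset$features))
    provenance <- vector("list", n_new)
    syn_count <- integer(m)
    names(syn_count) <- pheno$subject_id
    for (idx in seq_len(n_new)) {
      src <- sources[idx]
      nn <- knn_eros(src, dataset, w, config$k,
                     same_class_only = config$same_class_only, eigs = eigs)
      pick <- nn[sample.int(config$k, 1L)]
      phi <- stats::runif(1L, config$phi_range[1L], config$phi_range[2L])
      new_feats[idx, ] <- interpolate(dataset$features[src, ],
                                      dataset$features[pick, ], phi)
      syn_count[src] <- syn_count[src] + 1L
      src_row <- pheno[pheno$subject_id == src, ]
      syn_id <- sprintf("%s_syn%d", src, syn_count[src])
      new_rows[[idx]] <- data.frame(
        subject_id = syn_id, label = src_row$label, site_id = src_row$site_id,
        is_synthetic = TRUE, stringsAsFactors = FALSE
      )
      provenance[[idx]] <- data.frame(
        synthetic_id = syn_id, source_id = src, neighbor_id = pick, phi = phi,
        stringsAsFactors = FALSE
      )
    }
    new_pheno <- rbind(
      as.data.frame(pheno)[, c("subject_id", "label", "site_id", "is_synthetic")],
      do.call(rbind, new_rows)
    )
    rownames(new_feats) <- vapply(new_rows, `[[`, character(1), "subject_id")
    feats <- rbind(dataset$features, new_feats)
    out <- swnet_dataset(phenotype_table(new_pheno), dataset$series, feats)
    out$provenance <- do.call(rbind, provenance)
    out
  })
}
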