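#' Configuration for the synthetic two-class cohort generator
#'
#' The generator draws each subject's ROI signal as `n_timepoints` i.i.d.
#' samples from a zero-mean multivariate normal whose correlation matrix
#' depends on the class: a constant background correlation `base_rho`
#' everywhere, plus `delta` added on a chosen set of ROI pairs for the
#' patient class only. This is the simplest stationary process whose
#' functional connectivity equals the generating correlation exactly, which
#' is all the downstream method consumes.
#'
#' @param n_subjects_per_class subjects per class (cohort size is twice this).
#' @param n_rois number of ROIs `n >= 2`.
#' @param n_timepoints series length `T >= 3`.
#' @param effect_pairs two-column integer matrix of ROI pairs (`i < j`,
#'   1-based) whose correlation differs between classes; `NULL` selects the
#'   first `n_effect_pairs` pairs in row-major upper-triangle order.
#' @param n_effect_pairs used only when `effect_pairs` is `NULL`.
#' @param delta between-class correlation difference on the effect pairs,
#'   in `[0, 1)`; requires `abs(base_rho) + delta < 1`.
#' @param base_rho background correlation in `(-1, 1)`.
#' @param n_sites number of acquisition sites, assigned round-robin.
#' @param site_shift_sd standard deviation of additive per-site ROI mean
#'   offsets (0 disables site effects).
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects_per_class, n_rois, n_timepoints,
                              effect_pairs = NULL, n_effect_pairs = 0L,
                              delta = 0, base_rho = 0,
                              n_sites = 1L, site_shift_sd = 0, seed = 1L) {
  stopifnot(
    n_subjects_per_class >= 1L, n_rois >= 2L, n_timepoints >= 3L,
    delta >= 0, delta < 1, abs(base_rho) < 1,
    n_sites >= 1L, site_shift_sd >= 0
  )
  if (abs(base_rho) + delta >= 1) {
    stop("need abs(base_rho) + delta < 1 for a valid correlation", call. = FALSE)
  }
  if (is.null(effect_pairs)) {
    all_pairs <- upper_pairs(n_rois)
    if (n_effect_pairs > nrow(all_pairs)) {
      stop("n_effect_pairs exceeds the number of ROI pairs", call. = FALSE)
    }
    effect_pairs <- all_pairs[seq_len(n_effect_pairs), , drop = FALSE]
  } else {
    effect_pairs <- matrix(as.integer(effect_pairs), ncol = 2L)
    if (any(effect_pairs[, 1L] >= effect_pairs[, 2L]) ||
        any(effect_pairs < 1L) || any(effect_pairs > n_rois)) {
      stop("effect_pairs must satisfy 1 <= i < j <= n_rois", call. = FALSE)
    }
  }
  structure(
    list(
      n_subjects_per_class = as.integer(n_subjects_per_class),
      n_rois = as.integer(n_rois),
      n_timepoints = as.integer(n_timepoints),
      effect_pairs = effect_pairs,
      delta = delta, base_rho = base_rho,
      n_sites = as.integer(n_sites), site_shift_sd = site_shift_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# all i<j pairs in row-major upper-triangle order (i ascending, then j)
upper_pairs <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = i, j = j)
}

# eigenvalue-clipping projection to the nearest symmetric PD matrix with
# unit diagonal; iterates clip + rescale a few times
nearest_pd_correlation <- function(mat, eps = 1e-8, max_iter = 50L) {
  m <- (mat + t(mat)) / 2
  for (iter in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) > eps) {
      diag(m) <- 1
      e2 <- eigen(m, symmetric = TRUE)
      if (min(e2$values) > eps) return(m)
    }
    vals <- pmax(e$values, eps * 10)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
  }
  stop("could not reach a positive-definite correlation; ",
       "reduce delta and/or base_rho", call. = FALSE)
}

#' Class-specific generating correlation matrix
#'
#' Controls (label 0) get the background correlation `base_rho` everywhere;
#' patients (label 1) additionally get `+delta` on the configured effect
#' pairs, so the two class matrices differ by exactly `delta` on those
#' entries before any positive-definite re-projection.
#'
#' @param config a [simulation_config()].
#' @param class_label 0 (control) or 1 (patient).
#' @return symmetric positive-definite correlation matrix
#'   (`n_rois` x `n_rois`).
#' @export
make_class_correlation <- function(config, class_label) {
  stopifnot(inherits(config, "simulation_config"), class_label %in% c(0L, 1L))
  n <- config$n_rois
  m <- matrix(config$base_rho, n, n)
  diag(m) <- 1
  if (class_label == 1L && nrow(config$effect_pairs) > 0L) {
    ij <- config$effect_pairs
    m[ij] <- m[ij] + config$delta
    m[ij[, 2:1, drop = FALSE]] <- m[ij]
  }
  nearest_pd_correlation(m)
}

#' Simulate a two-class multi-site cohort
#'
#' Each subject's series is `T` i.i.d. draws from `N(0, R_class)` obtained by
#' a Cholesky transform of white noise, plus a per-site additive ROI mean
#' offset drawn with sd `site_shift_sd`. Sites are assigned round-robin and
#' label balance is exact. The result is a deterministic function of
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [swnet_dataset()] with subjects `ctrl_001...` (label 0) and
#'   `pat_001...` (label 1).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    chol_by_class <- list(
      "0" = chol(make_class_correlation(config, 0L)),
      "1" = chol(make_class_correlation(config, 1L))
    )
    site_ids <- paste0("site", seq_len(config$n_sites))
    # per-site ROI mean offsets, shared by every subject of the site
    site_shift <- matrix(
      stats::rnorm(config$n_sites * config$n_rois, sd = config$site_shift_sd),
      nrow = config$n_sites
    )
    m_per_class <- config$n_subjects_per_class
    ids <- c(sprintf("ctrl_%03d", seq_len(m_per_class)),
             sprintf("pat_%03d", seq_len(m_per_class)))
    labels <- rep(c(0L, 1L), each = m_per_class)
    site_idx <- rep_len(seq_len(config$n_sites), 2L * m_per_class)
    series <- vector("list", length(ids))
    names(series) <- ids
    for (s in seq_along(ids)) {
      z <- matrix(stats::rnorm(config$n_timepoints * config$n_rois),
                  nrow = config$n_timepoints)
      x <- z %*% chol_by_class[[as.character(labels[s])]]
      x <- sweep(x, 2L, site_shift[site_idx[s], ], "+")
      series[[s]] <- roi_timeseries(x, subject_id = ids[s])
    }
    pheno <- phenotype_table(data.frame(
      subject_id = ids, label = labels, site_id = site_ids[site_idx],
      stringsAsFactors = FALSE
    ))
    swnet_dataset(pheno, series)
  })
}
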