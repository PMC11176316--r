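# fixtures are built in code; nothing is read from disk except what the
# data_io tests themselves write to tempfiles

tiny_cohort <- function(n_per_class = 6, n_rois = 6, n_timepoints = 40,
                        delta = 0.5, n_sites = 1, seed = 101) {
  simulate_cohort(simulation_config(
    n_subjects_per_class = n_per_class, n_rois = n_rois,
    n_timepoints = n_timepoints,
    n_effect_pairs = min(5L, n_rois * (n_rois - 1L) / 2L),
    delta = delta, base_rho = 0.1, n_sites = n_sites, seed = seed
  ))
}

random_orthonormal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  q
}

random_eigstruct <- function(n, id = "x") {
  vals <- sort(abs(rnorm(n)) + 0.1, decreasing = TRUE)
  structure(
    list(subject_id = id, vectors = random_orthonormal(n), values = vals),
    class = "eigen_structure"
  )
}

uniform_weights <- function(n) {
  structure(list(omega = rep(1 / n, n)), class = "eros_weights")
}

# literal loop transcription of the weighted-absolute-cosine sum and its
# distance form, kept independent of the package's vectorized path
eros_distance_oracle <- function(a, b, w) {
  s <- 0
  for (i in seq_along(w$omega)) {
    s <- s + w$omega[i] * abs(sum(a$vectors[, i] * b$vectors[, i]))
  }
  sqrt(2 - 2 * s)
}

# confusion-table / pairwise-AUC oracle written with explicit loops
metrics_oracle <- function(y_true, y_prob, threshold = 0.5) {
  pred <- ifelse(y_prob >= threshold, 1L, 0L)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y_true)) {
    if (pred[i] == 1 && y_true[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && y_true[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && y_true[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && y_true[i] == 0) tn <- tn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  num <- 0
  den <- 0
  for (i in which(y_true == 1)) {
    for (j in which(y_true == 0)) {
      den <- den + 1
      if (y_prob[i] > y_prob[j]) num <- num + 1
      if (y_prob[i] == y_prob[j]) num <- num + 0.5
    }
  }
  list(accuracy = (tp + tn) / length(y_true), precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
       auc = num / den)
}

write_ts_file <- function(mat, delimiter = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(mat, path, sep = delimiter, row.names = FALSE, col.names = FALSE)
  path
}
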