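#' ROI time-series container
#'
#' Holds one subject's multivariate resting-state signal as a numeric matrix
#' with timepoints in rows and regions of interest (ROIs) in columns.
#'
#' @param values numeric matrix, `T` rows (timepoints, `T >= 3`) by `n`
#'   columns (ROIs, `n >= 2`); no missing values allowed.
#' @param subject_id single character string identifying the subject.
#' @param roi_labels optional character vector of length `n`.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id, roi_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 3L) {
    stop("time series must have at least 3 timepoints (rows)", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("time series must have at least 2 ROIs (columns)", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_rejected_subject(subject_id, "missing or non-finite cells")
  }
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  }
  if (!is.null(roi_labels)) {
    stopifnot(length(roi_labels) == ncol(values))
    colnames(values) <- roi_labels
  }
  structure(
    list(subject_id = subject_id, values = values, roi_labels = roi_labels),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> subject '%s': %d timepoints x %d ROIs\n",
    x$subject_id, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

stop_rejected_subject <- function(subject_id, why) {
  stop(structure(
    class = c("swnet_rejected_subject", "error", "condition"),
    list(
      message = sprintf("subject '%s' rejected: %s", subject_id, why),
      call = NULL
    )
  ))
}

#' Read one subject's ROI time series from delimited text
#'
#' Files are rectangular numeric tables, one subject per file, rows = time,
#' columns = ROI by default. Subjects whose files contain missing or
#' non-numeric cells are rejected with a condition of class
#' `swnet_rejected_subject` so callers may skip them; ragged files raise a
#' plain format error.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator; tab by default, `","` for CSV.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param transpose set `TRUE` for files written ROI-by-time.
#' @return a [roi_timeseries()].
#' @export
read_timeseries <- function(path, delimiter = "\t", subject_id = NULL,
                            transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty time-series file: ", path, call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  width <- lengths(fields)
  if (length(unique(width)) != 1L) {
    stop("format error: rows of unequal length in ", path, call. = FALSE)
  }
  cells <- suppressWarnings(as.numeric(trimws(unlist(fields))))
  values <- matrix(cells, nrow = length(lines), ncol = width[1L], byrow = TRUE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_rejected_subject(subject_id, sprintf("missing or non-numeric cells in %s", path))
  }
  if (transpose) values <- t(values)
  roi_timeseries(values, subject_id = subject_id)
}

#' Read a phenotype table
#'
#' CSV with header `subject_id,label,site_id`; labels use patient = 1,
#' control = 0, so a downstream sigmoid output reads as P(patient).
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(
    subject_id = "character", label = "integer", site_id = "character"
  ))
  phenotype_table(df)
}

#' Construct and validate a phenotype table
#'
#' @param df data.frame with columns `subject_id`, `label`, `site_id`.
#' @return `df` with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  need <- c("subject_id", "label", "site_id")
  if (!all(need %in% names(df))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in phenotype table", call. = FALSE)
  }
  if (!all(df$label %in% c(0L, 1L))) {
    stop("labels must be 0 (control) or 1 (patient)", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$site_id <- as.character(df$site_id)
  df$label <- as.integer(df$label)
  if (!"is_synthetic" %in% names(df)) df$is_synthetic <- FALSE
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Bundle phenotypes, time series and (optionally) features
#'
#' Every non-synthetic phenotype row must have a matching time series; all
#' series must share the same number of ROIs (`T` may vary by subject).
#' Synthetic subjects created by [augment()] carry interpolated feature
#' vectors but no raw series.
#'
#' @param phenotypes a [phenotype_table()].
#' @param series named list of [roi_timeseries()], keyed by subject id.
#' @param features optional numeric matrix (subjects x features) with
#'   rownames equal to subject ids.
#' @return an object of class `swnet_dataset`.
#' @export
swnet_dataset <- function(phenotypes, series, features = NULL) {
  phenotypes <- phenotype_table(phenotypes)
  real <- phenotypes$subject_id[!phenotypes$is_synthetic]
  missing <- setdiff(real, names(series))
  if (length(missing) > 0L) {
    stop("phenotype rows without a matching time series: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  n_rois <- vapply(series, function(ts) ncol(ts$values), integer(1))
  if (length(unique(n_rois)) > 1L) {
    stop("all subjects must share the same number of ROIs", call. = FALSE)
  }
  if (!is.null(features)) {
    if (is.null(rownames(features))) {
      stop("`features` must have subject ids as rownames", call. = FALSE)
    }
    absent <- setdiff(phenotypes$subject_id, rownames(features))
    if (length(absent) > 0L) {
      stop("features missing for subjects: ",
           paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(phenotypes = phenotypes, series = series, features = features),
    class = "swnet_dataset"
  )
}

#' @export
print.swnet_dataset <- function(x, ...) {
  n <- nrow(x$phenotypes)
  cat(sprintf(
    "<swnet_dataset> %d subjects (%d patient / %d control, %d synthetic), %d sites%s\n",
    n, sum(x$phenotypes$label == 1L), sum(x$phenotypes$label == 0L),
    sum(x$phenotypes$is_synthetic), length(unique(x$phenotypes$site_id)),
    if (is.null(x$features)) "" else sprintf(", %d features", ncol(x$features))
  ))
  invisible(x)
}

#' Write a dataset to disk in the package's on-disk formats
#'
#' One TSV per subject (rows = time, columns = ROI) plus `phenotypes.csv`.
#'
#' @param dataset a [swnet_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$series)) {
    utils::write.table(
      dataset$series[[id]]$values,
      file.path(dir, paste0(id, ".tsv")),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
  }
  utils::write.csv(
    dataset$phenotypes[, c("subject_id", "label", "site_id")],
    file.path(dir, "phenotypes.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Subjects whose time-series files contain missing cells are skipped with a
#' message (the exclusion is logged), mirroring cohort curation that discards
#' samples with anomalous or missing series.
#'
#' @param dir directory with per-subject TSVs and `phenotypes.csv`.
#' @param delimiter field separator of the per-subject files.
#' @param transpose set `TRUE` for files written ROI-by-time.
#' @return a [swnet_dataset()].
#' @export
read_dataset <- function(dir, delimiter = "\t", transpose = FALSE) {
  pheno <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  series <- list()
  kept <- logical(nrow(pheno))
  for (i in seq_len(nrow(pheno))) {
    id <- pheno$subject_id[i]
    path <- file.path(dir, paste0(id, ".tsv"))
    ts <- tryCatch(
      read_timeseries(path, delimiter = delimiter, subject_id = id,
                      transpose = transpose),
      swnet_rejected_subject = function(e) {
        message("excluding subject '", id, "': ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(ts)) {
      series[[id]] <- ts
      kept[i] <- TRUE
    }
  }
  swnet_dataset(pheno[kept, , drop = FALSE], series)
}

#' Persist an evaluation report as JSON
#'
#' @param report an `eval_report` produced by [run_protocol()] or built from
#'   [compute_metrics()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "eval_report")) stop("not an eval_report", call. = FALSE)
  if (is.null(report$folds) || nrow(report$folds) == 0L) {
    stop("empty report: nothing to persist", call. = FALSE)
  }
  doc <- list(
    schema = "swnet-eval-report/1",
    scheme = report$scheme,
    seed = report$seed,
    folds = report$folds,
    aggregate = report$aggregate,
    config = report$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path path to the JSON document.
#' @return an `eval_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "swnet-eval-report/1")) {
    stop("not a swnet evaluation report: ", path, call. = FALSE)
  }
  structure(
    list(
      scheme = doc$scheme, seed = doc$seed,
      folds = as.data.frame(doc$folds),
      aggregate = doc$aggregate, config = doc$config
    ),
    class = "eval_report"
  )
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single-file archive containing every weight tensor and
#' the full configuration used, so a loaded model reproduces the saved
#' model's predictions exactly.
#'
#' @param model a `swnet_model` (see [build_swnet()]).
#' @param path checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "swnet_model")) stop("not a swnet_model", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @param expected_input_dim optional integrity check: error if the stored
#'   encoder input dimension differs.
#' @export
load_model <- function(path, expected_input_dim = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "swnet_model")) {
    stop("file is not a swnet model checkpoint: ", path, call. = FALSE)
  }
  if (!is.null(expected_input_dim) &&
      nrow(model$encoder$W) != expected_input_dim) {
    stop(sprintf(
      "checkpoint/config mismatch: encoder expects %d input features, config says %d",
      nrow(model$encoder$W), expected_input_dim
    ), call. = FALSE)
  }
  model
}
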