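#' Cross-validation fold plans
#'
#' Builds the outer folds of the evaluation protocol. Test sets are pairwise
#' disjoint and jointly cover the cohort; for the nested k-fold scheme an
#' inner validation split (one fold of a stratified 9-way partition of the
#' outer-train set) is additionally carved out of each outer-train set for
#' model selection / early stopping. Folds are stratified by label where the
#' scheme permits.
#'
#' @param pheno a [phenotype_table()].
#' @param scheme `"nested_kfold"`, `"loocv"` or `"leave_one_site_out"`.
#' @param n_outer number of outer folds for the nested scheme (default 10).
#' @param seed integer seed for the shuffling.
#' @return a `fold_plan`: list with `scheme`, `n_outer`, `seed` and `folds`,
#'   each fold a list of `train_ids`, `validation_ids`, `test_ids`.
#' @export
make_folds <- function(pheno, scheme = c("nested_kfold", "loocv",
                                         "leave_one_site_out"),
                       n_outer = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  pheno <- phenotype_table(pheno)
  ids <- pheno$subject_id
  labels <- pheno$label
  withr::with_seed(seed, {
    folds <- switch(scheme,
      loocv = lapply(seq_along(ids), function(i) {
        list(train_ids = ids[-i], validation_ids = character(0),
             test_ids = ids[i])
      }),
      leave_one_site_out = {
        sites <- sort(unique(pheno$site_id))
        if (length(sites) < 2L) {
          stop("leave-one-site-out needs at least 2 sites", call. = FALSE)
        }
        lapply(sites, function(s) {
          list(train_ids = ids[pheno$site_id != s],
               validation_ids = character(0),
               test_ids = ids[pheno$site_id == s])
        })
      },
      nested_kfold = {
        if (length(ids) < n_outer) {
          stop("fewer subjects than folds", call. = FALSE)
        }
        assign_folds <- function(members, k) {
          # stratified: spread each class across folds in shuffled order
          f <- integer(length(members))
          for (lab in unique(labels[members])) {
            cls <- members[labels[members] == lab]
            cls <- sample(cls)
            f[match(cls, members)] <- rep_len(seq_len(k), length(cls))
          }
          f
        }
        outer <- assign_folds(seq_along(ids), n_outer)
        lapply(seq_len(n_outer), function(k) {
          test <- which(outer == k)
          rest <- which(outer != k)
          inner <- assign_folds(rest, 9L)
          list(train_ids = ids[rest[inner != 1L]],
               validation_ids = ids[rest[inner == 1L]],
               test_ids = ids[test])
        })
      }
    )
    plan <- structure(
      list(scheme = scheme, n_outer = length(folds), seed = as.integer(seed),
           folds = folds),
      class = "fold_plan"
    )
    validate_fold_plan(plan, ids)
    plan
  })
}

validate_fold_plan <- function(plan, ids) {
  tests <- unlist(lapply(plan$folds, `[[`, "test_ids"))
  if (anyDuplicated(tests) || !setequal(tests, ids)) {
    stop("fold plan invalid: test sets must partition the cohort", call. = FALSE)
  }
  for (f in plan$folds) {
    if (length(intersect(f$train_ids, f$test_ids)) > 0L ||
        length(intersect(f$validation_ids, f$test_ids)) > 0L) {
      stop("fold plan invalid: train/test overlap", call. = FALSE)
    }
  }
  invisible(plan)
}

#' Classification metrics from probabilities
#'
#' Accuracy, precision, recall and F1 come from the confusion table at the
#' given threshold (positive class = patient = 1). AUC uses the pairwise
#' (Mann-Whitney) definition — the probability that a random positive
#' outranks a random negative, ties counted 1/2 — which is exact for small
#' samples and agrees with the trapezoidal ROC area.
#'
#' @param y_true binary vector.
#' @param y_prob probability vector of equal length.
#' @param threshold decision threshold (ties classify positive).
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `auc` and
#'   `precision_defined` (`FALSE` when no positives were predicted, in which
#'   case precision is reported as 0 so aggregates stay defined).
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0L, 1L)))
  if (length(unique(y_true)) < 2L) {
    stop("AUC undefined: y_true contains a single class", call. = FALSE)
  }
  pred <- classify(y_prob, threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  accuracy <- (tp + tn) / length(y_true)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  pos <- y_prob[y_true == 1L]
  neg <- y_prob[y_true == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, auc = auc, precision_defined = precision_defined)
}

#' Full pipeline configuration for [run_protocol()]
#'
#' Bundles the per-fold stages: optional recursive feature elimination,
#' EROS-guided augmentation, denoising-autoencoder pretraining, and joint
#' shared-weight training. Everything is refit inside each fold from the
#' training subjects only.
#'
#' @param dae a [dae_config()].
#' @param cnn a [cnn_config()]; its `input_length` must equal the DAE
#'   bottleneck.
#' @param augmentation an [augmentation_config()], or `NULL` to disable.
#' @param rfe_target number of features kept by RFE, or `NULL` to feed the
#'   full feature vector to the autoencoder (the default path).
#' @param threshold decision threshold for the reported hard metrics.
#' @param seed integer master seed; per-fold seeds are derived from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(dae, cnn, augmentation = NULL, rfe_target = NULL,
                            threshold = 0.5, seed = 1L) {
  stopifnot(inherits(dae, "dae_config"), inherits(cnn, "cnn_config"))
  if (dae$bottleneck_dim != cnn$input_length) {
    stop("DAE bottleneck must equal CNN input_length", call. = FALSE)
  }
  if (!is.null(augmentation)) {
    stopifnot(inherits(augmentation, "augmentation_config"))
  }
  structure(
    list(dae = dae, cnn = cnn, augmentation = augmentation,
         rfe_target = rfe_target, threshold = threshold,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# small deterministic seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) * 1000 + fold * 7 + 13) %% 2147483647)
}

#' Run the evaluation protocol over a fold plan
#'
#' Per fold: (i) upper-triangle FC features are computed; (ii) RFE (if
#' enabled), EROS weights, augmentation, DAE pretraining and joint training
#' are all fitted on the TRAIN subjects only; (iii) the inner validation set
#' drives early stopping; (iv) metrics are computed on the untouched test
#' subjects. A leakage guard errors if any test subject reaches a fitting
#' stage. Deterministic given `config$seed`.
#'
#' @param dataset a [swnet_dataset()].
#' @param plan a `fold_plan` from [make_folds()].
#' @param config a [pipeline_config()].
#' @return an `eval_report`: per-fold metrics plus aggregate means and
#'   standard deviations.
#' @export
run_protocol <- function(dataset, plan, config) {
  stopifnot(inherits(dataset, "swnet_dataset"), inherits(plan, "fold_plan"),
            inherits(config, "pipeline_config"))
  dataset <- compute_features(dataset)
  pheno <- dataset$phenotypes
  fold_rows <- vector("list", length(plan$folds))
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    fold_seed <- derive_seed(config$seed, fi)
    train_ids <- fold$train_ids
    val_ids <- fold$validation_ids
    test_ids <- fold$test_ids
    if (length(intersect(train_ids, test_ids)) > 0L ||
        length(intersect(val_ids, test_ids)) > 0L) {
      stop("leakage guard: test subjects present in a fitting set", call. = FALSE)
    }
    fit_ids <- c(train_ids, val_ids)
    train_ds <- swnet_dataset(
      pheno[pheno$subject_id %in% train_ids, , drop = FALSE],
      dataset$series[train_ids],
      dataset$features[train_ids, , drop = FALSE]
    )
    feat_cols <- seq_len(ncol(dataset$features))
    if (!is.null(config$rfe_target)) {
      sel <- rfe_select(train_ds$features,
                        train_ds$phenotypes$label,
                        config$rfe_target, seed = fold_seed)
      feat_cols <- sel$selected_indices
    }
    if (!is.null(config$augmentation)) {
      aug_cfg <- config$augmentation
      aug_cfg$seed <- derive_seed(fold_seed, 1L)
      train_ds <- augment(train_ds, aug_cfg)
      if (length(intersect(train_ds$phenotypes$subject_id, test_ids)) > 0L) {
        stop("leakage guard: test subjects entered augmentation", call. = FALSE)
      }
    }
    x_train <- train_ds$features[, feat_cols, drop = FALSE]
    y_train <- train_ds$phenotypes$label
    dae_cfg <- config$dae
    dae_cfg$input_dim <- length(feat_cols)
    dae_cfg$seed <- derive_seed(fold_seed, 2L)
    dae_fit <- train_dae(x_train, dae_cfg)
    cnn_cfg <- config$cnn
    cnn_cfg$seed <- derive_seed(fold_seed, 3L)
    model <- build_swnet(dae_fit$encoder, cnn_cfg)
    val_x <- NULL
    val_y <- NULL
    if (length(val_ids) > 0L) {
      val_x <- dataset$features[val_ids, feat_cols, drop = FALSE]
      val_y <- pheno$label[match(val_ids, pheno$subject_id)]
      if (length(unique(val_y)) < 2L) {   # degenerate split: fall back
        val_x <- NULL
        val_y <- NULL
      }
    }
    fit <- train_joint(model, x_train, y_train, val_features = val_x,
                       val_labels = val_y, config = cnn_cfg)
    x_test <- dataset$features[test_ids, feat_cols, drop = FALSE]
    y_test <- pheno$label[match(test_ids, pheno$subject_id)]
    prob <- predict_proba(fit$model, x_test)
    if (length(unique(y_test)) < 2L) {
      # single-class test fold (possible under loocv / site scheme):
      # report threshold accuracy; rank metrics are undefined
      pred <- classify(prob, config$threshold)
      met <- list(accuracy = mean(pred == y_test), precision = NA_real_,
                  recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                  precision_defined = NA)
    } else {
      met <- compute_metrics(y_test, prob, config$threshold)
    }
    fold_rows[[fi]] <- data.frame(
      fold = fi, n_test = length(test_ids),
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1, auc = met$auc
    )
  }
  folds <- do.call(rbind, fold_rows)
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  aggregate <- list(
    mean = as.list(colMeans(folds[metric_names], na.rm = TRUE)),
    sd = as.list(apply(folds[metric_names], 2L, stats::sd, na.rm = TRUE))
  )
  structure(
    list(scheme = plan$scheme, seed = config$seed, folds = folds,
         aggregate = aggregate,
         config = list(
           rfe_target = config$rfe_target,
           bottleneck_dim = config$dae$bottleneck_dim,
           gamma = if (is.null(config$augmentation)) 1L else config$augmentation$gamma,
           threshold = config$threshold
         )),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d folds (seed %d)\n",
              x$scheme, nrow(x$folds), x$seed))
  m <- x$aggregate$mean
  s <- x$aggregate$sd
  for (nm in names(m)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", nm, m[[nm]], s[[nm]]))
  }
  invisible(x)
}

#' Paired two-sided t-test between per-fold metrics
#'
#' @param metrics_a,metrics_b numeric vectors of per-fold metrics for two
#'   models on the same folds (equal length >= 2).
#' @param alpha significance level (default 0.01).
#' @return list with `t`, `p`, `significant`, `flag` (`"zero_variance"` when
#'   the fold differences have no variance, in which case `p` is 1 for
#'   all-zero differences and 0 otherwise, by sign convention).
#' @export
compare_models <- function(metrics_a, metrics_b, alpha = 0.01) {
  if (length(metrics_a) != length(metrics_b) || length(metrics_a) < 2L) {
    stop("need equal fold counts >= 2", call. = FALSE)
  }
  d <- metrics_a - metrics_b
  if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    return(list(t = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p = p, significant = p < alpha, flag = "zero_variance"))
  }
  ht <- stats::t.test(metrics_a, metrics_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, flag = NULL)
}
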