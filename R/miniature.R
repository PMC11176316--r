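#' Desk-scale benchmark cohort and pipeline
#'
#' A frozen miniature of the full-scale setting, small enough to run on one
#' CPU in minutes: a two-class cohort of 40 subjects per class, 20 ROIs,
#' 150 timepoints, with a between-class correlation difference of 0.6 on 30
#' ROI pairs over a background correlation of 0.1 — a strong, recoverable
#' effect. The paired pipeline keeps the full-scale design (EROS-guided
#' augmentation with k = 5 and gamma = 2, Gaussian-noise DAE with sigma
#' 0.1 and SGD momentum 0.9, shared-weight CNN with dropout 0.3) while
#' shrinking widths and budgets: 190 input features, 64 bottleneck units,
#' DAE learning rate 1e-2 for 50 epochs (patience 10), and the
#' [cnn_config_miniature()] classifier.
#'
#' @param delta between-class correlation difference on the effect pairs;
#'   0.6 is the benchmark signal, 0 the null cohort used as a leakage guard.
#' @param seed integer seed.
#' @return `miniature_cohort()` returns a [simulation_config()];
#'   `miniature_pipeline()` a [pipeline_config()].
#' @export
miniature_cohort <- function(delta = 0.6, seed = 1L) {
  simulation_config(
    n_subjects_per_class = 40L, n_rois = 20L, n_timepoints = 150L,
    n_effect_pairs = 30L, delta = delta, base_rho = 0.1, seed = seed
  )
}

#' @rdname miniature_cohort
#' @export
miniature_pipeline <- function(seed = 1L) {
  pipeline_config(
    dae = dae_config(
      input_dim = 190L, bottleneck_dim = 64L, noise_sigma = 0.1,
      learning_rate = 1e-2, momentum = 0.9, max_epochs = 50L,
      early_stop_patience = 10L, batch_size = 16L, seed = seed
    ),
    cnn = cnn_config_miniature(seed = seed),
    augmentation = augmentation_config(k = 5L, gamma = 2L, seed = seed),
    seed = seed
  )
}
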