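# Cross-cohort transfer: zero-shot application, fine-tuning on a stratified
# fraction of the new cohort (weight reuse in the patch discriminator;
# WSI-level aggregators refit from scratch on the tuning subset), and the
# tuning-fraction sweep. Evaluation always uses the complement of the
# tuning subset.

#' Transfer-learning configuration
#'
#' @param fractions Tuning fractions (strictly increasing, in (0,1);
#'   default `c(0.1, 0.3, 0.4, 0.6, 0.7)`).
#' @param fine_tune_lr_scale Learning-rate multiplier for fine-tuning the
#'   patch model (default 0.1, all layers trained).
#' @param fine_tune_epochs Fine-tuning epochs (default 2).
#' @param cv_folds Folds used when refitting the aggregators (default 3;
#'   tuning subsets are small).
#' @param seed RNG seed shared by all fractions for comparability.
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(fractions = c(0.1, 0.3, 0.4, 0.6, 0.7),
                            fine_tune_lr_scale = 0.1, fine_tune_epochs = 2L,
                            cv_folds = 3L, seed = 1L) {
  if (length(fractions) > 0) {
    if (any(fractions <= 0 | fractions >= 1)) stop_pathomsi("fractions must lie in (0,1)")
    if (is.unsorted(fractions, strictly = TRUE)) {
      stop_pathomsi("fractions must be strictly increasing")
    }
  }
  structure(list(fractions = fractions, fine_tune_lr_scale = fine_tune_lr_scale,
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "transfer_config")
}

# Stratified tuning subset: per-class counts = round(fraction * n), no
# forcing — a class absent from tune (or eval) is an error.
transfer_partition <- function(records, fraction, seed) {
  if (fraction <= 0 || fraction >= 1) stop_pathomsi("fraction must lie in (0,1)")
  with_seed(seed, {
    tune_ids <- character(0)
    for (cls in unique(records$ms_label)) {
      idx <- which(records$ms_label == cls)
      k <- floor(length(idx) * fraction + 0.5)
      tune_ids <- c(tune_ids, records$slide_id[sample(idx, k)])
    }
    tune <- dplyr::filter(records, .data$slide_id %in% tune_ids)
    eval <- dplyr::filter(records, !.data$slide_id %in% tune_ids)
    if (length(unique(tune$ms_label)) < 2) {
      stop_pathomsi("tuning subset is single-class at this fraction")
    }
    if (length(unique(eval$ms_label)) < 2) {
      stop_pathomsi("evaluation complement is single-class at this fraction")
    }
    list(tune = tune, eval = eval)
  })
}

#' Zero-shot evaluation on a new cohort
#'
#' Applies a fitted EPLA model unchanged to a new cohort's likelihood bags;
#' labels are used only for scoring.
#'
#' @param fit An `epla_fit` trained on the source cohort.
#' @param likelihood_table New-cohort patch likelihoods.
#' @param records New-cohort labelled slides.
#' @return A `roc_result`.
#' @export
zero_shot_eval <- function(fit, likelihood_table, records) {
  pred <- predict(fit, likelihood_table)
  pred <- dplyr::left_join(pred, records[, c("slide_id", "ms_label")],
                           by = "slide_id")
  evaluate_scores(pred$ensemble_score, pred$ms_label)
}

#' Fine-tune on a fraction of a new cohort
#'
#' Draws a stratified tuning subset of the given fraction, refits the
#' WSI-level aggregators (vocabulary, PALHI, BoW, ensemble weight, cutoff)
#' on the tuning slides' likelihood bags — reusing the source model's
#' CV-chosen xgboost hyperparameters — and returns the refit together with
#' the held-out complement for evaluation. When `patch_model` and `patches`
#' are supplied (image cohorts), the patch discriminator is first fine-tuned
#' from the source weights at `fine_tune_lr_scale` times its base learning
#' rate and new likelihoods are predicted for all slides.
#'
#' @param fit Source `epla_fit`.
#' @param likelihood_table New-cohort patch likelihoods (ignored when
#'   `patch_model` is supplied).
#' @param records New-cohort labelled slides.
#' @param fraction Tuning fraction in (0,1).
#' @param cfg A [transfer_config()].
#' @param patch_model Optional source `patch_cnn` to fine-tune.
#' @param patches Optional new-cohort patch store (required with
#'   `patch_model`).
#' @return A list `fit` (refit `epla_fit`), `patch_model` (fine-tuned or
#'   NULL), `likelihoods`, `tune_records`, `eval_records`.
#' @export
fine_tune <- function(fit, likelihood_table, records, fraction,
                      cfg = transfer_config(), patch_model = NULL,
                      patches = NULL) {
  part <- transfer_partition(records, fraction, cfg$seed)
  new_patch_model <- NULL
  if (!is.null(patch_model)) {
    if (is.null(patches)) stop_pathomsi("patches are required to fine-tune the patch model")
    base_cfg <- patch_model$config
    ft_cfg <- patch_model_config(
      backbone = base_cfg$backbone, epochs = cfg$fine_tune_epochs,
      batch_size = base_cfg$batch_size,
      learning_rate = base_cfg$learning_rate * cfg$fine_tune_lr_scale,
      momentum = base_cfg$momentum,
      patches_per_slide_per_epoch = base_cfg$patches_per_slide_per_epoch,
      input_size = base_cfg$input_size, augment = base_cfg$augment,
      seed = cfg$seed)
    tune_patches <- dplyr::filter(patches, .data$slide_id %in% part$tune$slide_id)
    new_patch_model <- train_patch_model(tune_patches, part$tune, ft_cfg,
                                         init_model = patch_model)
    likelihood_table <- predict_patch_likelihoods(new_patch_model, patches)
  }
  tune_lik <- dplyr::filter(likelihood_table, .data$slide_id %in% part$tune$slide_id)
  refit <- epla_train(tune_lik, part$tune, n_bins = fit$n_bins,
                      n_words = fit$n_words, cv_folds = cfg$cv_folds,
                      seed = cfg$seed, palhi_params = fit$palhi$params)
  list(fit = refit, patch_model = new_patch_model,
       likelihoods = likelihood_table,
       tune_records = part$tune, eval_records = part$eval)
}

#' Tuning-fraction sweep
#'
#' Repeats [fine_tune()] for each configured fraction (shared seed policy)
#' and evaluates each refit on its own held-out complement.
#'
#' @inheritParams fine_tune
#' @return A tibble `fraction`, `n_tune`, `n_eval`, `auc`, `ci_low`,
#'   `ci_high`, `seed`, sorted by fraction.
#' @export
fraction_sweep <- function(fit, likelihood_table, records,
                           cfg = transfer_config(), patch_model = NULL,
                           patches = NULL) {
  rows <- lapply(sort(cfg$fractions), function(fr) {
    ft <- fine_tune(fit, likelihood_table, records, fr, cfg,
                    patch_model = patch_model, patches = patches)
    eval_lik <- dplyr::filter(ft$likelihoods,
                              .data$slide_id %in% ft$eval_records$slide_id)
    res <- zero_shot_eval(ft$fit, eval_lik, ft$eval_records)
    tibble(fraction = fr, n_tune = nrow(ft$tune_records),
           n_eval = nrow(ft$eval_records), auc = res$auc,
           ci_low = res$ci_low, ci_high = res$ci_high, seed = cfg$seed)
  })
  if (length(rows) == 0) {
    return(tibble(fraction = numeric(0), n_tune = integer(0),
                  n_eval = integer(0), auc = numeric(0), ci_low = numeric(0),
                  ci_high = numeric(0), seed = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' Plot a tuning-fraction sweep
#'
#' @param sweep Tibble from [fraction_sweep()].
#' @return A ggplot object.
#' @export
plot_fraction_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$fraction, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "#2166ac", alpha = 0.2) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "fraction of new cohort used for fine-tuning",
                  y = "held-out AUC") +
    ggplot2::theme_minimal()
}
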