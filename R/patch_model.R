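#' Patch model configuration
#'
#' Settings for the patch-level MIL discriminator. The `tinycnn` backbone
#' (2 convolutions + 1 dense layer, see the methods vignette) is the
#' implemented backbone, sized for CPU-scale experiments on small tiles; the
#' training scheme (slide-label inheritance, BCE loss, mini-batch SGD with
#' momentum) is independent of backbone depth.
#'
#' @param backbone Only `"tinycnn"` is available.
#' @param epochs Training epochs (default 4).
#' @param batch_size Mini-batch size (default 16).
#' @param learning_rate SGD learning rate (default 0.05).
#' @param momentum SGD momentum (default 0.9).
#' @param patches_per_slide_per_epoch Per-epoch cap on patches sampled from
#'   each slide (`Inf` = all patches); balances slide sizes.
#' @param input_size Model input edge in pixels (default 64 for synthetic
#'   tiles; tiles are centre-cropped to this size).
#' @param augment Apply flip/affine augmentation during training.
#' @param seed RNG seed governing initialisation, sampling and augmentation.
#' @return A `patch_model_config` list.
#' @export
patch_model_config <- function(backbone = "tinycnn", epochs = 4L,
                               batch_size = 16L, learning_rate = 0.05,
                               momentum = 0.9,
                               patches_per_slide_per_epoch = Inf,
                               input_size = 64L, augment = FALSE,
                               seed = 1L) {
  if (!identical(backbone, "tinycnn")) {
    stop_pathomsi("only the 'tinycnn' backbone is available in this package")
  }
  if (learning_rate <= 0) stop_pathomsi("learning_rate must be > 0")
  if (epochs < 1) stop_pathomsi("epochs must be >= 1")
  structure(list(backbone = backbone, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 patches_per_slide_per_epoch = patches_per_slide_per_epoch,
                 input_size = as.integer(input_size), augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "patch_model_config")
}

patch_preprocess_cfg <- function(cfg, stats, augment) {
  preprocess_config(crop_size = cfg$input_size,
                    channel_mean = stats$mean, channel_std = stats$std,
                    augment = augment)
}

#' Train the patch-level discriminator under MIL label inheritance
#'
#' Every patch is assigned its slide's MS label (the multiple-instance
#' shortcut: the bag label supervises all instances) and a compact CNN is
#' trained with binary cross-entropy and mini-batch SGD. Slides are
#' subsampled per epoch and loss terms are weighted by inverse slide-class
#' frequency so that large slides and the majority class do not dominate.
#'
#' @param patches Patch store: a tibble with `slide_id`, `grid_x`, `grid_y`
#'   and a list-column `img` of `H x W x 3` arrays in `[0, 1]`.
#' @param records Labelled slide tibble (`slide_id`, `ms_label`).
#' @param cfg A [patch_model_config()].
#' @param init_model Optional `patch_cnn` whose weights and channel
#'   statistics initialise training (weight reuse for transfer learning);
#'   by default weights are freshly initialised.
#' @return A `patch_cnn` model object holding weights, architecture, config,
#'   channel statistics and the per-epoch mean BCE loss trace.
#' @export
train_patch_model <- function(patches, records, cfg = patch_model_config(),
                              init_model = NULL) {
  if (nrow(patches) == 0) stop_pathomsi("empty patch store")
  lab <- setNames(as_label01(records$ms_label), records$slide_id)
  if (any(!patches$slide_id %in% names(lab))) {
    stop_pathomsi("patch store contains slides missing from the records")
  }
  y_all <- lab[patches$slide_id]
  check_both_classes(y_all, "training set (single-class)")
  stats <- if (is.null(init_model)) channel_stats(patches$img) else
    list(mean = init_model$channel_mean, std = init_model$channel_std)
  arch <- tinycnn_arch(cfg$input_size)
  pp_train <- patch_preprocess_cfg(cfg, stats, cfg$augment)
  class_n <- table(lab)  # slides per class
  slide_w <- length(lab) / (2 * class_n[as.character(lab)])
  names(slide_w) <- names(lab)

  with_seed(cfg$seed, {
    params <- if (is.null(init_model)) tinycnn_init(arch) else init_model$params
    velocity <- zero_like(params)
    trace <- numeric(cfg$epochs)
    by_slide <- split(seq_len(nrow(patches)), patches$slide_id)
    for (ep in seq_len(cfg$epochs)) {
      take <- unlist(lapply(by_slide, function(ix) {
        k <- min(length(ix), cfg$patches_per_slide_per_epoch)
        if (k < length(ix)) sample(ix, k) else ix
      }), use.names = FALSE)
      take <- sample(take)
      losses <- numeric(length(take))
      done <- 0L
      for (start in seq(1, length(take), by = cfg$batch_size)) {
        bidx <- take[start:min(start + cfg$batch_size - 1, length(take))]
        grads <- zero_like(params)
        for (i in bidx) {
          x <- preprocess_patch(patches$img[[i]], pp_train)
          fw <- tinycnn_forward(x, params, arch, keep_cache = TRUE)
          y <- unname(y_all[i]); w <- unname(slide_w[patches$slide_id[i]])
          bl <- bce_with_logits(fw$logit, y)
          done <- done + 1L
          losses[done] <- bl$loss
          g <- tinycnn_backward(w * bl$grad / length(bidx), fw, params, arch)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        upd <- sgd_step(params, velocity, grads, cfg$learning_rate, cfg$momentum)
        params <- upd$params; velocity <- upd$velocity
      }
      trace[ep] <- mean(losses[seq_len(done)])
    }
    structure(list(params = params, arch = arch, config = cfg,
                   channel_mean = stats$mean, channel_std = stats$std,
                   loss_trace = tibble(epoch = seq_len(cfg$epochs),
                                       mean_bce = trace)),
              class = "patch_cnn")
  })
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat("<patch_cnn> tinycnn, input", x$arch$input_size, "px,",
      nrow(x$loss_trace), "epochs, final BCE",
      signif(tail(x$loss_trace$mean_bce, 1), 4), "\n")
  invisible(x)
}

#' @export
tidy.patch_cnn <- function(x, ...) x$loss_trace

#' @export
glance.patch_cnn <- function(x, ...) {
  tibble(epochs = nrow(x$loss_trace),
         final_bce = tail(x$loss_trace$mean_bce, 1),
         n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Per-patch MSI likelihoods
#'
#' Runs the trained discriminator over a patch store and returns the sigmoid
#' likelihood of MSI for every patch. Deterministic for a fixed model and
#' independent of row order.
#'
#' @param model A `patch_cnn` from [train_patch_model()].
#' @param patches Patch store tibble (same layout as in training).
#' @return A tibble `slide_id`, `grid_x`, `grid_y`, `likelihood`.
#' @export
predict_patch_likelihoods <- function(model, patches) {
  if (nrow(patches) == 0) stop_pathomsi("empty patch store")
  pp <- preprocess_config(crop_size = model$config$input_size,
                          channel_mean = model$channel_mean,
                          channel_std = model$channel_std, augment = FALSE)
  lik <- vapply(patches$img, function(im) {
    if (any(dim(im)[1:2] < model$config$input_size)) {
      stop_pathomsi("patch smaller than the model input size (statistics mismatch)")
    }
    z <- tinycnn_forward(preprocess_patch(im, pp), model$params, model$arch)$logit
    1 / (1 + exp(-z))
  }, numeric(1))
  tibble(slide_id = patches$slide_id, grid_x = patches$grid_x,
         grid_y = patches$grid_y, likelihood = lik)
}

#' Patch-likelihood heat map for one slide
#'
#' Draws one cell per patch at its grid position, coloured by MSI likelihood
#' (monotone colour scale with a colourbar, y down as in the image frame).
#'
#' @param table Patch-likelihood tibble.
#' @param slide_id Slide to draw.
#' @return A ggplot object.
#' @export
plot_patch_heatmap <- function(table, slide_id) {
  sub <- dplyr::filter(table, .data$slide_id == !!slide_id)
  if (nrow(sub) == 0) stop_pathomsi(paste0("unknown slide: ", slide_id))
  sub <- dplyr::arrange(sub, .data$grid_y, .data$grid_x)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$grid_x, y = .data$grid_y,
                                    fill = .data$likelihood)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "MSI likelihood") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = slide_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a patch model artifact
#'
#' The artifact directory holds the weights (`weights.rds`), the training
#' config (`config.json`), the dataset channel statistics
#' (`channel_stats.json`) and the loss trace (`loss_trace.csv`).
#'
#' @param model A `patch_cnn`.
#' @param dir Artifact directory (created if needed).
#' @return `dir` (save) or the restored `patch_cnn` (load).
#' @export
save_patch_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  cfgl <- unclass(model$config)
  cfgl$patches_per_slide_per_epoch <-
    if (is.infinite(cfgl$patches_per_slide_per_epoch)) "all" else cfgl$patches_per_slide_per_epoch
  jsonlite::write_json(cfgl, file.path(dir, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(mean = model$channel_mean, std = model$channel_std),
                       file.path(dir, "channel_stats.json"), digits = NA)
  utils::write.csv(model$loss_trace, file.path(dir, "loss_trace.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_patch_model
#' @export
load_patch_model <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  if (identical(cfgl$patches_per_slide_per_epoch, "all")) {
    cfgl$patches_per_slide_per_epoch <- Inf
  }
  cfg <- do.call(patch_model_config, cfgl)
  st <- jsonlite::read_json(file.path(dir, "channel_stats.json"), simplifyVector = TRUE)
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 arch = tinycnn_arch(cfg$input_size), config = cfg,
                 channel_mean = st$mean, channel_std = st$std,
                 loss_trace = as_tibble(utils::read.csv(file.path(dir, "loss_trace.csv")))),
            class = "patch_cnn")
}

#' Write / read a patch store as PNG tiles plus an index TSV
#'
#' Tiles are written as `{slide_id}_{grid_x}_{grid_y}.png` with an
#' `index.tsv` (`slide_id`, `grid_x`, `grid_y`, and any further index
#' columns present).
#'
#' @param patches Patch store tibble with list-column `img`.
#' @param dir Target directory.
#' @return `dir` (write) or the patch store tibble (read).
#' @export
write_patch_store <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(patches))) {
    png::writePNG(patches$img[[i]],
                  file.path(dir, sprintf("%s_%d_%d.png", patches$slide_id[i],
                                         patches$grid_x[i], patches$grid_y[i])))
  }
  idx <- dplyr::select(patches, -dplyr::any_of("img"))
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patch_store
#' @export
read_patch_store <- function(dir) {
  idx <- as_tibble(utils::read.table(file.path(dir, "index.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE))
  idx$img <- lapply(seq_len(nrow(idx)), function(i) {
    png::readPNG(file.path(dir, sprintf("%s_%d_%d.png", idx$slide_id[i],
                                        idx$grid_x[i], idx$grid_y[i])))
  })
  idx
}
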