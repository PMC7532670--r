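# Synthetic cohort generators. The likelihood-space generator embodies the
# MIL premise that only a minority of "key" patches carry the MSI phenotype:
# MSS bags draw every likelihood from a low Beta, MSI bags mix a key-patch
# Beta concentrated near 1 into the same background. The image-space
# generator renders the analogous premise as textured tiles whose key tiles
# carry dense dark blobs, with an ImageScope ROI annotation per slide.

#' Synthetic cohort configuration
#'
#' @param n_slides Number of slides.
#' @param msi_prevalence MSI prevalence (default 0.17, a typical colorectal
#'   cohort class balance).
#' @param patches_per_slide Integer range `c(min, max)` of patches per slide
#'   (default 20-400, the scale of real per-slide tile counts).
#' @param mss_beta Beta parameters of background/MSS patch likelihoods
#'   (default `c(2, 8)`, mean 0.2).
#' @param msi_key_beta Beta parameters of MSI key-patch likelihoods
#'   (default `c(8, 2)`, mean 0.8).
#' @param key_patch_fraction Fraction of key patches in an MSI bag
#'   (default 0.3).
#' @param shift_strength Domain shift `s >= 0`: both Beta means are moved
#'   toward 0.5 by `0.15 * s` (concentration preserved), emulating the
#'   likelihood-space effect of a cohort change (e.g. frozen vs FFPE
#'   preparation); in image mode the same `s` adds a colour cast.
#' @param mode `"likelihood"` or `"image"`.
#' @param tile_size Image-mode tile edge in pixels (default 64).
#' @param seed RNG seed.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_slides = 300L, msi_prevalence = 0.17,
                                    patches_per_slide = c(20L, 400L),
                                    mss_beta = c(2, 8), msi_key_beta = c(8, 2),
                                    key_patch_fraction = 0.3,
                                    shift_strength = 0,
                                    mode = c("likelihood", "image"),
                                    tile_size = 64L, seed = 1L) {
  mode <- match.arg(mode)
  if (msi_prevalence < 0 || msi_prevalence > 1) stop_pathomsi("msi_prevalence must lie in [0,1]")
  if (key_patch_fraction <= 0 || key_patch_fraction > 1) {
    stop_pathomsi("key_patch_fraction must lie in (0,1]")
  }
  if (any(c(mss_beta, msi_key_beta) <= 0)) stop_pathomsi("beta parameters must be positive")
  if (shift_strength < 0) stop_pathomsi("shift_strength must be >= 0")
  structure(list(n_slides = as.integer(n_slides), msi_prevalence = msi_prevalence,
                 patches_per_slide = as.integer(patches_per_slide),
                 mss_beta = mss_beta, msi_key_beta = msi_key_beta,
                 key_patch_fraction = key_patch_fraction,
                 shift_strength = shift_strength, mode = mode,
                 tile_size = as.integer(tile_size), seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# Move a Beta's mean toward 0.5 by delta, preserving concentration a+b.
shift_beta <- function(ab, delta) {
  m <- ab[1] / sum(ab)
  m2 <- m + sign(0.5 - m) * min(delta, abs(0.5 - m))
  c(m2, 1 - m2) * sum(ab)
}

synthetic_labels <- function(cfg) {
  y <- rbinom(cfg$n_slides, 1, cfg$msi_prevalence)
  tibble(slide_id = sprintf("SYN%04d", seq_len(cfg$n_slides)),
         cohort = if (cfg$shift_strength > 0) "shifted" else "synthetic",
         msisensor_score = NA_real_, unstable_loci = NA_integer_,
         ms_label = label_chr(y),
         n_patches = NA_integer_, split = "unassigned")
}

#' Simulate a likelihood-space cohort
#'
#' Slide labels are Bernoulli(prevalence); MSS bags draw all likelihoods
#' from `Beta(mss_beta)`, MSI bags from the mixture
#' `pi * Beta(msi_key_beta) + (1 - pi) * Beta(mss_beta)` with
#' `pi = key_patch_fraction`. `shift_strength` moves both Beta means toward
#' 0.5 by `0.15 * s`. Deterministic per seed.
#'
#' @param cfg A [synthetic_cohort_config()] with `mode = "likelihood"`.
#' @return A list with `records` (labelled slide tibble) and `likelihoods`
#'   (tibble `slide_id`, `grid_x`, `grid_y`, `likelihood`, `is_key`).
#' @export
simulate_likelihood_cohort <- function(cfg = synthetic_cohort_config()) {
  if (cfg$mode != "likelihood") stop_pathomsi("cfg$mode must be 'likelihood'")
  with_seed(cfg$seed, {
    records <- synthetic_labels(cfg)
    delta <- 0.15 * cfg$shift_strength
    bg <- shift_beta(cfg$mss_beta, delta)
    key <- shift_beta(cfg$msi_key_beta, delta)
    rows <- lapply(seq_len(nrow(records)), function(i) {
      n <- sample(cfg$patches_per_slide[1]:cfg$patches_per_slide[2], 1)
      is_key <- if (records$ms_label[i] == "MSI") {
        runif(n) < cfg$key_patch_fraction
      } else rep(FALSE, n)
      lik <- ifelse(is_key, rbeta(n, key[1], key[2]), rbeta(n, bg[1], bg[2]))
      tibble(slide_id = records$slide_id[i],
             grid_x = seq_len(n) - 1L, grid_y = 0L,
             likelihood = lik, is_key = is_key)
    })
    likelihoods <- dplyr::bind_rows(rows)
    records$n_patches <- as.integer(table(likelihoods$slide_id)[records$slide_id])
    list(records = records, likelihoods = likelihoods)
  })
}

# One textured tile: noisy background plus `n_blobs` dark gaussian blobs.
render_tile <- function(size, n_blobs, cast = 0) {
  base <- c(0.82, 0.70, 0.78)  # eosin-like hue
  img <- array(rep(base, each = size * size), c(size, size, 3)) +
    array(rnorm(size * size * 3, 0, 0.04), c(size, size, 3))
  if (n_blobs > 0) {
    gx <- matrix(rep(seq_len(size), each = size), size)
    gy <- matrix(rep(seq_len(size), times = size), size)
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 3, size - 2); cy <- runif(1, 3, size - 2)
      r <- runif(1, 1.5, 3.5)
      mask <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * r^2))
      for (c in 1:3) img[, , c] <- img[, , c] - 0.55 * mask
    }
  }
  if (cast != 0) img[, , 1] <- img[, , 1] + cast  # colour cast = domain shift
  pmin(pmax(img, 0), 1)
}

#' Simulate an image-space cohort
#'
#' Each slide is a mosaic of textured tiles on a grid. Key tiles (fraction
#' `pi` of an MSI slide's tiles) carry dense dark blobs (count
#' `Poisson(25)`); all other tiles, including every MSS tile, carry sparse
#' blobs (`Poisson(5)`). A rectangular ROI covering a random sub-rectangle
#' of the mosaic is attached as an `roi_annotation` (writable as ImageScope
#' XML). `shift_strength` adds a red colour cast of `0.08 * s`.
#'
#' @param cfg A [synthetic_cohort_config()] with `mode = "image"`.
#' @return A list with `records`, `patches` (patch store tibble with
#'   list-column `img` and flag `is_key`), `rois` (named list of
#'   `roi_annotation`), and `extents` (named list of `c(width, height)`).
#' @export
simulate_image_cohort <- function(cfg = synthetic_cohort_config(
  n_slides = 30L, patches_per_slide = c(9L, 16L), mode = "image")) {
  if (cfg$mode != "image") stop_pathomsi("cfg$mode must be 'image'")
  lambda_key <- 25; lambda_bg <- 5
  with_seed(cfg$seed, {
    records <- synthetic_labels(cfg)
    cast <- 0.08 * cfg$shift_strength
    ts <- cfg$tile_size
    patch_rows <- list(); rois <- list(); extents <- list()
    for (i in seq_len(nrow(records))) {
      n <- sample(cfg$patches_per_slide[1]:cfg$patches_per_slide[2], 1)
      ncol_g <- ceiling(sqrt(n)); nrow_g <- ceiling(n / ncol_g)
      n <- ncol_g * nrow_g  # full mosaic
      is_key <- if (records$ms_label[i] == "MSI") {
        runif(n) < cfg$key_patch_fraction
      } else rep(FALSE, n)
      tiles <- lapply(seq_len(n), function(j) {
        render_tile(ts, rpois(1, if (is_key[j]) lambda_key else lambda_bg), cast)
      })
      gx <- (seq_len(n) - 1L) %% ncol_g
      gy <- (seq_len(n) - 1L) %/% ncol_g
      ext <- c(ncol_g * ts, nrow_g * ts)
      # ROI: a random sub-rectangle covering most of the mosaic
      x0 <- runif(1, 0, 0.1) * ext[1]; x1 <- runif(1, 0.9, 1) * ext[1]
      y0 <- runif(1, 0, 0.1) * ext[2]; y1 <- runif(1, 0.9, 1) * ext[2]
      roi <- new_roi_annotation(records$slide_id[i],
                                list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))))
      patch_rows[[i]] <- tibble(slide_id = records$slide_id[i],
                                grid_x = gx, grid_y = gy,
                                is_key = is_key, img = tiles)
      rois[[records$slide_id[i]]] <- roi
      extents[[records$slide_id[i]]] <- ext
    }
    patches <- dplyr::bind_rows(patch_rows)
    records$n_patches <- as.integer(table(patches$slide_id)[records$slide_id])
    list(records = records, patches = patches, rois = rois, extents = extents)
  })
}

#' Simulate omics tables correlated with the slide label
#'
#' Mutation rows per sample realise a tumour mutation burden drawn from
#' `logNormal(3.5, 0.3)` (MSI) vs `logNormal(1.5, 0.3)` (MSS) mutations/Mb
#' over a 38 Mb exome; INDEL counts are `Binomial(n_nonsyn, 0.25)` (MSI) vs
#' `Binomial(n_nonsyn, 0.08)` (MSS); a nonsynonymous hit in the MMR gene set
#' occurs with probability 0.8 (MSI) vs 0.05 (MSS); ~20% extra synonymous
#' rows exercise the exclusion rule. Expression contains the CYT and CD8
#' T-effector genes with a +2 log2-fold MSI shift plus Gaussian noise
#' (sd 1 on the log2 scale) over 20 background genes.
#'
#' @param records Labelled slide tibble.
#' @param seed RNG seed.
#' @param exome_size_mb Exome size used to realise mutation counts.
#' @return A list with `mutations` (a `mutation_profile`) and `expression`
#'   (genes x samples matrix).
#' @export
simulate_omics <- function(records, seed = 1L, exome_size_mb = 38) {
  if (any(is.na(records$ms_label))) stop_pathomsi("records must be labelled")
  immune_genes <- union(cyt_genes, cd8_t_effector_genes)
  bg_genes <- sprintf("GENE%04d", 1:20)
  with_seed(seed, {
    mut_rows <- lapply(seq_len(nrow(records)), function(i) {
      msi <- records$ms_label[i] == "MSI"
      tmb <- rlnorm(1, if (msi) 3.5 else 1.5, 0.3)
      n_nonsyn <- max(1L, round(tmb * exome_size_mb))
      n_indel <- rbinom(1, n_nonsyn, if (msi) 0.25 else 0.08)
      n_syn <- rbinom(1, n_nonsyn, 0.2)
      cls <- c(sample(c("INS", "DEL"), n_indel, replace = TRUE),
               sample(c("missense", "nonsense", "frameshift"),
                      n_nonsyn - n_indel, replace = TRUE,
                      prob = c(0.8, 0.1, 0.1)),
               rep("synonymous", n_syn))
      genes <- sample(sprintf("SOM%05d", 1:5000), length(cls), replace = TRUE)
      if (runif(1) < (if (msi) 0.8 else 0.05)) {
        genes[1] <- sample(mmr_genes, 1)  # guaranteed nonsynonymous slot
      }
      tibble(sample_id = records$slide_id[i], gene = genes, variant_class = cls)
    })
    mutations <- mutation_profile(dplyr::bind_rows(mut_rows),
                                  exome_size_mb = exome_size_mb)
    genes <- c(immune_genes, bg_genes)
    y <- as_label01(records$ms_label)
    log2expr <- matrix(rnorm(length(genes) * nrow(records), 5, 1),
                       nrow = length(genes), dimnames = list(genes, records$slide_id))
    log2expr[immune_genes, y == 1] <- log2expr[immune_genes, y == 1, drop = FALSE] + 2
    list(mutations = mutations, expression = 2^log2expr)
  })
}
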