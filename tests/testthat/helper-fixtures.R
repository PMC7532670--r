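# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# A star-shaped simple polygon: equally spaced angles with jitter keeps all
# angular gaps below pi, which guarantees simplicity.
random_simple_polygon <- function(n, centre = c(32, 32), r_range = c(8, 60)) {
  ang <- 2 * pi * (seq_len(n) - 1) / n + runif(n, 0, 0.8 * 2 * pi / n)
  rad <- runif(n, r_range[1], r_range[2])
  cbind(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang))
}

# Super-sampled point-in-polygon rasterisation oracle for the overlap
# fraction of the patch [0,size]^2 (ss subsamples per pixel per axis).
raster_overlap_oracle <- function(ring, size, ss = 16) {
  g <- (seq_len(size * ss) - 0.5) / ss
  px <- rep(g, times = length(g)); py <- rep(g, each = length(g))
  inside <- rep(FALSE, length(px))
  nv <- nrow(ring); j <- nv
  for (i in seq_len(nv)) {
    cross <- (ring[i, 2] > py) != (ring[j, 2] > py)
    xi <- ring[j, 1] + (py - ring[j, 2]) * (ring[i, 1] - ring[j, 1]) /
      (ring[i, 2] - ring[j, 2])
    inside <- xor(inside, cross & (px < xi))
    j <- i
  }
  mean(inside)
}

# In-domain likelihood cohort + trained EPLA model, reused across test files.
trained_epla_fixture <- function() {
  fixture("trained_epla", function() {
    sim <- simulate_likelihood_cohort(synthetic_cohort_config(n_slides = 160, seed = 11))
    fit <- epla_train(sim$likelihoods, sim$records, seed = 1)
    list(sim = sim, fit = fit)
  })
}

# Small textured image cohort + trained patch CNN.
trained_cnn_fixture <- function() {
  fixture("trained_cnn", function() {
    cfg <- synthetic_cohort_config(n_slides = 36, msi_prevalence = 0.4,
                                   patches_per_slide = c(9L, 16L),
                                   mode = "image", seed = 3)
    sim <- simulate_image_cohort(cfg)
    rec <- stratified_split(sim$records, 0.7, seed = 1)
    train <- dplyr::filter(rec, split == "train")
    test <- dplyr::filter(rec, split == "test")
    model <- train_patch_model(dplyr::filter(sim$patches, slide_id %in% train$slide_id),
                               train, patch_model_config(epochs = 3, seed = 1))
    list(sim = sim, records = rec, train = train, test = test, model = model)
  })
}

write_manifest_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
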