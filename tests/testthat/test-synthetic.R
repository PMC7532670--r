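test_that("likelihood cohorts are seed-deterministic with designed moments", {
  cfg <- synthetic_cohort_config(n_slides = 300, seed = 8)
  a <- simulate_likelihood_cohort(cfg)
  b <- simulate_likelihood_cohort(cfg)
  expect_identical(a, b)

  lab <- setNames(a$records$ms_label, a$records$slide_id)
  per_slide <- dplyr::summarise(dplyr::group_by(a$likelihoods, slide_id),
                                m = mean(likelihood), .groups = "drop")
  per_slide$lab <- lab[per_slide$slide_id]
  msi <- per_slide$m[per_slide$lab == "MSI"]
  mss <- per_slide$m[per_slide$lab == "MSS"]
  se <- sqrt(var(msi) / length(msi) + var(mss) / length(mss))
  expect_gt(mean(msi) - mean(mss), 5 * se)  # key-patch mixture lifts MSI bags

  degenerate <- simulate_likelihood_cohort(
    synthetic_cohort_config(n_slides = 40, msi_prevalence = 0, seed = 2))
  expect_true(all(degenerate$records$ms_label == "MSS"))
  expect_false(any(degenerate$likelihoods$is_key))
  # all-background likelihoods: Beta(2,8) mean 0.2
  expect_equal(mean(degenerate$likelihoods$likelihood), 0.2, tolerance = 0.02)
})

test_that("generator parameters are recoverable at n = 500", {
  cfg <- synthetic_cohort_config(n_slides = 500, seed = 14)
  sim <- simulate_likelihood_cohort(cfg)
  n <- nrow(sim$records)
  prev <- mean(sim$records$ms_label == "MSI")
  expect_lt(abs(prev - 0.17), 3 * sqrt(0.17 * 0.83 / n))

  msi_ids <- sim$records$slide_id[sim$records$ms_label == "MSI"]
  msi_rows <- dplyr::filter(sim$likelihoods, slide_id %in% msi_ids)
  pi_hat <- mean(msi_rows$is_key)
  expect_lt(abs(pi_hat - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(msi_rows)))

  bg <- dplyr::filter(sim$likelihoods, !is_key)
  expect_lt(abs(mean(bg$likelihood) - 0.2), 3 * sd(bg$likelihood) / sqrt(nrow(bg)))
  key <- dplyr::filter(sim$likelihoods, is_key)
  expect_lt(abs(mean(key$likelihood) - 0.8), 3 * sd(key$likelihood) / sqrt(nrow(key)))
})

test_that("the likelihood-space shift moves both mixture components toward 0.5", {
  base <- simulate_likelihood_cohort(synthetic_cohort_config(n_slides = 200, seed = 3))
  shifted <- simulate_likelihood_cohort(synthetic_cohort_config(
    n_slides = 200, shift_strength = 1, seed = 3))
  bg0 <- dplyr::filter(base$likelihoods, !is_key)$likelihood
  bg1 <- dplyr::filter(shifted$likelihoods, !is_key)$likelihood
  expect_lt(abs(mean(bg1) - mean(bg0) - 0.15), 0.02)
  key0 <- dplyr::filter(base$likelihoods, is_key)$likelihood
  key1 <- dplyr::filter(shifted$likelihoods, is_key)$likelihood
  expect_lt(abs(mean(key0) - mean(key1) - 0.15), 0.02)
})

test_that("zero-shot AUC is non-increasing in shift strength", {
  fx <- trained_epla_fixture()
  mean_auc <- vapply(c(0, 0.5, 1), function(s) {
    mean(vapply(1:5, function(sd) {
      sim <- simulate_likelihood_cohort(synthetic_cohort_config(
        n_slides = 150, shift_strength = s, seed = 300 + sd))
      zero_shot_eval(fx$fit, sim$likelihoods, sim$records)$auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) <= 0.02))
})

test_that("image cohorts render key tiles denser and round-trip their ROIs", {
  cfg <- synthetic_cohort_config(n_slides = 6, msi_prevalence = 1,
                                 key_patch_fraction = 1,
                                 patches_per_slide = c(4L, 9L),
                                 mode = "image", seed = 6)
  sim <- simulate_image_cohort(cfg)
  expect_true(all(sim$patches$is_key))  # pi = 1, prevalence = 1

  mixed <- simulate_image_cohort(synthetic_cohort_config(
    n_slides = 12, msi_prevalence = 0.5, patches_per_slide = c(9L, 9L),
    mode = "image", seed = 7))
  # generator self-check: dark-blob pixels make key tiles darker on average
  dark_frac <- vapply(mixed$patches$img, function(im) mean(im < 0.45), numeric(1))
  expect_gt(mean(dark_frac[mixed$patches$is_key]),
            mean(dark_frac[!mixed$patches$is_key]))

  id <- mixed$records$slide_id[1]
  path <- tempfile(fileext = ".xml")
  write_annotation_xml(mixed$rois[[id]], path)
  back <- parse_annotation_xml(path, id)
  expect_equal(back$polygons[[1]], mixed$rois[[id]]$polygons[[1]],
               tolerance = 1e-8)

  # the emitted ROI and extent feed the tiler
  refs <- tile_slide(mixed$rois[[id]], mixed$extents[[id]], patch_size = 64,
                     min_overlap = 0.8)
  expect_gt(nrow(refs), 0)
  expect_true(all(refs$overlap > 0.8))
})

test_that("synthetic omics tables are deterministic and label-linked", {
  rec <- as_slide_records(data.frame(
    slide_id = sprintf("O%03d", 1:40),
    ms_label = rep(c("MSI", "MSS"), each = 20)))
  om1 <- simulate_omics(rec, seed = 4)
  om2 <- simulate_omics(rec, seed = 4)
  expect_identical(om1, om2)
  expect_true(all(om1$mutations$variant_class %in% pathomsi:::variant_classes))
  expect_true(all(om1$expression >= 0))
  tmbs <- vapply(rec$slide_id, function(s) tmb(om1$mutations, s), numeric(1))
  expect_gt(median(tmbs[1:20]), median(tmbs[21:40]))  # MSI hypermutation

  expect_error(simulate_omics(as_slide_records(
    data.frame(slide_id = "x", msisensor_score = 1)), seed = 1), "labelled")
})
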