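# PALHI / BoW / ensemble / majority-vote behaviour.

separable_histograms <- function(n_per_class) {
  lows <- t(vapply(seq_len(n_per_class), function(i) palhi_histogram(
    runif(30, 0, 0.01)), numeric(100)))
  highs <- t(vapply(seq_len(n_per_class), function(i) palhi_histogram(
    runif(30, 0.99, 1)), numeric(100)))
  list(X = rbind(lows, highs), y = rep(c(0L, 1L), each = n_per_class))
}

test_that("PALHI fits separable histograms perfectly and deterministically", {
  set.seed(5)
  d <- separable_histograms(12)
  fixed <- list(max_depth = 2L, nrounds = 50L, eta = 0.3)
  fit1 <- fit_palhi(d$X, d$y, seed = 3, fixed_params = fixed)
  expect_equal(roc_auc(pathomsi:::xgb_score(fit1$booster, d$X), d$y), 1)

  fit2 <- fit_palhi(d$X, d$y, cv_folds = 3, seed = 9)
  fit3 <- fit_palhi(d$X, d$y, cv_folds = 3, seed = 9)
  expect_identical(fit2$params, fit3$params)
  expect_identical(fit2$cv_table, fit3$cv_table)
  expect_error(fit_palhi(d$X, rep(1, nrow(d$X))), "single-class")
})

test_that("Gaussian NB matches the closed-form oracle on a 4-slide toy", {
  X <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.8, 0.1), c(0.9, 0.3))
  y <- c(0L, 0L, 1L, 1L)
  nb <- pathomsi:::fit_gaussian_nb(X, y)
  got <- pathomsi:::predict_gaussian_nb(nb, X)

  # independent closed form: per-class ML gaussians with the same smoothing
  eps <- 1e-9 * max(apply(X, 2, function(c) mean((c - mean(c))^2)))
  post <- function(x) {
    ll <- vapply(list(X[y == 0, ], X[y == 1, ]), function(Xi) {
      mu <- colMeans(Xi)
      v <- colMeans((Xi - matrix(mu, nrow(Xi), 2, byrow = TRUE))^2) + eps
      sum(dnorm(x, mu, sqrt(v), log = TRUE)) + log(0.5)
    }, numeric(1))
    1 / (1 + exp(ll[1] - ll[2]))
  }
  oracle <- apply(X, 1, post)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("Gaussian NB agrees with an independent reference implementation", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3, rep(c(0, 1), each = 30)), 60, 3)
  y <- rep(c(0L, 1L), each = 30)
  nb <- pathomsi:::fit_gaussian_nb(X, y)
  got <- pathomsi:::predict_gaussian_nb(nb, X)
  ref <- e1071::naiveBayes(data.frame(X), factor(y))
  refp <- predict(ref, data.frame(X), type = "raw")[, "1"]
  # e1071 uses n-1 variance without smoothing; posteriors agree closely
  expect_equal(got, unname(refp), tolerance = 0.02)
})

test_that("uninformative features give posterior near the class prior", {
  X <- matrix(rep(c(0.3, 0.7), 30), ncol = 2, byrow = TRUE)
  y <- rep(c(0L, 1L), 15)
  nb <- pathomsi:::fit_gaussian_nb(X + rnorm(60, 0, 1e-6), y)
  p <- pathomsi:::predict_gaussian_nb(nb, X)
  expect_true(all(abs(p - 0.5) < 0.05))
})

test_that("ensemble weight maximises out-of-fold AUC with ties toward 0.5", {
  set.seed(13)
  y <- rep(c(0L, 1L), each = 40)
  perfect <- c(runif(40, 0, 0.4), runif(40, 0.6, 1))
  noise <- runif(80)
  a <- fit_ensemble_weight(perfect, noise, y)
  # independent grid-scan oracle
  alphas <- seq(0, 1, 0.01)
  aucs <- vapply(alphas, function(al) roc_auc(al * perfect + (1 - al) * noise, y),
                 numeric(1))
  plateau <- alphas[aucs >= max(aucs) - 1e-12]
  expect_true(a %in% plateau)
  expect_equal(a, plateau[which.min(abs(plateau - 0.5))])

  expect_equal(fit_ensemble_weight(perfect, perfect, y), 0.5)
  ens_auc <- roc_auc(a * perfect + (1 - a) * noise, y)
  expect_gte(ens_auc, max(roc_auc(perfect, y), roc_auc(noise, y)) - 1e-12)
  expect_error(fit_ensemble_weight(perfect, noise[-1], y), "equal length")
})

test_that("EPLA predictions obey the convex-combination and cutoff contract", {
  fx <- trained_epla_fixture()
  te <- simulate_likelihood_cohort(synthetic_cohort_config(n_slides = 40, seed = 77))
  pred <- predict(fx$fit, te$likelihoods)
  expect_equal(pred$ensemble_score,
               fx$fit$alpha * pred$palhi_score + (1 - fx$fit$alpha) * pred$bow_score)
  expect_equal(pred$predicted_label,
               ifelse(pred$ensemble_score >= fx$fit$cutoff, "MSI", "MSS"))
  expect_true(all(pred$palhi_score >= 0 & pred$palhi_score <= 1))
  expect_true(all(pred$bow_score >= 0 & pred$bow_score <= 1))
})

test_that("aggregator outputs are invariant to bag permutation", {
  fx <- trained_epla_fixture()
  bag <- dplyr::filter(fx$sim$likelihoods, slide_id == fx$sim$records$slide_id[1])
  base <- predict_wsi(fx$fit, bag$likelihood, "w")
  set.seed(99)
  for (i in 1:20) {
    perm <- sample(bag$likelihood)
    expect_identical(predict_wsi(fx$fit, perm, "w"), base)
  }
})

test_that("majority vote follows its strict-majority tie rule", {
  mv <- majority_vote(tibble::tibble(slide_id = "a",
                                     likelihood = c(0.9, 0.8, 0.1)))
  expect_equal(mv$vote_fraction, 2 / 3)
  expect_equal(mv$predicted_label, "MSI")

  mv2 <- majority_vote(tibble::tibble(slide_id = "b", likelihood = c(0.4, 0.4)))
  expect_equal(mv2$vote_fraction, 0)
  expect_equal(mv2$predicted_label, "MSS")

  mv3 <- majority_vote(tibble::tibble(slide_id = "c", likelihood = c(0.6, 0.4)))
  expect_equal(mv3$vote_fraction, 0.5)
  expect_equal(mv3$predicted_label, "MSS")  # strict > for the majority
})

test_that("EPLA artifacts round-trip through disk", {
  fx <- trained_epla_fixture()
  dir <- tempfile()
  save_epla(fx$fit, dir)
  back <- load_epla(dir)
  te <- simulate_likelihood_cohort(synthetic_cohort_config(n_slides = 20, seed = 55))
  expect_equal(predict(back, te$likelihoods), predict(fx$fit, te$likelihoods),
               tolerance = 1e-7)
})
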