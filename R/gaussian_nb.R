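# Gaussian naive Bayes for the BoW TF-IDF block.
#
# Per-class feature means/variances with variance smoothing
# eps = 1e-9 * max feature variance added to every variance, so constant
# features stay finite and uninformative.

fit_gaussian_nb <- function(X, y01) {
  X <- as.matrix(X)
  check_both_classes(y01)
  classes <- c(0L, 1L)
  eps <- 1e-9 * max(apply(X, 2, function(col) mean((col - mean(col))^2)), 0)
  eps <- max(eps, .Machine$double.xmin)
  stats_by <- lapply(classes, function(cl) {
    Xi <- X[y01 == cl, , drop = FALSE]
    list(mean = colMeans(Xi),
         var = apply(Xi, 2, function(col) mean((col - mean(col))^2)) + eps,
         prior = nrow(Xi) / nrow(X))
  })
  structure(list(classes = classes, stats = stats_by, eps = eps,
                 n_features = ncol(X)),
            class = "gaussian_nb")
}

# Posterior probability of the positive class (MSI) per row.
predict_gaussian_nb <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) stop_pathomsi("feature layout mismatch")
  loglik <- vapply(model$stats, function(st) {
    rowSums(sweep(-0.5 * sweep(X, 2, st$mean)^2, 2, st$var, "/") -
              matrix(0.5 * log(2 * pi * st$var), nrow(X), ncol(X), byrow = TRUE)) +
      log(st$prior)
  }, numeric(nrow(X)))
  loglik <- matrix(loglik, ncol = 2)
  m <- pmax(loglik[, 1], loglik[, 2])
  p <- exp(loglik[, 2] - m) / (exp(loglik[, 1] - m) + exp(loglik[, 2] - m))
  p
}
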