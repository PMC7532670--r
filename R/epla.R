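# WSI-level aggregation: PALHI (gradient-boosted trees on the likelihood
# histogram), BoW (Gaussian naive Bayes on the TF-IDF vector), their convex
# ensemble (EPLA), and the majority-voting baseline.

# Stratified fold assignment, deterministic per seed.
make_folds <- function(y01, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y01))
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

default_palhi_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), nrounds = c(50L, 100L, 200L),
              eta = c(0.05, 0.1, 0.3), KEEP.OUT.ATTRS = FALSE)
}

xgb_fit <- function(X, y01, max_depth, eta, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y01, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1, seed = seed),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_score <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
}

#' Fit the PALHI classifier (gradient-boosted trees)
#'
#' Trains an xgboost classifier on the 100-bin likelihood histograms.
#' Hyperparameters (tree depth 2/3/4, 50/100/200 trees, learning rate
#' 0.05/0.1/0.3) are chosen by stratified cross-validation maximising mean
#' out-of-fold AUC; pass `fixed_params` to skip the grid search (e.g. when
#' refitting during transfer with hyperparameters chosen on the source
#' cohort).
#'
#' @param X Histogram matrix (slides x bins).
#' @param labels Slide labels (`"MSI"`/`"MSS"` or 1/0).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed RNG seed for folds and boosting.
#' @param folds Optional externally supplied fold assignment.
#' @param fixed_params Optional list `max_depth`, `nrounds`, `eta`.
#' @return A `palhi_fit` with the booster, the chosen grid point, the CV
#'   table and the out-of-fold scores.
#' @export
fit_palhi <- function(X, labels, cv_folds = 5L, seed = 1L, folds = NULL,
                      fixed_params = NULL) {
  y <- as_label01(labels)
  check_both_classes(y)
  if (cv_folds < 2) stop_pathomsi("cv_folds must be >= 2")
  X <- as.matrix(X)
  folds <- folds %||% make_folds(y, cv_folds, seed)
  grid <- if (is.null(fixed_params)) default_palhi_grid() else
    as.data.frame(fixed_params[c("max_depth", "nrounds", "eta")])
  oof_by_point <- matrix(NA_real_, nrow(X), nrow(grid))
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(0)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      bst <- xgb_fit(X[tr, , drop = FALSE], y[tr], grid$max_depth[g],
                     grid$eta[g], grid$nrounds[g], seed)
      oof_by_point[!tr, g] <- xgb_score(bst, X[!tr, , drop = FALSE])
      aucs <- c(aucs, roc_auc(oof_by_point[!tr, g], y[!tr]))
    }
    cv_auc[g] <- mean(aucs)
  }
  best <- which.max(cv_auc)  # first maximum: deterministic tie-break
  booster <- xgb_fit(X, y, grid$max_depth[best], grid$eta[best],
                     grid$nrounds[best], seed)
  structure(list(booster = booster,
                 params = as.list(grid[best, ]),
                 cv_table = as_tibble(cbind(grid, cv_auc = cv_auc)),
                 oof_scores = oof_by_point[, best],
                 folds = folds, seed = seed),
            class = "palhi_fit")
}

#' @export
print.palhi_fit <- function(x, ...) {
  cat(sprintf("<palhi_fit> xgboost depth %d, %d trees, eta %.2f (CV AUC %.4f)\n",
              x$params$max_depth, x$params$nrounds, x$params$eta,
              max(x$cv_table$cv_auc)))
  invisible(x)
}

#' Fit the BoW classifier (Gaussian naive Bayes)
#'
#' Gaussian naive Bayes over the 100 TF-IDF features with variance smoothing
#' `1e-9 * max feature variance`; emits the class posterior for MSI.
#'
#' @param X TF-IDF matrix (slides x words).
#' @param labels Slide labels.
#' @return A `bow_fit`.
#' @export
fit_bow <- function(X, labels) {
  y <- as_label01(labels)
  check_both_classes(y)
  structure(list(nb = fit_gaussian_nb(X, y)), class = "bow_fit")
}

#' @export
print.bow_fit <- function(x, ...) {
  cat("<bow_fit> Gaussian naive Bayes on", x$nb$n_features, "TF-IDF features\n")
  invisible(x)
}

bow_oof_scores <- function(X, y01, folds) {
  X <- as.matrix(X)
  oof <- rep(NA_real_, nrow(X))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2) next
    nb <- fit_gaussian_nb(X[tr, , drop = FALSE], y01[tr])
    oof[!tr] <- predict_gaussian_nb(nb, X[!tr, , drop = FALSE])
  }
  oof
}

#' Optimal convex ensemble weight
#'
#' Scans `alpha` over `{0, grid_step, ..., 1}` and returns the weight
#' maximising the AUC of `alpha * palhi + (1 - alpha) * bow` on out-of-fold
#' training scores (never test data). Ties are broken toward 0.5 (then toward
#' the smaller alpha).
#'
#' @param palhi_scores,bow_scores Out-of-fold component scores (paired).
#' @param labels Slide labels.
#' @param grid_step Grid resolution (default 0.01).
#' @return The chosen `alpha` in `[0, 1]`.
#' @export
fit_ensemble_weight <- function(palhi_scores, bow_scores, labels,
                                grid_step = 0.01) {
  if (length(palhi_scores) != length(bow_scores)) {
    stop_pathomsi("palhi and bow score vectors must have equal length")
  }
  y <- as_label01(labels)
  ok <- !is.na(palhi_scores) & !is.na(bow_scores)
  alphas <- seq(0, 1, by = grid_step)
  aucs <- vapply(alphas, function(a) {
    roc_auc(a * palhi_scores[ok] + (1 - a) * bow_scores[ok], y[ok])
  }, numeric(1))
  best <- which(aucs >= max(aucs) - 1e-12)
  alphas[best[which.min(abs(alphas[best] - 0.5))]]
}

#' Train the full EPLA slide-level model
#'
#' Fits the vocabulary, builds the 200-feature signatures, tunes and fits
#' PALHI (xgboost, stratified CV) and BoW (Gaussian NB), chooses the convex
#' ensemble weight on out-of-fold scores, and sets the classification cutoff
#' at the Youden optimum of the out-of-fold ensemble scores. All randomness
#' is governed by `seed`.
#'
#' @param likelihood_table Patch-likelihood tibble (`slide_id`, `likelihood`)
#'   for the training slides.
#' @param records Labelled slide tibble covering those slides.
#' @param n_bins,n_words Signature layout (defaults 100 + 100).
#' @param cv_folds Stratified CV folds (default 5).
#' @param seed RNG seed.
#' @param palhi_params Optional fixed xgboost hyperparameters (skips the grid).
#' @return An `epla_fit`; see [predict.epla_fit()].
#' @export
epla_train <- function(likelihood_table, records, n_bins = 100L,
                       n_words = 100L, cv_folds = 5L, seed = 1L,
                       palhi_params = NULL) {
  lab <- setNames(records$ms_label, records$slide_id)
  bags <- as_bags(likelihood_table)
  if (any(!names(bags) %in% names(lab))) {
    stop_pathomsi("likelihood table contains slides missing from the records")
  }
  vocab <- fit_bow_vocabulary(likelihood_table, n_words)
  signatures <- build_signatures(likelihood_table, vocab, n_bins)
  y <- as_label01(lab[signatures$slide_id])
  check_both_classes(y)
  M <- signature_matrix(signatures)
  Xp <- M[, seq_len(n_bins), drop = FALSE]
  Xb <- M[, n_bins + seq_len(n_words), drop = FALSE]
  folds <- make_folds(y, cv_folds, seed)
  palhi <- fit_palhi(Xp, y, cv_folds, seed, folds = folds,
                     fixed_params = palhi_params)
  bow <- fit_bow(Xb, y)
  bow_oof <- bow_oof_scores(Xb, y, folds)
  alpha <- fit_ensemble_weight(palhi$oof_scores, bow_oof, y)
  ok <- !is.na(palhi$oof_scores) & !is.na(bow_oof)
  ens_oof <- alpha * palhi$oof_scores[ok] + (1 - alpha) * bow_oof[ok]
  cutoff <- youden_cutoff(ens_oof, y[ok])$cutoff
  structure(list(vocab = vocab, palhi = palhi, bow = bow, alpha = alpha,
                 cutoff = cutoff, n_bins = as.integer(n_bins),
                 n_words = as.integer(n_words), seed = as.integer(seed),
                 oof = tibble(slide_id = signatures$slide_id,
                              palhi_oof = palhi$oof_scores,
                              bow_oof = bow_oof, label = label_chr(y))),
            class = "epla_fit")
}

#' @export
print.epla_fit <- function(x, ...) {
  cat(sprintf("<epla_fit> alpha %.2f (PALHI) / %.2f (BoW), cutoff %.4f, %d+%d features\n",
              x$alpha, 1 - x$alpha, x$cutoff, x$n_bins, x$n_words))
  invisible(x)
}

#' @export
glance.epla_fit <- function(x, ...) {
  ok <- !is.na(x$oof$palhi_oof) & !is.na(x$oof$bow_oof)
  ens <- x$alpha * x$oof$palhi_oof[ok] + (1 - x$alpha) * x$oof$bow_oof[ok]
  tibble(alpha = x$alpha, cutoff = x$cutoff,
         cv_auc_palhi = max(x$palhi$cv_table$cv_auc),
         oof_auc_ensemble = roc_auc(ens, x$oof$label[ok]),
         n_slides = nrow(x$oof))
}

#' @export
tidy.epla_fit <- function(x, ...) x$palhi$cv_table

#' Score slides from a signature matrix
#'
#' Lower-level entry used by permutation importance: takes an already-built
#' signature tibble/matrix in the fitted layout and returns component and
#' ensemble scores.
#'
#' @param fit An `epla_fit`.
#' @param signatures Signature tibble (with `slide_id`) or bare matrix.
#' @return A tibble `slide_id`, `palhi_score`, `bow_score`, `ensemble_score`,
#'   `predicted_label`.
#' @export
predict_signatures <- function(fit, signatures) {
  if (is.data.frame(signatures)) {
    ids <- if ("slide_id" %in% names(signatures)) signatures$slide_id
           else as.character(seq_len(nrow(signatures)))
    M <- signature_matrix(signatures)
  } else {
    M <- as.matrix(signatures)
    ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  }
  if (ncol(M) != fit$n_bins + fit$n_words) {
    stop_pathomsi("signature layout mismatch with the fitted model")
  }
  p <- xgb_score(fit$palhi$booster, M[, seq_len(fit$n_bins), drop = FALSE])
  b <- predict_gaussian_nb(fit$bow$nb, M[, fit$n_bins + seq_len(fit$n_words), drop = FALSE])
  e <- fit$alpha * p + (1 - fit$alpha) * b
  tibble(slide_id = ids, palhi_score = p, bow_score = b, ensemble_score = e,
         predicted_label = label_chr(as.integer(e >= fit$cutoff)))
}

#' Predict MS status for slides from their patch likelihoods
#'
#' Builds the PALHI and BoW blocks with the fitted vocabulary, scores both
#' classifiers and combines them as
#' `ensemble = alpha * palhi + (1 - alpha) * bow`; a slide is called MSI when
#' the ensemble score is at or above the fitted cutoff. Invariant to patch
#' order within a bag.
#'
#' @param object An `epla_fit`.
#' @param likelihood_table Patch-likelihood tibble (`slide_id`, `likelihood`).
#' @param ... Unused.
#' @return A tibble as in [predict_signatures()].
#' @export
predict.epla_fit <- function(object, likelihood_table, ...) {
  signatures <- build_signatures(likelihood_table, object$vocab, object$n_bins)
  predict_signatures(object, signatures)
}

#' Predict one slide from its likelihood bag
#'
#' @param fit An `epla_fit`.
#' @param bag Numeric vector of patch likelihoods for one slide.
#' @param slide_id Identifier for the output row.
#' @return One-row prediction tibble.
#' @export
predict_wsi <- function(fit, bag, slide_id = "slide") {
  if (length(bag) == 0) stop_pathomsi("empty likelihood bag")
  predict(fit, tibble(slide_id = slide_id, likelihood = bag))
}

#' Majority-voting baseline
#'
#' The deep-learning majority-vote reference scheme: each patch votes MSI
#' when its likelihood is at or above `patch_threshold`; the slide is called
#' MSI when strictly more than half the patches vote MSI. The vote fraction
#' serves as the continuous ROC score.
#'
#' @param likelihood_table Patch-likelihood tibble (`slide_id`, `likelihood`).
#' @param patch_threshold Patch-level vote threshold (default 0.5).
#' @return A tibble `slide_id`, `vote_fraction`, `predicted_label`.
#' @export
majority_vote <- function(likelihood_table, patch_threshold = 0.5) {
  bags <- as_bags(likelihood_table)
  if (any(vapply(bags, length, integer(1)) == 0)) stop_pathomsi("empty likelihood bag")
  vf <- vapply(bags, function(b) mean(b >= patch_threshold), numeric(1))
  tibble(slide_id = names(bags), vote_fraction = unname(vf),
         predicted_label = label_chr(as.integer(vf > 0.5)))
}

#' Save / load an EPLA model artifact
#'
#' Directory layout: `palhi.xgb.json` (booster), `bow.json` (NB moments),
#' `meta.json` (layout, IDF vector, alpha, cutoff, chosen hyperparameters).
#'
#' @param fit An `epla_fit`.
#' @param dir Artifact directory.
#' @return `dir` / the restored `epla_fit`.
#' @export
save_epla <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(fit$palhi$booster, file.path(dir, "palhi.xgb.json"))
  nb <- fit$bow$nb
  jsonlite::write_json(list(eps = nb$eps, n_features = nb$n_features,
                            mean0 = nb$stats[[1]]$mean, var0 = nb$stats[[1]]$var,
                            prior0 = nb$stats[[1]]$prior,
                            mean1 = nb$stats[[2]]$mean, var1 = nb$stats[[2]]$var,
                            prior1 = nb$stats[[2]]$prior),
                       file.path(dir, "bow.json"), digits = NA)
  jsonlite::write_json(list(alpha = fit$alpha, cutoff = fit$cutoff,
                            n_bins = fit$n_bins, n_words = fit$n_words,
                            seed = fit$seed, idf = fit$vocab$idf,
                            n_slides_fit = fit$vocab$n_slides_fit,
                            palhi_params = fit$palhi$params),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_epla
#' @export
load_epla <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nbj <- jsonlite::read_json(file.path(dir, "bow.json"), simplifyVector = TRUE)
  nb <- structure(list(classes = c(0L, 1L),
                       stats = list(list(mean = nbj$mean0, var = nbj$var0,
                                         prior = nbj$prior0),
                                    list(mean = nbj$mean1, var = nbj$var1,
                                         prior = nbj$prior1)),
                       eps = nbj$eps, n_features = nbj$n_features),
                  class = "gaussian_nb")
  vocab <- structure(list(idf = meta$idf, n_words = meta$n_words,
                          n_slides_fit = meta$n_slides_fit),
                     class = "bow_vocabulary")
  structure(list(vocab = vocab,
                 palhi = structure(list(booster = xgboost::xgb.load(file.path(dir, "palhi.xgb.json")),
                                        params = as.list(meta$palhi_params),
                                        cv_table = tibble(), oof_scores = NULL),
                                   class = "palhi_fit"),
                 bow = structure(list(nb = nb), class = "bow_fit"),
                 alpha = meta$alpha, cutoff = meta$cutoff,
                 n_bins = meta$n_bins, n_words = meta$n_words,
                 seed = meta$seed, oof = tibble()),
            class = "epla_fit")
}
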