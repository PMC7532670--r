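# Signature importance and group testing.

#' Permutation importance of the pathological signatures
#'
#' The contribution weight of each signature to the slide-level prediction:
#' importance of feature k = mean decrease in ensemble AUC when column k of
#' the signature matrix is randomly shuffled (`n_repeats` shuffles, negatives
#' clipped to 0). Deterministic per seed. Native xgboost gain importance for
#' the PALHI block is available via `native = TRUE` for comparison.
#'
#' @param fit An `epla_fit`.
#' @param signatures Signature tibble in the fitted layout.
#' @param labels Slide labels aligned with `signatures`.
#' @param n_repeats Shuffles per feature (default 5).
#' @param seed RNG seed.
#' @param native Also attach the tree-gain importances (attribute
#'   `"native_gain"`).
#' @return A tibble `feature`, `importance`, `rank` (rank 1 = most
#'   important; importance non-increasing with rank).
#' @export
permutation_importance <- function(fit, signatures, labels, n_repeats = 5L,
                                   seed = 1L, native = FALSE) {
  M <- signature_matrix(signatures)
  if (ncol(M) != fit$n_bins + fit$n_words) {
    stop_pathomsi("signature layout mismatch with the fitted model")
  }
  y <- as_label01(labels)
  base_auc <- roc_auc(predict_signatures(fit, M)$ensemble_score, y)
  imp <- with_seed(seed, {
    vapply(seq_len(ncol(M)), function(k) {
      if (length(unique(M[, k])) == 1) return(0)  # constants cannot matter
      drops <- vapply(seq_len(n_repeats), function(r) {
        Mk <- M
        Mk[, k] <- sample(Mk[, k])
        base_auc - roc_auc(predict_signatures(fit, Mk)$ensemble_score, y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  imp <- pmax(imp, 0)
  out <- tibble(feature = colnames(M), importance = imp)
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  if (native) {
    gain <- xgboost::xgb.importance(model = fit$palhi$booster)
    attr(out, "native_gain") <- as_tibble(gain)
  }
  out
}

#' Plot an importance ranking
#'
#' @param ranking Tibble from [permutation_importance()].
#' @param top_n How many signatures to show (default 10).
#' @return A ggplot object.
#' @export
plot_importance <- function(ranking, top_n = 10L) {
  sub <- head(dplyr::arrange(ranking, .data$rank), top_n)
  ggplot2::ggplot(sub, ggplot2::aes(x = stats::reorder(.data$feature, -.data$rank),
                                    y = .data$importance)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean AUC decrease under permutation") +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midrank ties: exact enumeration for small
#' tie-free samples, otherwise the normal approximation with tie and
#' continuity correction (the policy of [stats::wilcox.test()], which this
#' wraps).
#'
#' @param x,y Non-empty numeric samples.
#' @return A list `W`, `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_pathomsi("empty sample")
  res <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(W = unname(res$statistic), p = res$p.value)
}

#' Per-signature group difference tests
#'
#' Wilcoxon rank-sum test of each listed signature between MSI and MSS
#' slides, with Benjamini-Hochberg adjustment.
#'
#' @param signatures Signature tibble.
#' @param labels Slide labels aligned with `signatures`.
#' @param features Signature names to test (default: all `FEA#` columns).
#' @return A tibble `feature`, `W`, `p`, `adjusted_p`, sorted by `p`.
#' @export
signature_group_tests <- function(signatures, labels,
                                  features = grep("^FEA#", names(signatures),
                                                  value = TRUE)) {
  y <- as_label01(labels)
  res <- lapply(features, function(f) {
    v <- signatures[[f]]
    w <- wilcoxon_rank_sum(v[y == 1], v[y == 0])
    tibble(feature = f, W = w$W, p = w$p)
  })
  out <- dplyr::bind_rows(res)
  out$adjusted_p <- p.adjust(out$p, method = "BH")
  dplyr::arrange(out, .data$p)
}
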