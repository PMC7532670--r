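# ROC machinery: Mann-Whitney AUC, DeLong variance/covariance from placement
# values, the paired Wald AUC-difference test, and the Youden cutoff.

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the mean over all (positive, negative) pairs of
#' `[score_pos > score_neg] + 0.5 [score_pos == score_neg]`, computed via
#' midranks.
#'
#' @param scores Numeric slide scores (higher = more MSI-like).
#' @param labels Binary labels (`"MSI"`/`"MSS"` or 1/0, 1 = MSI).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)  # midranks handle ties as half-wins
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values: V10[i] = P(score_neg < pos_i) + 0.5 P(equal),
# V01[j] = P(score_pos > neg_j) + 0.5 P(equal). Means equal the AUC.
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  v10 <- vapply(pos, function(s) mean(neg < s) + 0.5 * mean(neg == s), numeric(1))
  v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_var <- function(pl) {
  svar <- function(v) if (length(v) > 1) sum((v - mean(v))^2) / (length(v) - 1) else 0
  svar(pl$v10) / length(pl$v10) + svar(pl$v01) / length(pl$v01)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation interval using the DeLong placement-value variance,
#' clipped to `[0, 1]`. Degenerate zero variance (perfect separation) returns
#' `(auc, auc)` with a warning. A percentile bootstrap is available as a
#' cross-check.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return `c(low, high)`.
#' @export
delong_ci <- function(scores, labels, level = 0.95,
                      method = c("delong", "bootstrap"),
                      n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop_pathomsi("DeLong CI needs >= 2 slides per class")
  }
  if (method == "bootstrap") {
    return(with_seed(seed, {
      reps <- replicate(n_boot, {
        i <- c(sample(which(y == 1), replace = TRUE),
               sample(which(y == 0), replace = TRUE))
        roc_auc(scores[i], y[i])
      })
      unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
    }))
  }
  pl <- delong_placements(scores, y)
  v <- delong_var(pl)
  if (v <= 0) {
    rlang::warn("zero DeLong variance (perfect separation); returning a point interval")
    return(c(pl$auc, pl$auc))
  }
  z <- qnorm(1 - (1 - level) / 2)
  c(max(0, pl$auc - z * sqrt(v)), min(1, pl$auc + z * sqrt(v)))
}

#' Paired Wald test for an AUC difference
#'
#' Tests `AUC_a = AUC_b` for two score vectors on the same slides using the
#' DeLong paired covariance:
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)`, two-sided normal p.
#'
#' @param scores_a,scores_b Paired score vectors (same slides, same order).
#' @inheritParams roc_auc
#' @return A list `z`, `p`, `auc_a`, `auc_b`.
#' @export
wald_auc_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop_pathomsi("scores_a and scores_b must be paired (equal length)")
  }
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  scov <- function(u, v) if (length(u) > 1) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1) else 0
  cv <- scov(pa$v10, pb$v10) / length(pa$v10) + scov(pa$v01, pb$v01) / length(pa$v01)
  denom2 <- delong_var(pa) + delong_var(pb) - 2 * cv
  d <- pa$auc - pb$auc
  if (denom2 <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(denom2)
  }
  list(z = z, p = 2 * pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc)
}

#' Youden-index optimal cutoff
#'
#' Scans all midpoints between adjacent distinct scores (plus infinities) and
#' returns the cutoff maximising `sensitivity + specificity - 1`; ties go to
#' the smallest cutoff. A score at the cutoff is called positive
#' (`score >= cutoff` = MSI call).
#'
#' @inheritParams roc_auc
#' @return A list `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  best <- list(cutoff = -Inf, sensitivity = 1, specificity = 0, youden = 0)
  best_j <- -Inf
  for (c0 in cand) {
    sens <- mean(pos >= c0); spec <- mean(neg < c0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best <- list(cutoff = c0, sensitivity = sens, specificity = spec, youden = j)
    }
  }
  best
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble `threshold`, `fpr`, `tpr` (thresholds descending).
#' @export
roc_curve_points <- function(scores, labels) {
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tibble(threshold = thr,
         fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
         tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
}

#' Evaluate slide scores against labels
#'
#' Bundles AUC, the DeLong 95% interval, the Youden cutoff and the
#' sensitivity/specificity at that cutoff into a `roc_result`.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return A `roc_result` list; see [tidy.roc_result()] and
#'   [autoplot.roc_result()].
#' @export
evaluate_scores <- function(scores, labels, level = 0.95) {
  y <- as_label01(labels)
  check_both_classes(y, "label vector")
  ci <- withCallingHandlers(
    delong_ci(scores, y, level = level),
    warning = function(w) invokeRestart("muffleWarning")
  )
  yc <- youden_cutoff(scores, y)
  structure(list(auc = roc_auc(scores, y), ci_low = ci[1], ci_high = ci[2],
                 level = level, cutoff = yc$cutoff,
                 sensitivity = yc$sensitivity, specificity = yc$specificity,
                 n_pos = sum(y == 1), n_neg = sum(y == 0),
                 curve = roc_curve_points(scores, y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d%% CI %.4f-%.4f), cutoff %.4g, sens %.3f, spec %.3f (n+=%d, n-=%d)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high, x$cutoff,
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy a `roc_result`
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return `tidy()` returns the ROC curve points; `glance()` a one-row
#'   summary (auc, ci, cutoff, sensitivity, specificity, class sizes).
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         cutoff = x$cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f)", object$auc,
                                  100 * object$level, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as JSON
#'
#' @param result A `roc_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  jsonlite::write_json(list(auc = result$auc,
                            ci = c(result$ci_low, result$ci_high),
                            cutoff = result$cutoff,
                            sensitivity = result$sensitivity,
                            specificity = result$specificity,
                            n_pos = result$n_pos, n_neg = result$n_neg),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
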