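#' Area under the ROC curve separating difference from null replicates
#'
#' Treats difference-regime replicates as positives, ranked by ascending
#' p-value, and computes the AUC through the rank (Mann-Whitney)
#' formulation: the probability that a random difference replicate has a
#' smaller p-value than a random null replicate, with ties counted one
#' half. Identical to integrating the empirical ROC curve.
#'
#' @param null_p,diff_p Non-empty numeric p-value vectors from the null and
#'   difference simulations.
#' @return The AUC, a number in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(null_p = c(0.6, 0.7), diff_p = c(0.01, 0.02))
roc_auc <- function(null_p, diff_p) {
  if (length(null_p) == 0 || length(diff_p) == 0) {
    stop("both p-value vectors must be non-empty", call. = FALSE)
  }
  stopifnot(!anyNA(null_p), !anyNA(diff_p))
  n0 <- length(null_p)
  n1 <- length(diff_p)
  r <- rank(c(null_p, diff_p))
  # pairs with p_null > p_diff (ties half-weighted)
  u <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2
  u / (n0 * n1)
}

#' Rejection rate at a significance threshold
#'
#' The proportion of p-values strictly below `alpha`, with its exact
#' (Clopper-Pearson) binomial 95% confidence interval. Applied to null
#' replicates this is the false positive rate; to difference replicates,
#' the true positive rate.
#'
#' @param p Non-empty numeric vector of p-values.
#' @param alpha Threshold in (0, 1).
#' @return One-row tibble: `rate`, `lower`, `upper`, `n_rejected`, `n`.
#' @export
rejection_rate <- function(p, alpha = 0.05) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, !anyNA(p))
  k <- sum(p < alpha)
  ci <- stats::binom.test(k, length(p))$conf.int
  tibble::tibble(rate = k / length(p), lower = ci[1], upper = ci[2],
                 n_rejected = k, n = length(p))
}

#' Summarize a simulation benchmark
#'
#' One row per weighting mode: AUC of the null-vs-difference
#' discrimination, and false / true positive rates at `alpha` with exact
#' binomial intervals.
#'
#' @param bench A `benchmark_result` from [run_benchmark()].
#' @param alpha Significance threshold for the rejection rates.
#' @return A tibble with columns `mode`, `auc`, `fpr`, `fpr_lower`,
#'   `fpr_upper`, `tpr`, `tpr_lower`, `tpr_upper`, `n_null`, `n_diff`,
#'   `failures`.
#' @export
summarize_benchmark <- function(bench, alpha = 0.05) {
  stopifnot(inherits(bench, "benchmark_result"))
  p <- bench$p_values
  purrr::map_dfr(unique(p$mode), function(m) {
    null_p <- p$p[p$regime == "null" & p$mode == m]
    diff_p <- p$p[p$regime == "difference" & p$mode == m]
    fp <- rejection_rate(null_p, alpha)
    tp <- rejection_rate(diff_p, alpha)
    tibble::tibble(mode = m, auc = roc_auc(null_p, diff_p),
                   fpr = fp$rate, fpr_lower = fp$lower,
                   fpr_upper = fp$upper, tpr = tp$rate,
                   tpr_lower = tp$lower, tpr_upper = tp$upper,
                   n_null = length(null_p), n_diff = length(diff_p),
                   failures = length(bench$failures))
  })
}

roc_points <- function(null_p, diff_p) {
  thr <- sort(unique(c(0, null_p, diff_p, 1)))
  tibble::tibble(
    fpr = vapply(thr, function(a) mean(null_p <= a), numeric(1)),
    tpr = vapply(thr, function(a) mean(diff_p <= a), numeric(1))
  )
}

#' Plot the benchmark ROC curves
#'
#' ROC curves of the null-vs-difference discrimination, one per weighting
#' mode, annotated with the AUC.
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  p <- object$p_values
  curves <- purrr::map_dfr(unique(p$mode), function(m) {
    pts <- roc_points(p$p[p$regime == "null" & p$mode == m],
                      p$p[p$regime == "difference" & p$mode == m])
    pts$mode <- sprintf(
      "%s (AUC = %.3f)", m,
      roc_auc(p$p[p$regime == "null" & p$mode == m],
              p$p[p$regime == "difference" & p$mode == m]))
    pts
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$mode)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Bar plot of rejection rates at a threshold
#'
#' False and true positive rates per weighting mode at `alpha`, with exact
#' binomial intervals.
#'
#' @param bench A `benchmark_result`.
#' @param alpha Significance threshold.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(bench, alpha = 0.05) {
  s <- summarize_benchmark(bench, alpha = alpha)
  df <- dplyr::bind_rows(
    tibble::tibble(mode = s$mode, which = "false positives (null)",
                   rate = s$fpr, lower = s$fpr_lower, upper = s$fpr_upper),
    tibble::tibble(mode = s$mode, which = "true positives (difference)",
                   rate = s$tpr, lower = s$tpr_lower, upper = s$tpr_upper)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$which, y = .data$rate,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = sprintf("rejection rate at p < %.2f", alpha),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
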