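# Monotone non-increasing piecewise-linear basis on x with the given knots:
# column k is the negative saturating ramp -min(max(x - t_k, 0), t_{k+1}-t_k),
# so any non-negative coefficient vector yields a non-increasing function
# that extrapolates flat beyond the knot range.
mono_decreasing_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 2) return(matrix(0, nrow = length(x), ncol = 0))
  B <- vapply(seq_len(k - 1), function(s) {
    -pmin(pmax(x - knots[s], 0), knots[s + 1] - knots[s])
  }, numeric(length(x)))
  matrix(B, nrow = length(x))
}

pick_knots <- function(x, n_knots) {
  ks <- unique(quantile(x, probs = seq(0, 1, length.out = n_knots),
                        names = FALSE, type = 7))
  if (length(ks) < 2) ks <- c(ks[1] - 1e-8, ks[1] + 1e-8)
  ks
}

# Constrained least squares for log(u^2 + delta) on the additive monotone
# basis. Fitting on the log scale keeps predictions strictly positive and
# stops the heavy right tail of the chi-squared-like u^2 response from
# dominating the fit (errors are roughly symmetric in log variance). The
# non-negative intercept constraint is made harmless by shifting the
# response to be non-negative and shifting back. Rank-deficient bases
# (heavily tied counts) retry with fewer knots.
fit_mono_surface <- function(log_ni, log_nj, y_raw, n_knots) {
  delta <- 1e-6 * mean(y_raw)
  if (delta <= 0) {
    # all scores exactly zero: constant (floored) surface
    return(list(knots_i = range(log_ni), knots_j = range(log_nj),
                log_intercept = log(.Machine$double.xmin),
                beta_i = 0, beta_j = 0, resnorm = 0))
  }
  y <- log(y_raw + delta)
  shift <- min(y)
  while (n_knots >= 2) {
    k1 <- pick_knots(log_ni, n_knots)
    k2 <- pick_knots(log_nj, n_knots)
    B1 <- mono_decreasing_basis(log_ni, k1)
    B2 <- mono_decreasing_basis(log_nj, k2)
    A <- cbind(1, B1, B2)
    sol <- tryCatch(pracma::lsqnonneg(A, y - shift),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      coefs <- sol$x
      fit <- list(knots_i = k1, knots_j = k2,
                  log_intercept = coefs[1] + shift,
                  beta_i = coefs[1 + seq_len(ncol(B1))],
                  beta_j = coefs[1 + ncol(B1) + seq_len(ncol(B2))],
                  resnorm = sol$resnorm)
      # moment-match back to the raw scale: the log-scale fit estimates
      # exp(E[log u^2]), which understates E[u^2] by a roughly constant
      # factor for a heavy-tailed response; a global rescale fixes the
      # level without touching shape or monotonicity (and cancels in the
      # normalized weights)
      fitted_raw <- eval_mono_surface(fit, log_ni, log_nj)
      fit$log_intercept <- fit$log_intercept +
        log(mean(y_raw) / mean(fitted_raw))
      return(fit)
    }
    n_knots <- n_knots %/% 2
  }
  # constant surface: monotone fits admit constants
  list(knots_i = range(log_ni), knots_j = range(log_nj),
       log_intercept = mean(y), beta_i = 0, beta_j = 0,
       resnorm = sum((y - mean(y))^2))
}

eval_mono_surface <- function(fit, log_ni, log_nj) {
  B1 <- mono_decreasing_basis(log_ni, fit$knots_i)
  B2 <- mono_decreasing_basis(log_nj, fit$knots_j)
  exp(as.numeric(fit$log_intercept +
                   (if (ncol(B1)) B1 %*% fit$beta_i else 0) +
                   (if (ncol(B2)) B2 %*% fit$beta_j else 0)))
}

#' Fit the count-dependent variance surface of co-localization scores
#'
#' The spread of the score u shrinks as the pairwise cell counts grow, so
#' u-squared is modelled as a smooth surface of the two counts under a
#' monotone non-increasing constraint in each count. The fit is a
#' constrained least-squares regression of \eqn{\log u^2} on an additive
#' basis of decreasing saturating ramps over \eqn{\log n_i} and
#' \eqn{\log n_j} with non-negative coefficients, exponentiated back to
#' the variance scale: the surface is piecewise-log-linear, strictly
#' positive, non-increasing in each count, and extrapolates flat beyond
#' the observed count range. Fitting on the log scale keeps the
#' heavy-tailed squared scores from letting the high-count corner of the
#' surface collapse towards zero, which would blow up the weights there.
#' The reciprocal of the fitted surface supplies observation weights for
#' inference ([compute_weights()]).
#'
#' @param scores Score table from [score_pairs()] (columns `type_i`,
#'   `type_j`, `u`, `n_i`, `n_j`; rows with `NA` u are ignored).
#' @param pooling `"all_pairs"` (default) fits one surface to the scores of
#'   all cell-type pairs concurrently — the recommended choice, since the
#'   count-variance relationship is shared and per-pair data is often
#'   scarce; `"per_pair"` fits one surface per ordered pair.
#' @param n_knots Knots per count axis for the piecewise-linear basis.
#' @param min_scores Minimum number of defined scores required per fit.
#' @return A `coloc_varmodel`: predictions via [predict()][predict.coloc_varmodel],
#'   probe-grid summary via [tidy()], weights via [compute_weights()].
#' @export
fit_variance_surface <- function(scores, pooling = c("all_pairs", "per_pair"),
                                 n_knots = 8, min_scores = 20) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("type_i", "type_j", "u", "n_i", "n_j") %in% names(scores)))
  ok <- !is.na(scores$u) & scores$n_i >= 1 & scores$n_j >= 1
  dat <- scores[ok, ]
  fit_one <- function(d, label) {
    if (nrow(d) < min_scores) {
      stop("only ", nrow(d), " defined scores for ", label,
           " (need >= ", min_scores, "); pool with pooling = \"all_pairs\" ",
           "or run an unweighted analysis", call. = FALSE)
    }
    y <- d$u^2
    if (sd(y) == 0) {
      warning("all squared scores identical for ", label,
              "; variance surface is constant", call. = FALSE)
    }
    fit <- fit_mono_surface(log(d$n_i), log(d$n_j), y, n_knots)
    fitted_vals <- eval_mono_surface(fit, log(d$n_i), log(d$n_j))
    fit$floor <- max(1e-3 * median(fitted_vals), 1e-10)
    fit$count_range <- list(n_i = range(d$n_i), n_j = range(d$n_j))
    fit
  }
  fits <- if (pooling == "all_pairs") {
    list(all_pairs = fit_one(dat, "the pooled score table"))
  } else {
    keys <- split(dat, paste(dat$type_i, dat$type_j, sep = "->"))
    purrr::imap(keys, fit_one)
  }
  structure(
    list(fits = fits, pooling = pooling, n_knots = n_knots,
         n_used = nrow(dat), n_dropped = sum(!ok)),
    class = "coloc_varmodel"
  )
}

#' Predict the variance proxy (fitted u-squared) at given counts
#'
#' @param object A `coloc_varmodel` from [fit_variance_surface()].
#' @param newdata Data frame with columns `n_i` and `n_j` (and `type_i`,
#'   `type_j` for a per-pair model).
#' @param ... Unused.
#' @return Numeric vector of fitted \eqn{u^2} values, floored at the
#'   model's positive lower bound so downstream weights stay finite.
#' @export
predict.coloc_varmodel <- function(object, newdata, ...) {
  stopifnot(all(c("n_i", "n_j") %in% names(newdata)))
  if (any(newdata$n_i < 1 | newdata$n_j < 1, na.rm = TRUE)) {
    stop("counts must be >= 1 for prediction", call. = FALSE)
  }
  if (object$pooling == "all_pairs") {
    fit <- object$fits[[1]]
    pred <- eval_mono_surface(fit, log(newdata$n_i), log(newdata$n_j))
    return(pmax(pred, fit$floor))
  }
  key <- paste(newdata$type_i, newdata$type_j, sep = "->")
  pred <- rep(NA_real_, nrow(newdata))
  for (k in unique(key)) {
    fit <- object$fits[[k]]
    if (is.null(fit)) stop("no per-pair variance fit for ", k, call. = FALSE)
    idx <- key == k
    pred[idx] <- pmax(
      eval_mono_surface(fit, log(newdata$n_i[idx]), log(newdata$n_j[idx])),
      fit$floor
    )
  }
  pred
}

#' @export
print.coloc_varmodel <- function(x, ...) {
  cat("<coloc_varmodel> pooling = ", x$pooling, ", fitted on ", x$n_used,
      " scores (", x$n_dropped, " undefined dropped)\n", sep = "")
  invisible(x)
}

#' @rdname fit_variance_surface
#' @param x A `coloc_varmodel`.
#' @param probe_n Number of probe counts per axis for the tidy grid.
#' @param ... Unused.
#' @method tidy coloc_varmodel
#' @export
tidy.coloc_varmodel <- function(x, probe_n = 25, ...) {
  grids <- purrr::imap(x$fits, function(fit, key) {
    ni <- round(exp(seq(log(fit$count_range$n_i[1]),
                        log(fit$count_range$n_i[2]), length.out = probe_n)))
    nj <- round(exp(seq(log(fit$count_range$n_j[1]),
                        log(fit$count_range$n_j[2]), length.out = probe_n)))
    g <- tidyr::expand_grid(n_i = unique(ni), n_j = unique(nj))
    g$fitted_u2 <- pmax(eval_mono_surface(fit, log(g$n_i), log(g$n_j)),
                        fit$floor)
    g$pair <- key
    g
  })
  dplyr::bind_rows(grids)
}

#' Plot the fitted variance surface
#'
#' Shows fitted u-squared against the count of type i, one line per
#' quantile slice of the type-j count — the package's analogue of a
#' variance-versus-count diagnostic plot.
#'
#' @param object A `coloc_varmodel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_varmodel
#' @export
autoplot.coloc_varmodel <- function(object, ...) {
  grid <- tidy(object)
  slice_vals <- quantile(unique(grid$n_j), c(0.05, 0.5, 0.95), names = FALSE)
  keep <- purrr::map_dbl(slice_vals, function(v) {
    u <- unique(grid$n_j); u[which.min(abs(u - v))]
  })
  grid <- grid[grid$n_j %in% keep, ]
  grid$n_j <- factor(grid$n_j)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_i, y = .data$fitted_u2,
                                     colour = .data$n_j)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "count of type i (log scale)",
                  y = expression("fitted " * u^2),
                  colour = "count of\ntype j") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::theme_minimal()
}

#' Convert a variance surface into per-row observation weights
#'
#' Each defined score row gets weight \eqn{1 / \max(\hat v(n_i, n_j),
#' \text{floor})}, so images with lower cell counts — noisier scores — are
#' down-weighted. Weights are normalized to mean 1 over defined rows (a
#' presentation choice; both downstream models are invariant to a global
#' weight rescale). Rows with an undefined score get weight 0.
#'
#' @param scores Score table from [score_pairs()].
#' @param model A `coloc_varmodel`, or `NULL` for uniform weights.
#' @return `scores` with an added `weight` column.
#' @export
compute_weights <- function(scores, model) {
  ok <- !is.na(scores$u)
  w <- numeric(nrow(scores))
  if (is.null(model)) {
    w[ok] <- 1
  } else {
    stopifnot(inherits(model, "coloc_varmodel"))
    pred <- predict(model, scores[ok, ])
    w_raw <- 1 / pred
    w[ok] <- w_raw / mean(w_raw)
  }
  out <- scores
  out$weight <- w
  out
}
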