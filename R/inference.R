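#' Test one cell-type pair's scores for a condition effect
#'
#' Fits the per-pair model for the co-localization score u: a weighted
#' linear model \eqn{u = \alpha + \beta x + \Gamma W + \varepsilon} or, when
#' subjects contribute multiple images, a random-intercept mixed-effects
#' model \eqn{u = \alpha_s + \beta x + \Gamma W + \varepsilon} with
#' \eqn{\alpha_s} a subject-level random effect. Weights act as precision
#' weights (a row's residual variance is \eqn{\sigma^2 / w}), so any global
#' rescaling of the weights leaves estimates, standard errors and p-values
#' unchanged. Mixed models are fitted by REML with lme4 and tested with
#' Satterthwaite degrees of freedom (lmerTest); linear models use the exact
#' t-test with residual degrees of freedom.
#'
#' @param data Data frame with one row per image: a score column `u`,
#'   the condition column, optional covariate and subject columns, and an
#'   optional `weight` column (default: equal weights). Rows with missing
#'   `u` or zero weight are dropped and counted.
#' @param condition Name of the tested variable (categorical with >= 2
#'   levels, or continuous). Categorical conditions are treatment-coded
#'   against `reference`; one result row is returned per non-reference
#'   level.
#' @param covariates Optional character vector of additional fixed-effect
#'   column names.
#' @param subject Name of the subject column (required for
#'   `model = "mixed"`).
#' @param model `"linear"` or `"mixed"`.
#' @param reference Reference level for a categorical condition (default:
#'   first level).
#' @return A tibble with one row per condition contrast: `term`, `beta`,
#'   `se`, `df`, `t`, `p_raw`, `n_used`, `n_dropped`, `model`, `boundary`
#'   (mixed fit on the zero-variance boundary), `subject_var`,
#'   `residual_var`. If fewer rows survive than fixed-effect columns plus
#'   two, the pair is untestable and a single `NA` row is returned.
#' @export
fit_score_model <- function(data, condition, covariates = NULL,
                            subject = NULL, model = c("linear", "mixed"),
                            reference = NULL) {
  model <- match.arg(model)
  stopifnot("u" %in% names(data), condition %in% names(data))
  if (!is.null(covariates)) stopifnot(all(covariates %in% names(data)))
  if (model == "mixed") {
    if (is.null(subject)) stop("`subject` is required for a mixed model",
                               call. = FALSE)
    stopifnot(subject %in% names(data))
  }
  d <- as.data.frame(data)
  if (!"weight" %in% names(d)) d$weight <- 1
  if (any(d$weight < 0, na.rm = TRUE)) stop("negative weights", call. = FALSE)

  cond <- d[[condition]]
  categorical <- is.character(cond) || is.factor(cond) || is.logical(cond)
  if (categorical) {
    cond <- factor(cond)
    if (!is.null(reference)) {
      if (!reference %in% levels(cond)) {
        stop("reference level ", dQuote(reference, FALSE),
             " not found in ", condition, call. = FALSE)
      }
      cond <- stats::relevel(cond, ref = reference)
    }
    d[[condition]] <- cond
  }

  keep <- !is.na(d$u) & !is.na(d$weight) & d$weight > 0 &
    !is.na(d[[condition]])
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (categorical) d[[condition]] <- droplevels(d[[condition]])

  n_fixed <- 1 +
    (if (categorical) max(nlevels(d[[condition]]) - 1, 1) else 1) +
    length(covariates)
  terms_expected <- if (categorical && nlevels(d[[condition]]) >= 2) {
    paste0(condition, levels(d[[condition]])[-1])
  } else {
    condition
  }
  na_row <- function() tibble::tibble(
    term = terms_expected, beta = NA_real_, se = NA_real_, df = NA_real_,
    t = NA_real_, p_raw = NA_real_, n_used = nrow(d), n_dropped = n_dropped,
    model = model, boundary = NA, subject_var = NA_real_,
    residual_var = NA_real_
  )
  if (nrow(d) < n_fixed + 2 ||
      (categorical && nlevels(d[[condition]]) < 2)) {
    return(na_row())
  }

  rhs <- paste(c(condition, covariates), collapse = " + ")
  if (model == "linear") {
    fit <- lm(as.formula(paste("u ~", rhs)), data = d, weights = weight)
    if (anyNA(coef(fit))) {
      stop("rank-deficient design; collinear term(s): ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
           call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    rows <- rownames(sm) %in% terms_expected
    out <- tibble::tibble(
      term = rownames(sm)[rows],
      beta = sm[rows, "Estimate"], se = sm[rows, "Std. Error"],
      df = fit$df.residual, t = sm[rows, "t value"],
      p_raw = sm[rows, "Pr(>|t|)"], n_used = nrow(d),
      n_dropped = n_dropped, model = "linear", boundary = NA,
      subject_var = NA_real_, residual_var = summary(fit)$sigma^2
    )
    return(out)
  }

  d$.subject <- factor(d[[subject]])
  if (categorical) {
    subjects_per_level <- colSums(table(d$.subject, d[[condition]]) > 0)
    if (any(subjects_per_level < 2)) {
      warning("fewer than 2 subjects in some condition level; ",
              "mixed-model inference may be unstable", call. = FALSE)
    }
  }
  form <- as.formula(paste("u ~", rhs, "+ (1 | .subject)"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, weights = weight, REML = TRUE,
                   control = ctrl),
    message = function(m) invokeRestart("muffleMessage")
  )
  sm <- summary(fit)$coefficients  # Satterthwaite df (lmerTest default)
  vc <- as.data.frame(lme4::VarCorr(fit))
  subj_var <- vc$vcov[vc$grp == ".subject"][1]
  resid_var <- vc$vcov[vc$grp == "Residual"][1]
  rows <- rownames(sm) %in% terms_expected
  tibble::tibble(
    term = rownames(sm)[rows],
    beta = sm[rows, "Estimate"], se = sm[rows, "Std. Error"],
    df = sm[rows, "df"], t = sm[rows, "t value"],
    p_raw = sm[rows, "Pr(>|t|)"], n_used = nrow(d), n_dropped = n_dropped,
    model = "mixed", boundary = lme4::isSingular(fit),
    subject_var = subj_var, residual_var = resid_var
  )
}

#' Test all cell-type pairs for differential co-localization
#'
#' The full pipeline: score every ordered cell-type pair in every image
#' ([score_pairs()]), optionally fit the count-dependent variance surface
#' and convert it into precision weights ([fit_variance_surface()],
#' [compute_weights()]), then test each pair's scores for a condition
#' effect with a weighted linear or random-intercept mixed-effects model
#' ([fit_score_model()]). The mixed model is selected automatically when a
#' subject column is given and any subject contributes more than one image.
#'
#' @param study A [cell_study()] whose image table carries the condition
#'   (and, for mixed models, subject) columns.
#' @param condition,covariates,subject,reference As in [fit_score_model()].
#'   `subject = "subject_id"` is used automatically when that column exists.
#' @param types Cell types to analyse (default: all observed).
#' @param radii,correction Scoring configuration, as in [kcross()].
#' @param weights `"fitted"` (count-based precision weights, the default)
#'   or `"none"`.
#' @param pooling Variance-surface pooling, see [fit_variance_surface()].
#' @param model `"auto"`, `"linear"` or `"mixed"`.
#' @param p_adjust Multiple-testing adjustment across pairs: `"none"`
#'   (default; raw p-values are reported either way) or `"BH"`.
#' @param scores Optional precomputed score table from [score_pairs()]
#'   (with matching `types`, `radii`, `correction`) to skip re-scoring.
#' @return A `coloc_results` object; `tidy()` returns the per-pair result
#'   table, `glance()` a one-row summary, `autoplot()` the signed
#'   significance heatmap, [signed_logp_matrix()] the matrix itself.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(n_subjects = 8,
#'                                  cell_counts = c(50, 100)),
#'                       regime = "difference", seed = 1)
#' res <- test_coloc(sim, condition = "condition", subject = "subject_id")
#' tidy(res)
#' }
test_coloc <- function(study, condition = "condition", subject = NULL,
                       covariates = NULL, types = NULL,
                       radii = default_radii(), correction = "translation",
                       weights = c("fitted", "none"),
                       pooling = "all_pairs",
                       model = c("auto", "linear", "mixed"),
                       reference = NULL, p_adjust = c("none", "BH"),
                       scores = NULL) {
  weights <- match.arg(weights)
  model <- match.arg(model)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(study, "cell_study"))
  if (!condition %in% names(study$images)) {
    stop("condition column ", dQuote(condition, FALSE),
         " not found in the image metadata", call. = FALSE)
  }
  if (is.null(subject) && "subject_id" %in% names(study$images) &&
      model != "linear") {
    subject <- "subject_id"
  }
  val <- validate_study(study, types = types)
  if (!val$ok) {
    stop("condition is not constant within subject(s): ",
         paste(val$inconsistent_subjects$subject_id, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(scores)) {
    scores <- score_pairs(study, types = types, radii = radii,
                          correction = correction)
  }

  varmodel <- NULL
  if (weights == "fitted") {
    varmodel <- fit_variance_surface(scores, pooling = pooling)
  }
  scored <- compute_weights(scores, varmodel)

  if (model == "auto") {
    multi <- !is.null(subject) &&
      anyDuplicated(study$images[[subject]]) > 0
    model <- if (multi) "mixed" else "linear"
  }
  if (model == "mixed" && is.null(subject)) {
    stop("mixed model requested but no `subject` column given", call. = FALSE)
  }

  meta_cols <- unique(c("image_id", condition, covariates, subject))
  meta <- study$images[, meta_cols]
  dat <- dplyr::left_join(scored, meta, by = "image_id")

  pair_tbl <- dplyr::distinct(scores[, c("type_i", "type_j")])
  results <- purrr::map(seq_len(nrow(pair_tbl)), function(k) {
    ti <- pair_tbl$type_i[k]; tj <- pair_tbl$type_j[k]
    sub <- dat[dat$type_i == ti & dat$type_j == tj, ]
    res <- tryCatch(
      fit_score_model(sub, condition = condition, covariates = covariates,
                      subject = subject, model = model,
                      reference = reference),
      error = function(e) {
        stop("pair ", ti, " -> ", tj, " (model stage): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    res$type_i <- ti
    res$type_j <- tj
    res
  })
  results <- dplyr::bind_rows(results)
  results$direction <- sign(results$beta)
  results <- results[, c("type_i", "type_j", "term", "beta", "se", "df",
                         "t", "p_raw", "n_used", "n_dropped", "model",
                         "boundary", "subject_var", "residual_var",
                         "direction")]
  out <- structure(
    list(results = results, scores = scored, varmodel = varmodel,
         config = list(condition = condition, subject = subject,
                       covariates = covariates, radii = radii,
                       correction = correction, weights = weights,
                       pooling = pooling, model = model,
                       reference = reference, p_adjust = p_adjust,
                       version = as.character(utils::packageVersion("coloctest")))),
    class = "coloc_results"
  )
  adjust_pvalues(out, method = p_adjust)
}

#' Adjust per-pair p-values across the tested pairs
#'
#' Applies the Benjamini-Hochberg step-up procedure across all tested
#' ordered pairs, separately for each condition contrast, or copies the raw
#' p-values when `method = "none"`.
#'
#' @param results A `coloc_results` object.
#' @param method `"none"` or `"BH"`.
#' @return The `coloc_results` with its `p_adjusted` column (re)computed.
#' @export
adjust_pvalues <- function(results, method = c("none", "BH")) {
  method <- match.arg(method)
  tbl <- results$results
  tbl$p_adjusted <- if (method == "none") {
    tbl$p_raw
  } else {
    stats::ave(tbl$p_raw, tbl$term,
               FUN = function(p) p.adjust(p, method = "BH"))
  }
  results$results <- tbl
  results$config$p_adjust <- method
  results
}

#' @export
print.coloc_results <- function(x, ...) {
  r <- x$results
  cat("<coloc_results> ", dplyr::n_distinct(paste(r$type_i, r$type_j)),
      " ordered pairs, model = ", x$config$model,
      ", weights = ", x$config$weights,
      ", correction = ", x$config$correction, "\n", sep = "")
  shown <- r[order(r$p_raw), c("type_i", "type_j", "term", "beta", "se",
                               "df", "p_raw", "p_adjusted")]
  print(tibble::as_tibble(shown), n = 10)
  invisible(x)
}

#' @rdname test_coloc
#' @param x,object A `coloc_results` object.
#' @param ... Unused.
#' @method tidy coloc_results
#' @export
tidy.coloc_results <- function(x, ...) tibble::as_tibble(x$results)

#' @rdname test_coloc
#' @method glance coloc_results
#' @export
glance.coloc_results <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_pairs = dplyr::n_distinct(paste(r$type_i, r$type_j)),
    n_tested = sum(!is.na(r$p_raw)),
    n_significant_raw = sum(r$p_raw < 0.05, na.rm = TRUE),
    model = x$config$model, weights = x$config$weights,
    correction = x$config$correction,
    adjustment = x$config$p_adjust
  )
}

#' Signed significance matrix of the pairwise tests
#'
#' Builds the matrix \eqn{M[i, j] = \mathrm{sign}(\beta_{ij}) \cdot
#' (-\log_{10} p_{ij})} with rows the "from" type i and columns the "to"
#' type j: positive entries mean increased co-localization with the
#' condition, negative entries decreased. Untestable pairs are `NA`.
#'
#' @param results A `coloc_results` object.
#' @param term Condition contrast to display; default the first.
#' @param p Use `"raw"` (default) or `"adjusted"` p-values.
#' @return A numeric matrix with cell types as dimnames.
#' @export
signed_logp_matrix <- function(results, term = NULL, p = c("raw", "adjusted")) {
  p <- match.arg(p)
  tbl <- results$results
  if (is.null(term)) term <- tbl$term[1]
  tbl <- tbl[tbl$term == term, ]
  if (nrow(tbl) == 0) stop("term not found: ", term, call. = FALSE)
  types_i <- sort(unique(tbl$type_i))
  types_j <- sort(unique(tbl$type_j))
  m <- matrix(NA_real_, length(types_i), length(types_j),
              dimnames = list(from = types_i, to = types_j))
  pv <- if (p == "raw") tbl$p_raw else tbl$p_adjusted
  val <- sign(tbl$beta) * (-log10(pv))
  m[cbind(match(tbl$type_i, types_i), match(tbl$type_j, types_j))] <- val
  m
}

#' @rdname test_coloc
#' @param term,p Passed to [signed_logp_matrix()].
#' @method autoplot coloc_results
#' @export
autoplot.coloc_results <- function(object, term = NULL,
                                   p = c("raw", "adjusted"), ...) {
  m <- signed_logp_matrix(object, term = term, p = p)
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m, rownames = "from")),
    -"from", names_to = "to", values_to = "signed_logp"
  )
  df$from <- factor(df$from, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$signed_logp)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = "to cell type (j)", y = "from cell type (i)",
                  fill = expression(sign(beta) %.% -log[10] * p)) +
    ggplot2::theme_minimal()
}

#' Export test results, matrix and heatmap to a directory
#'
#' Writes `results.csv` (the tidy per-pair table), `signed_logp_matrix.csv`,
#' `weights.csv` (per image and pair) and `heatmap.png`.
#'
#' @param results A `coloc_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(results), file.path(dir, "results.csv"))
  m <- signed_logp_matrix(results)
  readr::write_csv(tibble::as_tibble(m, rownames = "from"),
                   file.path(dir, "signed_logp_matrix.csv"))
  readr::write_csv(results$scores, file.path(dir, "weights.csv"))
  plt <- autoplot(results)
  ggplot2::ggsave(file.path(dir, "heatmap.png"), plt, width = 6, height = 5,
                  dpi = 150)
  invisible(dir)
}
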