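#' Configuration for the two-type co-localization simulator
#'
#' Describes a simulated study: two cell types A and B in square images,
#' where B cells are placed preferentially around A cells within a
#' subject-specific disc radius. The defaults are the benchmark study
#' design used throughout the package: 1000x1000-unit images, 40 subjects
#' split into two groups of 20, three images per subject, per-image
#' expected counts drawn uniformly from {20, 40, ..., 400}, a
#' co-localization disc scale of sigma = 40 units and a group shift of
#' delta = sigma / 3.
#'
#' @param window Numeric `c(x_min, x_max, y_min, y_max)` image window.
#' @param n_subjects Number of subjects, split into two equal groups.
#' @param images_per_subject Images per subject.
#' @param cell_counts Set of expected per-image counts; one value is drawn
#'   uniformly (and independently) for each type in each image.
#' @param sigma Mean disc radius (coordinate units) controlling how tightly
#'   B cells cluster around A cells.
#' @param delta Group-2 shift of the mean disc radius under the
#'   `"difference"` regime.
#' @param count_multiplier Multiplies every drawn count (density sweeps).
#' @param density_grid Pixels per axis for evaluating the disc-kernel
#'   density of the A pattern.
#' @param count_draw `"per_image"` (default): the expected counts of A and
#'   B are re-drawn from the menu for every image, so images within a study
#'   differ widely in cell number — the regime the variance-weighting
#'   scheme targets. `"per_study"`: one A-count and one B-count draw are
#'   shared by every image of the study, giving count-homogeneous studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(window = c(0, 1000, 0, 1000), n_subjects = 40,
                       images_per_subject = 3,
                       cell_counts = seq(20, 400, by = 20), sigma = 40,
                       delta = sigma / 3, count_multiplier = 1,
                       density_grid = 128,
                       count_draw = c("per_image", "per_study")) {
  check_window_vec(window)
  count_draw <- match.arg(count_draw)
  stopifnot(n_subjects >= 2, n_subjects %% 2 == 0,
            images_per_subject >= 1, all(cell_counts >= 1), sigma > 0,
            delta >= 0, count_multiplier > 0, density_grid >= 8)
  structure(
    list(window = window, n_subjects = n_subjects,
         images_per_subject = images_per_subject,
         cell_counts = cell_counts, sigma = sigma, delta = delta,
         count_multiplier = count_multiplier, density_grid = density_grid,
         count_draw = count_draw),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects x ", x$images_per_subject,
      " images, window ", x$window[2] - x$window[1], "x",
      x$window[4] - x$window[3], ", sigma = ", x$sigma, ", delta = ",
      x$delta, ", counts in {", min(x$cell_counts), "..",
      max(x$cell_counts), "} x ", x$count_multiplier, "\n", sep = "")
  invisible(x)
}

#' Simulate a two-type co-localization study
#'
#' Generates one complete study under the given configuration. Per image:
#' (1) type-A cells are a homogeneous Poisson process whose expected count
#' is drawn uniformly from `cell_counts * count_multiplier`; (2) the
#' A-pattern's disc-kernel density is evaluated on a `density_grid` pixel
#' grid, with the disc radius drawn once per subject from a Poisson
#' distribution with mean `sigma` (group 1, and group 2 under the null
#' regime) or `sigma + delta` (group 2 under the difference regime), and
#' normalized to integrate to one over the window; (3) type-B cells are an
#' inhomogeneous Poisson process with intensity equal to an independently
#' drawn expected count times that normalized density (per-pixel Poisson
#' counts, uniform placement within pixels). Sharing the disc radius across
#' a subject's images induces the subject-level correlation that the
#' random-intercept model targets. A zero disc-radius draw is redrawn; an
#' empty A pattern makes B fall back to a homogeneous process.
#'
#' @param config A [sim_config()].
#' @param regime `"null"` (both groups share mean disc radius `sigma`) or
#'   `"difference"` (group 2 mean is `sigma + delta`).
#' @param seed Integer seed; the study is bit-reproducible given
#'   `config`, `regime` and `seed`.
#' @return A [cell_study()] with condition `"group1"`/`"group2"`, subject
#'   identifiers, and a `truth` attribute (tibble: `subject_id`, `group`,
#'   `disc_radius`, `regime`, `seed`) retrievable with [sim_truth()].
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_subjects = 4), "difference", seed = 7)
#' sim
#' sim_truth(sim)
simulate_study <- function(config, regime = c("null", "difference"), seed) {
  stopifnot(inherits(config, "sim_config"))
  regime <- match.arg(regime)
  set.seed(as.integer(seed))
  w <- config$window
  n_half <- config$n_subjects / 2
  groups <- rep(c("group1", "group2"), each = n_half)
  rate2 <- config$sigma + if (regime == "difference") config$delta else 0

  disc <- vapply(seq_len(config$n_subjects), function(s) {
    rate <- if (groups[s] == "group1") config$sigma else rate2
    r <- rpois(1, rate)
    while (r == 0) r <- rpois(1, rate)
    r
  }, numeric(1))

  counts_menu <- config$cell_counts * config$count_multiplier
  ng <- config$density_grid
  px <- (w[2] - w[1]) / ng
  py <- (w[4] - w[3]) / ng

  draw_count <- function() counts_menu[sample.int(length(counts_menu), 1)]
  per_study <- identical(config$count_draw, "per_study")
  if (per_study) {
    study_c_a <- draw_count()
    study_c_b <- draw_count()
  }

  all_cells <- vector("list", config$n_subjects * config$images_per_subject)
  img_meta <- vector("list", length(all_cells))
  k <- 0
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("subj%03d", s)
    for (im in seq_len(config$images_per_subject)) {
      k <- k + 1
      iid <- sprintf("%s_im%d", sid, im)
      c_a <- if (per_study) study_c_a else draw_count()
      n_a <- rpois(1, c_a)
      xa <- runif(n_a, w[1], w[2])
      ya <- runif(n_a, w[3], w[4])
      c_b <- if (per_study) study_c_b else draw_count()
      if (n_a > 0) {
        dens <- disc_kernel_counts(xa, ya, disc[s], ng, ng,
                                   w[1], w[2], w[3], w[4])
        total <- sum(dens)
      } else {
        total <- 0
      }
      if (total > 0) {
        lambda <- c_b * as.vector(dens) / total
        nb_pix <- rpois(length(lambda), lambda)
        idx <- rep(seq_along(nb_pix), nb_pix)
        ix <- (idx - 1) %% ng
        iy <- (idx - 1) %/% ng
        xb <- w[1] + (ix + runif(length(idx))) * px
        yb <- w[3] + (iy + runif(length(idx))) * py
      } else {
        n_b <- rpois(1, c_b)
        xb <- runif(n_b, w[1], w[2])
        yb <- runif(n_b, w[3], w[4])
      }
      all_cells[[k]] <- tibble::tibble(
        image_id = iid,
        x = c(xa, xb), y = c(ya, yb),
        cell_type = rep(c("A", "B"), c(length(xa), length(xb)))
      )
      img_meta[[k]] <- tibble::tibble(image_id = iid, subject_id = sid,
                                      condition = groups[s])
    }
  }
  study <- cell_study(dplyr::bind_rows(all_cells),
                      images = dplyr::bind_rows(img_meta), window = w)
  attr(study, "truth") <- tibble::tibble(
    subject_id = sprintf("subj%03d", seq_len(config$n_subjects)),
    group = groups, disc_radius = disc, regime = regime,
    seed = as.integer(seed)
  )
  study
}

#' Ground truth of a simulated study
#'
#' @param study A study produced by [simulate_study()].
#' @return Tibble with per-subject group, realized disc radius, regime and
#'   seed.
#' @export
sim_truth <- function(study) {
  truth <- attr(study, "truth")
  if (is.null(truth)) stop("not a simulated study", call. = FALSE)
  truth
}

#' Run the null / difference simulation benchmark
#'
#' Repeatedly simulates studies under the null and difference regimes and
#' runs the full testing pipeline on the A -> B pair of each, producing the
#' paired p-value collections from which ROC curves, AUC, and false/true
#' positive rates are computed ([summarize_benchmark()], [roc_auc()]).
#' Variance weights, when fitted, use the scores of all four ordered pairs
#' concurrently; each weighting mode re-analyses the same scored
#' replicates, so modes are compared on identical data. Replicate seeds are
#' derived from `master_seed` by a fixed counter scheme (`master_seed + i`
#' for null replicate i, `master_seed + 500000 + i` for difference
#' replicate i), making every run reproducible.
#'
#' @param config A [sim_config()].
#' @param n_null,n_diff Numbers of null and difference replicates.
#' @param weights Character vector of weighting modes to analyse:
#'   subset of `c("fitted", "none")`.
#' @param model `"mixed"` (default) or `"linear"`.
#' @param radii,correction Scoring configuration.
#' @param master_seed Integer master seed.
#' @param max_fail Maximum tolerated fraction of failed replicates.
#' @return A `benchmark_result`: list with tibble `p_values` (`regime`,
#'   `replicate`, `seed`, `mode`, `beta`, `p`), the configuration, and the
#'   count of failed replicates.
#' @export
run_benchmark <- function(config = sim_config(), n_null = 100,
                          n_diff = 100, weights = c("fitted", "none"),
                          model = c("mixed", "linear"),
                          radii = default_radii(),
                          correction = "translation", master_seed = 1,
                          max_fail = 0.05) {
  model <- match.arg(model)
  weights <- match.arg(weights, several.ok = TRUE)
  stopifnot(n_null >= 1, n_diff >= 1)
  plan <- dplyr::bind_rows(
    tibble::tibble(regime = "null", replicate = seq_len(n_null),
                   seed = master_seed + seq_len(n_null)),
    tibble::tibble(regime = "difference", replicate = seq_len(n_diff),
                   seed = master_seed + 500000L + seq_len(n_diff))
  )
  failures <- character(0)
  rows <- purrr::map(seq_len(nrow(plan)), function(i) {
    regime <- plan$regime[i]
    seed <- plan$seed[i]
    res <- tryCatch({
      sim <- simulate_study(config, regime = regime, seed = seed)
      scores <- score_pairs(sim, radii = radii, correction = correction)
      meta <- sim$images[, c("image_id", "subject_id", "condition")]
      purrr::map(weights, function(mode) {
        varmodel <- if (mode == "fitted") {
          fit_variance_surface(scores)
        } else NULL
        scored <- compute_weights(scores, varmodel)
        sub <- scored[scored$type_i == "A" & scored$type_j == "B", ]
        sub <- dplyr::left_join(sub, meta, by = "image_id")
        fit <- fit_score_model(sub, condition = "condition",
                               subject = "subject_id", model = model)
        tibble::tibble(regime = regime, replicate = plan$replicate[i],
                       seed = seed, mode = mode, beta = fit$beta[1],
                       p = fit$p_raw[1])
      })
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <<- c(failures,
                     sprintf("%s replicate %d: %s", regime,
                             plan$replicate[i], res))
      return(NULL)
    }
    dplyr::bind_rows(res)
  })
  if (length(failures) / nrow(plan) > max_fail) {
    stop("too many failed replicates (", length(failures), "/", nrow(plan),
         "):\n", paste(head(failures, 5), collapse = "\n"), call. = FALSE)
  }
  structure(
    list(p_values = dplyr::bind_rows(rows),
         config = config,
         analysis = list(weights = weights, model = model, radii = radii,
                         correction = correction,
                         master_seed = master_seed),
         failures = failures),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  p <- x$p_values
  cat("<benchmark_result> ",
      sum(p$regime == "null" & p$mode == p$mode[1]), " null + ",
      sum(p$regime == "difference" & p$mode == p$mode[1]),
      " difference replicates, modes: ",
      paste(unique(p$mode), collapse = ", "),
      ", failures: ", length(x$failures), "\n", sep = "")
  print(summarize_benchmark(x))
  invisible(x)
}
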