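corrections <- c(none = 0L, translation = 1L, isotropic = 2L)

check_correction <- function(correction) {
  if (!is.character(correction) || length(correction) != 1 ||
      !correction %in% names(corrections)) {
    stop("`correction` must be one of ",
         paste(dQuote(names(corrections), FALSE), collapse = ", "),
         call. = FALSE)
  }
  correction
}

#' Cross-type Ripley K function for one image
#'
#' Estimates, for each radius r, the scaled average number of type-j cells
#' within distance r of a type-i cell:
#' \deqn{\hat K_{ij}(r) = \frac{|W|}{n_i n_j} \sum_{a \in i}\sum_{b \in j}
#'   1[d_{ab} \le r]\, e(a, b)}
#' where \eqn{|W|} is the window area and \eqn{e} an edge-correction weight
#' (`"none"`: 1; `"translation"`: \eqn{|W| / |W \cap W_{a-b}|};
#' `"isotropic"`: the reciprocal of the fraction of the circle centred on
#' the i-cell through the j-cell that lies inside the window). For a
#' self-pair (`type_i == type_j`) zero-distance self matches are excluded
#' and the normalizer is \eqn{n(n-1)}, the standard univariate convention.
#' Under independence of the two types, \eqn{K_{ij}(r) = \pi r^2}.
#'
#' @param cells Data frame of one image's cells (`x`, `y`, `cell_type`), or
#'   a [cell_study()] together with `image_id`.
#' @param type_i,type_j Cell-type labels; `type_i` is the "from" type on
#'   which circles are centred.
#' @param radii Strictly increasing positive radii, in coordinate units.
#' @param correction `"none"`, `"translation"` or `"isotropic"`.
#' @param window Numeric `c(x_min, x_max, y_min, y_max)`. Required when
#'   `cells` is a bare data frame; ignored (taken from the study) otherwise.
#' @param image_id Image to use when `cells` is a [cell_study()].
#' @return A tibble of class `coloc_curve` with columns `r` and `est`, and
#'   attributes `statistic` (`"K"`), `type_i`, `type_j`, `n_i`, `n_j`,
#'   `correction` and `window`. When either count is zero (or `n_i < 2` for
#'   a self-pair) the estimate is `NA` at every radius.
#' @export
#' @examples
#' cells <- data.frame(x = c(50, 53), y = c(50, 54),
#'                     cell_type = c("A", "B"))
#' kcross(cells, "A", "B", radii = 10, correction = "none",
#'        window = c(0, 100, 0, 100))
kcross <- function(cells, type_i, type_j, radii = default_radii(),
                   correction = "translation", window = NULL,
                   image_id = NULL) {
  if (inherits(cells, "cell_study")) {
    if (is.null(image_id)) stop("supply `image_id` with a cell_study",
                                call. = FALSE)
    win_row <- cells$images[cells$images$image_id == image_id, ]
    if (nrow(win_row) != 1) stop("unknown image_id: ", image_id,
                                 call. = FALSE)
    window <- c(win_row$x_min, win_row$x_max, win_row$y_min, win_row$y_max)
    cells <- cells$cells[cells$cells$image_id == image_id, ]
  }
  if (is.null(window)) stop("`window` is required with a bare cell table",
                            call. = FALSE)
  check_window_vec(window)
  radii <- check_radii(radii)
  check_correction(correction)

  pi_pts <- cells[cells$cell_type == type_i, c("x", "y")]
  pj_pts <- cells[cells$cell_type == type_j, c("x", "y")]
  self <- identical(type_i, type_j)
  n_i <- nrow(pi_pts)
  n_j <- nrow(pj_pts)
  area <- (window[2] - window[1]) * (window[4] - window[3])

  denom <- if (self) n_i * (n_i - 1) else n_i * n_j
  if (denom <= 0) {
    est <- rep(NA_real_, length(radii))
  } else {
    counts <- cross_pair_counts(pi_pts$x, pi_pts$y, pj_pts$x, pj_pts$y,
                                radii, window[1], window[2], window[3],
                                window[4], corrections[[correction]], self)
    est <- area * counts / denom
  }
  new_curve(radii, est, "K", type_i, type_j, n_i, n_j, correction, window)
}

new_curve <- function(radii, est, statistic, type_i, type_j, n_i, n_j,
                      correction, window) {
  out <- tibble::tibble(r = radii, est = est)
  class(out) <- c("coloc_curve", class(out))
  attr(out, "statistic") <- statistic
  attr(out, "type_i") <- type_i
  attr(out, "type_j") <- type_j
  attr(out, "n_i") <- n_i
  attr(out, "n_j") <- n_j
  attr(out, "correction") <- correction
  attr(out, "window") <- window
  out
}

#' Variance-stabilized L curve from a K curve
#'
#' Transforms a cross-type K estimate to the L scale,
#' \eqn{\hat L(r) = \sqrt{\hat K(r) / \pi}}, whose reference value under
#' complete spatial randomness is the identity \eqn{L(r) = r}. Curves above
#' the line indicate attraction of type j around type i, curves below it
#' avoidance. Undefined K values propagate.
#'
#' @param k A `coloc_curve` with statistic `"K"`, from [kcross()].
#' @return A `coloc_curve` with statistic `"L"`.
#' @export
lcross <- function(k) {
  stopifnot(inherits(k, "coloc_curve"))
  if (!identical(attr(k, "statistic"), "K")) {
    stop("`lcross()` expects a K curve", call. = FALSE)
  }
  if (any(k$est < 0, na.rm = TRUE)) {
    stop("internal error: negative K estimate", call. = FALSE)
  }
  new_curve(k$r, sqrt(k$est / pi), "L", attr(k, "type_i"),
            attr(k, "type_j"), attr(k, "n_i"), attr(k, "n_j"),
            attr(k, "correction"), attr(k, "window"))
}

#' @export
print.coloc_curve <- function(x, ...) {
  cat("<coloc_curve> ", attr(x, "statistic"), " curve, ",
      attr(x, "type_i"), " -> ", attr(x, "type_j"),
      " (n_i = ", attr(x, "n_i"), ", n_j = ", attr(x, "n_j"),
      "), correction = ", attr(x, "correction"), "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Co-localization score for one ordered cell-type pair in one image
#'
#' Sums the departure of the observed L curve from the Poisson reference
#' over the radius grid:
#' \deqn{u = \sum_{r'} [\hat L_{ij}(r') - r']}
#' Positive u means the two types attract (type j is enriched around type i
#' relative to randomness); negative u means avoidance. With a single
#' radius the score reduces to \eqn{\hat L(r_0) - r_0}. The score is
#' undefined (`NA`) when either type has no cells in the image.
#'
#' @inheritParams kcross
#' @return A one-row tibble: `type_i`, `type_j`, `u`, `n_i`, `n_j`.
#' @export
coloc_score <- function(cells, type_i, type_j, radii = default_radii(),
                        correction = "translation", window = NULL,
                        image_id = NULL) {
  l <- lcross(kcross(cells, type_i, type_j, radii = radii,
                     correction = correction, window = window,
                     image_id = image_id))
  tibble::tibble(type_i = type_i, type_j = type_j,
                 u = sum(l$est - l$r),
                 n_i = attr(l, "n_i"), n_j = attr(l, "n_j"))
}

#' Score every ordered cell-type pair in every image
#'
#' Computes the co-localization score u for each image and each ordered
#' pair of the requested types, including self-pairs (i -> i co-localization
#' is a meaningful clustering measure). Rows whose score is undefined
#' (a zero count) carry `NA` and are retained so that downstream stages can
#' drop them with an explicit count.
#'
#' @param study A [cell_study()].
#' @param types Character vector of cell types to score; default all types
#'   observed in the study. A type absent from every image is an error.
#' @param radii,correction As in [kcross()].
#' @return A tibble with one row per (image, ordered pair): `image_id`,
#'   `type_i`, `type_j`, `u`, `n_i`, `n_j`. Attribute `radii` and
#'   `correction` record the configuration.
#' @export
score_pairs <- function(study, types = NULL, radii = default_radii(),
                        correction = "translation") {
  stopifnot(inherits(study, "cell_study"))
  radii <- check_radii(radii)
  check_correction(correction)
  observed <- unique(study$cells$cell_type)
  if (is.null(types)) {
    types <- sort(observed)
  } else {
    absent <- setdiff(types, observed)
    if (length(absent) > 0) {
      stop("cell type(s) absent from every image: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  if (length(types) == 0) stop("no cell types to score", call. = FALSE)

  pairs <- tidyr::expand_grid(type_i = types, type_j = types)
  cells_by_img <- split(study$cells, study$cells$image_id)
  imgs <- study$images
  corr_code <- corrections[[correction]]
  n_pair <- nrow(pairs)

  res <- purrr::map(seq_len(nrow(imgs)), function(k) {
    id <- imgs$image_id[k]
    win <- c(imgs$x_min[k], imgs$x_max[k], imgs$y_min[k], imgs$y_max[k])
    area <- (win[2] - win[1]) * (win[4] - win[3])
    img_cells <- cells_by_img[[id]]
    if (is.null(img_cells)) img_cells <- study$cells[0, ]
    xs <- ys <- setNames(vector("list", length(types)), types)
    for (ty in types) {
      sel <- img_cells$cell_type == ty
      xs[[ty]] <- img_cells$x[sel]
      ys[[ty]] <- img_cells$y[sel]
    }
    u <- n_i <- n_j <- numeric(n_pair)
    for (p in seq_len(n_pair)) {
      ti <- pairs$type_i[p]; tj <- pairs$type_j[p]
      self <- ti == tj
      n_i[p] <- length(xs[[ti]])
      n_j[p] <- length(xs[[tj]])
      denom <- if (self) n_i[p] * (n_i[p] - 1) else n_i[p] * n_j[p]
      if (denom <= 0) {
        u[p] <- NA_real_
      } else {
        counts <- cross_pair_counts(xs[[ti]], ys[[ti]], xs[[tj]], ys[[tj]],
                                    radii, win[1], win[2], win[3], win[4],
                                    corr_code, self)
        u[p] <- sum(sqrt(area * counts / (denom * pi)) - radii)
      }
    }
    tibble::tibble(image_id = id, type_i = pairs$type_i,
                   type_j = pairs$type_j, u = u, n_i = n_i, n_j = n_j)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "radii") <- radii
  attr(out, "correction") <- correction
  out
}
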