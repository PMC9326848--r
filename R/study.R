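#' Assemble a co-localization study from per-cell and per-image tables
#'
#' A study bundles the segmented, classified cells of many images with the
#' image-level metadata (subject, condition, covariates) needed for
#' inference. Cells are centroids in continuous, unit-agnostic coordinates;
#' each image has a rectangular observation window whose area enters the
#' K-function directly, so the window policy is explicit and overridable.
#'
#' @param cells Data frame with one row per cell and columns `image_id`,
#'   `x`, `y`, `cell_type`. Extra columns are carried along untouched.
#'   Cell-type labels are trimmed of surrounding whitespace and matched
#'   case-sensitively.
#' @param images Optional data frame with one row per image: `image_id` plus
#'   any of `subject_id`, `condition` and further covariate columns. When
#'   omitted, per-image metadata is taken from constant extra columns of
#'   `cells` named `subject_id`/`condition` if present.
#' @param window Window policy: `"bounding_box"` (default; each image's
#'   window is the bounding box of its own points), a numeric vector
#'   `c(x_min, x_max, y_min, y_max)` applied to every image, or a data frame
#'   with columns `image_id`, `x_min`, `x_max`, `y_min`, `y_max` for
#'   per-image windows. Points outside a user-supplied window are an error.
#'
#' @return An object of class `cell_study`: a list with tibbles `cells`
#'   (`image_id`, `x`, `y`, `cell_type`) and `images` (`image_id`, window
#'   bounds, and any metadata columns).
#' @export
#' @examples
#' cells <- data.frame(
#'   image_id = rep(c("im1", "im2"), each = 3),
#'   x = c(10, 20, 30, 15, 25, 35), y = c(10, 25, 5, 30, 10, 20),
#'   cell_type = c("A", "B", "A", "B", "A", "B")
#' )
#' study <- cell_study(cells, window = c(0, 100, 0, 100))
#' study
cell_study <- function(cells, images = NULL, window = "bounding_box") {
  cells <- tibble::as_tibble(cells)
  required <- c("image_id", "x", "y", "cell_type")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("`cells` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(cells$x))) |
                   is.na(suppressWarnings(as.numeric(cells$y))))
    stop("non-numeric coordinates in `cells` (first offending row: ",
         if (length(bad)) bad[1] else NA, ")", call. = FALSE)
  }
  if (anyNA(cells$x) || anyNA(cells$y)) {
    stop("missing coordinates in `cells` (row ",
         which(is.na(cells$x) | is.na(cells$y))[1], ")", call. = FALSE)
  }
  cells$image_id <- as.character(cells$image_id)
  cells$cell_type <- trimws(as.character(cells$cell_type))

  ids <- unique(cells$image_id)
  windows <- resolve_windows(cells, ids, window)

  meta <- NULL
  if (!is.null(images)) {
    meta <- tibble::as_tibble(images)
    if (!"image_id" %in% names(meta)) {
      stop("`images` must contain an `image_id` column", call. = FALSE)
    }
    meta$image_id <- as.character(meta$image_id)
    if (anyDuplicated(meta$image_id)) {
      stop("`images` has duplicated image_id rows", call. = FALSE)
    }
    unknown <- setdiff(ids, meta$image_id)
    if (length(unknown) > 0) {
      stop("images present in `cells` but absent from `images`: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  } else {
    # lift constant per-image metadata out of the cell table if present
    carry <- intersect(c("subject_id", "condition"), names(cells))
    if (length(carry) > 0) {
      meta <- dplyr::distinct(cells[, c("image_id", carry)])
      if (anyDuplicated(meta$image_id)) {
        stop("columns ", paste(carry, collapse = ", "),
             " are not constant within image_id", call. = FALSE)
      }
    }
  }

  img_tbl <- windows
  if (!is.null(meta)) {
    img_tbl <- dplyr::left_join(img_tbl, meta, by = "image_id")
  }
  out <- structure(
    list(cells = cells[, union(required, names(cells))],
         images = img_tbl),
    class = "cell_study"
  )
  check_points_in_windows(out)
  out
}

resolve_windows <- function(cells, ids, window) {
  if (is.character(window) && length(window) == 1 &&
      window == "bounding_box") {
    if (nrow(cells) == 0) {
      return(tibble::tibble(image_id = character(), x_min = numeric(),
                            x_max = numeric(), y_min = numeric(),
                            y_max = numeric()))
    }
    by_img <- dplyr::summarise(
      dplyr::group_by(cells, .data$image_id),
      x_min = min(.data$x), x_max = max(.data$x),
      y_min = min(.data$y), y_max = max(.data$y),
      .groups = "drop"
    )
    # degenerate bounding boxes (single cell / collinear) get a unit pad
    pad <- function(lo, hi) ifelse(hi > lo, hi, lo + 1)
    by_img$x_max <- pad(by_img$x_min, by_img$x_max)
    by_img$y_max <- pad(by_img$y_min, by_img$y_max)
    return(by_img[match(ids, by_img$image_id), ])
  }
  if (is.numeric(window) && length(window) == 4) {
    check_window_vec(window)
    return(tibble::tibble(image_id = ids, x_min = window[1],
                          x_max = window[2], y_min = window[3],
                          y_max = window[4]))
  }
  if (is.data.frame(window)) {
    need <- c("image_id", "x_min", "x_max", "y_min", "y_max")
    if (!all(need %in% names(window))) {
      stop("per-image window table needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    window <- tibble::as_tibble(window)
    window$image_id <- as.character(window$image_id)
    missing_w <- setdiff(ids, window$image_id)
    if (length(missing_w) > 0) {
      stop("no window supplied for image(s): ",
           paste(head(missing_w, 5), collapse = ", "), call. = FALSE)
    }
    apply(window[, need[-1]], 1, check_window_vec)
    return(window[match(ids, window$image_id), need])
  }
  stop("invalid `window`: use \"bounding_box\", c(x_min, x_max, y_min, y_max), ",
       "or a per-image window table", call. = FALSE)
}

check_window_vec <- function(w) {
  if (anyNA(w) || w[2] <= w[1] || w[4] <= w[3]) {
    stop("window must satisfy x_max > x_min and y_max > y_min", call. = FALSE)
  }
  invisible(w)
}

check_points_in_windows <- function(study) {
  joined <- dplyr::left_join(study$cells, study$images, by = "image_id")
  out_rows <- which(joined$x < joined$x_min | joined$x > joined$x_max |
                      joined$y < joined$y_min | joined$y > joined$y_max)
  if (length(out_rows) > 0) {
    stop("cells outside their image window (rows ",
         paste(head(out_rows, 10), collapse = ", "),
         if (length(out_rows) > 10) ", ..." else "", ")", call. = FALSE)
  }
  invisible(study)
}

#' @export
print.cell_study <- function(x, ...) {
  n_img <- nrow(x$images)
  types <- sort(unique(x$cells$cell_type))
  cat("<cell_study> ", nrow(x$cells), " cells, ", n_img, " images, ",
      length(types), " cell types\n", sep = "")
  if ("subject_id" %in% names(x$images)) {
    cat("  subjects: ", length(unique(x$images$subject_id)), "\n", sep = "")
  }
  if ("condition" %in% names(x$images)) {
    cond <- x$images$condition
    if (is.numeric(cond)) {
      cat("  condition: continuous\n")
    } else {
      cat("  condition: ", paste(names(table(cond)), collapse = " / "),
          "\n", sep = "")
    }
  }
  cat("  cell types: ", paste(types, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a segmented-cell table from delimited text
#'
#' Reads a CSV/TSV export of a segmented, classified image dataset into a
#' [cell_study()]. The default header is `imageID, x, y, cellType,
#' subjectID, condition`; any other naming is handled through `column_map`.
#' The delimiter is inferred from the file extension (`.tsv`/`.txt` are
#' tab-delimited, everything else comma) unless `delim` is given.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named character vector mapping internal names
#'   (`image_id`, `x`, `y`, `cell_type`, `subject_id`, `condition`, ...) to
#'   the file's column names. Entries for `subject_id`/`condition` are
#'   optional; unmapped internal names fall back to the default header.
#' @param window Window policy passed to [cell_study()].
#' @param delim Field delimiter override (e.g. `","`).
#' @return A [cell_study()].
#' @export
#' @examples
#' path <- system.file("extdata", "example_cells.csv",
#'                     package = "coloctest")
#' study <- read_cells(path, window = c(0, 1000, 0, 1000))
#' validate_study(study)
read_cells <- function(path, column_map = NULL, window = "bounding_box",
                       delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  default_map <- c(image_id = "imageID", x = "x", y = "y",
                   cell_type = "cellType", subject_id = "subjectID",
                   condition = "condition")
  map <- default_map
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(default_map))
    if (length(unknown) > 0) {
      stop("unknown column_map target(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  required <- c("image_id", "x", "y", "cell_type")
  for (nm in required) {
    if (!map[[nm]] %in% names(raw)) {
      stop("column `", map[[nm]], "` (mapped to ", nm, ") not found in ",
           path, call. = FALSE)
    }
  }
  present <- names(map)[map %in% names(raw)]
  cells <- raw[, map[present]]
  names(cells) <- present
  for (ax in c("x", "y")) {
    if (!is.numeric(cells[[ax]])) {
      num <- suppressWarnings(as.numeric(cells[[ax]]))
      if (anyNA(num) && !all(is.na(cells[[ax]]) == is.na(num))) {
        stop("non-numeric ", ax, " coordinate at data row ",
             which(is.na(num) & !is.na(cells[[ax]]))[1], call. = FALSE)
      }
      cells[[ax]] <- num
    }
  }
  cell_study(cells, window = window)
}

#' Write a study back to delimited text
#'
#' Writes the per-cell table with the default header (`imageID, x, y,
#' cellType` plus `subjectID`/`condition` when present) so that
#' [read_cells()] round-trips coordinates, labels and identifiers.
#'
#' @param study A [cell_study()].
#' @param path Output path; `.tsv`/`.txt` write tab-delimited, else CSV.
#' @return `path`, invisibly.
#' @export
write_cells <- function(study, path) {
  stopifnot(inherits(study, "cell_study"))
  out <- study$cells[, c("image_id", "x", "y", "cell_type")]
  meta_cols <- intersect(c("subject_id", "condition"), names(study$images))
  if (length(meta_cols) > 0) {
    out <- dplyr::left_join(out,
                            study$images[, c("image_id", meta_cols)],
                            by = "image_id")
  }
  rename_to <- c(image_id = "imageID", x = "x", y = "y",
                 cell_type = "cellType", subject_id = "subjectID",
                 condition = "condition")
  names(out) <- rename_to[names(out)]
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Validate a study's structure and report per-image composition
#'
#' Report-only diagnostics ahead of scoring and inference: per-image
#' cell-type counts, images lacking any analysed type, the subject/image
#' layout, and whether each subject carries a single condition value (a
#' requirement of the subject-level models). The study is never modified.
#'
#' @param study A [cell_study()].
#' @param types Cell types to check for zero counts; default all observed.
#' @return A list of class `study_validation` with tibbles `type_counts`
#'   (image x type counts, long form), `zero_count_images`, `subjects`
#'   (image counts per subject), `inconsistent_subjects` (subjects whose
#'   images disagree on condition), and logical `ok`.
#' @export
validate_study <- function(study, types = NULL) {
  stopifnot(inherits(study, "cell_study"))
  all_types <- sort(unique(study$cells$cell_type))
  if (is.null(types)) types <- all_types
  ids <- study$images$image_id

  counts <- count_by_type(study, types)
  zero <- counts[counts$n == 0, c("image_id", "cell_type")]

  subjects <- tibble::tibble(subject_id = character(), n_images = integer())
  inconsistent <- tibble::tibble(subject_id = character())
  if ("subject_id" %in% names(study$images)) {
    subjects <- dplyr::count(study$images, .data$subject_id,
                             name = "n_images")
    if ("condition" %in% names(study$images)) {
      per_subj <- dplyr::summarise(
        dplyr::group_by(study$images, .data$subject_id),
        n_conditions = dplyr::n_distinct(.data$condition),
        .groups = "drop"
      )
      inconsistent <- per_subj[per_subj$n_conditions > 1, "subject_id"]
    }
  }
  structure(
    list(n_images = length(ids), n_cells = nrow(study$cells),
         types = all_types, type_counts = counts,
         zero_count_images = zero, subjects = subjects,
         inconsistent_subjects = inconsistent,
         ok = nrow(inconsistent) == 0),
    class = "study_validation"
  )
}

count_by_type <- function(study, types) {
  grid <- tidyr::expand_grid(image_id = study$images$image_id,
                             cell_type = types)
  obs <- dplyr::count(
    dplyr::filter(study$cells, .data$cell_type %in% types),
    .data$image_id, .data$cell_type
  )
  out <- dplyr::left_join(grid, obs, by = c("image_id", "cell_type"))
  out$n <- ifelse(is.na(out$n), 0L, out$n)
  out
}

#' @export
print.study_validation <- function(x, ...) {
  cat("<study_validation> ", x$n_images, " images, ", x$n_cells,
      " cells, types: ", paste(x$types, collapse = ", "), "\n", sep = "")
  if (nrow(x$subjects) > 0) {
    cat("  subjects: ", nrow(x$subjects), " (images per subject ",
        min(x$subjects$n_images), "-", max(x$subjects$n_images), ")\n",
        sep = "")
  }
  if (nrow(x$zero_count_images) > 0) {
    cat("  images with a zero count for some type: ",
        length(unique(x$zero_count_images$image_id)), "\n", sep = "")
  }
  if (!x$ok) {
    cat("  PROBLEM: subjects with non-constant condition: ",
        paste(x$inconsistent_subjects$subject_id, collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  conditions consistent within subjects\n")
  }
  invisible(x)
}
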