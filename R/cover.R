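#' Percent cover of a category from a point-count image
#'
#' Random-point scoring: each of the sampler's `points_per_image` points on a
#' photoquadrat is classified to a benthic category, and cover is the scored
#' fraction as a percentage. A category with no points (including one absent
#' from the table) has 0% cover, because scoring is exhaustive per image.
#'
#' @param counts Point counts for one image: a named numeric vector
#'   (category -> points) or a data frame with `category` and `points`.
#' @param category Benthic category label.
#' @param sampler A [sampler_spec()]; supplies the expected point total.
#' @return Cover as a percentage in \[0, 100\].
#' @examples
#' cover_from_points(c(coral = 30, other = 170), "coral") # 15
#' @export
cover_from_points <- function(counts, category, sampler = sampler_spec()) {
  counts <- .as_category_counts(counts, "points")
  total <- sum(counts)
  if (total != sampler$points_per_image) {
    .abort("point counts sum to ", total, ", expected points_per_image = ",
           sampler$points_per_image)
  }
  hit <- if (category %in% names(counts)) counts[[category]] else 0
  100 * hit / total
}

#' Percent cover of a category from a grid-scored image
#'
#' Grid dominance scoring: the photoquadrat is divided into `grid_cells`
#' equal cells, each assigned to its dominant occupant; cover is the
#' dominated fraction as a percentage. With the default 25-cell grid the
#' estimate is quantised to 4% steps.
#'
#' @param counts Cell counts for one image: a named numeric vector
#'   (category -> cells) or a data frame with `category` and `cells`.
#' @inheritParams cover_from_points
#' @return Cover as a percentage, a multiple of `100/grid_cells`.
#' @examples
#' cover_from_grid(c(coral = 5, sand = 20), "coral") # 20
#' @export
cover_from_grid <- function(counts, category, sampler = sampler_spec()) {
  counts <- .as_category_counts(counts, "cells")
  total <- sum(counts)
  if (total != sampler$grid_cells) {
    .abort("grid cell counts sum to ", total, ", expected grid_cells = ",
           sampler$grid_cells)
  }
  hit <- if (category %in% names(counts)) counts[[category]] else 0
  100 * hit / total
}

.as_category_counts <- function(counts, value_col) {
  if (is.data.frame(counts)) {
    .check_columns(counts, c("category", value_col), "image counts")
    counts <- stats::setNames(counts[[value_col]], counts$category)
  }
  if (!is.numeric(counts) || is.null(names(counts))) {
    .abort("counts must be a named numeric vector or a category/", value_col,
           " data frame")
  }
  if (any(counts < 0)) .abort("category counts must be non-negative")
  counts
}

#' Per-image percent cover for every category
#'
#' Expands a long point-count or grid-score table to one row per image x
#' category with the image's percent cover. Categories unscored on an image
#' are filled in at 0% (scoring is exhaustive), so group summaries are not
#' biased upward by missing zeros.
#'
#' @param records Long table (`point_counts` or `grids` component of a
#'   [survey_dataset()]).
#' @param sampler A [sampler_spec()].
#' @param scheme `"points"` (200-random-point scoring) or `"grid"` (25-cell
#'   dominance scoring).
#' @return A tibble with the image's grouping columns plus `category` and
#'   `cover` (percent).
#' @export
per_image_cover <- function(records, sampler = sampler_spec(),
                            scheme = c("points", "grid")) {
  scheme <- match.arg(scheme)
  value_col <- if (scheme == "points") "points" else "cells"
  denom <- if (scheme == "points") sampler$points_per_image else sampler$grid_cells
  keys <- intersect(c("image_id", "site", "habitat", "depth_m", "year"),
                    names(records))
  .check_columns(records, c(keys, "category", value_col), "cover records")
  if (nrow(records) == 0) {
    return(tibble::tibble(!!!records[keys], category = character(), cover = numeric()))
  }
  sums <- tapply(records[[value_col]], records$image_id, sum)
  if (any(sums != denom)) {
    .abort("per-image ", value_col, " must sum to ", denom,
           "; violated for image ",
           paste(utils::head(names(sums)[sums != denom], 5), collapse = ", "))
  }
  images <- dplyr::distinct(records, dplyr::across(dplyr::all_of(keys)))
  full <- tidyr::crossing(images, category = unique(records$category))
  full |>
    dplyr::left_join(records, by = c(keys, "category")) |>
    dplyr::mutate(cover = 100 * dplyr::coalesce(.data[[value_col]], 0L) / denom) |>
    dplyr::select(dplyr::all_of(c(keys, "category", "cover")))
}

#' Summarise per-image covers into site-level estimates
#'
#' Aggregates per-image percent covers into a mean with standard error for
#' each site/habitat/depth/year/category group. The SE uses the sample SD
#' (n-1 denominator) over images divided by sqrt(n); single-image groups get
#' SE 0 by convention and are identifiable by `n_images == 1`.
#'
#' @param covers Per-image cover table from [per_image_cover()], or any
#'   tibble with a `cover` column plus grouping columns among
#'   `site`, `habitat`, `depth_m`, `year`, `category`.
#' @return A tibble of cover estimates: grouping columns plus `mean_cover`,
#'   `se_cover`, `n_images`.
#' @export
summarize_cover <- function(covers) {
  .check_columns(covers, "cover", "per-image covers")
  if (nrow(covers) == 0) {
    warning("summarize_cover: no images supplied; empty summary", call. = FALSE)
  }
  keys <- intersect(c("site", "habitat", "depth_m", "year", "category"),
                    names(covers))
  covers |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_cover = mean(.data$cover),
      se_cover = ifelse(dplyr::n() == 1, 0,
                        stats::sd(.data$cover) / sqrt(dplyr::n())),
      n_images = dplyr::n(),
      .groups = "drop"
    )
}
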