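#' Describe a reef habitat
#'
#' A habitat is the spatial unit over which sampler densities are scaled to
#' shore-wide abundances. The hard-bottom area is the settleable substratum
#' available to coral recruits, measured planimetrically (e.g., from
#' satellite imagery).
#'
#' @param name Habitat label, e.g. `"back_reef"` or `"outer_reef"`.
#' @param hard_bottom_area_km2 Hard-bottom area in km2; must be positive.
#' @param depth_range_m Ascending pair of depths (m) delimiting the habitat.
#' @param shore_length_km Length of shore sampled (km); informational.
#'
#' @return An object of class `habitat_spec`. The area is also stored
#'   pre-converted to cm2 (`hard_bottom_area_cm2`), the unit system used by
#'   every downstream calculation.
#' @examples
#' habitat_spec("back_reef", 4.58, c(2, 5), shore_length_km = 16)
#' @export
habitat_spec <- function(name, hard_bottom_area_km2, depth_range_m = c(0, 30),
                         shore_length_km = NA_real_) {
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name)) {
    .abort("habitat name must be a single non-empty string")
  }
  if (!is.numeric(hard_bottom_area_km2) || length(hard_bottom_area_km2) != 1 ||
      is.na(hard_bottom_area_km2) || hard_bottom_area_km2 <= 0) {
    .abort("hard_bottom_area_km2 must be a single positive number (habitat ", sQuote(name), ")")
  }
  depth_range_m <- as.numeric(depth_range_m)
  if (length(depth_range_m) != 2 || anyNA(depth_range_m) ||
      depth_range_m[1] > depth_range_m[2]) {
    .abort("depth_range_m must be an ascending pair of depths (habitat ", sQuote(name), ")")
  }
  structure(
    list(
      name = name,
      hard_bottom_area_km2 = hard_bottom_area_km2,
      hard_bottom_area_cm2 = .km2_to_cm2(hard_bottom_area_km2),
      depth_range_m = depth_range_m,
      shore_length_km = shore_length_km
    ),
    class = "habitat_spec"
  )
}

#' @export
print.habitat_spec <- function(x, ...) {
  cat(sprintf(
    "<habitat_spec> %s: %.3g km2 hard bottom, %g-%g m depth\n",
    x$name, x$hard_bottom_area_km2, x$depth_range_m[1], x$depth_range_m[2]
  ))
  invisible(x)
}

#' Describe the sampling gear geometry
#'
#' Holds the fixed areas and scoring resolutions of the samplers: the scored
#' (lower) surface of a settlement tile, the quadrat area used for colony
#' counts, the number of random points classified per photoquadrat image, and
#' the number of cells in the coarse grid-scoring scheme.
#'
#' @param tile_scoring_area_cm2 Scored tile surface, cm2.
#' @param quadrat_area_m2 Quadrat area, m2.
#' @param points_per_image Random points classified per image.
#' @param grid_cells Number of equal grid cells per image in grid scoring.
#'
#' @return An object of class `sampler_spec`, with the quadrat area also
#'   stored in cm2.
#' @examples
#' sampler_spec() # the defaults: 225 cm2 tiles, 0.25 m2 quadrats, 200 pts, 25 cells
#' @export
sampler_spec <- function(tile_scoring_area_cm2 = 225, quadrat_area_m2 = 0.25,
                         points_per_image = 200, grid_cells = 25) {
  vals <- c(
    tile_scoring_area_cm2 = tile_scoring_area_cm2,
    quadrat_area_m2 = quadrat_area_m2,
    points_per_image = points_per_image,
    grid_cells = grid_cells
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .abort("all sampler_spec fields must be positive")
  }
  structure(
    list(
      tile_scoring_area_cm2 = tile_scoring_area_cm2,
      quadrat_area_m2 = quadrat_area_m2,
      quadrat_area_cm2 = .m2_to_cm2(quadrat_area_m2),
      points_per_image = as.integer(points_per_image),
      grid_cells = as.integer(grid_cells)
    ),
    class = "sampler_spec"
  )
}

#' @export
print.sampler_spec <- function(x, ...) {
  cat(sprintf(
    "<sampler_spec> tile %g cm2 | quadrat %g m2 | %d points/image | %d grid cells\n",
    x$tile_scoring_area_cm2, x$quadrat_area_m2, x$points_per_image, x$grid_cells
  ))
  invisible(x)
}

# Zero-row templates for each census table -------------------------------

.empty_tiles <- function() {
  tibble::tibble(
    site = character(), habitat = character(), depth_m = numeric(),
    year = integer(), period = character(), tile_id = character(),
    recruit_count = integer()
  )
}

.empty_quadrats <- function() {
  tibble::tibble(
    site = character(), habitat = character(), depth_m = numeric(),
    year = integer(), quadrat_id = character(), life_stage = character(),
    colony_count = integer()
  )
}

.empty_colonies <- function() {
  tibble::tibble(
    site = character(), habitat = character(), year = integer(),
    diameter_cm = numeric()
  )
}

.empty_points <- function() {
  tibble::tibble(
    image_id = character(), site = character(), habitat = character(),
    depth_m = numeric(), year = integer(), category = character(),
    points = integer()
  )
}

.empty_grids <- function() {
  tibble::tibble(
    image_id = character(), site = character(), habitat = character(),
    year = integer(), category = character(), cells = integer()
  )
}

.empty_fecundity <- function() {
  tibble::tibble(
    study = character(), taxon = character(), value = numeric(),
    unit = character()
  )
}

.empty_fertilization <- function() {
  tibble::tibble(
    study = character(), taxon = character(), n = integer(),
    success_fraction = numeric()
  )
}

#' Assemble and validate a survey dataset
#'
#' The container for one shore's census tables: settlement-tile recruit
#' counts, quadrat colony counts by life stage, colony diameters, and the two
#' photoquadrat scoring tables (random point counts and grid dominance
#' scores). Every record is validated against the schema invariants on
#' construction; violations are reported with 1-based row numbers.
#'
#' Point-count and grid-score tables are held in long form, one row per image
#' x benthic category; the per-image counts must sum to the sampler's
#' `points_per_image` and `grid_cells` respectively, because both scoring
#' schemes are exhaustive.
#'
#' @param habitats List of [habitat_spec()] objects.
#' @param sampler A [sampler_spec()].
#' @param tiles,quadrats,colonies,points,grids Census tables (data frames);
#'   omitted tables default to empty.
#' @param fecundity_studies,fertilization_studies Optional literature tables
#'   feeding the reproduction model.
#'
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(habitats, sampler = sampler_spec(),
                           tiles = .empty_tiles(), quadrats = .empty_quadrats(),
                           colonies = .empty_colonies(), points = .empty_points(),
                           grids = .empty_grids(),
                           fecundity_studies = .empty_fecundity(),
                           fertilization_studies = .empty_fertilization()) {
  if (inherits(habitats, "habitat_spec")) habitats <- list(habitats)
  if (!length(habitats) || !all(vapply(habitats, inherits, logical(1), "habitat_spec"))) {
    .abort("habitats must be a list of habitat_spec objects")
  }
  names(habitats) <- vapply(habitats, `[[`, character(1), "name")
  if (anyDuplicated(names(habitats))) .abort("duplicate habitat names")
  if (!inherits(sampler, "sampler_spec")) .abort("sampler must be a sampler_spec")

  ds <- structure(
    list(
      habitats = habitats, sampler = sampler,
      tiles = tibble::as_tibble(tiles), quadrats = tibble::as_tibble(quadrats),
      colonies = tibble::as_tibble(colonies), points = tibble::as_tibble(points),
      grids = tibble::as_tibble(grids),
      fecundity_studies = tibble::as_tibble(fecundity_studies),
      fertilization_studies = tibble::as_tibble(fertilization_studies)
    ),
    class = "survey_dataset"
  )
  validate_survey_dataset(ds)
}

#' Validate a survey dataset against its schema invariants
#'
#' Checks column presence, value invariants (non-negative counts, positive
#' diameters, period and life-stage vocabularies, per-image count sums), and
#' that every record's habitat matches a declared [habitat_spec()]. Errors
#' cite the table and the 1-based row numbers of offending rows.
#'
#' @param ds A `survey_dataset`.
#' @return `ds`, invisibly usable, after passing all checks.
#' @export
validate_survey_dataset <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  hab_names <- names(ds$habitats)
  check_habitat <- function(df, what) {
    .check_rows(df, df$habitat %in% hab_names, what,
                "habitat must match a configured habitat_spec")
  }

  .check_columns(ds$tiles, names(.empty_tiles()), "tile_census")
  .check_rows(ds$tiles, .is_count(ds$tiles$recruit_count), "tile_census",
              "recruit_count must be a non-negative integer")
  .check_rows(ds$tiles, ds$tiles$period %in% c("early", "late"), "tile_census",
              "period must be 'early' or 'late'")
  check_habitat(ds$tiles, "tile_census")

  .check_columns(ds$quadrats, names(.empty_quadrats()), "quadrat_census")
  .check_rows(ds$quadrats, .is_count(ds$quadrats$colony_count), "quadrat_census",
              "colony_count must be a non-negative integer")
  .check_rows(ds$quadrats, ds$quadrats$life_stage %in% c("juvenile", "all"),
              "quadrat_census", "life_stage must be 'juvenile' or 'all'")
  check_habitat(ds$quadrats, "quadrat_census")

  .check_columns(ds$colonies, names(.empty_colonies()), "colony_sizes")
  .check_rows(ds$colonies,
              is.finite(ds$colonies$diameter_cm) & ds$colonies$diameter_cm > 0,
              "colony_sizes", "diameter_cm must be positive")
  check_habitat(ds$colonies, "colony_sizes")

  .check_columns(ds$points, names(.empty_points()), "point_counts")
  .check_rows(ds$points, .is_count(ds$points$points), "point_counts",
              "points must be a non-negative integer")
  check_habitat(ds$points, "point_counts")
  if (nrow(ds$points) > 0) {
    sums <- tapply(ds$points$points, ds$points$image_id, sum)
    bad <- names(sums)[sums != ds$sampler$points_per_image]
    if (length(bad) > 0) {
      .abort("point_counts: per-image points must sum to ",
             ds$sampler$points_per_image, "; violated for image ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
  }

  .check_columns(ds$grids, names(.empty_grids()), "grid_scores")
  .check_rows(ds$grids, .is_count(ds$grids$cells), "grid_scores",
              "cells must be a non-negative integer")
  check_habitat(ds$grids, "grid_scores")
  if (nrow(ds$grids) > 0) {
    sums <- tapply(ds$grids$cells, ds$grids$image_id, sum)
    bad <- names(sums)[sums != ds$sampler$grid_cells]
    if (length(bad) > 0) {
      .abort("grid_scores: per-image cells must sum to ", ds$sampler$grid_cells,
             "; violated for image ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }

  .check_columns(ds$fecundity_studies, c("study", "value", "unit"), "fecundity_studies")
  if (nrow(ds$fecundity_studies) > 0) {
    .check_rows(ds$fecundity_studies,
                is.finite(ds$fecundity_studies$value) & ds$fecundity_studies$value > 0,
                "fecundity_studies", "value must be positive")
    .check_rows(ds$fecundity_studies,
                ds$fecundity_studies$unit %in% c("eggs_per_polyp", "eggs_per_cm2_per_yr"),
                "fecundity_studies", "unit must be eggs_per_polyp or eggs_per_cm2_per_yr")
  }
  .check_columns(ds$fertilization_studies, c("study", "success_fraction"),
                 "fertilization_studies")
  if (nrow(ds$fertilization_studies) > 0) {
    sf <- ds$fertilization_studies$success_fraction
    .check_rows(ds$fertilization_studies, is.finite(sf) & sf >= 0 & sf <= 1,
                "fertilization_studies", "success_fraction must lie in [0, 1]")
  }
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat("  habitats: ", paste(names(x$habitats), collapse = ", "), "\n", sep = "")
  for (tab in c("tiles", "quadrats", "colonies", "points", "grids")) {
    cat(sprintf("  %-9s %d records\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

# Reading ----------------------------------------------------------------

.read_table <- function(path, cols, what) {
  if (!file.exists(path)) .abort(what, ": file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, cols, what)
  tibble::as_tibble(df[cols])
}

#' Read a survey dataset from CSV tables
#'
#' Reads any subset of the census tables (comma-separated, UTF-8, header row,
#' `.` decimal) and assembles a validated [survey_dataset()]. Habitat areas
#' and sampler geometry come from `config`, either a YAML file path (see
#' [read_pipeline_config()]) or an equivalent nested list such as
#' [moorea_config()].
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   `tiles`, `quadrats`, `colonies`, `points`, `grids`,
#'   `fecundity_studies`, `fertilization_studies`. Omitted tables are empty.
#' @param config Pipeline configuration (path or list).
#' @return A validated `survey_dataset`.
#' @export
read_survey_dataset <- function(paths, config) {
  config <- as_pipeline_config(config)
  paths <- as.list(paths)
  known <- c("tiles", "quadrats", "colonies", "points", "grids",
             "fecundity_studies", "fertilization_studies")
  unknown <- setdiff(names(paths), known)
  if (length(unknown) > 0) {
    .abort("unrecognised table name", if (length(unknown) > 1) "s" else "",
           ": ", paste(sQuote(unknown), collapse = ", "))
  }
  grab <- function(name, cols, what, empty) {
    if (is.null(paths[[name]])) return(empty)
    .read_table(paths[[name]], cols, what)
  }
  survey_dataset(
    habitats = config$habitats,
    sampler = config$sampler,
    tiles = grab("tiles", names(.empty_tiles()), "tile_census", .empty_tiles()),
    quadrats = grab("quadrats", names(.empty_quadrats()), "quadrat_census", .empty_quadrats()),
    colonies = grab("colonies", names(.empty_colonies()), "colony_sizes", .empty_colonies()),
    points = grab("points", names(.empty_points()), "point_counts", .empty_points()),
    grids = grab("grids", names(.empty_grids()), "grid_scores", .empty_grids()),
    fecundity_studies = grab("fecundity_studies",
                             c("study", "taxon", "value", "unit"),
                             "fecundity_studies", .empty_fecundity()),
    fertilization_studies = grab("fertilization_studies",
                                 c("study", "taxon", "n", "success_fraction"),
                                 "fertilization_studies", .empty_fertilization())
  )
}

#' Write a survey dataset to CSV tables
#'
#' Inverse of [read_survey_dataset()]: writes one CSV per non-empty table
#' into `dir` using the canonical file names, so the output can be read back
#' with the same configuration. Content is deterministic for a fixed dataset.
#'
#' @param ds A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_survey_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "survey_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    tiles = "tile_census.csv", quadrats = "quadrat_census.csv",
    colonies = "colony_sizes.csv", points = "point_counts.csv",
    grids = "grid_scores.csv", fecundity_studies = "fecundity_studies.csv",
    fertilization_studies = "fertilization_studies.csv"
  )
  written <- character(0)
  for (tab in names(files)) {
    df <- ds[[tab]]
    if (nrow(df) == 0) next
    path <- file.path(dir, files[[tab]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written[tab] <- path
  }
  written
}
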