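#' Aggregate period-level densities to annual habitat densities
#'
#' The aggregation path used for all density summaries, applied to densities
#' rather than raw counts so that published site or depth means can be fed in
#' directly. Within each habitat-year the order is fixed: sum densities over
#' sampling periods within a site x depth cell, then average across sites
#' within a depth, then average across depths. Levels that are absent (e.g.,
#' no depth stratification in the back reef) collapse harmlessly.
#'
#' Periods may be `"early"` (Jan/Feb), `"late"` (Aug/Sep), or `"annual"` for
#' densities already summed over the year. A habitat-year seeing only one of
#' the two field periods is flagged `partial`, because the annual estimate is
#' defined as the sum of exactly two samplings.
#'
#' @param densities Tibble with columns `habitat`, `year`, `period`,
#'   `density`, and optionally `site` and `depth_m`.
#' @param life_stage Life-stage label attached to the output.
#' @param sampler_area_cm2 Area (cm2) to which the densities are referenced.
#' @return A tibble with one row per habitat-year: `habitat`, `year`,
#'   `life_stage`, `density`, `sampler_area_cm2`, `n_values`, `partial`, and
#'   a `trace` list-column recording the per-level means.
#' @examples
#' # Outer-reef recruit densities: period sums 3.58 and 2.99 average to 3.285
#' d <- tibble::tibble(
#'   habitat = "outer_reef", year = 2010L, site = "m",
#'   depth_m = c(10, 10, 17, 17), period = c("early", "late", "early", "late"),
#'   density = c(0.21, 3.37, 0.93, 2.06)
#' )
#' annual_density_from_period_means(d, "recruit", 225)$density
#' @export
annual_density_from_period_means <- function(densities, life_stage = "recruit",
                                             sampler_area_cm2 = 225) {
  .check_columns(densities, c("habitat", "year", "period", "density"), "densities")
  if (nrow(densities) == 0) .abort("no densities supplied")
  bad <- !densities$period %in% c("early", "late", "annual")
  .check_rows(densities, !bad, "densities", "period must be early, late, or annual")
  if (!"site" %in% names(densities)) densities$site <- "all"
  if (!"depth_m" %in% names(densities)) densities$depth_m <- NA_real_

  per_cell <- densities |>
    dplyr::group_by(.data$habitat, .data$year, .data$depth_m, .data$site) |>
    dplyr::summarise(
      annual = sum(.data$density),
      n_periods = dplyr::n_distinct(.data$period),
      partial = all(.data$period %in% c("early", "late")) &&
        dplyr::n_distinct(.data$period) < 2,
      .groups = "drop"
    )
  per_depth <- per_cell |>
    dplyr::group_by(.data$habitat, .data$year, .data$depth_m) |>
    dplyr::summarise(
      site_mean = mean(.data$annual),
      n_sites = dplyr::n(),
      partial = any(.data$partial),
      .groups = "drop"
    )
  out <- per_depth |>
    dplyr::group_by(.data$habitat, .data$year) |>
    dplyr::summarise(
      density = mean(.data$site_mean),
      n_values = sum(.data$n_sites),
      partial = any(.data$partial),
      .groups = "drop"
    ) |>
    dplyr::mutate(life_stage = life_stage, sampler_area_cm2 = sampler_area_cm2) |>
    dplyr::select("habitat", "year", "life_stage", "density",
                  "sampler_area_cm2", "n_values", "partial")
  traces <- lapply(seq_len(nrow(out)), function(i) {
    h <- out$habitat[i]; y <- out$year[i]
    list(
      site_annual = per_cell[per_cell$habitat == h & per_cell$year == y, ],
      depth_means = per_depth[per_depth$habitat == h & per_depth$year == y, ]
    )
  })
  out$trace <- traces
  out
}

#' Annual recruit density from settlement-tile counts
#'
#' Converts raw per-tile recruit counts into annual recruit densities per
#' tile scoring area for each habitat-year. Under `"simple"` weighting, tile
#' counts are first averaged per site x depth x period, period means are
#' summed to an annual density, and the result is averaged across sites and
#' then depths. Under `"pooled"` weighting the per-period density is total
#' recruits / total tiles across all sites and depths; the two agree exactly
#' when effort is balanced.
#'
#' @param tiles Tile census records (the `tiles` table of a
#'   [survey_dataset()]), any number of habitat-years.
#' @param sampler A [sampler_spec()].
#' @param weighting `"simple"` (mean of site means; the default) or
#'   `"pooled"` (count-weighted).
#' @return A density tibble as from [annual_density_from_period_means()],
#'   one row per habitat-year, `life_stage = "recruit"`.
#' @export
annual_recruit_density <- function(tiles, sampler = sampler_spec(),
                                   weighting = c("simple", "pooled")) {
  weighting <- match.arg(weighting)
  .check_columns(tiles, names(.empty_tiles()), "tile_census")
  if (nrow(tiles) == 0) .abort("no tile records supplied")
  .check_rows(tiles, tiles$period %in% c("early", "late"), "tile_census",
              "period must be 'early' or 'late'")
  if (weighting == "simple") {
    period_means <- tiles |>
      dplyr::group_by(.data$habitat, .data$year, .data$depth_m, .data$site,
                      .data$period) |>
      dplyr::summarise(density = mean(.data$recruit_count), .groups = "drop")
  } else {
    period_means <- tiles |>
      dplyr::group_by(.data$habitat, .data$year, .data$period) |>
      dplyr::summarise(density = sum(.data$recruit_count) / dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(site = "pooled", depth_m = NA_real_)
  }
  out <- annual_density_from_period_means(
    period_means, life_stage = "recruit",
    sampler_area_cm2 = sampler$tile_scoring_area_cm2
  )
  n_tiles <- tiles |>
    dplyr::count(.data$habitat, .data$year, name = "n_values")
  out$n_values <- n_tiles$n_values[match(
    paste(out$habitat, out$year), paste(n_tiles$habitat, n_tiles$year)
  )]
  out
}

#' Mean colony density from quadrat counts
#'
#' Summarises quadrat colony counts into a mean density per quadrat area for
#' each habitat-year and life stage. Under `"simple"` weighting, counts are
#' averaged per quadrat within site (within depth where stratified), then
#' across sites and depths; under `"pooled"`, the density is total colonies /
#' total quadrats.
#'
#' @param quadrats Quadrat census records (`quadrats` table of a
#'   [survey_dataset()]).
#' @inheritParams annual_recruit_density
#' @return A density tibble, one row per habitat-year-stage, with
#'   `life_stage` `"juvenile"` or `"all_colonies"` and
#'   `sampler_area_cm2` the quadrat area.
#' @export
mean_quadrat_density <- function(quadrats, sampler = sampler_spec(),
                                 weighting = c("simple", "pooled")) {
  weighting <- match.arg(weighting)
  .check_columns(quadrats, names(.empty_quadrats()), "quadrat_census")
  if (nrow(quadrats) == 0) .abort("no quadrat records supplied")
  stage_out <- function(stage_in, stage_label) {
    df <- quadrats[quadrats$life_stage == stage_in, ]
    if (nrow(df) == 0) return(NULL)
    if (weighting == "simple") {
      means <- df |>
        dplyr::group_by(.data$habitat, .data$year, .data$depth_m, .data$site) |>
        dplyr::summarise(density = mean(.data$colony_count), .groups = "drop") |>
        dplyr::mutate(period = "annual")
    } else {
      means <- df |>
        dplyr::group_by(.data$habitat, .data$year) |>
        dplyr::summarise(density = sum(.data$colony_count) / dplyr::n(),
                         .groups = "drop") |>
        dplyr::mutate(site = "pooled", depth_m = NA_real_, period = "annual")
    }
    out <- annual_density_from_period_means(
      means, life_stage = stage_label,
      sampler_area_cm2 = sampler$quadrat_area_cm2
    )
    n_q <- df |> dplyr::count(.data$habitat, .data$year, name = "n_values")
    out$n_values <- n_q$n_values[match(
      paste(out$habitat, out$year), paste(n_q$habitat, n_q$year)
    )]
    out
  }
  dplyr::bind_rows(
    stage_out("juvenile", "juvenile"),
    stage_out("all", "all_colonies")
  )
}

#' Scale sampler densities to habitat-wide abundances
#'
#' Converts a density per sampler area into a count of individuals over a
#' habitat's hard-bottom area: `abundance = density / sampler_area_cm2 *
#' hard_bottom_area_cm2`. This assumes the sampled density is representative
#' of all hard bottom in the habitat.
#'
#' @param densities A density tibble (from [annual_recruit_density()],
#'   [mean_quadrat_density()], or [annual_density_from_period_means()]).
#' @param habitats A named list of [habitat_spec()], a single `habitat_spec`,
#'   or a pipeline config.
#' @return The input with `hard_bottom_area_km2` and `abundance` columns
#'   appended.
#' @examples
#' d <- tibble::tibble(habitat = "back_reef", year = 2010L,
#'                     life_stage = "recruit", density = 0.38,
#'                     sampler_area_cm2 = 225)
#' scale_to_habitat(d, moorea_config()$habitats)$abundance # ~7.74e7
#' @export
scale_to_habitat <- function(densities, habitats) {
  if (inherits(habitats, "habitat_spec")) {
    habitats <- stats::setNames(list(habitats), habitats$name)
  }
  if (is.list(habitats) && !is.null(habitats$habitats)) habitats <- habitats$habitats
  .check_columns(densities, c("habitat", "density", "sampler_area_cm2"), "densities")
  unknown <- setdiff(unique(densities$habitat), names(habitats))
  if (length(unknown) > 0) {
    .abort("habitat", if (length(unknown) > 1) "s" else "", " ",
           paste(sQuote(unknown), collapse = ", "), " not found in habitat specs")
  }
  if (any(densities$density < 0)) .abort("densities must be non-negative")
  if (any(densities$sampler_area_cm2 <= 0)) .abort("sampler_area_cm2 must be positive")
  areas <- vapply(habitats, `[[`, numeric(1), "hard_bottom_area_cm2")
  if (any(areas <= 0)) .abort("habitat areas must be positive")
  densities |>
    dplyr::mutate(
      hard_bottom_area_km2 = vapply(habitats[.data$habitat], `[[`, numeric(1),
                                    "hard_bottom_area_km2"),
      abundance = .data$density / .data$sampler_area_cm2 *
        unname(areas[.data$habitat])
    )
}

#' Fold change between two density or abundance estimates
#'
#' Ratio of a later to an earlier estimate of the same quantity. Scalars are
#' divided directly; single-row density/abundance tibbles are checked for
#' matching habitat, life stage, and sampler area before their densities (or
#' abundances, if `on = "abundance"`) are compared.
#'
#' @param later,earlier Numeric scalars, or single-row tibbles from the
#'   density/abundance functions.
#' @param on For tibble inputs: compare `"density"` (default) or
#'   `"abundance"`.
#' @return The ratio later/earlier.
#' @examples
#' fold_change(0.80, 0.10) # 8
#' @export
fold_change <- function(later, earlier, on = c("density", "abundance")) {
  on <- match.arg(on)
  pick <- function(x) {
    if (is.numeric(x) && length(x) == 1) return(x)
    if (is.data.frame(x) && nrow(x) == 1 && on %in% names(x)) return(x[[on]])
    .abort("fold_change expects numeric scalars or single-row estimate tibbles")
  }
  if (is.data.frame(later) && is.data.frame(earlier)) {
    for (col in c("habitat", "life_stage", "sampler_area_cm2")) {
      if (col %in% names(later) && col %in% names(earlier) &&
          !identical(later[[col]][1], earlier[[col]][1])) {
        .abort("fold_change: ", col, " differs between estimates (",
               later[[col]][1], " vs ", earlier[[col]][1], ")")
      }
    }
  }
  a <- pick(later); b <- pick(earlier)
  if (!is.finite(b) || b <= 0) {
    .abort("fold_change: earlier value must be positive (undefined baseline)")
  }
  a / b
}
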