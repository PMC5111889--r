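#' Self-seeding scenario assumptions
#'
#' The scenario parameters of the feasibility assessment: the assumed
#' fraction of produced larvae that fail to recruit locally (an assumption,
#' not an estimate, so it is swept over a grid), and whether production is
#' compared with recruitment of the same year or the following year.
#'
#' @param larval_loss_fraction Fraction of larvae lost before local
#'   recruitment, in \[0, 1); default 0.999 (~99.9% loss).
#' @param loss_grid Loss fractions over which the sufficiency ratio is swept.
#' @param year_matching `"same"` (default) or `"lag1"`.
#' @return An object of class `self_seeding_scenario`.
#' @export
self_seeding_scenario <- function(larval_loss_fraction = 0.999,
                                  loss_grid = c(0.9, 0.99, 0.999),
                                  year_matching = c("same", "lag1")) {
  year_matching <- match.arg(year_matching)
  check_loss <- function(x) {
    if (any(!is.finite(x)) || any(x < 0) || any(x >= 1)) {
      .abort("larval loss fractions must lie in [0, 1)")
    }
  }
  check_loss(larval_loss_fraction)
  check_loss(loss_grid)
  structure(
    list(larval_loss_fraction = larval_loss_fraction,
         loss_grid = sort(unique(c(loss_grid, larval_loss_fraction))),
         year_matching = year_matching),
    class = "self_seeding_scenario"
  )
}

#' Larvae required to account for observed recruits
#'
#' Inverts the loss assumption: if a fraction `L` of larvae fail to recruit
#' locally, producing `R` recruits requires `R / (1 - L)` larvae. Linear in
#' recruits and strictly increasing in the loss fraction.
#'
#' @param recruits Observed recruit count (shore-wide).
#' @param scenario A [self_seeding_scenario()], or a bare loss fraction.
#' @return Required larvae.
#' @examples
#' required_larvae(5.05e8, 0.999) # 5.05e11
#' @export
required_larvae <- function(recruits, scenario = self_seeding_scenario()) {
  loss <- if (inherits(scenario, "self_seeding_scenario")) {
    scenario$larval_loss_fraction
  } else {
    scenario
  }
  if (any(!is.finite(loss)) || any(loss < 0) || any(loss >= 1)) {
    .abort("larval loss fraction must lie in [0, 1)")
  }
  if (any(recruits < 0)) .abort("recruits must be non-negative")
  recruits / (1 - loss)
}

#' Sufficiency ratio of larval production
#'
#' Ratio of larvae produced to larvae required; a value above 1 means the
#' populations produced an excess of larvae relative to the observed
#' recruitment under the loss assumption.
#'
#' @param produced Larvae produced (zygotes).
#' @param required Larvae required (from [required_larvae()]); must be > 0.
#' @return Dimensionless ratio.
#' @export
sufficiency_ratio <- function(produced, required) {
  if (any(!is.finite(required)) || any(required <= 0)) {
    .abort("sufficiency ratio undefined: required larvae must be positive")
  }
  if (any(produced < 0)) .abort("produced larvae must be non-negative")
  produced / required
}

#' Apparent recruit-to-juvenile survival
#'
#' Fraction of one year's recruits that would have to survive to produce the
#' observed juvenile abundance. Values above 1 are biologically implausible
#' (juveniles cannot outnumber the recruits that produced them) and are
#' returned as-is but flagged via the `"implausible"` attribute, never
#' clamped.
#'
#' @param juveniles Observed juvenile abundance.
#' @param recruits Observed recruit abundance; must be > 0.
#' @return Survival fraction with attribute `implausible`.
#' @export
recruit_to_juvenile_survival <- function(juveniles, recruits) {
  if (any(!is.finite(recruits)) || any(recruits <= 0)) {
    .abort("survival undefined: recruits must be positive")
  }
  if (any(juveniles < 0)) .abort("juveniles must be non-negative")
  out <- juveniles / recruits
  attr(out, "implausible") <- out > 1
  out
}

#' Assemble the self-seeding feasibility report
#'
#' Combines shore-wide abundances, the egg/zygote chains, and optional Monte
#' Carlo summaries into the four-stage demographic report
#' (zygotes/larvae -> recruits -> juveniles -> colonies). Production and
#' requirement are totalled across habitats within each production year, so
#' a habitat with no mature colonies contributes zero production and the
#' assessment rests on the remaining habitats. Missing stages are reported
#' as explicit `NA` gaps (and listed in `$flags`), never as silent zeros.
#'
#' @param abundances Abundance tibble from [scale_to_habitat()] (columns
#'   `habitat`, `year`, `life_stage`, `abundance`), possibly spanning
#'   several habitat-years.
#' @param reproduction Tibble with one row per habitat-year of the egg
#'   chain: `habitat`, `year`, `eggs_per_year`, `zygotes_per_year`, and
#'   optionally `prop_mature`, `mean_mature_diameter_cm`, `n_colonies`.
#' @param mc Optional tibble of Monte Carlo summaries keyed by `habitat`,
#'   `year` (as from [propagate_larval_production()] summaries bound
#'   together).
#' @param scenario A [self_seeding_scenario()].
#' @details Surveys conducted shortly after a focal year (e.g., a January
#'   census representing the previous season) should be assigned to the
#'   focal year before calling this function; the report compares production
#'   and recruitment within the `year` labels it is given.
#' @return An object of class `self_seeding_report`: list with
#'   `by_habitat`, `by_year`, `loss_sweep`, `abundances`, `reproduction`,
#'   `mc`, `scenario`, `flags`.
#' @export
build_report <- function(abundances, reproduction, mc = NULL,
                         scenario = self_seeding_scenario()) {
  .check_columns(abundances, c("habitat", "year", "life_stage", "abundance"),
                 "abundances")
  .check_columns(reproduction, c("habitat", "year", "eggs_per_year", "zygotes_per_year"),
                 "reproduction")
  ab_keys <- unique(paste(abundances$habitat, abundances$year))
  rp_keys <- unique(paste(reproduction$habitat, reproduction$year))
  orphan <- setdiff(rp_keys, ab_keys)
  if (length(orphan) > 0) {
    .abort("reproduction rows with no matching abundance estimate: ",
           paste(orphan, collapse = ", "))
  }
  flags <- character(0)

  wide <- abundances |>
    dplyr::select("habitat", "year", "life_stage", "abundance") |>
    tidyr::pivot_wider(names_from = "life_stage", values_from = "abundance")
  for (stage in c("recruit", "juvenile", "all_colonies")) {
    if (!stage %in% names(wide)) wide[[stage]] <- NA_real_
  }
  by_habitat <- wide |>
    dplyr::full_join(
      dplyr::select(reproduction, dplyr::any_of(c(
        "habitat", "year", "eggs_per_year", "zygotes_per_year",
        "prop_mature", "mean_mature_diameter_cm"
      ))),
      by = c("habitat", "year")
    ) |>
    dplyr::rename(
      recruits_observed = "recruit", juveniles_observed = "juvenile",
      colonies_observed = "all_colonies", larvae_produced = "zygotes_per_year"
    ) |>
    dplyr::arrange(.data$year, .data$habitat)
  for (col in c("recruits_observed", "juveniles_observed", "colonies_observed",
                "larvae_produced")) {
    gaps <- is.na(by_habitat[[col]])
    if (any(gaps)) {
      flags <- c(flags, paste0(
        col, " missing for ",
        paste(by_habitat$habitat[gaps], by_habitat$year[gaps], collapse = "; ")
      ))
    }
  }

  # Whole-shore totals by production year; NA components propagate as gaps.
  by_year <- by_habitat |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      larvae_produced = sum(.data$larvae_produced),
      recruits_observed = sum(.data$recruits_observed),
      juveniles_observed = sum(.data$juveniles_observed),
      colonies_observed = sum(.data$colonies_observed),
      .groups = "drop"
    )
  recruit_year <- if (scenario$year_matching == "lag1") by_year$year - 1L else by_year$year
  matched_recruits <- by_year$recruits_observed[match(recruit_year, by_year$year)]
  by_year <- by_year |>
    dplyr::mutate(
      larvae_required = ifelse(is.na(matched_recruits), NA_real_,
                               required_larvae(matched_recruits, scenario)),
      sufficiency_ratio = ifelse(
        !is.na(.data$larvae_required) & .data$larvae_required > 0 &
          !is.na(.data$larvae_produced),
        .data$larvae_produced / .data$larvae_required, NA_real_
      ),
      recruit_to_juvenile_survival = ifelse(
        !is.na(.data$recruits_observed) & .data$recruits_observed > 0 &
          !is.na(.data$juveniles_observed),
        .data$juveniles_observed / .data$recruits_observed, NA_real_
      )
    )
  implausible <- !is.na(by_year$recruit_to_juvenile_survival) &
    by_year$recruit_to_juvenile_survival > 1
  if (any(implausible)) {
    flags <- c(flags, paste0(
      "recruit_to_juvenile_survival > 1 (implausible) in ",
      paste(by_year$year[implausible], collapse = ", ")
    ))
  }

  loss_sweep <- tidyr::crossing(
    dplyr::select(by_year, "year", "larvae_produced", "recruits_observed"),
    larval_loss_fraction = scenario$loss_grid
  ) |>
    dplyr::mutate(
      larvae_required = ifelse(
        is.na(.data$recruits_observed), NA_real_,
        .data$recruits_observed / (1 - .data$larval_loss_fraction)
      ),
      sufficiency_ratio = ifelse(
        !is.na(.data$larvae_required) & .data$larvae_required > 0 &
          !is.na(.data$larvae_produced),
        .data$larvae_produced / .data$larvae_required, NA_real_
      )
    )

  structure(
    list(by_habitat = by_habitat, by_year = by_year, loss_sweep = loss_sweep,
         abundances = abundances, reproduction = reproduction, mc = mc,
         scenario = scenario, flags = flags),
    class = "self_seeding_report"
  )
}

#' @export
print.self_seeding_report <- function(x, ...) {
  cat("<self_seeding_report>\n")
  cat(sprintf("  loss assumption: %.3g%% of larvae fail to recruit locally\n",
              100 * x$scenario$larval_loss_fraction))
  df <- x$by_year
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %d: produced %s larvae, required %s; sufficiency %s; recruit->juvenile survival %s\n",
      df$year[i], .fmt(df$larvae_produced[i]), .fmt(df$larvae_required[i]),
      .fmt(df$sufficiency_ratio[i]), .fmt(df$recruit_to_juvenile_survival[i])
    ))
  }
  if (length(x$flags) > 0) {
    cat("  flags:\n")
    for (f in x$flags) cat("   - ", f, "\n", sep = "")
  }
  invisible(x)
}

.fmt <- function(x) {
  if (length(x) != 1 || is.na(x)) "NA" else format(signif(x, 3), big.mark = ",")
}

#' Write the report tables to disk
#'
#' Writes the abundance, reproduction, Monte Carlo, per-habitat, per-year,
#' and loss-sweep tables as CSV, plus a human-readable `summary.txt`
#' rendered at 3 significant figures. Output is byte-identical for a fixed
#' report.
#'
#' @param report A [build_report()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "self_seeding_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) .abort("cannot create output directory: ", out_dir)
  drop_list_cols <- function(df) df[!vapply(df, is.list, logical(1))]
  tabs <- list(
    abundance_summary = drop_list_cols(report$abundances),
    reproduction_summary = report$reproduction,
    self_seeding_by_habitat = report$by_habitat,
    self_seeding_by_year = report$by_year,
    loss_sweep = report$loss_sweep
  )
  if (!is.null(report$mc)) tabs$mc_summary <- report$mc
  written <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], path, row.names = FALSE, quote = FALSE)
    written <- c(written, path)
  }
  txt <- file.path(out_dir, "summary.txt")
  con <- file(txt, open = "wt")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  written <- c(written, txt)
  written
}
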