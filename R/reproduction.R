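#' Power-law diameter-to-tissue-area calibration
#'
#' Constructs the allometric model `area = a * diameter^b` relating colony
#' diameter (cm) to live tissue surface area (cm2). The defaults are the
#' wax-dipping calibration for P. verrucosa from 10 m depth in Moorea
#' (a = 2.493, b = 2.312, r2 = 0.986 on the log-log regression).
#'
#' @param coefficient_a Scale factor (cm2 at 1 cm diameter); positive.
#' @param exponent_b Allometric exponent; positive.
#' @param r_squared Fit quality of the calibration regression, in \[0, 1\].
#' @param b_ci Optional 95% confidence interval for the exponent (length-2),
#'   populated by [fit_allometry()].
#' @param n Number of calibration pairs, if known.
#' @return An object of class `allometry_model`.
#' @export
allometry_model <- function(coefficient_a = 2.493, exponent_b = 2.312,
                            r_squared = 0.986, b_ci = NULL, n = NA_integer_) {
  if (!is.numeric(coefficient_a) || coefficient_a <= 0) .abort("coefficient_a must be > 0")
  if (!is.numeric(exponent_b) || exponent_b <= 0) .abort("exponent_b must be > 0")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    .abort("r_squared must lie in [0, 1]")
  }
  structure(
    list(coefficient_a = coefficient_a, exponent_b = exponent_b,
         r_squared = r_squared, b_ci = b_ci, n = n),
    class = "allometry_model"
  )
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("<allometry_model> area = %.4g * diameter^%.4g (r2 = %.3f)\n",
              x$coefficient_a, x$exponent_b, x$r_squared))
  invisible(x)
}

#' Tissue area of a colony from its diameter
#'
#' Evaluates the allometric calibration `a * diameter^b`, giving live tissue
#' area in cm2 for a colony diameter in cm.
#'
#' @param diameter_cm Colony diameter(s) in cm; must be positive.
#' @param model An [allometry_model()].
#' @return Tissue area(s) in cm2.
#' @examples
#' tissue_area(22.3) # ~3268 cm2 for the default Moorea calibration
#' @export
tissue_area <- function(diameter_cm, model = allometry_model()) {
  if (!is.numeric(diameter_cm) || length(diameter_cm) == 0 ||
      any(!is.finite(diameter_cm)) || any(diameter_cm <= 0)) {
    .abort("diameter_cm must be positive")
  }
  model$coefficient_a * diameter_cm^model$exponent_b
}

#' Fit the diameter-to-tissue-area allometry
#'
#' Least-squares fit of `log(area)` on `log(diameter)`; the back-transformed
#' intercept gives the scale factor `a`, the slope gives the exponent `b`,
#' and r2 is that of the log-log regression. The fitted 95% confidence
#' interval for `b` is attached for parameter-recovery checks.
#'
#' @param diameter_cm,area_cm2 Paired positive measurements (>= 3 pairs).
#' @return An [allometry_model()] with `b_ci` and `n` populated.
#' @export
fit_allometry <- function(diameter_cm, area_cm2) {
  if (length(diameter_cm) != length(area_cm2)) .abort("inputs must have equal length")
  if (length(diameter_cm) < 3) .abort("at least 3 calibration pairs are required")
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0) ||
      any(!is.finite(area_cm2)) || any(area_cm2 <= 0)) {
    .abort("all diameters and areas must be positive")
  }
  fit <- stats::lm(log(area_cm2) ~ log(diameter_cm))
  co <- stats::coef(fit)
  # summary.lm warns on exact power-law data ("essentially perfect fit");
  # exact recovery is a supported input here, not a numerical accident
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # a perfect fit leaves r.squared fractionally above 1 in floating point
  r2 <- min(max(r2, 0), 1)
  ci <- tryCatch(suppressWarnings(stats::confint(fit)[2, ]), error = function(e) NULL)
  allometry_model(
    coefficient_a = unname(exp(co[1])), exponent_b = unname(co[2]),
    r_squared = r2, b_ci = ci, n = length(diameter_cm)
  )
}

#' Pooled distribution of a reproductive rate
#'
#' A mean/SD summary of a quantity pooled over studies, used for fecundity
#' (eggs cm-2 y-1) and fertilization success (fraction). Constructed directly
#' when only the pooled values are published, or via [pooled_fecundity()] /
#' [pooled_fertilization()] from study-level values.
#'
#' @param mean Pooled mean.
#' @param sd Pooled sample SD (n-1 denominator); `NA` when only one study
#'   is available.
#' @param n_studies Number of pooled studies/observations.
#' @param unit Unit label for the pooled quantity.
#' @return An object of class `pooled_distribution`.
#' @export
pooled_distribution <- function(mean, sd, n_studies, unit = "") {
  if (!is.na(sd) && sd < 0) .abort("sd must be >= 0")
  if (n_studies < 1) .abort("n_studies must be >= 1")
  structure(
    list(mean = mean, sd = sd, n_studies = as.integer(n_studies), unit = unit),
    class = "pooled_distribution"
  )
}

#' @export
print.pooled_distribution <- function(x, ...) {
  cat(sprintf("<pooled_distribution> %.4g +/- %.4g%s (n = %d studies)\n",
              x$mean, x$sd, if (nzchar(x$unit)) paste0(" ", x$unit) else "", x$n_studies))
  invisible(x)
}

#' Pool literature fecundity estimates to a common per-area unit
#'
#' Converts per-polyp fecundities to area-normalised fecundity (eggs cm-2
#' y-1) by multiplying with the polyp density, then computes the mean and
#' sample SD over the converted study values. With the Moorea study table
#' ([moorea_fecundity_studies()]) and 66 polyps cm-2 this yields
#' 6,327 +/- 1,882 eggs cm-2 y-1.
#'
#' @param studies Tibble with columns `study`, `value`, `unit`
#'   (`eggs_per_polyp` or `eggs_per_cm2_per_yr`).
#' @param polyp_density_cm2 Polyps per cm2 of tissue used in the conversion.
#' @return A [pooled_distribution()] in eggs cm-2 y-1; `sd` is `NA` (with a
#'   warning) when only one study is supplied.
#' @export
pooled_fecundity <- function(studies, polyp_density_cm2 = 66) {
  .check_columns(studies, c("study", "value", "unit"), "fecundity_studies")
  if (nrow(studies) == 0) .abort("at least one fecundity study is required")
  unknown <- setdiff(unique(studies$unit), c("eggs_per_polyp", "eggs_per_cm2_per_yr"))
  if (length(unknown) > 0) {
    .abort("unknown fecundity unit: ", paste(sQuote(unknown), collapse = ", "))
  }
  if (any(studies$value <= 0)) .abort("fecundity values must be positive")
  if (polyp_density_cm2 <= 0) .abort("polyp_density_cm2 must be positive")
  converted <- ifelse(studies$unit == "eggs_per_polyp",
                      studies$value * polyp_density_cm2, studies$value)
  if (length(converted) == 1) {
    warning("single fecundity study: pooled SD undefined", call. = FALSE)
  }
  pooled_distribution(
    mean = mean(converted), sd = .sample_sd(converted),
    n_studies = length(converted), unit = "eggs_per_cm2_per_yr"
  )
}

#' Pool fertilization success fractions
#'
#' Mean and sample SD over per-observation fertilization success fractions.
#' When only the published pooled values are available (as for the Moorea
#' assessment, 0.15 +/- 0.21), construct a [pooled_distribution()] directly
#' instead.
#'
#' @param fractions Numeric vector of success fractions in \[0, 1\], or a
#'   tibble with a `success_fraction` column.
#' @return A [pooled_distribution()] (dimensionless fraction).
#' @export
pooled_fertilization <- function(fractions) {
  if (is.data.frame(fractions)) {
    .check_columns(fractions, "success_fraction", "fertilization_studies")
    fractions <- fractions$success_fraction
  }
  if (length(fractions) == 0) .abort("at least one fertilization observation is required")
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    .abort("fertilization fractions must lie in [0, 1]")
  }
  pooled_distribution(
    mean = mean(fractions), sd = .sample_sd(fractions),
    n_studies = length(fractions), unit = "fraction"
  )
}

#' Reproduction parameters for the larval-production chain
#'
#' Bundles the constants of the egg/zygote chain: the diameter at sexual
#' maturity (inclusive threshold), polyp density, pooled fecundity and
#' fertilization distributions, and the tissue-area allometry.
#'
#' @param maturity_threshold_cm Diameter (cm) at which colonies are counted
#'   as sexually mature (inclusive); default 14 cm.
#' @param polyp_density_cm2 Polyps per cm2 of tissue; default 66.
#' @param fecundity A [pooled_distribution()] in eggs cm-2 y-1; defaults to
#'   pooling [moorea_fecundity_studies()].
#' @param fertilization A [pooled_distribution()] as a fraction; default
#'   0.15 +/- 0.21.
#' @param allometry An [allometry_model()].
#' @return An object of class `reproduction_params`.
#' @export
reproduction_params <- function(maturity_threshold_cm = 14,
                                polyp_density_cm2 = 66,
                                fecundity = NULL,
                                fertilization = pooled_distribution(0.15, 0.21, 2, "fraction"),
                                allometry = allometry_model()) {
  if (maturity_threshold_cm <= 0) .abort("maturity_threshold_cm must be positive")
  if (polyp_density_cm2 <= 0) .abort("polyp_density_cm2 must be positive")
  if (is.null(fecundity)) {
    fecundity <- pooled_fecundity(moorea_fecundity_studies(), polyp_density_cm2)
  }
  stopifnot(inherits(fecundity, "pooled_distribution"),
            inherits(fertilization, "pooled_distribution"),
            inherits(allometry, "allometry_model"))
  if (fertilization$mean < 0 || fertilization$mean > 1) {
    .abort("fertilization mean must lie in [0, 1]")
  }
  structure(
    list(maturity_threshold_cm = maturity_threshold_cm,
         polyp_density_cm2 = polyp_density_cm2,
         fecundity = fecundity, fertilization = fertilization,
         allometry = allometry),
    class = "reproduction_params"
  )
}

# Build reproduction_params from the `reproduction` section of a config.
params_from_config <- function(config, fecundity_studies = NULL) {
  rp <- config$reproduction
  fec <- if (!is.null(fecundity_studies) && nrow(fecundity_studies) > 0) {
    pooled_fecundity(fecundity_studies, rp$polyp_density_cm2)
  } else {
    pooled_fecundity(moorea_fecundity_studies(), rp$polyp_density_cm2)
  }
  reproduction_params(
    maturity_threshold_cm = rp$maturity_threshold_cm,
    polyp_density_cm2 = rp$polyp_density_cm2,
    fecundity = fec,
    fertilization = pooled_distribution(rp$fertilization$mean, rp$fertilization$sd,
                                        rp$fertilization$n_studies, "fraction"),
    allometry = allometry_model(rp$allometry$coefficient_a, rp$allometry$exponent_b,
                                rp$allometry$r_squared)
  )
}

#' Classify colonies by sexual maturity
#'
#' Counts colonies at or above the maturity threshold diameter (the
#' threshold is inclusive) and computes the mean diameter of the mature
#' colonies, the representative colony size of the egg-production chain.
#'
#' @param colonies Numeric vector of diameters (cm) or a tibble with a
#'   `diameter_cm` column.
#' @param params A [reproduction_params()].
#' @return An object of class `maturity_summary`: `n_colonies`, `n_mature`,
#'   `prop_mature`, `mean_mature_diameter_cm` (`NA` when nothing is mature).
#' @examples
#' classify_maturity(c(14, 22), reproduction_params())$mean_mature_diameter_cm # 18
#' @export
classify_maturity <- function(colonies, params = reproduction_params()) {
  d <- if (is.data.frame(colonies)) {
    .check_columns(colonies, "diameter_cm", "colony_sizes")
    colonies$diameter_cm
  } else {
    colonies
  }
  if (length(d) == 0) .abort("at least one colony is required")
  if (any(!is.finite(d)) || any(d <= 0)) .abort("diameters must be positive")
  mature <- d >= params$maturity_threshold_cm
  structure(
    list(
      n_colonies = length(d),
      n_mature = sum(mature),
      prop_mature = mean(mature),
      mean_mature_diameter_cm = if (any(mature)) mean(d[mature]) else NA_real_
    ),
    class = "maturity_summary"
  )
}

#' @export
print.maturity_summary <- function(x, ...) {
  cat(sprintf("<maturity_summary> %d/%d mature (%.1f%%), mean mature diameter %s cm\n",
              x$n_mature, x$n_colonies, 100 * x$prop_mature,
              if (is.na(x$mean_mature_diameter_cm)) "NA"
              else sprintf("%.1f", x$mean_mature_diameter_cm)))
  invisible(x)
}

#' Annual egg output of a single colony
#'
#' Tissue area from the allometric calibration multiplied by the pooled mean
#' fecundity: `a * d^b * fecundity`. A mature 22.3-cm colony under the
#' Moorea defaults releases ~2.07e7 eggs per year.
#'
#' @param diameter_cm Colony diameter(s), cm.
#' @param params A [reproduction_params()].
#' @return Eggs per year.
#' @export
colony_egg_output <- function(diameter_cm, params = reproduction_params()) {
  tissue_area(diameter_cm, params$allometry) * params$fecundity$mean
}

#' Annual egg output of a population
#'
#' Scales the egg output of a representative mature colony to the population:
#' `abundance * prop_mature * colony_egg_output(mean_mature_diameter)`. When
#' no colony is mature the output is zero. With `method = "integrate"` and a
#' full diameter census, the per-colony expectation is instead averaged over
#' all censused colonies (mature ones contributing their individual outputs),
#' a sensitivity variant that drops the representative-colony simplification.
#'
#' @param abundance Number of colonies in the habitat (all sizes).
#' @param maturity A [classify_maturity()] summary, or a list with
#'   `prop_mature` and `mean_mature_diameter_cm`.
#' @param params A [reproduction_params()].
#' @param method `"representative"` (default) or `"integrate"`.
#' @param diameters Full diameter census (cm), required for
#'   `method = "integrate"`.
#' @return Eggs per year for the population.
#' @export
population_egg_output <- function(abundance, maturity,
                                  params = reproduction_params(),
                                  method = c("representative", "integrate"),
                                  diameters = NULL) {
  method <- match.arg(method)
  if (abundance < 0) .abort("abundance must be non-negative")
  if (method == "integrate") {
    if (is.null(diameters)) .abort("method = 'integrate' requires the diameter census")
    mature <- diameters >= params$maturity_threshold_cm
    if (!any(mature)) return(0)
    per_colony <- mean(ifelse(mature, colony_egg_output(pmax(diameters, 1e-12), params), 0))
    return(abundance * per_colony)
  }
  p <- maturity$prop_mature
  if (p < 0 || p > 1) .abort("prop_mature must lie in [0, 1]")
  if (p == 0 || abundance == 0) return(0)
  d <- maturity$mean_mature_diameter_cm
  if (is.null(d) || is.na(d)) {
    .abort("prop_mature > 0 but mean_mature_diameter_cm is undefined")
  }
  abundance * p * colony_egg_output(d, params)
}

#' Zygotes produced from an egg output
#'
#' Applies the pooled mean fertilization success to an annual egg output.
#' Without information on larval development, the zygote count is the
#' first-order estimate of larval production.
#'
#' @param eggs Eggs per year; non-negative.
#' @param params A [reproduction_params()].
#' @return Zygotes per year.
#' @export
zygote_production <- function(eggs, params = reproduction_params()) {
  if (any(eggs < 0)) .abort("eggs must be non-negative")
  eggs * params$fertilization$mean
}
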