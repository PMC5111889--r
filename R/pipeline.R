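#' Run the full self-seeding assessment pipeline
#'
#' Executes the stages in order: cover estimation (when scored images are
#' present), density estimation and habitat scaling, maturity classification
#' and the egg/zygote chains, Monte Carlo uncertainty propagation, and the
#' self-seeding report. Any stage failure aborts with the stage name. With a
#' fixed configuration (including its seed) the run is exactly reproducible,
#' and identical output files are written on rerun.
#'
#' @param config Pipeline configuration: a list like [moorea_config()] or a
#'   YAML file path. `config$paths` may name CSV inputs (see
#'   [read_survey_dataset()]) when `dataset` is not given; `config$seed`
#'   seeds the Monte Carlo stage.
#' @param dataset Optional [survey_dataset()]; when supplied, `config$paths`
#'   is ignored.
#' @param out_dir Optional output directory; when given, all summary tables
#'   plus a `run_info.txt` stamp (seed and config hash) are written there.
#' @param weighting Site/depth weighting passed to the density estimators.
#' @return An object of class `pipeline_result`: list with `report`
#'   (a [build_report()] result), `cover`, `densities`, `abundances`,
#'   `maturity`, `reproduction`, `mc`, `params`, and `files` (paths written,
#'   or `NULL`).
#' @export
run_pipeline <- function(config, dataset = NULL, out_dir = NULL,
                         weighting = c("simple", "pooled")) {
  weighting <- match.arg(weighting)
  config <- as_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .abort(name, " stage failed: ", conditionMessage(e))
    })
  }

  dataset <- stage("input", {
    if (is.null(dataset)) {
      if (is.null(config$paths)) {
        .abort("no dataset supplied and config$paths is empty")
      }
      read_survey_dataset(config$paths, config)
    } else {
      validate_survey_dataset(dataset)
    }
  })

  cover <- stage("cover", {
    pieces <- list()
    if (nrow(dataset$points) > 0) {
      pieces$points <- summarize_cover(
        per_image_cover(dataset$points, dataset$sampler, "points")
      ) |> dplyr::mutate(scheme = "points")
    }
    if (nrow(dataset$grids) > 0) {
      pieces$grids <- summarize_cover(
        per_image_cover(dataset$grids, dataset$sampler, "grid")
      ) |> dplyr::mutate(scheme = "grid")
    }
    if (length(pieces) > 0) dplyr::bind_rows(pieces) else NULL
  })

  densities <- stage("abundance", {
    if (nrow(dataset$tiles) == 0) .abort("no tile records in dataset")
    dplyr::bind_rows(
      annual_recruit_density(dataset$tiles, dataset$sampler, weighting),
      if (nrow(dataset$quadrats) > 0) {
        mean_quadrat_density(dataset$quadrats, dataset$sampler, weighting)
      }
    )
  })
  abundances <- stage("abundance", scale_to_habitat(densities, config$habitats))

  params <- stage("reproduction", {
    params_from_config(config, dataset$fecundity_studies)
  })
  maturity <- stage("reproduction", {
    if (nrow(dataset$colonies) == 0) {
      NULL
    } else {
      dataset$colonies |>
        dplyr::group_by(.data$habitat, .data$year) |>
        dplyr::group_modify(function(df, key) {
          m <- classify_maturity(df$diameter_cm, params)
          tibble::tibble(
            n_colonies = m$n_colonies, n_mature = m$n_mature,
            prop_mature = m$prop_mature,
            mean_mature_diameter_cm = m$mean_mature_diameter_cm
          )
        }) |>
        dplyr::ungroup()
    }
  })
  reproduction <- stage("reproduction", {
    colonies_ab <- abundances[abundances$life_stage == "all_colonies", ]
    if (nrow(colonies_ab) == 0) {
      tibble::tibble(
        habitat = character(), year = integer(), prop_mature = numeric(),
        mean_mature_diameter_cm = numeric(), eggs_per_year = numeric(),
        zygotes_per_year = numeric()
      )
    } else {
      out <- colonies_ab |> dplyr::select("habitat", "year", "abundance")
      key <- paste(out$habitat, out$year)
      if (!is.null(maturity)) {
        idx <- match(key, paste(maturity$habitat, maturity$year))
        out$n_colonies <- maturity$n_colonies[idx]
        out$prop_mature <- maturity$prop_mature[idx]
        out$mean_mature_diameter_cm <- maturity$mean_mature_diameter_cm[idx]
      } else {
        out$n_colonies <- NA_integer_
        out$prop_mature <- NA_real_
        out$mean_mature_diameter_cm <- NA_real_
      }
      out$eggs_per_year <- vapply(seq_len(nrow(out)), function(i) {
        p <- out$prop_mature[i]
        if (is.na(p)) return(NA_real_)
        population_egg_output(
          out$abundance[i],
          list(prop_mature = p,
               mean_mature_diameter_cm = out$mean_mature_diameter_cm[i]),
          params
        )
      }, numeric(1))
      out$zygotes_per_year <- ifelse(
        is.na(out$eggs_per_year), NA_real_,
        zygote_production(pmax(out$eggs_per_year, 0), params)
      )
      dplyr::select(out, -"abundance")
    }
  })

  mc <- stage("mc", {
    runs <- reproduction[!is.na(reproduction$eggs_per_year), ]
    if (nrow(runs) == 0) {
      NULL
    } else {
      colonies_ab <- abundances[abundances$life_stage == "all_colonies", ]
      idx <- match(paste(runs$habitat, runs$year),
                   paste(colonies_ab$habitat, colonies_ab$year))
      seed0 <- if (is.null(config$seed)) NULL else as.integer(config$seed)
      res <- lapply(seq_len(nrow(runs)), function(i) {
        cfg <- mc_config(
          n_draws = config$mc$n_draws,
          seed = if (is.null(seed0)) NULL else seed0 + i,
          truncate_negative = isTRUE(config$mc$truncate_negative),
          fecundity = params$fecundity,
          fertilization = params$fertilization
        )
        r <- propagate_larval_production(
          colonies_ab$abundance[idx[i]], runs$prop_mature[i],
          runs$mean_mature_diameter_cm[i], params$allometry, cfg
        )
        dplyr::mutate(r$summary,
                      habitat = runs$habitat[i], year = runs$year[i],
                      seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
                      .before = 1)
      })
      dplyr::bind_rows(res)
    }
  })

  report <- stage("assessment", {
    build_report(
      abundances, reproduction, mc = mc,
      scenario = self_seeding_scenario(
        larval_loss_fraction = config$scenario$larval_loss_fraction,
        loss_grid = config$scenario$loss_grid,
        year_matching = config$scenario$year_matching
      )
    )
  })

  files <- NULL
  if (!is.null(out_dir)) {
    files <- stage("output", {
      written <- write_report_tables(report, out_dir)
      if (!is.null(cover)) {
        path <- file.path(out_dir, "cover_summary.csv")
        utils::write.csv(cover, path, row.names = FALSE, quote = FALSE)
        written <- c(written, path)
      }
      info <- file.path(out_dir, "run_info.txt")
      writeLines(c(
        paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
        paste0("config_hash: ", .config_hash(config)),
        paste0("n_draws: ", config$mc$n_draws)
      ), info)
      c(written, info)
    })
  }

  structure(
    list(report = report, cover = cover, densities = densities,
         abundances = abundances, maturity = maturity,
         reproduction = reproduction, mc = mc, params = params,
         files = files),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d abundance estimates, %d reproduction chains, %s MC runs\n",
              nrow(x$abundances), nrow(x$reproduction),
              if (is.null(x$mc)) "no" else nrow(x$mc)))
  print(x$report)
  invisible(x)
}

# Small order-sensitive FNV-style hash of the deparsed configuration, for
# stamping outputs; not cryptographic.
.config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2^31
  sprintf("%08x", h)
}
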