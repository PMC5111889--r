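test_that("CSV readers preserve records and validate against the schema", {
  cfg <- moorea_config()
  path <- tiny_tile_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_survey_dataset(list(tiles = path), cfg)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$tiles), 3)
  expect_equal(ds$tiles$recruit_count, c(0L, 3L, 2L))
  expect_equal(nrow(ds$quadrats), 0)

  # missing column is a schema error naming the column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,habitat,depth_m,year,period,tile_id",
               "LTER1,outer_reef,10,2010,early,T1"), bad)
  expect_error(read_survey_dataset(list(tiles = bad), cfg), "recruit_count")

  # unknown table name is rejected outright
  expect_error(read_survey_dataset(list(bogus = path), cfg), "bogus")
})

test_that("validation rejects invariant-violating rows with 1-based row numbers", {
  cfg <- moorea_config()
  tiles <- tibble::tibble(
    site = "A", habitat = "back_reef", depth_m = 3, year = 2010L,
    period = c("early", "late", "late"), tile_id = c("T1", "T2", "T3"),
    recruit_count = c(1L, -1L, 2L)
  )
  expect_error(
    survey_dataset(cfg$habitats, cfg$sampler, tiles = tiles),
    "recruit_count.*row.* 2"
  )
  tiles$recruit_count <- c(1L, 1L, 2L)
  tiles$period[3] <- "spring"
  expect_error(
    survey_dataset(cfg$habitats, cfg$sampler, tiles = tiles),
    "period.*row.* 3"
  )
  tiles$period[3] <- "late"
  tiles$habitat <- c("back_reef", "lagoon", "back_reef")
  expect_error(
    survey_dataset(cfg$habitats, cfg$sampler, tiles = tiles),
    "habitat.*row.* 2"
  )

  quads <- tibble::tibble(
    site = "A", habitat = "back_reef", depth_m = 3, year = 2010L,
    quadrat_id = "Q1", life_stage = "adultish", colony_count = 1L
  )
  expect_error(survey_dataset(cfg$habitats, cfg$sampler, quadrats = quads),
               "life_stage.*row.* 1")

  col <- tibble::tibble(site = "A", habitat = "back_reef", year = 2010L,
                        diameter_cm = c(5, 0))
  expect_error(survey_dataset(cfg$habitats, cfg$sampler, colonies = col),
               "diameter_cm.*row.* 2")
})

test_that("per-image point and grid sums are enforced at dataset level", {
  cfg <- moorea_config()
  pts <- tibble::tibble(
    image_id = "I1", site = "A", habitat = "back_reef", depth_m = 3,
    year = 2010L, category = c("coral", "other"), points = c(30L, 100L)
  )
  expect_error(survey_dataset(cfg$habitats, cfg$sampler, points = pts),
               "sum to 200")
  pts$points <- c(30L, 170L)
  expect_silent(survey_dataset(cfg$habitats, cfg$sampler, points = pts))
})

test_that("a simulated survey round-trips through write and read unchanged", {
  sc <- small_scenario(seed = 3)
  ds <- simulate_survey(sc)
  dir <- withr::local_tempdir()
  files <- write_survey_dataset(ds, dir)
  expect_true(all(file.exists(files)))
  cfg <- moorea_config()
  back <- read_survey_dataset(
    list(tiles = files[["tiles"]], quadrats = files[["quadrats"]],
         colonies = files[["colonies"]], points = files[["points"]],
         grids = files[["grids"]],
         fecundity_studies = files[["fecundity_studies"]]),
    cfg
  )
  for (tab in c("tiles", "quadrats", "points", "grids")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(ds[[tab]]),
                 ignore_attr = TRUE)
  }
  # diameters go through decimal formatting; equal within print precision
  expect_equal(back$colonies$diameter_cm, ds$colonies$diameter_cm,
               tolerance = 1e-12)
})

test_that("YAML configs override the defaults they name and keep the rest", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 99",
    "habitats:",
    "  - name: lagoon",
    "    hard_bottom_area_km2: 1.5",
    "    depth_range_m: [1, 4]",
    "sampler:",
    "  tile_scoring_area_cm2: 400"
  ), yml)
  cfg <- read_pipeline_config(yml)
  expect_equal(cfg$seed, 99)
  expect_named(cfg$habitats, "lagoon")
  expect_equal(cfg$habitats$lagoon$hard_bottom_area_cm2, 1.5e10)
  expect_equal(cfg$sampler$tile_scoring_area_cm2, 400)
  # untouched sections keep package defaults
  expect_equal(cfg$reproduction$maturity_threshold_cm, 14)
  expect_equal(cfg$mc$n_draws, 20000L)
  expect_error(read_pipeline_config("no/such/file.yaml"), "not found")

  shipped <- system.file("extdata", "moorea_config.yaml", package = "reefseed")
  cfg2 <- read_pipeline_config(shipped)
  expect_equal(cfg2$habitats$outer_reef$hard_bottom_area_km2, 3.15)
  expect_equal(cfg2$reproduction$allometry$exponent_b, 2.312)
})

test_that("report tables are written deterministically and round-trip", {
  ab <- tibble::tibble(
    habitat = rep(c("back_reef", "outer_reef"), each = 6),
    year = rep(rep(c(2010L, 2014L), each = 3), 2),
    life_stage = rep(c("recruit", "juvenile", "all_colonies"), 4),
    density = c(0.38, 0.025, 0.10, 0.47, 0.60, 0.80,
                3.285, 0.19, 0.05, 0.88, 4.75, 9.08),
    sampler_area_cm2 = rep(c(225, 2500, 2500), 4)
  )
  ab <- scale_to_habitat(ab, moorea_config()$habitats)
  rp <- tibble::tibble(
    habitat = rep(c("back_reef", "outer_reef"), each = 2),
    year = rep(c(2010L, 2014L), 2),
    eggs_per_year = c(5.23e11, 3.03e13, 5.29e11, 0),
    zygotes_per_year = c(7.85e10, 4.54e12, 7.94e10, 0)
  )
  report <- build_report(ab, rp)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_report_tables(report, d1)
  f2 <- write_report_tables(report, d2)
  expect_setequal(basename(f1), basename(f2))
  for (f in basename(f1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # abundance table shape: one row per habitat-year per life stage
  abtab <- utils::read.csv(file.path(d1, "abundance_summary.csv"))
  expect_equal(nrow(abtab), 12)
  expect_equal(sort(unique(abtab$life_stage)),
               c("all_colonies", "juvenile", "recruit"))
  # round-trip of the abundance values within formatting precision
  expect_equal(abtab$abundance, ab$abundance, tolerance = 1e-10)
})
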