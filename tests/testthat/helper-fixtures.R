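# Shared fixtures built in code: a small fast scenario for generator-based
# tests and a tiny hand-written dataset for I/O tests.

small_scenario <- function(seed = 11, ...) {
  simulation_scenario(
    seed = seed,
    cells = tibble::tibble(
      habitat = c("outer_reef", "back_reef"),
      year = c(2010L, 2010L),
      recruit_early = c(0.57, 0.10),
      recruit_late = c(2.72, 0.28),
      juvenile = c(0.20, 0.025),
      colony = c(0.30, 0.10),
      size_meanlog = c(log(8), log(8)),
      size_sdlog = c(0.6, 0.6),
      n_colonies = c(25L, 25L)
    ),
    cover = tibble::tibble(
      habitat = c("outer_reef", "back_reef"),
      year = c(2010L, 2010L),
      category = "coral",
      fraction = c(0.39, 0.20)
    ),
    allometry = list(a = 2.493, b = 2.312, noise_sdlog = 0.1, n_pairs = 30,
                     diameter_range = c(4, 30)),
    effort = list(n_sites = 2, n_tiles = 8, n_quadrats = 20, n_images = 10),
    ...
  )
}

# Hand-written three-tile census used by the reader tests.
tiny_tile_csv <- function(path) {
  writeLines(c(
    "site,habitat,depth_m,year,period,tile_id,recruit_count",
    "LTER1,outer_reef,10,2010,early,T1,0",
    "LTER1,outer_reef,10,2010,late,T2,3",
    "LTER2,outer_reef,17,2010,late,T3,2"
  ), path)
  path
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
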