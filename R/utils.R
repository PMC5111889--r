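# Internal helpers shared across modules. All areas are carried in cm2
# internally; conversion happens once at ingest.

.km2_to_cm2 <- function(x) x * 1e10
.m2_to_cm2 <- function(x) x * 1e4

# Stop with a message and no call; keeps error text stable for tests.
.abort <- function(...) stop(..., call. = FALSE)

# Check that `df` has every column in `cols`; `what` names the table in the
# error so users can find the offending file.
.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    .abort(
      what, ": missing required column",
      if (length(missing) > 1) "s" else "",
      " ", paste(sQuote(missing), collapse = ", ")
    )
  }
  invisible(df)
}

# Row-level validation reporting 1-based row numbers of the offending rows.
.check_rows <- function(df, ok, what, rule) {
  bad <- which(!ok)
  if (length(bad) > 0) {
    shown <- utils::head(bad, 5)
    .abort(
      what, ": ", rule, " violated at row",
      if (length(bad) > 1) "s" else "",
      " ", paste(shown, collapse = ", "),
      if (length(bad) > length(shown)) sprintf(" (and %d more)", length(bad) - length(shown)) else ""
    )
  }
  invisible(df)
}

.is_count <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & (x == round(x))

# Sample SD with the n-1 denominator; NA (not error) for n = 1.
.sample_sd <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}
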