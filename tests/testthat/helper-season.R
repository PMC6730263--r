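# Shared synthetic-season fixtures, generated once per test run.

.season_cache <- new.env(parent = emptyenv())

# Full default season (183 days, 10 campaigns); the workhorse fixture.
test_season <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.season_cache[[key]])) {
    .season_cache[[key]] <- generate_season(truth_config(seed = seed))
  }
  .season_cache[[key]]
}

# Short six-week season for cheap structural checks.
test_season_short <- function(seed = 3, ...) {
  key <- paste0("short", seed, paste(..., collapse = "_"))
  if (is.null(.season_cache[[key]])) {
    .season_cache[[key]] <- generate_season(truth_config(
      seed = seed,
      season_start = "2017-06-01", season_end = "2017-07-15",
      stage_breaks = c("2017-06-10", "2017-06-20", "2017-07-01"),
      campaign_dates = c("2017-06-07", "2017-06-21", "2017-07-05"),
      ...))
  }
  .season_cache[[key]]
}

# Truth values aligned to a set of sampled records.
truth_for <- function(season, records) {
  do.call(rbind, lapply(split(records, records$treatment), function(sub) {
    truth_fluxes(season, sub$timestamp, sub$treatment[1])
  }))
}
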