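# Cached-versus-fresh designation: the four criteria, the decision order,
# dominance of criteria over availability flags, and dataset-level
# summaries.

prof_row <- function(taxon = "Tax", known = TRUE, year_round = FALSE,
                     absence = NA, underground = NA, stage = NA,
                     substrate = NA, fresh = NA, storable = TRUE) {
  tibble::tibble(taxon = taxon, known = known, year_round = year_round,
                 migratory_absence = absence, underground_window = underground,
                 stage_presence = stage, substrate_height_cm = substrate,
                 fresh_windows = fresh, storable_season_available = storable)
}

ob <- function(date = "2017-01-15", to_species = TRUE, stage = NA_character_) {
  list(obs_id = "o1", date = as.Date(date), to_species = to_species,
       life_stage = stage)
}

test_that("each cache criterion fires on its canonical example", {
  # C1: migratory butterfly detected in April, absent Sep-May
  monarch <- nh_profile(prof_row("Danaus plexippus", absence = "09-15:05-31"))
  d <- classify(ob("2017-04-10"), monarch)
  expect_equal(d$designation, "likely_cached")
  expect_equal(d$criteria_fired, "C1")

  # C2: adult dragonfly in a winter stomach; adults fly mid-Jun to Sep
  darner <- nh_profile(prof_row("Aeshna canadensis", stage = "adult=06-15:09-30"))
  d <- classify(ob("2017-01-20", stage = "adult"), darner)
  expect_equal(d$criteria_fired, "C2")
  # same taxon inside the flight season: criterion silent
  d <- classify(ob("2016-07-20", stage = "adult"), darner)
  expect_false(grepl("C2", d$criteria_fired))

  # C3: hibernating jumping mouse, underground mid-Oct to April
  zapus <- nh_profile(prof_row("Zapus hudsonius", underground = "10-15:04-30"))
  d <- classify(ob("2017-01-20"), zapus)
  expect_equal(d$criteria_fired, "C3")

  # C4: low-bush berry a few cm off the substrate, under 40 cm of snow
  berry <- nh_profile(prof_row("Vaccinium oxycoccos", substrate = 5,
                               fresh = "07-15:09-30"))
  d <- classify(ob("2017-01-20"), berry, snow = 40)
  expect_equal(d$criteria_fired, "C4")
  # no snow record: the criterion cannot fire
  d <- classify(ob("2017-01-20"), berry, snow = NA)
  expect_false(grepl("C4", d$criteria_fired))
})

test_that("non-criterion paths follow the stated decision order", {
  shrew <- nh_profile(prof_row("Sorex cinereus", year_round = TRUE))
  expect_equal(classify(ob("2017-01-20"), shrew)$designation, "either_possible")

  snowfly <- nh_profile(prof_row("Chionea scita", fresh = "11-01:03-31",
                                 storable = FALSE))
  d <- classify(ob("2017-01-20"), snowfly)
  expect_equal(d$designation, "likely_fresh")
  expect_match(d$rationale, "storage season")

  # outside every window and not year-round: either possible
  plain <- nh_profile(prof_row("Tax", fresh = "06-01:06-30"))
  expect_equal(classify(ob("2017-01-20"), plain)$designation, "either_possible")

  # unknown paths
  expect_equal(classify(ob(), NULL)$designation, "unknown")
  expect_equal(classify(ob(), nh_profile(prof_row(known = FALSE)))$designation,
               "unknown")
  expect_equal(classify(ob(to_species = FALSE), shrew)$designation, "unknown")
  mis <- ob(); mis$misidentified <- TRUE
  expect_equal(classify(mis, shrew)$designation, "unknown")
})

test_that("a firing criterion dominates availability flags", {
  set.seed(77)
  for (i in 1:50) {
    date <- as.Date("2016-11-01") + sample(0:150, 1)
    md <- format(date, "%m-%d")
    window_hit <- paste0(md, ":", md)
    crit <- sample(c("C1", "C3", "C4"), 1)
    row <- prof_row(
      absence = if (crit == "C1") window_hit else NA,
      underground = if (crit == "C3") window_hit else NA,
      substrate = if (crit == "C4") sample(0:20, 1) else NA,
      fresh = "01-01:12-31", storable = sample(c(TRUE, FALSE), 1)
    )
    snow <- if (crit == "C4") row$substrate_height_cm + sample(1:60, 1) else NA
    d <- classify(ob(date), nh_profile(row), snow = snow)
    expect_equal(d$designation, "likely_cached")
    expect_match(d$criteria_fired, crit)
  }
})

test_that("contradictory profiles are rejected", {
  expect_error(nh_profile(prof_row(year_round = TRUE, absence = "11-01:03-31")),
               "contradictory")
})

test_that("snow lookup honours station, date, and gap tolerance", {
  s <- gen_snow_series("2017-01-01", "2017-01-31", c("01-01:01-31" = 25))
  expect_equal(snow_depth_at(s, "SYN", "2017-01-10"), 25)
  expect_error(snow_depth_at(s, "XXX", "2017-01-10"), "unknown snow station")
  gappy <- s[s$date < as.Date("2017-01-05") | s$date > as.Date("2017-01-20"), ]
  expect_equal(snow_depth_at(gappy, "SYN", "2017-01-06", max_gap_days = 3), 25)
  expect_true(is.na(snow_depth_at(gappy, "SYN", "2017-01-12", max_gap_days = 3)))
})

test_that("dataset classification conserves items and honours overrides", {
  dat <- build_synthetic_jay_data()
  cl <- classify_dataset(dat$observations, dat$traits, dat$snow)
  expect_equal(nrow(cl), nrow(dat$observations))
  expect_equal(sum(table(cl$designation)), nrow(cl))
  expect_true(all(cl$designation %in% c("unknown", "either_possible",
                                        "likely_fresh", "likely_cached")))
  # likely_cached if and only if some criterion fired (no overrides here)
  expect_equal(cl$designation == "likely_cached", nzchar(cl$criteria_fired))

  obs <- dat$observations
  obs$expert_call <- NA_character_
  obs$expert_call[1] <- "likely_fresh"
  cl2 <- classify_dataset(obs, dat$traits, dat$snow, override_col = "expert_call")
  expect_equal(cl2$designation[1], "likely_fresh")
  expect_equal(cl2$rationale[1], "expert override")
  expect_equal(cl2$designation[-1], cl$designation[-1])

  obs$expert_call[2] <- "definitely_cached"
  expect_error(classify_dataset(obs, dat$traits, dat$snow,
                                override_col = "expert_call"), "invalid expert override")
})

test_that("empty inputs classify to empty outputs", {
  dat <- build_synthetic_jay_data()
  cl <- classify_dataset(dat$observations[0, ], dat$traits, dat$snow)
  expect_equal(nrow(cl), 0)
  expect_equal(nrow(attr(cl, "summary")), 0)
})

test_that("sac-level cached presence equals a groupby-any tally", {
  dat <- build_synthetic_jay_data()
  cl <- classify_dataset(dat$observations, dat$traits, dat$snow)
  got <- sac_level_cached_presence(cl)
  fs <- cl[cl$method == "FS", ]
  brute <- tapply(fs$designation == "likely_cached", fs$sac_id, any)
  expect_equal(got$n_sacs, length(brute))
  expect_equal(got$n_cached_sacs, sum(brute))

  all_fresh <- cl
  all_fresh$designation[all_fresh$method == "FS"] <- "likely_fresh"
  expect_equal(sac_level_cached_presence(all_fresh)$n_cached_sacs, 0)

  expect_null(sac_level_cached_presence(cl[cl$method != "FS", ]))
})
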