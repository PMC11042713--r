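# Synthetic dated diet observations with known cached/fresh ground truth,
# plus matching natural-history trait tables and daily snow series.
#
# Ground-truth construction is criterion-first: a cached item is built by
# choosing one of the four cache criteria and then a taxon/date (and, for
# the snow criterion, snow conditions) under which that criterion provably
# holds; a fresh item is built from a taxon with no criterion windows, no
# substrate height, not year-round, dated inside its declared
# fresh-availability window. The classifier is therefore guaranteed to
# recover the labels, which is what makes the generator a usable oracle.

#' Generate a daily snow-depth series
#'
#' @param start,end first and last day (inclusive).
#' @param depth_profile named numeric vector mapping month-day windows to
#'   depths, e.g. `c("11-15:03-31" = 45, "04-01:04-15" = 25)`; days outside
#'   all windows get 0 cm.
#' @param station station label.
#' @param jitter_sd standard deviation of non-negative day-to-day noise
#'   (0 = deterministic).
#' @param drop_dates dates to omit from the series (to exercise
#'   nearest-day lookups).
#' @param seed RNG seed (used only when `jitter_sd > 0`).
#' @return snow tibble (`station`, `date`, `depth_cm`), one row per day.
#' @export
gen_snow_series <- function(start, end,
                            depth_profile = c("11-15:03-31" = 45),
                            station = "SYN", jitter_sd = 0,
                            drop_dates = NULL, seed = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) abort("start must not be after end")
  dates <- seq(start, end, by = "day")
  depth <- rep(0, length(dates))
  for (w in names(depth_profile)) {
    inw <- in_md_window(dates, w)
    depth[inw] <- depth_profile[[w]]
  }
  if (jitter_sd > 0) {
    depth <- with_seed(seed, pmax(0, depth + stats::rnorm(length(depth), 0, jitter_sd)))
  }
  out <- tibble(station = station, date = dates, depth_cm = depth)
  if (!is.null(drop_dates)) out <- out[!(out$date %in% as.Date(drop_dates)), , drop = FALSE]
  out
}

#' Standard synthetic natural-history trait table
#'
#' Covers, for each food group, at least one taxon per cache criterion
#' (migratory absence C1, stage phenology C2, underground C3, low substrate
#' for the snow criterion C4), one year-round taxon, and one
#' winter-fresh taxon, so cached and fresh items can be constructed in any
#' group inside a winter observation window.
#'
#' @return trait tibble in the [load_traits()] schema.
#' @export
gen_trait_table <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~taxon, ~known, ~year_round, ~migratory_absence, ~underground_window,
    ~stage_presence, ~substrate_height_cm, ~fresh_windows, ~storable_season_available,
    "Danaus plexippus",      TRUE, FALSE, "09-15:05-31", NA, NA, NA, NA, TRUE,
    "Vanessa cardui",        TRUE, FALSE, "10-01:05-31", NA, NA, NA, NA, TRUE,
    "Aeshna canadensis",     TRUE, FALSE, NA, NA, "adult=06-15:09-30", NA, NA, TRUE,
    "Zapus hudsonius",       TRUE, FALSE, NA, "10-15:04-30", NA, NA, NA, TRUE,
    "Vaccinium angustifolium", TRUE, FALSE, NA, NA, NA, 5, "07-15:09-30", TRUE,
    "Gaultheria hispidula",  TRUE, FALSE, NA, NA, NA, 4, "07-15:09-30", TRUE,
    "Boreus brumalis",       TRUE, FALSE, NA, NA, NA, NA, "11-01:03-31", FALSE,
    "Chionea scita",         TRUE, FALSE, NA, NA, NA, NA, "11-01:03-31", FALSE,
    "Tsuga canadensis",      TRUE, FALSE, NA, NA, NA, NA, "11-01:03-31", FALSE,
    "Poecile atricapillus",  TRUE, FALSE, NA, NA, NA, NA, "11-01:03-31", FALSE,
    "Sorex cinereus",        TRUE, TRUE,  NA, NA, NA, NA, NA, TRUE,
    "Picea mariana",         TRUE, TRUE,  NA, NA, NA, NA, NA, TRUE,
    "Clubiona canadensis",   TRUE, TRUE,  NA, NA, NA, NA, NA, TRUE
  )
}

# which food group each standard synthetic taxon belongs to
SYN_TAXON_GROUP <- c(
  "Danaus plexippus" = "A", "Vanessa cardui" = "A", "Aeshna canadensis" = "A",
  "Boreus brumalis" = "A", "Chionea scita" = "A", "Clubiona canadensis" = "A",
  "Vaccinium angustifolium" = "P", "Gaultheria hispidula" = "P",
  "Tsuga canadensis" = "P", "Picea mariana" = "P",
  "Zapus hudsonius" = "V", "Poecile atricapillus" = "V", "Sorex cinereus" = "V"
)

#' Specification for synthetic diet observations
#'
#' @param n_items number of observations.
#' @param group_probs probabilities over food groups (A, P, V); must sum
#'   to 1 (within 1e-9).
#' @param cached_fraction probability an item is generated as ground-truth
#'   cached.
#' @param date_start,date_end observation date window.
#' @param location label used as both location and snow station.
#' @param seed RNG seed.
#' @return validated list of class `obs_sim_spec`.
#' @export
obs_sim_spec <- function(n_items, group_probs = c(A = 0.6, P = 0.3, V = 0.1),
                         cached_fraction = 0.5,
                         date_start = "2016-11-01", date_end = "2017-03-31",
                         location = "SYN", seed = 1) {
  check_count(n_items + 1, "n_items") # allows 0
  if (length(group_probs) != 3 || abs(sum(group_probs) - 1) > 1e-9 || any(group_probs < 0)) {
    abort("invalid 'group_probs': three non-negative probabilities summing to 1")
  }
  check_fraction(cached_fraction, "cached_fraction")
  structure(list(
    n_items = as.integer(n_items),
    group_probs = stats::setNames(as.numeric(group_probs), c("A", "P", "V")),
    cached_fraction = cached_fraction,
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    location = location, seed = seed
  ), class = "obs_sim_spec")
}

# candidate dates (inside the observation window) on which a given
# criterion provably fires for a given trait row
criterion_dates <- function(row, criterion, dates, snow) {
  switch(criterion,
    C1 = dates_in_window(dates, row$migratory_absence),
    C2 = {
      stages <- parse_stage_presence(row$stage_presence)
      if (length(stages) == 0) return(as.Date(character(0)))
      ok <- in_md_window(dates, stages[[1]])
      dates[!is.na(ok) & !ok]
    },
    C3 = dates_in_window(dates, row$underground_window),
    C4 = {
      if (is.na(row$substrate_height_cm)) return(as.Date(character(0)))
      deep <- snow$date[snow$depth_cm > row$substrate_height_cm]
      dates[dates %in% deep]
    }
  )
}

#' Generate diet observations with known cached/fresh ground truth
#'
#' Every ground-truth cached item is constructed so that at least one of
#' the four cache criteria provably holds on its date; every fresh item so
#' that none holds and the date lies in the taxon's fresh-availability
#' window. The hidden label is returned in `truth_cached`.
#'
#' @param spec an [obs_sim_spec()].
#' @param traits trait table (default [gen_trait_table()]); every usable
#'   taxon must have a row.
#' @param snow snow series (default: [gen_snow_series()] over the spec's
#'   date window at the spec's location).
#' @return observation tibble (`obs_id`, `date`, `location`, `method`,
#'   `age_class`, `food_group`, `taxon`, `to_species`, `sac_id`,
#'   `life_stage`, `truth_cached`); the trait and snow tables used are
#'   attached as attributes `traits` and `snow`.
#' @export
gen_observations <- function(spec, traits = gen_trait_table(), snow = NULL) {
  if (!inherits(spec, "obs_sim_spec")) abort("spec must be an obs_sim_spec")
  snow <- snow %||% gen_snow_series(spec$date_start, spec$date_end,
                                    station = spec$location)
  dates <- seq(spec$date_start, spec$date_end, by = "day")
  groups_of <- SYN_TAXON_GROUP[traits$taxon]

  # enumerate (taxon, criterion, valid dates) options once
  cached_opts <- list(); fresh_opts <- list()
  for (i in seq_len(nrow(traits))) {
    row <- traits[i, ]
    g <- groups_of[[i]]
    if (is.na(g)) next
    for (cr in c("C1", "C2", "C3", "C4")) {
      dd <- criterion_dates(row, cr, dates, snow)
      if (length(dd) > 0) {
        cached_opts[[length(cached_opts) + 1]] <-
          list(taxon = row$taxon, group = g, criterion = cr, dates = dd,
               life_stage = if (cr == "C2") names(parse_stage_presence(row$stage_presence))[1] else NA_character_)
      }
    }
    no_crit <- nrow(parse_md_windows(row$migratory_absence)) == 0 &&
      nrow(parse_md_windows(row$underground_window)) == 0 &&
      length(parse_stage_presence(row$stage_presence)) == 0 &&
      is.na(row$substrate_height_cm) && !isTRUE(row$year_round)
    if (no_crit) {
      dd <- dates_in_window(dates, row$fresh_windows)
      if (length(dd) > 0) {
        fresh_opts[[length(fresh_opts) + 1]] <-
          list(taxon = row$taxon, group = g, dates = dd)
      }
    }
  }
  opt_groups <- function(opts) vapply(opts, `[[`, character(1), "group")
  cg <- opt_groups(cached_opts); fg <- opt_groups(fresh_opts)
  for (g in names(spec$group_probs)[spec$group_probs > 0]) {
    if (!g %in% cg || !g %in% fg) {
      abort(paste0("trait table offers no cached or fresh option for group ", g))
    }
  }

  with_seed(spec$seed, {
    if (spec$n_items == 0) {
      return(tibble(obs_id = character(0), date = as.Date(character(0)),
                    location = character(0), method = character(0),
                    age_class = character(0), food_group = character(0),
                    taxon = character(0), to_species = logical(0),
                    sac_id = character(0), life_stage = character(0),
                    truth_cached = logical(0)))
    }
    truth <- stats::runif(spec$n_items) < spec$cached_fraction
    grp <- sample(c("A", "P", "V"), spec$n_items, replace = TRUE,
                  prob = spec$group_probs)
    rows <- lapply(seq_len(spec$n_items), function(i) {
      opts <- if (truth[i]) cached_opts else fresh_opts
      opts <- opts[opt_groups(opts) == grp[i]]
      o <- opts[[sample.int(length(opts), 1)]]
      d <- o$dates[sample.int(length(o$dates), 1)]
      tibble(obs_id = sprintf("syn%04d", i), date = d,
             location = spec$location, method = "SC", age_class = "adult",
             food_group = grp[i], taxon = o$taxon, to_species = TRUE,
             sac_id = NA_character_,
             life_stage = o$life_stage %||% NA_character_,
             truth_cached = truth[i])
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "traits") <- traits
    attr(out, "snow") <- snow
    out
  })
}
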