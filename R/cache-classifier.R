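# Cached-versus-fresh designation of diet items.
#
# Each item identified to species is assigned one of four categories —
# unknown, either_possible, likely_fresh, likely_cached — from the
# taxon's natural history and the snow conditions on the observation
# date. "Likely cached" requires at least one of four criteria:
#   C1 the species is entirely absent from the area on that date
#      (migratory absence window),
#   C2 the observed life stage is not present on that date,
#   C3 all individuals of the taxon are underground then and there,
#   C4 snow depth would have precluded access to the item in its source
#      location (snow deeper than the item's height above substrate).

DESIGNATIONS <- c("unknown", "either_possible", "likely_fresh", "likely_cached")

#' Load a natural-history trait table from CSV
#'
#' One row per taxon. Date windows are `MM-DD:MM-DD` strings (several may
#' be separated by `;`); `stage_presence` maps life stages to presence
#' windows as `stage=MM-DD:MM-DD;stage2=...`.
#'
#' @param path CSV with columns `taxon`, `known`, `year_round`,
#'   `migratory_absence`, `underground_window`, `stage_presence`,
#'   `substrate_height_cm`, `fresh_windows`, `storable_season_available`.
#' @return trait tibble.
#' @export
load_traits <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    taxon = readr::col_character(),
                    known = readr::col_logical(),
                    year_round = readr::col_logical(),
                    migratory_absence = readr::col_character(),
                    underground_window = readr::col_character(),
                    stage_presence = readr::col_character(),
                    substrate_height_cm = readr::col_double(),
                    fresh_windows = readr::col_character(),
                    storable_season_available = readr::col_logical()
                  ))
}

#' Load a daily snow-depth table from CSV
#'
#' @param path CSV with columns `station`, `date` (`YYYY-MM-DD`),
#'   `depth_cm`.
#' @return snow tibble; negative depths are rejected.
#' @export
load_snow <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         station = readr::col_character(),
                         date = readr::col_date(),
                         depth_cm = readr::col_double()
                       ))
  if (any(x$depth_cm < 0, na.rm = TRUE)) abort("snow depths must be >= 0")
  x
}

parse_stage_presence <- function(spec) {
  if (is.null(spec) || is.na(spec) || !nzchar(trimws(spec))) return(list())
  parts <- strsplit(trimws(spec), ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("stage_presence entry must be 'stage=MM-DD:MM-DD': ", p))
    key <- trimws(kv[1])
    out[[key]] <- rbind(out[[key]], parse_md_windows(kv[2]))
  }
  out
}

#' Build a natural-history profile from a trait-table row
#'
#' Parses the window columns and validates internal consistency: a taxon
#' cannot be both available year-round and seasonally absent/underground.
#'
#' @param row one-row trait tibble (or a named list).
#' @return a `nh_profile` list.
#' @export
nh_profile <- function(row) {
  g <- function(f) if (f %in% names(row)) row[[f]][[1]] else NA
  known <- isTRUE(g("known"))
  prof <- list(
    taxon = g("taxon"),
    known = known,
    year_round = isTRUE(g("year_round")),
    migratory_absence = parse_md_windows(g("migratory_absence")),
    underground_window = parse_md_windows(g("underground_window")),
    stage_phenology = parse_stage_presence(g("stage_presence")),
    substrate_height_cm = suppressWarnings(as.numeric(g("substrate_height_cm"))),
    fresh_windows = parse_md_windows(g("fresh_windows")),
    storable_season_available = isTRUE(g("storable_season_available"))
  )
  if (known && prof$year_round &&
      (nrow(prof$migratory_absence) > 0 || nrow(prof$underground_window) > 0)) {
    abort(paste0("contradictory profile for '", prof$taxon,
                 "': year_round with an absence/underground window"))
  }
  structure(prof, class = "nh_profile")
}

#' Snow depth at a station on (or near) a date
#'
#' Exact-date value if present, otherwise the nearest available day within
#' `max_gap_days` (earlier day wins a tie), otherwise `NA`.
#'
#' @param records snow tibble (`station`, `date`, `depth_cm`).
#' @param station station identifier.
#' @param date target date.
#' @param max_gap_days tolerated distance to the nearest record (default 3).
#' @return depth in cm, or `NA` if no record is close enough.
#' @export
snow_depth_at <- function(records, station, date, max_gap_days = 3) {
  rec <- records[records$station == station, , drop = FALSE]
  if (nrow(rec) == 0) abort(paste0("unknown snow station: ", station))
  date <- as.Date(date)
  if (is.na(date)) return(NA_real_)
  gap <- abs(as.numeric(rec$date - date))
  i <- which.min(gap)
  if (gap[i] <= max_gap_days) rec$depth_cm[i] else NA_real_
}

#' Classify one diet item as cached, fresh, either, or unknown
#'
#' Decision procedure, in order: (a) items not identified to species,
#' flagged as misidentified, or whose taxon has no known natural history
#' are `unknown`; (b) all four cache criteria are evaluated and any firing
#' makes the item `likely_cached` (the fired subset is recorded); (c)
#' taxa present and accessible year-round are `either_possible`; (d) items
#' dated inside a declared fresh-availability window are `likely_fresh`
#' (strengthened when the taxon was unavailable in the preceding
#' summer/fall storage season); (e) anything else is `either_possible`.
#'
#' @param obs one observation (list/row with `date`, `to_species`, and
#'   optionally `misidentified`).
#' @param profile an [nh_profile()], or `NULL` when the taxon has no trait
#'   row (yields `unknown`).
#' @param snow snow depth (cm) on the observation date, or `NA`/`NULL`.
#' @param life_stage observed life stage, if any (enables criterion C2).
#' @return one-row tibble: `designation`, `criteria_fired` (comma string),
#'   `rationale`.
#' @export
classify <- function(obs, profile, snow = NULL, life_stage = NULL) {
  res <- function(value, criteria = character(0), why = "") {
    tibble(designation = value,
           criteria_fired = paste(criteria, collapse = ","),
           rationale = why)
  }
  if (isTRUE(obs$misidentified %||% FALSE)) {
    return(res("unknown", why = "flagged as misidentified"))
  }
  if (!isTRUE(obs$to_species)) {
    return(res("unknown", why = "not identified to species"))
  }
  if (is.null(profile) || !isTRUE(profile$known)) {
    return(res("unknown", why = "no known natural history"))
  }
  date <- as.Date(obs$date)
  if (is.na(date)) {
    return(res("unknown", why = "observation date not resolvable"))
  }
  life_stage <- life_stage %||% obs$life_stage %||% NULL
  snow <- if (is.null(snow)) NA_real_ else snow

  fired <- character(0)
  if (isTRUE(in_md_window(date, profile$migratory_absence))) fired <- c(fired, "C1")
  if (!is.null(life_stage) && !is.na(life_stage) && nzchar(life_stage) &&
      life_stage %in% names(profile$stage_phenology) &&
      !isTRUE(in_md_window(date, profile$stage_phenology[[life_stage]]))) {
    fired <- c(fired, "C2")
  }
  if (isTRUE(in_md_window(date, profile$underground_window))) fired <- c(fired, "C3")
  if (!is.na(snow) && !is.na(profile$substrate_height_cm) &&
      snow > profile$substrate_height_cm) {
    fired <- c(fired, "C4")
  }
  if (length(fired) > 0) {
    return(res("likely_cached", fired,
               paste0("criteria ", paste(fired, collapse = "+"), " fired")))
  }
  if (profile$year_round) {
    return(res("either_possible", why = "taxon present and accessible year-round"))
  }
  if (isTRUE(in_md_window(date, profile$fresh_windows))) {
    strong <- !profile$storable_season_available
    return(res("likely_fresh",
               why = if (strong) "fresh window; unavailable in storage season"
                     else "inside fresh-availability window"))
  }
  res("either_possible", why = "no criterion fired; availability ambiguous")
}

#' Classify a whole observation dataset
#'
#' Looks up each item's natural-history profile and local snow depth,
#' applies [classify()], honours an optional per-item expert-override
#' column (which takes precedence and is logged in the rationale), and
#' attaches cohort summary tallies.
#'
#' @param observations observation tibble ([load_observations()] output or
#'   equivalent; `location` is used as the snow station).
#' @param traits trait tibble ([load_traits()]).
#' @param snow snow tibble ([load_snow()]), or `NULL` to disable C4.
#' @param max_gap_days snow-lookup tolerance in days.
#' @param override_col name of an expert-override column, or `NULL`.
#' @return the observations with `designation`, `criteria_fired`,
#'   `rationale` columns; cohort tallies in `attr(, "summary")` (see
#'   [designation_summary()]).
#' @export
classify_dataset <- function(observations, traits, snow = NULL,
                             max_gap_days = 3, override_col = NULL) {
  profiles <- lapply(seq_len(nrow(traits)), function(i) nh_profile(traits[i, ]))
  names(profiles) <- traits$taxon
  stations <- if (is.null(snow)) character(0) else unique(snow$station)

  rows <- lapply(seq_len(nrow(observations)), function(i) {
    ob <- as.list(observations[i, ])
    if (!is.null(override_col) && override_col %in% names(observations)) {
      ov <- observations[[override_col]][i]
      if (!is.na(ov) && nzchar(ov)) {
        if (!ov %in% DESIGNATIONS) {
          abort(paste0("invalid expert override '", ov, "' for ", ob$obs_id))
        }
        return(tibble(designation = ov, criteria_fired = "",
                      rationale = "expert override"))
      }
    }
    tx <- ob$taxon %||% NA_character_
    prof <- if (!is.na(tx) && tx %in% names(profiles)) profiles[[tx]] else NULL
    sd <- NA_real_
    if (!is.null(snow) && !is.null(ob$location) && ob$location %in% stations &&
        !is.na(ob$date)) {
      sd <- snow_depth_at(snow, ob$location, ob$date, max_gap_days)
    }
    classify(ob, prof, snow = sd)
  })
  out <- dplyr::bind_cols(observations, dplyr::bind_rows(rows))
  attr(out, "summary") <- designation_summary(out)
  out
}

cohort_of <- function(obs) {
  dplyr::case_when(
    obs$age_class == "nestling" ~ "nestling",
    obs$age_class == "adult" & obs$method == "SC" &
      season_of(obs$date) == "winter" ~ "winter_adult",
    TRUE ~ NA_character_
  )
}

#' Designation tallies for the winter-adult and nestling cohorts
#'
#' Winter adults are adult stomach-contents items dated Nov 1 - Mar 31;
#' nestlings are all nestling items. For each cohort and food group
#' (plus an `all` margin) the three informative designations are counted;
#' percentages use the items-identified-to-species denominator (all
#' designations except `unknown`), which is also reported (`n_designated`)
#' alongside the full denominator (`n_total`).
#'
#' @param classified output of [classify_dataset()].
#' @return tibble: `cohort`, `food_group`, `designation`, `n`, `pct`,
#'   `n_designated`, `n_total`.
#' @export
designation_summary <- function(classified) {
  classified$cohort <- cohort_of(classified)
  x <- classified[!is.na(classified$cohort), , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble(cohort = character(0), food_group = character(0),
                  designation = character(0), n = integer(0), pct = numeric(0),
                  n_designated = integer(0), n_total = integer(0)))
  }
  groups <- function(sub, cohort, fg) {
    designated <- sub[sub$designation != "unknown", , drop = FALSE]
    denom <- nrow(designated)
    purrr::map_dfr(c("likely_cached", "either_possible", "likely_fresh"), function(d) {
      n <- sum(designated$designation == d)
      tibble(cohort = cohort, food_group = fg, designation = d, n = n,
             pct = if (denom > 0) pct_of(n, denom) else NA_real_,
             n_designated = denom, n_total = nrow(sub))
    })
  }
  purrr::map_dfr(unique(stats::na.omit(x$cohort)), function(co) {
    sub <- x[x$cohort == co, , drop = FALSE]
    dplyr::bind_rows(
      groups(sub, co, "all"),
      purrr::map_dfr(OBS_GROUPS, function(g) {
        groups(sub[sub$food_group == g, , drop = FALSE], co, g)
      })
    )
  })
}

#' Fraction of fecal sacs containing at least one likely-cached item
#'
#' @param classified output of [classify_dataset()]; FS rows must carry a
#'   `sac_id`.
#' @return list with `n_cached_sacs`, `n_sacs`, and `fraction`; `NULL` if
#'   there are no FS observations with sac identifiers.
#' @export
sac_level_cached_presence <- function(classified) {
  fs <- classified[classified$method == "FS" & !is.na(classified$sac_id %||% NA), , drop = FALSE]
  if (nrow(fs) == 0) return(NULL)
  per_sac <- fs |>
    dplyr::group_by(.data$sac_id) |>
    dplyr::summarise(any_cached = any(.data$designation == "likely_cached"),
                     .groups = "drop")
  list(n_cached_sacs = sum(per_sac$any_cached),
       n_sacs = nrow(per_sac),
       fraction = sum(per_sac$any_cached) / nrow(per_sac))
}
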