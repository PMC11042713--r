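# Compilation of the multi-method diet-observation dataset and the
# descriptive tallies behind its summary figures.
#
# Observation schema (one row per food item):
#   obs_id, date, location, method (DO direct observation / SC stomach
#   contents / FS fecal metabarcoding), age_class (adult/juvenile/
#   nestling), food_group (A arthropod / P plant incl. fungi & slime
#   moulds / V vertebrate), subcategory (plants: vascular/fungus/
#   slime_mould; vertebrates: egg/carrion/live_prey), taxon, to_species
#   (logical), sac_id (fecal-sac identifier for FS rows), life_stage.

OBS_METHODS <- c("DO", "SC", "FS")
OBS_GROUPS <- c("A", "P", "V")
OBS_AGES <- c("adult", "juvenile", "nestling")

required_obs_cols <- c("obs_id", "date", "location", "method", "age_class",
                       "food_group", "taxon", "to_species")

parse_obs_date <- function(x) {
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x %||% "")
  d <- rep(as.Date(NA), length(x))
  d[full] <- as.Date(x[full])
  d
}

#' Load a diet-observation table from CSV
#'
#' Validates every row; rows with unknown method/food-group/age codes are
#' collected into an error report (attached as `attr(, "errors")`), not
#' silently dropped from the report. Dates that are not full
#' `YYYY-MM-DD` values (e.g. year-only historic records) are kept with
#' `date = NA` and `partial_date = TRUE`; they participate in food-group
#' tallies but are excluded from seasonal ones.
#'
#' @param path CSV file matching the observation schema.
#' @return tibble of valid observations with a `season` column; invalid
#'   rows in `attr(, "errors")`.
#' @export
load_observations <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required_obs_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("observation file lacks columns: ", paste(missing, collapse = ", ")))
  }
  raw$to_species <- toupper(raw$to_species) %in% c("TRUE", "T", "1", "YES")
  problems <- character(nrow(raw))
  bad <- function(cond, msg) {
    problems[cond & !nzchar(problems)] <<- msg
  }
  bad(!(raw$method %in% OBS_METHODS), "unknown method code")
  bad(!(raw$food_group %in% OBS_GROUPS), "unknown food_group code")
  bad(!(raw$age_class %in% OBS_AGES), "unknown age_class")
  ok <- !nzchar(problems)
  obs <- as_tibble(raw[ok, , drop = FALSE])
  obs$date_raw <- obs$date
  obs$date <- parse_obs_date(obs$date_raw)
  obs$partial_date <- is.na(obs$date)
  obs$season <- season_of(obs$date)
  attr(obs, "errors") <- tibble(obs_id = raw$obs_id[!ok], problem = problems[!ok])
  obs
}

#' Season of a calendar date
#'
#' Year-agnostic month/day logic: winter is Nov 1 - Mar 31, non-winter is
#' May 1 - Oct 31, and April (left unassigned by both windows) is
#' `"neither"`. Missing dates (partial records) are also `"neither"`.
#'
#' @param date Date vector (or coercible).
#' @return character vector: `"winter"`, `"non_winter"`, or `"neither"`.
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  out <- rep("neither", length(date))
  w <- in_md_window(date, "11-01:03-31")
  nw <- in_md_window(date, "05-01:10-31")
  out[!is.na(w) & w] <- "winter"
  out[!is.na(nw) & nw] <- "non_winter"
  out
}

#' Contingency tallies of diet observations
#'
#' Counts observations per cell of the requested partition and attaches
#' percentages rounded to whole percent (half away from zero, the printed
#' convention). With `within` given, percentages are computed within each
#' level of those key(s) instead of over the grand total.
#'
#' @param obs observation tibble.
#' @param by character vector of partition keys (columns of `obs`).
#' @param within optional character vector of margin keys.
#' @return tibble of `by`/`within` keys, `n`, and `pct`.
#' @export
tally_diet <- function(obs, by, within = NULL) {
  keys <- c(within, by)
  missing <- setdiff(keys, names(obs))
  if (length(missing) > 0) {
    abort(paste0("unknown partition key(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(obs) == 0) {
    return(tibble(n = integer(0), pct = numeric(0)))
  }
  out <- dplyr::count(obs, dplyr::across(dplyr::all_of(keys)), name = "n")
  if (is.null(within)) {
    out$pct <- pct_of(out$n, sum(out$n))
  } else {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(within))) |>
      dplyr::mutate(pct = pct_of(.data$n, sum(.data$n))) |>
      dplyr::ungroup()
  }
  out
}
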