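# Synthetic reconstruction of the compiled Canada jay diet dataset.
#
# The published supplementary tables behind the compiled dataset are not
# redistributable, so the package carries a synthetic stand-in built here
# in code: 662 observations whose margins reproduce every count and
# percentage printed in the study's text (method split 121/147/394;
# direct-observation food groups 20/23/78; vertebrate subcategories
# 6/34/35 of 75; 194 winter-adult items with 87 identified to species
# splitting 34/48/5 across cached/either/fresh; 212 nestling items with
# 125 to species splitting 35/42/48; plant cached fractions 32/56 and
# 22/33; 10 of 15 fecal sacs with a cached item), together with the trait
# and snow tables that make the classifier produce those designations.
# Cells not pinned down by the printed text are filled in consistently
# with the margins. Copies live in inst/extdata as
# jay_observations_synthetic.csv, jay_traits_synthetic.csv and
# jay_snow_synthetic.csv.

fixture_block <- function(n, method, age, group, taxon, to_species, dates,
                          location, subcat = NA_character_,
                          sac = NA_character_, stage = NA_character_) {
  tibble(
    date = rep_len(as.character(dates), n), location = location,
    method = method, age_class = age, food_group = group,
    subcategory = rep_len(subcat, n), taxon = taxon,
    to_species = to_species, sac_id = rep_len(sac, n),
    life_stage = rep_len(stage, n)
  )
}

#' Build the synthetic compiled diet dataset
#'
#' Constructs the 662-observation synthetic dataset plus the matching
#' natural-history trait table and daily snow series (stations `APP` and
#' `NON`, Nov 2016 - Apr 2017). Deterministic; no RNG involved.
#'
#' @return list with `observations`, `traits`, and `snow` tibbles.
#' @export
build_synthetic_jay_data <- function() {
  b <- fixture_block
  winter <- c("2016-12-12", "2017-01-10", "2017-01-20", "2017-02-05", "2017-03-01")
  summer <- c("2016-06-15", "2016-07-20", "2016-09-05")

  wa <- dplyr::bind_rows(
    # winter-adult stomach contents (194 items, station NON) --------------
    # likely cached: 32 plant items under snow (C4) + 2 arthropods (C1/C2)
    b(9, "SC", "adult", "P", "Vaccinium angustifolium", TRUE,
      c("2017-01-10", "2017-01-20", "2017-02-05"), "NON"),
    b(8, "SC", "adult", "P", "Vaccinium oxycoccos", TRUE,
      c("2017-01-15", "2017-02-10"), "NON"),
    b(8, "SC", "adult", "P", "Viburnum edule", TRUE,
      c("2016-12-12", "2017-03-01"), "NON"),
    b(7, "SC", "adult", "P", "Gaultheria hispidula", TRUE,
      c("2017-02-20", "2016-12-20"), "NON"),
    b(1, "SC", "adult", "A", "Danaus plexippus", TRUE, "2017-01-18", "NON"),
    b(1, "SC", "adult", "A", "Aeshna canadensis", TRUE, "2017-01-25", "NON",
      stage = "adult"),
    # either possible: year-round taxa
    b(8, "SC", "adult", "P", "Picea mariana", TRUE, winter, "NON"),
    b(7, "SC", "adult", "P", "Abies balsamea", TRUE, winter, "NON"),
    b(7, "SC", "adult", "P", "Pinus banksiana", TRUE, winter, "NON"),
    b(8, "SC", "adult", "A", "Clubiona canadensis", TRUE, winter, "NON"),
    b(7, "SC", "adult", "A", "Pityokteines sparsus", TRUE, winter, "NON"),
    b(4, "SC", "adult", "V", "Sorex cinereus", TRUE, winter, "NON"),
    b(4, "SC", "adult", "V", "Peromyscus maniculatus", TRUE, winter, "NON"),
    b(3, "SC", "adult", "V", "Myodes gapperi", TRUE, winter, "NON"),
    # likely fresh: winter-available, not storable in summer/fall
    b(2, "SC", "adult", "P", "Tsuga canadensis", TRUE, "2017-01-30", "NON"),
    b(2, "SC", "adult", "A", "Boreus brumalis", TRUE, "2017-02-02", "NON"),
    b(1, "SC", "adult", "A", "Chionea scita", TRUE, "2017-01-12", "NON"),
    # not identified to species -> unknown
    b(30, "SC", "adult", "A", "Lepidoptera", FALSE, winter, "NON"),
    b(25, "SC", "adult", "A", "Coleoptera", FALSE, winter, "NON"),
    b(20, "SC", "adult", "A", "Araneae", FALSE, winter, "NON"),
    b(8, "SC", "adult", "P", "Poaceae", FALSE, winter, "NON"),
    b(6, "SC", "adult", "P", "Bryophyta", FALSE, winter, "NON"),
    b(10, "SC", "adult", "V", "Mammalia", FALSE, winter, "NON"),
    b(8, "SC", "adult", "V", "Aves", FALSE, winter, "NON")
  )

  sc_nonwinter <- dplyr::bind_rows(
    # adult stomach contents outside winter (135 items) -------------------
    b(30, "SC", "adult", "A", "Camponotus pennsylvanicus", TRUE, summer, "NON"),
    b(50, "SC", "adult", "A", "Coleoptera", FALSE, summer, "NON"),
    b(20, "SC", "adult", "P", "Vaccinium angustifolium", TRUE, "2016-07-20", "NON"),
    b(20, "SC", "adult", "P", "Poaceae", FALSE, summer, "NON"),
    b(10, "SC", "adult", "V", "Peromyscus maniculatus", TRUE, summer, "NON"),
    b(5, "SC", "adult", "V", "Mammalia", FALSE, summer, "NON")
  )

  do_obs <- dplyr::bind_rows(
    # direct observations (121 items: 20 A, 23 P, 78 V) -------------------
    b(10, "DO", "adult", "A", "Cicindela sexguttata", TRUE, "2016-06-10", "APP"),
    b(10, "DO", "adult", "A", "Orthoptera", FALSE, "2016-08-15", "APP"),
    b(10, "DO", "adult", "P", "Vaccinium angustifolium", TRUE, "2016-08-01", "APP",
      subcat = "vascular"),
    b(5, "DO", "adult", "P", "Sorbus americana", TRUE, "2016-09-10", "APP",
      subcat = "vascular"),
    b(6, "DO", "adult", "P", "Boletus edulis", TRUE, "2016-08-20", "APP",
      subcat = "fungus"),
    b(2, "DO", "adult", "P", "Fuligo septica", TRUE, "2016-07-05", "APP",
      subcat = "slime_mould"),
    b(6, "DO", "adult", "V", "Turdus migratorius", TRUE, "2016-06-05", "APP",
      subcat = "egg"),
    b(20, "DO", "adult", "V", "Alces alces", TRUE, "2016-05-15", "APP",
      subcat = "carrion"),
    b(14, "DO", "adult", "V", "Tamiasciurus hudsonicus", TRUE, "2016-06-20", "APP",
      subcat = "carrion"),
    b(20, "DO", "adult", "V", "Peromyscus maniculatus", TRUE, "2016-07-10", "APP",
      subcat = "live_prey"),
    b(15, "DO", "adult", "V", "Poecile atricapillus", TRUE, "2016-06-25", "APP",
      subcat = "live_prey"),
    b(3, "DO", "adult", "V", "Aves", FALSE, "2016-08-05", "APP")
  )

  sacs10 <- sprintf("S%02d", 1:10)
  fs_cached <- dplyr::bind_rows(
    # nestling fecal metabarcoding (147 items, 15 sacs) -------------------
    b(8, "FS", "nestling", "P", "Vaccinium angustifolium", TRUE, "2017-04-03",
      "APP", sac = sacs10[1:8]),
    b(6, "FS", "nestling", "P", "Vaccinium oxycoccos", TRUE, "2017-04-05",
      "APP", sac = sacs10[c(9, 10, 1, 2, 3, 4)]),
    b(3, "FS", "nestling", "A", "Danaus plexippus", TRUE, "2017-04-20",
      "APP", sac = sacs10[5:7]),
    b(3, "FS", "nestling", "A", "Vanessa cardui", TRUE, "2017-04-25",
      "APP", sac = sacs10[8:10])
  )
  fs_rest <- dplyr::bind_rows(
    b(4, "FS", "nestling", "P", "Picea mariana", TRUE, "2017-04-15", "APP"),
    b(14, "FS", "nestling", "A", "Clubiona canadensis", TRUE, "2017-04-16", "APP"),
    b(13, "FS", "nestling", "A", "Pityokteines sparsus", TRUE, "2017-04-17", "APP"),
    b(1, "FS", "nestling", "V", "Sorex cinereus", TRUE, "2017-04-18", "APP"),
    b(3, "FS", "nestling", "P", "Salix discolor", TRUE, "2017-05-02", "APP"),
    b(2, "FS", "nestling", "P", "Acer rubrum", TRUE, "2017-05-10", "APP"),
    b(12, "FS", "nestling", "A", "Bibio femoratus", TRUE, "2017-04-22", "APP"),
    b(11, "FS", "nestling", "A", "Culiseta inornata", TRUE, "2017-05-15", "APP"),
    b(9, "FS", "nestling", "A", "Formica neorufibarbis", TRUE, "2017-05-20", "APP"),
    b(1, "FS", "nestling", "V", "Lithobates sylvaticus", TRUE, "2017-05-01", "APP"),
    b(27, "FS", "nestling", "A", "Lepidoptera", FALSE, "2017-04-25", "APP"),
    b(26, "FS", "nestling", "A", "Diptera", FALSE, "2017-04-26", "APP"),
    b(4, "FS", "nestling", "P", "Poaceae", FALSE, "2017-04-27", "APP")
  )
  fs_rest$sac_id <- rep_len(sprintf("S%02d", 1:15), nrow(fs_rest))

  sc_nestling <- dplyr::bind_rows(
    # nestling stomach contents (65 items) --------------------------------
    b(8, "SC", "nestling", "P", "Gaultheria hispidula", TRUE, "2017-04-04", "APP"),
    b(7, "SC", "nestling", "A", "Vanessa cardui", TRUE, "2017-04-18", "APP"),
    b(1, "SC", "nestling", "P", "Picea mariana", TRUE, "2017-04-20", "APP"),
    b(8, "SC", "nestling", "A", "Clubiona canadensis", TRUE, "2017-04-21", "APP"),
    b(1, "SC", "nestling", "V", "Sorex cinereus", TRUE, "2017-04-22", "APP"),
    b(1, "SC", "nestling", "P", "Salix discolor", TRUE, "2017-05-05", "APP"),
    b(9, "SC", "nestling", "A", "Bibio femoratus", TRUE, "2017-04-22", "APP"),
    b(15, "SC", "nestling", "A", "Lepidoptera", FALSE, "2017-04-23", "APP"),
    b(13, "SC", "nestling", "A", "Coleoptera", FALSE, "2017-04-24", "APP"),
    b(1, "SC", "nestling", "P", "Poaceae", FALSE, "2017-04-25", "APP"),
    b(1, "SC", "nestling", "V", "Aves", FALSE, "2017-04-26", "APP")
  )

  obs <- dplyr::bind_rows(wa, sc_nonwinter, do_obs, fs_cached, fs_rest, sc_nestling)
  obs <- dplyr::bind_cols(tibble(obs_id = sprintf("obs%03d", seq_len(nrow(obs)))), obs)

  tr <- function(taxon, known = TRUE, year_round = FALSE, absence = NA,
                 underground = NA, stage = NA, substrate = NA,
                 fresh = NA, storable = TRUE) {
    tibble(taxon = taxon, known = known, year_round = year_round,
           migratory_absence = absence, underground_window = underground,
           stage_presence = stage, substrate_height_cm = substrate,
           fresh_windows = fresh, storable_season_available = storable)
  }
  traits <- dplyr::bind_rows(
    tr("Vaccinium angustifolium", substrate = 5, fresh = "07-15:09-30"),
    tr("Vaccinium oxycoccos", substrate = 6, fresh = "07-15:09-30"),
    tr("Viburnum edule", substrate = 10, fresh = "07-15:10-15"),
    tr("Gaultheria hispidula", substrate = 4, fresh = "07-15:09-30"),
    tr("Danaus plexippus", absence = "09-15:05-31"),
    tr("Vanessa cardui", absence = "10-01:05-31"),
    tr("Aeshna canadensis", stage = "adult=06-15:09-30"),
    tr("Zapus hudsonius", underground = "10-15:04-30"),
    tr("Picea mariana", year_round = TRUE),
    tr("Abies balsamea", year_round = TRUE),
    tr("Pinus banksiana", year_round = TRUE),
    tr("Clubiona canadensis", year_round = TRUE),
    tr("Pityokteines sparsus", year_round = TRUE),
    tr("Sorex cinereus", year_round = TRUE),
    tr("Peromyscus maniculatus", year_round = TRUE),
    tr("Myodes gapperi", year_round = TRUE),
    tr("Tsuga canadensis", fresh = "11-01:03-31", storable = FALSE),
    tr("Boreus brumalis", fresh = "11-01:03-31", storable = FALSE),
    tr("Chionea scita", fresh = "11-01:03-31", storable = FALSE),
    tr("Salix discolor", fresh = "04-10:06-15", storable = FALSE),
    tr("Acer rubrum", fresh = "04-10:06-15", storable = FALSE),
    tr("Bibio femoratus", fresh = "04-10:10-31", storable = FALSE),
    tr("Culiseta inornata", fresh = "04-10:10-31", storable = FALSE),
    tr("Formica neorufibarbis", fresh = "04-10:10-31", storable = FALSE),
    tr("Lithobates sylvaticus", fresh = "04-10:10-31", storable = FALSE),
    tr("Camponotus pennsylvanicus", year_round = TRUE),
    tr("Cicindela sexguttata", fresh = "05-01:09-15"),
    tr("Sorbus americana", fresh = "08-01:10-31"),
    tr("Boletus edulis", fresh = "08-01:10-15"),
    tr("Fuligo septica", fresh = "07-01:09-30"),
    tr("Turdus migratorius", absence = "11-01:03-15"),
    tr("Alces alces", year_round = TRUE),
    tr("Tamiasciurus hudsonicus", year_round = TRUE),
    tr("Poecile atricapillus", year_round = TRUE)
  )

  snow <- dplyr::bind_rows(
    gen_snow_series("2016-11-01", "2017-04-30",
                    c("11-10:11-30" = 15, "12-01:03-31" = 35, "04-01:04-10" = 30),
                    station = "APP"),
    gen_snow_series("2016-11-01", "2017-04-30",
                    c("11-10:11-30" = 20, "12-01:03-31" = 45, "04-01:04-15" = 25),
                    station = "NON")
  )
  list(observations = obs, traits = traits, snow = snow)
}

#' Write the synthetic compiled dataset to CSV files
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_synthetic_jay_data <- function(dir) {
  dat <- build_synthetic_jay_data()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    observations = file.path(dir, "jay_observations_synthetic.csv"),
    traits = file.path(dir, "jay_traits_synthetic.csv"),
    snow = file.path(dir, "jay_snow_synthetic.csv")
  )
  readr::write_csv(dat$observations, paths[["observations"]], na = "")
  readr::write_csv(dat$traits, paths[["traits"]], na = "")
  readr::write_csv(dat$snow, paths[["snow"]], na = "")
  invisible(paths)
}

#' Path to a packaged synthetic fixture file
#'
#' @param name `"observations"`, `"traits"`, or `"snow"`.
#' @return path to the installed CSV.
#' @export
jay_fixture_path <- function(name = c("observations", "traits", "snow")) {
  name <- match.arg(name)
  fn <- paste0("jay_", name, "_synthetic.csv")
  path <- system.file("extdata", fn, package = "jaydiet")
  if (!nzchar(path)) abort(paste0("fixture not found: ", fn))
  path
}
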