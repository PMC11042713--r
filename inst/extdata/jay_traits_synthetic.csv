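taxon,known,year_round,migratory_absence,underground_window,stage_presence,substrate_height_cm,fresh_windows,storable_season_available
Vaccinium angustifolium,TRUE,FALSE,,,,5,07-15:09-30,TRUE
Vaccinium oxycoccos,TRUE,FALSE,,,,6,07-15:09-30,TRUE
Viburnum edule,TRUE,FALSE,,,,10,07-15:10-15,TRUE
Gaultheria hispidula,TRUE,FALSE,,,,4,07-15:09-30,TRUE
Danaus plexippus,TRUE,FALSE,09-15:05-31,,,,,TRUE
Vanessa cardui,TRUE,FALSE,10-01:05-31,,,,,TRUE
Aeshna canadensis,TRUE,FALSE,,,adult=06-15:09-30,,,TRUE
Zapus hudsonius,TRUE,FALSE,,10-15:04-30,,,,TRUE
Picea mariana,TRUE,TRUE,,,,,,TRUE
Abies balsamea,TRUE,TRUE,,,,,,TRUE
Pinus banksiana,TRUE,TRUE,,,,,,TRUE
Clubiona canadensis,TRUE,TRUE,,,,,,TRUE
Pityokteines sparsus,TRUE,TRUE,,,,,,TRUE
Sorex cinereus,TRUE,TRUE,,,,,,TRUE
Peromyscus maniculatus,TRUE,TRUE,,,,,,TRUE
Myodes gapperi,TRUE,TRUE,,,,,,TRUE
Tsuga canadensis,TRUE,FALSE,,,,,11-01:03-31,FALSE
Boreus brumalis,TRUE,FALSE,,,,,11-01:03-31,FALSE
Chionea scita,TRUE,FALSE,,,,,11-01:03-31,FALSE
Salix discolor,TRUE,FALSE,,,,,04-10:06-15,FALSE
Acer rubrum,TRUE,FALSE,,,,,04-10:06-15,FALSE
Bibio femoratus,TRUE,FALSE,,,,,04-10:10-31,FALSE
Culiseta inornata,TRUE,FALSE,,,,,04-10:10-31,FALSE
Formica neorufibarbis,TRUE,FALSE,,,,,04-10:10-31,FALSE
Lithobates sylvaticus,TRUE,FALSE,,,,,04-10:10-31,FALSE
Camponotus pennsylvanicus,TRUE,TRUE,,,,,,TRUE
Cicindela sexguttata,TRUE,FALSE,,,,,05-01:09-15,TRUE
Sorbus americana,TRUE,FALSE,,,,,08-01:10-31,TRUE
Boletus edulis,TRUE,FALSE,,,,,08-01:10-15,TRUE
Fuligo septica,TRUE,FALSE,,,,,07-01:09-30,TRUE
Turdus migratorius,TRUE,FALSE,11-01:03-15,,,,,TRUE
Alces alces,TRUE,TRUE,,,,,,TRUE
Tamiasciurus hudsonicus,TRUE,TRUE,,,,,,TRUE
Poecile atricapillus,TRUE,TRUE,,,,,,TRUE
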