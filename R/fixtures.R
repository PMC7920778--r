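# Packaged study tables: the ladybird mating-trial contingency counts and the
# comparative table of CSP species pairs.

.ladybird_counts_data <- function() {
  data.frame(
    behavior = rep(c("male_mating_attempt", "female_rejection"), each = 4L),
    year = rep(c(2014L, 2014L, 2015L, 2015L), 2L),
    species = rep(c("H. yedoensis", "H. axyridis"), 4L),
    hit = c(30L, 47L, 28L, 67L, 16L, 14L, 13L, 97L),
    miss = c(115L, 40L, 95L, 26L, 14L, 33L, 18L, 57L),
    false_alarm = c(13L, 10L, 3L, 8L, 3L, 7L, 8L, 3L),
    correct_rejection = c(22L, 32L, 13L, 15L, 6L, 7L, 13L, 0L),
    stringsAsFactors = FALSE
  )
}

.csp_pairs_data <- function() {
  rows <- list(
    c("Marine invertebrate", "Abalone", "Haliotis corrugata and H. rufescens", "sympatry", "Niche overlap in terms of water depth and habitat", "1-3"),
    c("Marine invertebrate", "Abalone", "Haliotis cracherodii and H. rufescens", "niche_partitioning", "Intertidal zone versus kelp forest habitat", "3, 4"),
    c("Marine invertebrate", "Abalone", "Haliotis fulgens and H. rufescens", "niche_partitioning", "Shallow versus deep water habitats", "2, 3, 5"),
    c("Marine invertebrate", "Blue mussel", "Mytilus trossulus and M. edulis", "sympatry", "Hybrid zone is not narrow", "6, 7"),
    c("Marine invertebrate", "Starfish", "Asterias forbesi and A. rubens", "sympatry", "Similar habitats, food resources, and spawning time", "8, 9"),
    c("Marine invertebrate", "Coral", "Montastraea annularis and M. franksi", "niche_partitioning", "Separation in (slightly overlapped) spawning time", "10"),
    c("Marine invertebrate", "Sea urchin", "Echinometra mathaei and E. oblonga", "sympatry", "Slight ecological differences", "11"),
    c("Marine invertebrate", "Sea urchin", "Echinometra oblonga and E. sp. C", "sympatry", "Slight difference in habitat but similar spawning time", "12"),
    c("Terrestrial invertebrate", "Cricket", "Allonemobius fasciatus and A. socius", "parapatry", "", "13, 14"),
    c("Terrestrial invertebrate", "Cricket", "Gryllus firmus and G. pennsylvanicus", "parapatry", "", "15, 16"),
    c("Terrestrial invertebrate", "Cricket", "Gryllus bimaculatus and G. campestris", "parapatry", "", "17, 18"),
    c("Terrestrial invertebrate", "Grasshopper", "Chorthippus p. parallelus and C. p. erythropus", "parapatry", "", "19, 20"),
    c("Terrestrial invertebrate", "Grasshopper", "Podisma pedestris races", "parapatry", "", "21, 22"),
    c("Terrestrial invertebrate", "Ladybird", "Epilachna pustulosa and E. vigintioctomaculata", "niche_partitioning", "Host plant separation", "23, 24"),
    c("Terrestrial invertebrate", "Ladybird", "Harmonia yedoensis and H. axyridis", "niche_partitioning", "Difference in prey item and habitat", "25"),
    c("Terrestrial invertebrate", "Fruit fly", "Drosophila yakuba and D. santomea", "parapatry", "Lowland versus highland distributions", "26, 27"),
    c("Terrestrial invertebrate", "Stalk-eyed fly", "Teleopsis dalmanni diverged populations", "allopatry", "", "28, 29"),
    c("Terrestrial invertebrate", "Damselfly", "Ischnura graellsii and I. elegans", "niche_partitioning", "The two species are rarely found in the same localities", "30-33"),
    c("Vertebrate", "Darter fish", "Etheostoma barrenense and E. zonale", "sympatry", "Not closely related within the genus", "34"),
    c("Vertebrate", "Darter fish", "Etheostoma hopkinsi and E. luteovinctum", "allopatry", "", "35"),
    c("Vertebrate", "Salmonid", "Salmo salar and S. trutta", "niche_partitioning", "Spatial and temporal segregation in spawning activities", "36-38"),
    c("Vertebrate", "Sunfish", "Lepomis macrochirus and L. gibbosus", "niche_partitioning", "Differences in nesting and breeding habits", "39, 40"),
    c("Vertebrate", "Bird", "Ficedula hypoleuca and F. albicollis", "niche_partitioning", "Separation in breeding habitat", "41-43"),
    c("Vertebrate", "Mouse", "Mus domesticus and M. musculus", "parapatry", "", "44, 45")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("group", "common_name", "species_pair", "category",
                 "description", "references")
  df
}

#' Path to the packaged mating-trial counts table
#'
#' @return File path of the packaged CSV of ladybird contingency counts (two
#'   behaviours x two years x two species).
#' @export
response_counts_file <- function() {
  system.file("extdata", "ladybird_response_counts.csv", package = "cspdyn",
              mustWork = TRUE)
}

#' Write the packaged study tables as CSV fixtures
#'
#' Writes `ladybird_response_counts.csv` (the 8 contingency-count rows for
#' male mating attempts and female rejection behaviour of the two *Harmonia*
#' species in the 2014 and 2015 trials) and `csp_species_pairs.csv` (the 24
#' comparative species-pair records) to `outdir`. Output is byte-stable across
#' runs.
#'
#' @param outdir a writable directory (created if necessary).
#' @return Invisibly, the two file paths.
#' @export
make_fixtures <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  counts_path <- file.path(outdir, "ladybird_response_counts.csv")
  pairs_path <- file.path(outdir, "csp_species_pairs.csv")
  write.csv(.ladybird_counts_data(), counts_path, row.names = FALSE)
  write.csv(.csp_pairs_data(), pairs_path, row.names = FALSE)
  invisible(c(counts = counts_path, pairs = pairs_path))
}
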