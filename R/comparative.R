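# Comparative table of species pairs exhibiting conspecific sperm precedence,
# classified by distribution/niche category.

.pair_categories <- c("sympatry", "niche_partitioning", "parapatry", "allopatry")

#' Load and validate a CSP species-pair table
#'
#' Reads a delimited table of congeneric species pairs in which conspecific
#' sperm precedence has been detected, each classified into one of four
#' distribution/niche categories: `sympatry` (broad range overlap with little
#' niche separation), `niche_partitioning` (range overlap but local separation
#' by food, habitat or season), `parapatry` (adjacent ranges with a narrow
#' contact zone), or `allopatry` (disjoint ranges).
#'
#' @param file path to a CSV file with columns `group`, `common_name`,
#'   `species_pair`, `category`, `description`, `references`. Defaults to the
#'   packaged 24-pair table.
#' @return A data frame of validated records (class `csp_pairs`).
#' @examples
#' pairs <- load_pairs()
#' nrow(pairs) # 24
#' @export
load_pairs <- function(file = csp_pairs_file()) {
  if (!file.exists(file)) stop("pairs file not found: ", file, call. = FALSE)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("group", "common_name", "species_pair", "category", "description",
            "references")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("pairs table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) stop("pairs table is empty", call. = FALSE)
  bad <- which(!df$category %in% .pair_categories)
  if (length(bad)) {
    stop("invalid category in row(s) ", paste(bad, collapse = ", "), ": ",
         paste(unique(df$category[bad]), collapse = ", "),
         " (must be one of ", paste(.pair_categories, collapse = ", "), ")",
         call. = FALSE)
  }
  structure(df, class = c("csp_pairs", "data.frame"))
}

#' Path to the packaged CSP species-pair table
#'
#' @return File path of the packaged CSV.
#' @export
csp_pairs_file <- function() {
  system.file("extdata", "csp_species_pairs.csv", package = "cspdyn",
              mustWork = TRUE)
}

#' Summarise species pairs by distribution/niche category
#'
#' @param records a data frame of species-pair records (from [load_pairs()]).
#' @return A list with `n` (record count), `by_category` (named integer vector
#'   in the fixed order sympatry, niche_partitioning, parapatry, allopatry)
#'   and `by_group` (a `table` of group x category).
#' @examples
#' category_summary(load_pairs())$by_category
#' @export
category_summary <- function(records) {
  if (!is.data.frame(records) || !nrow(records)) {
    stop("'records' must be a non-empty data frame", call. = FALSE)
  }
  cat_f <- factor(records$category, levels = .pair_categories)
  if (any(is.na(cat_f))) stop("records contain invalid categories", call. = FALSE)
  by_category <- table(cat_f)
  list(n = nrow(records),
       by_category = setNames(as.integer(by_category), .pair_categories),
       by_group = table(group = records$group, category = cat_f))
}
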