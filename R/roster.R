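#' Read a roster of individuals
#'
#' A roster lists every individual that can appear in the point-sample log,
#' one row per animal, with its species, sex and social group. Identifiers
#' are matched case-sensitively after stripping surrounding whitespace.
#'
#' @param path Path to a CSV file with header columns
#'   `id,species,sex,group` and optionally `age` (years).
#'
#' @return A tibble with columns `id`, `species`, `sex`, `group` and `age`
#'   (`NA` when absent from the file), one row per individual.
#' @seealso [living_links_roster()] for the packaged example roster.
#' @export
#' @examples
#' roster <- living_links_roster()
#' dplyr::count(roster, group, species)
read_roster <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("id", "species", "sex", "group")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("roster is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "groupness_format_error")
  }
  if (!"age" %in% names(df)) df$age <- NA_character_
  roster <- tibble(
    id      = trimws(df$id),
    species = trimws(df$species),
    sex     = trimws(df$sex),
    group   = trimws(df$group),
    age     = suppressWarnings(as.numeric(df$age))
  )
  validate_roster(roster)
}

#' Validate a roster data frame
#'
#' Checks the invariants every downstream step relies on: unique ids and
#' non-empty species and group labels.
#'
#' @param roster A data frame with columns `id`, `species`, `sex`, `group`
#'   and optionally `age`.
#' @return The roster as a tibble, invisibly unchanged, or an error.
#' @export
validate_roster <- function(roster) {
  roster <- as_tibble(roster)
  required <- c("id", "species", "sex", "group")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0) {
    abort(paste0("roster is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "groupness_format_error")
  }
  if (!"age" %in% names(roster)) roster$age <- NA_real_
  dup <- roster$id[duplicated(roster$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate individual id(s) in roster: ",
                 paste(unique(dup), collapse = ", ")),
          class = "groupness_validation_error")
  }
  if (nrow(roster) > 0 && any(!nzchar(roster$species) | is.na(roster$species))) {
    abort("species labels must be non-empty", class = "groupness_validation_error")
  }
  if (nrow(roster) > 0 && any(!nzchar(roster$group) | is.na(roster$group))) {
    abort("group labels must be non-empty", class = "groupness_validation_error")
  }
  roster[c("id", "species", "sex", "group", "age")]
}

#' Packaged roster of the Living Links mixed-species exhibit
#'
#' Demographics of the two mixed groups of tufted capuchins and common
#' squirrel monkeys housed at the Living Links Research Centre (Edinburgh
#' Zoo) at the time of the observational study the package's defaults
#' emulate: a West group of 18 capuchins and 9 squirrel monkeys and an
#' East group of 17 of each. Ages given as a range in the published
#' demographic table are stored as the midpoint.
#'
#' @param group Optional group label (`"West"` or `"East"`) to subset to.
#' @return A roster tibble (see [read_roster()]).
#' @export
#' @examples
#' nrow(living_links_roster("West"))
living_links_roster <- function(group = NULL) {
  path <- system.file("extdata", "living_links_roster.csv", package = "groupness")
  roster <- read_roster(path)
  if (!is.null(group)) {
    if (!all(group %in% roster$group)) {
      abort(paste0("unknown group label: ", paste(setdiff(group, roster$group), collapse = ", ")))
    }
    roster <- dplyr::filter(roster, .data$group %in% .env$group)
  }
  roster
}
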