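#' Read focal point samples
#'
#' An instantaneous point sample records a focal individual together with
#' every individual within the proximity threshold at that instant (its
#' neighbours); a focal with no neighbours is a solitary sample. Two CSV
#' dialects are accepted and auto-detected from the header:
#'
#' * **long** (canonical): one row per `(period, individual)` with columns
#'   `period_id,individual_id,role`, `role` being `"focal"` or
#'   `"neighbor"`; a solitary sample is a lone focal row.
#' * **wide**: one row per period with columns
#'   `period_id,focal_id,neighbor_ids`, neighbours separated by `;` (or
#'   empty for a solitary focal).
#'
#' @param path Path to a CSV file in either dialect.
#' @param roster Roster tibble (see [read_roster()]); every id in the log
#'   must resolve against it.
#' @return A tibble in canonical long form with columns `period_id`,
#'   `individual_id`, `role`, one row per identified individual per
#'   period.
#' @export
read_point_samples <- function(path, roster) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (all(c("period_id", "individual_id", "role") %in% names(df))) {
    samples <- tibble(
      period_id     = trimws(df$period_id),
      individual_id = trimws(df$individual_id),
      role          = trimws(df$role)
    )
  } else if (all(c("period_id", "focal_id", "neighbor_ids") %in% names(df))) {
    neighbors <- strsplit(ifelse(is.na(df$neighbor_ids), "", df$neighbor_ids), ";", fixed = TRUE)
    neighbors <- lapply(neighbors, function(x) trimws(x[nzchar(trimws(x))]))
    samples <- dplyr::bind_rows(
      tibble(period_id = trimws(df$period_id), individual_id = trimws(df$focal_id),
             role = "focal"),
      tibble(period_id = rep(trimws(df$period_id), lengths(neighbors)),
             individual_id = unlist(neighbors, use.names = FALSE) %||% character(0),
             role = "neighbor")
    )
    samples <- dplyr::arrange(samples, match(.data$period_id, trimws(df$period_id)))
  } else {
    abort(paste0(
      "unrecognised point-sample dialect; expected columns ",
      "period_id,individual_id,role (long) or period_id,focal_id,neighbor_ids (wide)"),
      class = "groupness_format_error")
  }
  validate_point_samples(samples, roster)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate point samples against a roster
#'
#' @param samples Tibble in canonical long form (`period_id`,
#'   `individual_id`, `role`).
#' @param roster Roster tibble.
#' @return The validated samples tibble.
#' @export
validate_point_samples <- function(samples, roster) {
  samples <- as_tibble(samples)
  stopifnot(all(c("period_id", "individual_id", "role") %in% names(samples)))
  bad_role <- setdiff(unique(samples$role), c("focal", "neighbor"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role label(s): ", paste(bad_role, collapse = ", ")),
          class = "groupness_validation_error")
  }
  unknown <- setdiff(unique(samples$individual_id), roster$id)
  if (length(unknown) > 0) {
    abort(paste0("id(s) not in roster: ", paste(unknown, collapse = ", ")),
          class = "groupness_validation_error")
  }
  dup <- duplicated(samples[c("period_id", "individual_id")])
  if (any(dup)) {
    offenders <- unique(paste0("(", samples$period_id[dup], ", ",
                               samples$individual_id[dup], ")"))
    abort(paste0("duplicated (period, individual) row(s): ",
                 paste(head(offenders, 10), collapse = ", ")),
          class = "groupness_validation_error")
  }
  focal_per_period <- tapply(samples$role == "focal", samples$period_id, sum)
  if (any(focal_per_period != 1)) {
    bad <- names(focal_per_period)[focal_per_period != 1]
    abort(paste0("each period must have exactly one focal; offending period(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "groupness_validation_error")
  }
  samples
}

#' Write point samples to CSV
#'
#' Writes the canonical long dialect read back by [read_point_samples()].
#'
#' @param samples Canonical long samples tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_samples <- function(samples, path) {
  readr::write_csv(samples[c("period_id", "individual_id", "role")], path)
  invisible(path)
}

#' Build a group-by-individual (GBI) matrix
#'
#' Pools point samples into the binary periods-by-individuals occurrence
#' matrix that association indices are computed from. Under the gambit of
#' the group, the focal and all of its neighbours in one period form one
#' observed group and are treated as mutually associated; a solitary focal
#' is a group of one. Each 1-minute point sample is one sampling period
#' (one row); rows are ordered by period id, columns follow roster order.
#'
#' @param samples Canonical long samples tibble (see
#'   [read_point_samples()]).
#' @param roster Roster tibble; defines the column set and order.
#' @return A binary matrix of class `gbi` with periods as rows and roster
#'   ids as columns, carrying the roster as attribute `roster`.
#' @export
#' @examples
#' roster <- tibble::tibble(id = c("A", "B", "C"), species = "sp",
#'                          sex = "F", group = "G", age = NA_real_)
#' samples <- tibble::tibble(period_id = c("p1", "p1", "p2"),
#'                           individual_id = c("A", "B", "C"),
#'                           role = c("focal", "neighbor", "focal"))
#' build_gbi(samples, roster)
build_gbi <- function(samples, roster) {
  samples <- validate_point_samples(samples, roster)
  if (nrow(samples) == 0) abort("no point samples supplied")
  periods <- sort(unique(samples$period_id))
  gbi <- matrix(0L, nrow = length(periods), ncol = nrow(roster),
                dimnames = list(periods, roster$id))
  gbi[cbind(match(samples$period_id, periods),
            match(samples$individual_id, roster$id))] <- 1L
  new_gbi(gbi, roster)
}

new_gbi <- function(mat, roster) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (any(rowSums(mat) < 1)) abort("every GBI row must contain at least one individual")
  structure(mat, roster = as_tibble(roster), class = c("gbi", class(mat)))
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("<gbi> %d sampling periods x %d individuals (%d solitary periods)\n",
              nrow(x), ncol(x), sum(rowSums(x) == 1)))
  invisible(x)
}

gbi_roster <- function(gbi) {
  roster <- attr(gbi, "roster")
  if (is.null(roster)) {
    abort("GBI matrix carries no roster attribute; build it with build_gbi()")
  }
  roster
}

# Strip the class/attributes for raw matrix arithmetic.
gbi_matrix <- function(gbi) {
  mat <- unclass(gbi)
  attr(mat, "roster") <- NULL
  mat
}
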