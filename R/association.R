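#' Dyadic association counts
#'
#' For every unordered pair of individuals `(a, b)` in the GBI, classifies
#' each sampling period into the counts that the simple ratio index is
#' built from:
#'
#' * `x` — periods with a and b observed associated (members of the same
#'   observed group);
#' * `ya` / `yb` — periods with just a (just b) identified;
#' * `yab` — periods with both identified but in different observed
#'   groups. Under single-focal sampling every period holds one observed
#'   group, so `yab` is structurally zero; it becomes informative when
#'   several observed groups share a sampling period, which is supported
#'   through the `periods` argument.
#'
#' Periods in which neither member is identified (`yNull`) never enter
#' the index and are not returned.
#'
#' @param gbi A `gbi` matrix (rows = observed groups, columns =
#'   individuals; see [build_gbi()]).
#' @param periods Optional vector, one entry per GBI row, mapping observed
#'   groups to sampling periods. Defaults to one group per period (the
#'   row names). An individual may belong to at most one observed group
#'   per period.
#' @return A tibble with one row per unordered dyad: `id_a`, `id_b`, `x`,
#'   `ya`, `yb`, `yab`, and `sri` (see [sri()]).
#' @export
dyad_counts <- function(gbi, periods = NULL) {
  mat <- gbi_matrix(gbi)
  if (nrow(mat) < 1) abort("GBI must contain at least one period")
  counts <- dyad_count_matrices(mat, periods)
  ids <- colnames(mat)
  idx <- which(upper.tri(counts$x), arr.ind = TRUE)
  n_ident <- counts$n_identified
  tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    x    = counts$x[idx],
    ya   = unname(n_ident[idx[, 1]]) - counts$both[idx],
    yb   = unname(n_ident[idx[, 2]]) - counts$both[idx],
    yab  = counts$both[idx] - counts$x[idx],
    sri  = counts$sri[idx]
  )
}

# Core vectorised counts shared by dyad_counts() and association_matrix().
# x: periods in same observed group; both: periods both identified;
# n_identified: periods each individual was identified in.
dyad_count_matrices <- function(mat, periods = NULL) {
  if (is.null(periods)) periods <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  stopifnot(length(periods) == nrow(mat))
  x <- crossprod(mat)
  if (anyDuplicated(periods)) {
    pres <- rowsum(mat, group = periods, reorder = FALSE)
    if (any(pres > 1)) {
      abort("an individual appears in more than one observed group within a period")
    }
  } else {
    pres <- mat
  }
  both <- crossprod(pres)
  n_identified <- diag(both)
  denom <- outer(n_identified, n_identified, "+") - both
  sri <- ifelse(denom > 0, x / denom, 0)
  diag(sri) <- 0
  list(x = x, both = both, n_identified = n_identified, sri = sri,
       never_identified = denom == 0)
}

#' Simple ratio index from dyadic counts
#'
#' The simple ratio index (SRI) estimates the proportion of sampling
#' periods a dyad spent associated among the periods in which either
#' member was identified:
#' \deqn{SRI = x / (y_a + y_b + y_{ab} + x)}
#' assuming periods where neither was identified (`yNull`) contribute
#' nothing. Values near 0 indicate the pair was rarely in proximity,
#' values near 1 that they were together whenever seen.
#'
#' @param x,ya,yb,yab Non-negative counts (vectorised); see
#'   [dyad_counts()].
#' @return SRI values in `[0, 1]`. A dyad whose denominator is zero (the
#'   pair was never identified) is defined as 0, with a warning.
#' @export
#' @examples
#' sri(x = 2, ya = 3, yb = 1, yab = 2)  # 0.25
sri <- function(x, ya, yb, yab = 0) {
  counts <- cbind(x, ya, yb, yab)
  if (any(counts < 0)) abort("association counts must be non-negative")
  denom <- x + ya + yb + yab
  out <- ifelse(denom > 0, x / denom, 0)
  if (any(denom == 0)) {
    warn("dyad(s) never identified in any period; SRI defined as 0")
  }
  unname(out)
}

#' SRI association matrix
#'
#' Applies the simple ratio index to every unordered dyad of the roster,
#' returning the symmetric individual-by-individual association matrix
#' that the social network is built from. The diagonal is undefined and
#' stored as 0.
#'
#' @inheritParams dyad_counts
#' @return A symmetric numeric matrix of class `association_matrix` with
#'   SRI entries in `[0, 1]`, the roster attached as attribute `roster`,
#'   and a logical attribute `never_identified` flagging dyads whose
#'   denominator was zero (stored as 0).
#' @export
association_matrix <- function(gbi, periods = NULL) {
  mat <- gbi_matrix(gbi)
  counts <- dyad_count_matrices(mat, periods)
  out <- counts$sri
  flag <- counts$never_identified
  diag(flag) <- FALSE
  structure(out,
            roster = attr(gbi, "roster"),
            never_identified = flag,
            class = c("association_matrix", class(out)))
}

#' @export
print.association_matrix <- function(x, ...) {
  vals <- x[upper.tri(x)]
  cat(sprintf("<association_matrix> %d individuals, mean SRI %.3f (range %.3f-%.3f)\n",
              ncol(x), mean(vals), min(vals), max(vals)))
  invisible(x)
}

#' Mean dyadic association rate
#'
#' Arithmetic mean and sample standard deviation of the SRI over unordered
#' dyads, zeros included. An optional predicate on the two species labels
#' restricts the summary to a dyad class, e.g. mixed-species dyads only.
#'
#' @param matrix An `association_matrix` (or plain symmetric matrix with a
#'   roster supplied).
#' @param dyad_filter Optional predicate `function(species_a, species_b)`
#'   returning `TRUE` for dyads to keep. Convenience helpers:
#'   [within_species_dyads()], [mixed_species_dyads()].
#' @param roster Roster tibble; defaults to the matrix's `roster`
#'   attribute.
#' @return A one-row tibble with `mean`, `sd` and `n_dyads`.
#' @export
#' @examples
#' # m <- association_matrix(gbi)
#' # mean_association_rate(m, mixed_species_dyads)
mean_association_rate <- function(matrix, dyad_filter = NULL, roster = NULL) {
  roster <- roster %||% attr(matrix, "roster")
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(dyad_filter)) {
    if (is.null(roster)) abort("a roster is required to filter dyads by species")
    sp <- roster$species[match(colnames(matrix), roster$id)]
    keep <- mapply(dyad_filter, sp[idx[, 1]], sp[idx[, 2]])
  }
  if (!any(keep)) abort("no dyads left after filtering")
  vals <- matrix[idx][keep]
  tibble(mean = mean(vals), sd = sd(vals), n_dyads = length(vals))
}

#' Dyad class predicates
#'
#' Helpers for `dyad_filter` arguments: keep within-species or
#' mixed-species dyads.
#'
#' @param species_a,species_b Species labels of the two dyad members.
#' @return Logical.
#' @export
within_species_dyads <- function(species_a, species_b) species_a == species_b

#' @rdname within_species_dyads
#' @export
mixed_species_dyads <- function(species_a, species_b) species_a != species_b

#' Write an association matrix as labelled adjacency CSV
#'
#' @param matrix Association (or any labelled symmetric) matrix.
#' @param path Output CSV path; first column holds the row ids.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(matrix, path) {
  df <- as.data.frame(unclass(matrix)[seq_len(nrow(matrix)), , drop = FALSE])
  df <- cbind(id = rownames(matrix) %||% colnames(matrix), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}
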