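# Small in-code fixtures shared across test files.

toy_roster <- function(ids = c("A", "B", "C"),
                       species = rep("sp1", length(ids)),
                       group = rep("G", length(ids))) {
  tibble::tibble(id = ids, species = species, sex = "F", group = group,
                 age = NA_real_)
}

# GBI from a list of character vectors, one observed group per period.
gbi_from_groups <- function(groups, roster) {
  samples <- dplyr::bind_rows(lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    tibble::tibble(period_id = sprintf("p%03d", i),
                   individual_id = members,
                   role = c("focal", rep("neighbor", length(members) - 1)))
  }))
  build_gbi(samples, roster)
}

# Network straight from a weighted adjacency matrix.
net_from_adjacency <- function(adj, roster = NULL, threshold = 0) {
  roster <- roster %||% toy_roster(rownames(adj))
  attr(adj, "roster") <- roster
  build_network(adj, threshold = threshold, roster = roster)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
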