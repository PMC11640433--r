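#' Run the full mixed-species groupness analysis
#'
#' One call from point samples to inference, per social group: builds the
#' GBI and SRI association matrix, the SRI-weighted network and its node
#' and species-level metrics, then runs (i) the data-stream randomization
#' test of the mean association rate (overall and mixed-species dyads)
#' and (ii) a node-label permutation t-test per node metric (degree,
#' eigenvector, betweenness, clustering) between the two species, flagged
#' against the Bonferroni-adjusted alpha. Groups are always analyzed as
#' separate networks.
#'
#' @param samples Canonical long point-sample tibble.
#' @param roster Roster tibble; the `group` column partitions the
#'   analysis.
#' @param groups Group labels to analyze (default: all in the roster).
#' @param threshold Edge threshold on the SRI (default 0).
#' @param iterations Permutation iterations for both tests (default
#'   1000).
#' @param burn_in,swaps_per_iteration Data-stream chain settings (see
#'   [network_randomization_test()]).
#' @param seed Integer seed, required; sub-seeds for each test are
#'   derived from it deterministically.
#' @param alpha Family-wise significance level (default 0.05).
#' @param comparisons Size of the metric family for the Bonferroni
#'   adjustment (default 4).
#' @param path_weight Geodesic convention for path-based metrics (see
#'   [betweenness_centrality()]).
#' @param datastream Set `FALSE` to skip the (comparatively slow)
#'   data-stream randomization tests.
#' @param output_dir If non-`NULL`, artifacts (CSV/GraphML/JSON and a run
#'   log) are written here, one subdirectory per group.
#' @return A list of class `groupness_analysis`: one entry per group
#'   (class `groupness_group_analysis`) plus `settings`.
#' @export
run_analysis <- function(samples, roster, groups = NULL, threshold = 0,
                         iterations = 1000, burn_in = 1000,
                         swaps_per_iteration = 10, seed, alpha = 0.05,
                         comparisons = 4, path_weight = c("sri", "inverse"),
                         datastream = TRUE, output_dir = NULL) {
  if (missing(seed) || is.null(seed)) abort("a seed is required for permutation tests")
  path_weight <- match.arg(path_weight)
  roster <- validate_roster(roster)
  groups <- groups %||% unique(roster$group)
  alpha_adjusted <- bonferroni_adjust(alpha, comparisons)
  settings <- list(threshold = threshold, iterations = iterations,
                   burn_in = burn_in, swaps_per_iteration = swaps_per_iteration,
                   seed = seed, alpha = alpha, comparisons = comparisons,
                   alpha_adjusted = alpha_adjusted, path_weight = path_weight,
                   version = as.character(packageVersion("groupness")))
  result <- list(settings = settings)
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    result[[grp]] <- analyze_one_group(
      samples, roster, grp, settings,
      seed = seed + 1000L * gi, datastream = datastream
    )
  }
  class(result) <- "groupness_analysis"
  if (!is.null(output_dir)) write_analysis(result, output_dir)
  result
}

analyze_one_group <- function(samples, roster, grp, settings, seed, datastream) {
  sub_roster <- roster[roster$group == grp, ]
  if (nrow(sub_roster) < 2) abort(paste0("group '", grp, "' has fewer than 2 individuals"))
  sub_samples <- samples[samples$individual_id %in% sub_roster$id, ]
  sub_samples <- sub_samples[sub_samples$period_id %in%
                               sub_samples$period_id[sub_samples$role == "focal"], ]
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("analysis of group '", grp, "' failed at stage <", stage, ">: ",
                   conditionMessage(e)))
    })
  }
  gbi <- step("build_gbi", build_gbi(sub_samples, sub_roster))
  amat <- step("association_matrix", association_matrix(gbi))
  net <- step("build_network", build_network(amat, threshold = settings$threshold))
  metrics <- step("node_metrics", node_metrics(net, settings$path_weight))
  summary <- step("species_summary", species_summary(metrics))
  overall_rate <- mean_association_rate(amat)
  two_species <- length(unique(sub_roster$species)) == 2
  rand_tests <- list()
  if (datastream) {
    rand_tests$mean_sri <- step("network_randomization_test", network_randomization_test(
      gbi, function(m) mean_association_rate(m)$mean,
      iterations = settings$iterations, burn_in = settings$burn_in,
      swaps_per_iteration = settings$swaps_per_iteration, seed = seed))
    if (two_species) {
      rand_tests$mixed_mean_sri <- step("network_randomization_test", network_randomization_test(
        gbi, function(m) mean_association_rate(m, mixed_species_dyads)$mean,
        iterations = settings$iterations, burn_in = settings$burn_in,
        swaps_per_iteration = settings$swaps_per_iteration, seed = seed + 1L))
    }
  }
  metric_tests <- NULL
  if (two_species) {
    species_levels <- unique(sub_roster$species)
    metric_tests <- purrr::imap(
      c(degree = "degree", eigenvector = "eigenvector",
        betweenness = "betweenness", clustering = "clustering"),
      function(col, name) {
        step(paste0("node_label_permutation_test[", name, "]"),
             node_label_permutation_test(
               metrics[[col]], factor(metrics$species, levels = species_levels),
               iterations = settings$iterations, seed = seed + 10L + match(name, names(metrics))))
      })
  }
  out <- list(
    group = grp, roster = sub_roster, gbi = gbi, matrix = amat, network = net,
    metrics = metrics, species_summary = summary,
    density = network_density(net),
    mean_association = overall_rate,
    mean_association_within = if (two_species)
      mean_association_rate(amat, within_species_dyads) else NULL,
    mean_association_mixed = if (two_species)
      mean_association_rate(amat, mixed_species_dyads) else NULL,
    path_length = average_path_length(net, path_weight = settings$path_weight),
    randomization_tests = rand_tests,
    metric_tests = metric_tests,
    counts = list(
      n_periods = nrow(gbi),
      n_solitary = sum(rowSums(gbi) == 1),
      n_never_identified_dyads =
        sum(attr(amat, "never_identified")[upper.tri(amat)])
    ),
    seed = seed
  )
  class(out) <- "groupness_group_analysis"
  out
}

#' @export
print.groupness_group_analysis <- function(x, ...) {
  cat(sprintf("<groupness analysis: group %s>\n", x$group))
  cat(sprintf("  %d individuals, %d periods (%d solitary)\n",
              nrow(x$roster), x$counts$n_periods, x$counts$n_solitary))
  cat(sprintf("  density %.3f; mean SRI %.3f (SD %.3f)\n",
              x$density, x$mean_association$mean, x$mean_association$sd))
  if (!is.null(x$metric_tests)) {
    for (nm in names(x$metric_tests)) {
      t <- x$metric_tests[[nm]]
      cat(sprintf("  %-12s diff = %8.3f  p = %.4g\n", nm, t$observed, t$p_two_tailed))
    }
  }
  invisible(x)
}

#' @export
print.groupness_analysis <- function(x, ...) {
  for (nm in setdiff(names(x), "settings")) print(x[[nm]])
  invisible(x)
}

#' @export
tidy.groupness_group_analysis <- function(x, ...) {
  if (is.null(x$metric_tests)) return(tibble())
  purrr::imap_dfr(x$metric_tests, function(t, metric) {
    dplyr::mutate(tidy(t), metric = metric, group = x$group,
                  .before = 1)
  })
}

#' @export
tidy.groupness_analysis <- function(x, ...) {
  purrr::map_dfr(x[setdiff(names(x), "settings")], tidy)
}

#' @export
glance.groupness_group_analysis <- function(x, ...) {
  tibble(group = x$group, n_individuals = nrow(x$roster),
         n_periods = x$counts$n_periods, n_solitary = x$counts$n_solitary,
         density = x$density, mean_sri = x$mean_association$mean,
         sd_sri = x$mean_association$sd)
}

#' @export
glance.groupness_analysis <- function(x, ...) {
  purrr::map_dfr(x[setdiff(names(x), "settings")], glance)
}

write_analysis <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  settings <- result$settings
  for (nm in setdiff(names(result), "settings")) {
    x <- result[[nm]]
    gdir <- file.path(output_dir, nm)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    write_association_matrix(x$matrix, file.path(gdir, "association_matrix.csv"))
    write_network(x$network, file.path(gdir, "network.graphml"), "graphml")
    write_network(x$network, file.path(gdir, "edges.csv"), "edgelist")
    readr::write_csv(x$metrics, file.path(gdir, "node_metrics.csv"))
    readr::write_csv(x$species_summary, file.path(gdir, "species_summary.csv"))
    tests <- c(
      purrr::imap(x$randomization_tests, function(t, nm2) {
        write_permutation_result(t, file.path(gdir, paste0("randomization_", nm2, ".json")))
        NULL
      }),
      purrr::imap(x$metric_tests %||% list(), function(t, nm2) {
        write_permutation_result(t, file.path(gdir, paste0("metric_test_", nm2, ".json")))
        NULL
      })
    )
    summary_json <- list(
      group = x$group, density = x$density,
      mean_association = as.list(x$mean_association),
      path_length = as.list(x$path_length),
      counts = x$counts, seed = x$seed, settings = settings
    )
    jsonlite::write_json(summary_json, file.path(gdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_lines <- c(
      sprintf("groupness %s analysis run, group %s", settings$version, x$group),
      sprintf("seed: %d (root %d)", x$seed, settings$seed),
      sprintf("periods: %d; solitary samples: %d; never-identified dyads: %d",
              x$counts$n_periods, x$counts$n_solitary,
              x$counts$n_never_identified_dyads),
      sprintf("iterations: %d, burn-in: %d, swaps/iteration: %d",
              settings$iterations, settings$burn_in, settings$swaps_per_iteration),
      sprintf("alpha: %g (Bonferroni-adjusted: %g over %d comparisons)",
              settings$alpha, settings$alpha_adjusted, settings$comparisons)
    )
    writeLines(log_lines, file.path(gdir, "run_log.txt"))
  }
  invisible(output_dir)
}

#' Analyze deposited observation CSVs end to end
#'
#' Thin wrapper for reproducing a published analysis from its deposited
#' roster and point-sample files: reads both, runs [run_analysis()], and
#' returns the headline per-group summary (density, mean +/- SD
#' association rate, observed species differences per metric).
#'
#' @param roster_path,samples_path CSV paths (see [read_roster()],
#'   [read_point_samples()]).
#' @param ... Passed to [run_analysis()].
#' @return A list with the full `groupness_analysis` (`analysis`) and a
#'   headline tibble (`headline`): one row per group with `density`,
#'   `mean_sri`, `sd_sri` and `diff_<metric>` columns.
#' @export
analyze_deposit <- function(roster_path, samples_path, ...) {
  if (!file.exists(roster_path)) abort(paste0("roster file not found: ", roster_path))
  if (!file.exists(samples_path)) abort(paste0("samples file not found: ", samples_path))
  roster <- read_roster(roster_path)
  samples <- read_point_samples(samples_path, roster)
  analysis <- run_analysis(samples, roster, ...)
  headline <- glance(analysis)
  diffs <- tidy(analysis)
  if (nrow(diffs) > 0) {
    wide <- tidyr::pivot_wider(diffs[c("group", "metric", "observed")],
                               names_from = "metric", values_from = "observed",
                               names_prefix = "diff_")
    headline <- dplyr::left_join(headline, wide, by = "group")
  }
  list(analysis = analysis, headline = headline)
}

#' Published species-level network summary
#'
#' The species-by-group table of network metric means (and SDs) reported
#' for the Living Links mixed-species networks, packaged for
#' internal-consistency checks such as recovering the printed network
#' densities from the size-weighted mean degree.
#'
#' @return Tibble with columns `group`, `species`, `n` and
#'   `<metric>_mean`/`<metric>_sd` for the four node metrics.
#' @export
published_network_summary <- function() {
  readr::read_csv(system.file("extdata", "published_network_summary.csv",
                              package = "groupness"),
                  col_types = readr::cols(group = readr::col_character(),
                                          species = readr::col_character(),
                                          .default = readr::col_double()))
}

#' @rdname published_network_summary
#' @export
published_group_statistics <- function() {
  readr::read_csv(system.file("extdata", "published_group_statistics.csv",
                              package = "groupness"),
                  col_types = readr::cols(group = readr::col_character(),
                                          .default = readr::col_double()))
}
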