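#' Configure a synthetic focal-sampling study
#'
#' Describes a latent dyadic association model plus the focal observation
#' design used to sample it. The defaults emulate the observational study
#' the package's examples are based on: every individual is the focal of
#' 18 ten-minute follows sampled at 1-minute intervals (180 point samples
#' each), and association is strongly species-assortative — a same-species
#' dyad is in proximity in a given sample with probability `p_within`,
#' a mixed-species dyad with the much smaller `p_between`.
#'
#' @param species_sizes Named integer vector, individuals per species.
#'   Defaults to a West-like composition of 18 capuchins and 9 squirrel
#'   monkeys; use `c(capuchin = 17, squirrel_monkey = 17)` for an
#'   East-like group.
#' @param p_within Per-sample association probability for same-species
#'   dyads (default 0.15).
#' @param p_between Per-sample association probability for mixed-species
#'   dyads (default 0.01).
#' @param gregariousness_sd SD (log scale) of per-individual lognormal
#'   multipliers on association probabilities; mean 1, default 0
#'   (homogeneous, required for closed-form checks).
#' @param subgroup_split Optional named list `list(species =, n_cliques =,
#'   cross_multiplier =)` partitioning one species into equally sized
#'   cliques whose cross-clique association probability is `p_within *
#'   cross_multiplier`.
#' @param shared_space_prob Multiplicative gate in `[0, 1]` applied to
#'   mixed-species dyads only, emulating limited co-use of shared
#'   enclosure space (default 1 = no gating).
#' @param follows_per_individual,samples_per_follow Observation design
#'   (defaults 18 and 10).
#' @param group_label Group label written into the synthetic roster.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(species_sizes = c(capuchin = 18, squirrel_monkey = 9),
                             p_within = 0.15, p_between = 0.01,
                             gregariousness_sd = 0, subgroup_split = NULL,
                             shared_space_prob = 1,
                             follows_per_individual = 18, samples_per_follow = 10,
                             group_label = "synthetic", seed = 1L) {
  if (is.null(names(species_sizes)) || any(!nzchar(names(species_sizes)))) {
    abort("species_sizes must be a named vector")
  }
  if (any(species_sizes < 1)) abort("each species needs at least one individual")
  for (p in c(p_within, p_between, shared_space_prob)) {
    if (!is.numeric(p) || p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (gregariousness_sd < 0) abort("gregariousness_sd must be non-negative")
  if (follows_per_individual < 1 || samples_per_follow < 1) {
    abort("follows and samples per follow must be at least 1")
  }
  if (!is.null(subgroup_split)) {
    stopifnot(all(c("species", "n_cliques", "cross_multiplier") %in% names(subgroup_split)),
              subgroup_split$species %in% names(species_sizes),
              subgroup_split$n_cliques >= 2)
  }
  structure(list(
    species_sizes = species_sizes, p_within = p_within, p_between = p_between,
    gregariousness_sd = gregariousness_sd, subgroup_split = subgroup_split,
    shared_space_prob = shared_space_prob,
    follows_per_individual = as.integer(follows_per_individual),
    samples_per_follow = as.integer(samples_per_follow),
    group_label = group_label, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic roster
#'
#' Ids are deterministic (`<species>_01`, ...); sex is assigned uniformly
#' at random under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A roster tibble (see [read_roster()]).
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  species <- rep(names(config$species_sizes), config$species_sizes)
  ids <- unlist(lapply(names(config$species_sizes), function(s) {
    sprintf("%s_%02d", s, seq_len(config$species_sizes[[s]]))
  }), use.names = FALSE)
  sex <- with_seed(config$seed, sample(c("F", "M"), length(ids), replace = TRUE))
  validate_roster(tibble(id = ids, species = species, sex = sex,
                         group = config$group_label, age = NA_real_))
}

# Latent per-dyad per-sample association probabilities (before
# gregariousness), as a symmetric matrix over the roster.
pair_probability_matrix <- function(config, roster) {
  n <- nrow(roster)
  same <- outer(roster$species, roster$species, "==")
  pm <- ifelse(same, config$p_within, config$p_between * config$shared_space_prob)
  split <- config$subgroup_split
  if (!is.null(split)) {
    in_sp <- roster$species == split$species
    clique <- integer(n)
    clique[in_sp] <- rep(seq_len(split$n_cliques), length.out = sum(in_sp))
    cross <- in_sp & outer(clique, clique, "!=") & same
    cross <- cross & matrix(in_sp, n, n) & matrix(in_sp, n, n, byrow = TRUE)
    pm[cross] <- config$p_within * split$cross_multiplier
  }
  diag(pm) <- 0
  dimnames(pm) <- list(roster$id, roster$id)
  pm
}

#' Simulate focal point samples
#'
#' Runs the focal observation design over the latent dyadic model: the
#' focal schedule is a round robin (each individual focal in
#' `follows_per_individual * samples_per_follow` periods) and, in each
#' period, every non-focal individual independently joins the focal's
#' neighbour set with probability
#' `min(1, p_pair(focal, j) * g_focal * g_j)`, where `g` are the lognormal
#' gregariousness multipliers. Draws are independent across periods and
#' dyads; beyond the focal there is no group coherence, which is a
#' documented simplification.
#'
#' @param roster Roster from [generate_roster()] (or any roster whose
#'   species appear in the config).
#' @param config A [synthetic_config()].
#' @return A canonical long point-sample tibble (see
#'   [read_point_samples()]).
#' @export
simulate_point_samples <- function(roster, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(roster)
  per_focal <- config$follows_per_individual * config$samples_per_follow
  pm <- pair_probability_matrix(config, roster)
  with_seed(config$seed + 1L, {
    g <- if (config$gregariousness_sd > 0) {
      exp(rnorm(n, mean = -config$gregariousness_sd^2 / 2,
                sd = config$gregariousness_sd))
    } else {
      rep(1, n)
    }
    prob <- pmin(pm * outer(g, g), 1)
    # one block of periods per focal; vectorised Bernoulli draws
    blocks <- lapply(seq_len(n), function(f) {
      draws <- matrix(runif(per_focal * n) < rep(prob[f, ], each = per_focal),
                      nrow = per_focal)
      draws[, f] <- FALSE
      hits <- which(draws, arr.ind = TRUE)
      period_ids <- sprintf("p%06d", (f - 1L) * per_focal + seq_len(per_focal))
      dplyr::bind_rows(
        tibble(period_id = period_ids, individual_id = roster$id[f], role = "focal"),
        tibble(period_id = period_ids[hits[, 1]],
               individual_id = roster$id[hits[, 2]], role = "neighbor")
      )
    })
    samples <- dplyr::bind_rows(blocks)
  })
  dplyr::arrange(samples, .data$period_id, .data$role, .data$individual_id)
}

#' Closed-form expected SRI for a dyad class
#'
#' For the homogeneous model (`gregariousness_sd = 0`) the per-period
#' probabilities of co-occurrence and identification follow directly from
#' the sampling schedule, giving the plug-in approximation
#' `E[x] / (E[x] + E[ya] + E[yb])` to the expected SRI of a dyad class
#' (under single-focal sampling `yab` is structurally 0). This is an
#' approximation — the expectation of a ratio is not the ratio of
#' expectations — and is intended for tolerance-based checks of parameter
#' recovery, not exact prediction.
#'
#' @param config A [synthetic_config()] with `gregariousness_sd = 0`.
#' @param dyad_type `"within"` (same species, same clique) or
#'   `"between"` (mixed species).
#' @param species For `"within"`, which species (default: the first); for
#'   `"between"`, a length-2 vector (default: the first two).
#' @return Approximate expected SRI (single number).
#' @export
expected_sri <- function(config, dyad_type = c("within", "between"), species = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dyad_type <- match.arg(dyad_type)
  if (config$gregariousness_sd > 0) {
    abort("no closed form with heterogeneous gregariousness; set gregariousness_sd = 0")
  }
  roster <- suppressWarnings(generate_roster(config))
  pm <- pair_probability_matrix(config, roster)
  sp <- roster$species
  if (dyad_type == "within") {
    species <- species %||% names(config$species_sizes)[1]
    cand <- which(sp == species)
    if (length(cand) < 2) abort("need at least two individuals of the species")
    a <- cand[1]; b <- cand[2]
  } else {
    species <- species %||% names(config$species_sizes)[1:2]
    if (length(unique(species)) < 2) abort("'between' needs two distinct species")
    a <- which(sp == species[1])[1]
    b <- which(sp == species[2])[1]
  }
  t_per <- config$follows_per_individual * config$samples_per_follow
  others <- setdiff(seq_len(nrow(roster)), c(a, b))
  e_x <- t_per * (2 * pm[a, b] + sum(pm[a, others] * pm[b, others]))
  e_na <- t_per * (1 + sum(pm[a, -a]))
  e_nb <- t_per * (1 + sum(pm[b, -b]))
  # denominator = n_a + n_b - both identified; both identified = associated here
  e_x / (e_na + e_nb - e_x)
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: roster, point samples, GBI and association matrix
#' in one call.
#'
#' @param config A [synthetic_config()].
#' @return List with `roster`, `samples`, `gbi`, `matrix`.
#' @export
simulate_study <- function(config) {
  roster <- generate_roster(config)
  samples <- simulate_point_samples(roster, config)
  gbi <- build_gbi(samples, roster)
  list(roster = roster, samples = samples, gbi = gbi,
       matrix = association_matrix(gbi))
}
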