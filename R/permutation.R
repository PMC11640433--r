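#' One data-stream swap on a GBI matrix
#'
#' The elementary move of the data-stream (network) permutation: find a
#' 2x2 checkerboard — two periods `p`, `q` and two individuals `A`, `B`
#' with `A` present only in `p` and `B` present only in `q` — and exchange
#' them. The swap preserves every individual's total number of
#' observations (column sums) and every period's observed group size (row
#' sums), so the randomized data keep the gregariousness and sampling
#' structure of the original while shuffling who associates with whom.
#'
#' @param gbi A `gbi` matrix.
#' @param max_tries Bounded retries before declaring the data degenerate
#'   (e.g. a single period, or all periods identical).
#' @return The GBI with one swap applied.
#' @export
datastream_swap <- function(gbi, max_tries = 1000) {
  mat <- gbi_matrix(gbi)
  swapped <- swap_once(mat, max_tries)
  new_gbi(swapped, attr(gbi, "roster"))
}

swap_once <- function(mat, max_tries = 1000) {
  n_row <- nrow(mat)
  if (n_row < 2) abort("no valid swap exists: fewer than two periods")
  for (i in seq_len(max_tries)) {
    pq <- sample.int(n_row, 2)
    a_candidates <- which(mat[pq[1], ] == 1L & mat[pq[2], ] == 0L)
    b_candidates <- which(mat[pq[2], ] == 1L & mat[pq[1], ] == 0L)
    if (length(a_candidates) > 0 && length(b_candidates) > 0) {
      a <- a_candidates[sample.int(length(a_candidates), 1)]
      b <- b_candidates[sample.int(length(b_candidates), 1)]
      mat[pq[1], a] <- 0L; mat[pq[2], a] <- 1L
      mat[pq[2], b] <- 0L; mat[pq[1], b] <- 1L
      return(mat)
    }
  }
  abort(paste0("no valid swap found after ", max_tries,
               " tries; the GBI is degenerate for data-stream permutation"))
}

#' Data-stream network randomization test
#'
#' Tests whether a statistic of the association matrix differs from what
#' random association under the observed sampling structure would
#' produce. A serial chain of checkerboard swaps (see [datastream_swap()])
#' randomizes the GBI; after `burn_in` swaps the statistic is recorded
#' every `swaps_per_iteration` swaps, giving `iterations` null values
#' against which the observed statistic is compared. Because each null
#' network differs from the previous one by a few swaps, the chain as a
#' whole — not any single draw — represents the null.
#'
#' p-values follow the proportion-more-extreme rule, counting null values
#' equal to the observed statistic as extreme: `p_lower = P(null <=
#' observed)`, `p_upper = P(null >= observed)`, and the two-tailed value
#' is `min(1, 2 min(p_lower, p_upper))`. Add-one corrected versions
#' `(b + 1)/(N + 1)` are reported alongside the raw proportions.
#'
#' @param gbi A `gbi` matrix.
#' @param statistic Function mapping an [association_matrix()] to a
#'   single finite number, e.g.
#'   `function(m) mean_association_rate(m)$mean`.
#' @param iterations Number of null statistics to record (default 1000).
#' @param burn_in Swaps applied before recording starts (default 1000).
#' @param swaps_per_iteration Swaps between recorded statistics (default
#'   10).
#' @param seed Integer seed; the whole chain is reproducible from it.
#' @return A `permutation_result` (see [node_label_permutation_test()]
#'   for the shared fields).
#' @export
network_randomization_test <- function(gbi, statistic, iterations = 1000,
                                       burn_in = 1000, swaps_per_iteration = 10,
                                       seed) {
  stopifnot(iterations >= 1, burn_in >= 0, swaps_per_iteration >= 1)
  roster <- attr(gbi, "roster")
  mat <- gbi_matrix(gbi)
  eval_stat <- function(m) {
    val <- statistic(association_matrix(new_gbi(m, roster)))
    if (!is.finite(val)) abort("statistic returned a non-finite value")
    val
  }
  observed <- eval_stat(mat)
  null_values <- numeric(iterations)
  with_seed(seed, {
    for (i in seq_len(burn_in)) mat <- swap_once(mat)
    for (it in seq_len(iterations)) {
      for (i in seq_len(swaps_per_iteration)) mat <- swap_once(mat)
      null_values[it] <- eval_stat(mat)
    }
  })
  new_permutation_result(
    observed = observed, null_values = null_values, seed = seed,
    method = "datastream",
    settings = list(iterations = iterations, burn_in = burn_in,
                    swaps_per_iteration = swaps_per_iteration)
  )
}

#' Node-label permutation t-test
#'
#' Compares the mean of a node-level metric between two species by
#' shuffling the species labels: the observed statistic is
#' `mean(first level) - mean(second level)`; each iteration reassigns the
#' labels at random (without replacement) and recomputes the difference.
#' The two-tailed p-value is the proportion of permuted differences at
#' least as large in absolute value as the observed one; directional
#' p-values and add-one corrected versions are reported as well.
#'
#' With `method = "exhaustive"` all distinct label assignments are
#' enumerated instead of sampled, giving the exact permutation p-value
#' (feasible for small groups; the observed assignment is one of the
#' enumerated cases, so raw p-values are strictly positive).
#'
#' @param values Numeric vector of per-individual metric values.
#'   Non-finite values (e.g. undefined clustering coefficients) are
#'   dropped with their labels.
#' @param labels Two-level factor/character vector, same length as
#'   `values`. The first level (factor order, or order of first
#'   appearance) is the minuend of the difference.
#' @param iterations Number of random shuffles (ignored for exhaustive).
#' @param seed Integer seed (ignored for exhaustive).
#' @param method `"sampled"` (default) or `"exhaustive"`.
#' @return A `permutation_result`: list with `observed`, `null_values`,
#'   `iterations`, `seed`, `p_lower`, `p_upper`, `p_two_tailed`, their
#'   `_add_one` variants, `method` and `settings`.
#' @export
#' @examples
#' node_label_permutation_test(c(10, 11, 1, 2), c("a", "a", "b", "b"),
#'                             method = "exhaustive")$p_two_tailed  # 1/3
node_label_permutation_test <- function(values, labels, iterations = 1000,
                                        seed = NULL, method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  keep <- is.finite(values)
  values <- values[keep]
  labels <- if (is.factor(labels)) droplevels(labels[keep]) else labels[keep]
  lev <- if (is.factor(labels)) levels(labels) else unique(labels)
  if (length(lev) != 2) abort("labels must have exactly two levels")
  is_first <- labels == lev[1]
  n1 <- sum(is_first); n2 <- sum(!is_first)
  if (n1 == 0 || n2 == 0) abort("both label levels must have at least one member")
  diff_for <- function(first_idx) {
    mean(values[first_idx]) - mean(values[-first_idx])
  }
  observed <- mean(values[is_first]) - mean(values[!is_first])
  if (method == "exhaustive") {
    combos <- combn(length(values), n1)
    null_values <- apply(combos, 2, diff_for)
    iterations <- ncol(combos)
    seed <- NA_integer_
  } else {
    stopifnot(iterations >= 1)
    null_values <- numeric(iterations)
    with_seed(seed, {
      for (it in seq_len(iterations)) {
        null_values[it] <- diff_for(sample.int(length(values), n1))
      }
    })
  }
  new_permutation_result(
    observed = observed, null_values = null_values,
    seed = seed %||% NA_integer_, method = paste0("node_label_", method),
    settings = list(iterations = iterations, n_first = n1, n_second = n2,
                    levels = lev)
  )
}

# p-values by the proportion-equal-or-more-extreme rule; ties counted as
# extreme, with a tiny tolerance so floating-point jitter in recomputed
# means does not break exact ties.
new_permutation_result <- function(observed, null_values, seed, method, settings) {
  tol <- 1e-12
  n <- length(null_values)
  b_lower <- sum(null_values <= observed + tol)
  b_upper <- sum(null_values >= observed - tol)
  b_two <- sum(abs(null_values) >= abs(observed) - tol)
  structure(list(
    observed = observed,
    null_values = null_values,
    iterations = n,
    seed = seed,
    p_lower = b_lower / n,
    p_upper = b_upper / n,
    p_two_tailed = if (startsWith(method, "node_label")) b_two / n
                   else min(1, 2 * min(b_lower, b_upper) / n),
    p_lower_add_one = (b_lower + 1) / (n + 1),
    p_upper_add_one = (b_upper + 1) / (n + 1),
    p_two_tailed_add_one = if (startsWith(method, "node_label")) (b_two + 1) / (n + 1)
                           else min(1, 2 * min(b_lower + 1, b_upper + 1) / (n + 1)),
    add_one_correction = TRUE,
    method = method,
    settings = settings
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: %s>\n", x$method))
  cat(sprintf("  observed = %.6g  (null mean %.6g over %d iterations)\n",
              x$observed, mean(x$null_values), x$iterations))
  cat(sprintf("  p_two_tailed = %.4g   p_lower = %.4g   p_upper = %.4g\n",
              x$p_two_tailed, x$p_lower, x$p_upper))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_values),
         null_sd = sd(x$null_values),
         p_two_tailed = x$p_two_tailed, p_lower = x$p_lower,
         p_upper = x$p_upper,
         p_two_tailed_add_one = x$p_two_tailed_add_one)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(method = x$method, iterations = x$iterations, seed = x$seed)
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, linetype = "dashed") +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = sprintf("%s permutation (p = %.4g, %d iterations)",
                                  object$method, object$p_two_tailed,
                                  object$iterations))
}

#' Serialize a permutation result to JSON
#'
#' @param x A `permutation_result`.
#' @param path Output path.
#' @param include_null Store the full null vector (default: a summary
#'   only).
#' @return `path`, invisibly.
#' @export
write_permutation_result <- function(x, path, include_null = FALSE) {
  out <- x[c("observed", "iterations", "seed", "p_lower", "p_upper",
             "p_two_tailed", "p_lower_add_one", "p_upper_add_one",
             "p_two_tailed_add_one", "add_one_correction", "method", "settings")]
  out$null_summary <- list(mean = mean(x$null_values), sd = sd(x$null_values),
                           quantiles = as.list(quantile(x$null_values,
                                                        c(0.025, 0.5, 0.975))))
  if (include_null) out$null_values <- x$null_values
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise alpha by the number of comparisons; with the
#' four node-level metrics compared per group this gives 0.05/4 = 0.0125.
#'
#' @param alpha Significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_adjust <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m)) abort("m must be a positive integer")
  alpha / m
}

# Run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
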