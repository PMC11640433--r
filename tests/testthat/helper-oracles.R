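# Independent brute-force reference implementations used to check the
# package's association and network code. Everything here is deliberately
# naive (per-period loops, exhaustive path enumeration, dense eigensolver)
# and shares no code with the implementation under test.

# SRI for every pair by classifying each period explicitly.
bf_sri_matrix <- function(gbi) {
  m <- unclass(gbi); attr(m, "roster") <- NULL
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      x <- ya <- yb <- 0
      for (p in seq_len(nrow(m))) {
        ia <- m[p, a] == 1; ib <- m[p, b] == 1
        if (ia && ib) x <- x + 1
        else if (ia) ya <- ya + 1
        else if (ib) yb <- yb + 1
      }
      denom <- x + ya + yb
      out[a, b] <- out[b, a] <- if (denom > 0) x / denom else 0
    }
  }
  out
}

bf_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[upper.tri(adj)] > 0) / (n * (n - 1) / 2)
}

bf_degree <- function(adj) rowSums(adj > 0)

# Dense eigensolver route (vs the implementation's ARPACK path).
bf_eigenvector <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  if (max(v) > 0) v <- v / max(v)
  setNames(v, rownames(adj))
}

# All simple paths between two nodes, returned with their total length.
bf_all_paths <- function(adj, lengths, from, to) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(node, visited, len) {
    if (node == to) {
      paths[[length(paths) + 1]] <<- list(path = visited, length = len)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (adj[node, nxt] > 0 && !(nxt %in% visited)) {
        walk(nxt, c(visited, nxt), len + lengths[node, nxt])
      }
    }
  }
  walk(from, from, 0)
  paths
}

# Betweenness by exhaustive shortest-path enumeration with fractional
# credit shared among tied geodesics.
bf_betweenness <- function(adj, lengths = adj, tol = 1e-12) {
  n <- nrow(adj)
  btw <- setNames(numeric(n), rownames(adj))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_paths(adj, lengths, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "length")
      shortest <- paths[lens <= min(lens) + tol]
      for (p in shortest) {
        inner <- setdiff(p$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(shortest)
      }
    }
  }
  btw
}

# Pairwise geodesic distances by the same enumeration (Inf if unreachable).
bf_distances <- function(adj, lengths = adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_paths(adj, lengths, s, t)
      if (length(paths) > 0) {
        d[s, t] <- d[t, s] <- min(vapply(paths, `[[`, numeric(1), "length"))
      }
    }
  }
  dimnames(d) <- dimnames(adj)
  d
}

# Local clustering by explicit triangle counting on the binarized graph.
bf_clustering <- function(adj) {
  bin <- adj > 0
  n <- nrow(adj)
  out <- setNames(rep(NaN, n), rownames(adj))
  for (i in seq_len(n)) {
    nb <- which(bin[i, ])
    k <- length(nb)
    if (k < 2) next
    ties <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (bin[nb[a], nb[b]]) ties <- ties + 1
    }
    out[i] <- ties / (k * (k - 1) / 2)
  }
  out
}

# Random symmetric weighted adjacency matrix on n nodes.
random_adjacency <- function(n, p_edge = 0.6) {
  adj <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- runif(1, 0.01, 1)
  }
  adj
}

# Random GBI over n individuals and n_periods periods (every period
# non-empty).
random_gbi <- function(n = 5, n_periods = 12) {
  roster <- tibble::tibble(id = LETTERS[1:n],
                           species = rep(c("sp1", "sp2"), length.out = n),
                           sex = "F", group = "G", age = NA_real_)
  m <- matrix(0L, n_periods, n,
              dimnames = list(sprintf("p%02d", 1:n_periods), roster$id))
  for (p in seq_len(n_periods)) {
    size <- sample.int(n, 1)
    m[p, sample.int(n, size)] <- 1L
  }
  groupness:::new_gbi(m, roster)
}
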