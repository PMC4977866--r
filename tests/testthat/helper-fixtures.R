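# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (adjacency matrices, Floyd-Warshall, explicit path
# enumeration) so they share no code path with the implementation they check.

toy_codebook <- function() {
  codebook(list(
    factor_spec("Ethnicity", c("Han", "Minority"), role = "sociodemographic"),
    factor_spec("Education", c("None", "1-5 years", "6-9 years", ">10 years"),
                role = "sociodemographic"),
    factor_spec("Reuse", c("1", "2", ">3"), role = "drug_use")),
    outcome_name = "Shared")
}

# n random records over a codebook, uniform categories, Bernoulli outcome
random_dataset <- function(cb, n, p_outcome = 0.4) {
  rec <- as.data.frame(lapply(cb$factors, function(f)
    sample(f$categories, n, replace = TRUE)),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(rec) <- names(cb$factors)
  rec[[cb$outcome_name]] <- stats::rbinom(n, 1, p_outcome)
  survey_dataset(rec, cb)
}

# Erdos-Renyi-ish random graph as an igraph object with letter names
random_graph <- function(n, p = 0.35) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

graph_adjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
bf_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Per-definition network statistics from the adjacency matrix
bf_global_stats <- function(A) {
  n <- nrow(A); deg <- rowSums(A); m <- sum(A) / 2
  D <- bf_distances(A)
  ut <- D[upper.tri(D)]; fin <- ut[is.finite(ut)]
  loc <- sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(NA_real_)
    sum(A[nb, nb]) / 2 / choose(length(nb), 2)
  })
  list(n_nodes = n, n_edges = m, avg_neighbours = 2 * m / n,
       density = 2 * m / (n * (n - 1)),
       diameter = max(fin),
       heterogeneity = sqrt(mean((deg - mean(deg))^2)) / mean(deg),
       centralization = (n / (n - 2)) * (max(deg) / (n - 1) - 2 * m / (n * (n - 1))),
       clustering_coefficient = mean(loc, na.rm = TRUE),
       characteristic_path_length = mean(fin))
}

# All shortest paths between s and t, enumerated by walking down the
# distance gradient from the Floyd-Warshall matrix
bf_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  expand <- function(path) {
    u <- path[length(path)]
    if (u == t) return(list(path))
    nxt <- which(A[u, ] > 0 & D[, t] == D[u, t] - 1)
    unlist(lapply(nxt, function(w) expand(c(path, w))), recursive = FALSE)
  }
  expand(s)
}

# Normalized betweenness by explicit shortest-path enumeration
bf_betweenness <- function(A) {
  n <- nrow(A); D <- bf_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- bf_shortest_paths(A, D, s, t)
    if (!length(paths)) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      b[interior] <- b[interior] + 1 / length(paths)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Closeness per definition, with component scaling for disconnected graphs
bf_closeness <- function(A) {
  n <- nrow(A); D <- bf_distances(A)
  sapply(seq_len(n), function(v) {
    dv <- D[v, -v]; reach <- dv[is.finite(dv)]
    if (!length(reach)) return(0)
    nc <- length(reach) + 1
    ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
  })
}

# Build a corr_matrix object directly from an r matrix (tests engineer these)
manual_corr <- function(r, p, n = 100) {
  structure(list(r = r, p = p, n = n, method = "spearman"),
            class = "corr_matrix")
}

# Printed-table helpers used by several files
yunnan_printed_flags <- function() {
  t3 <- yunnan_table3()
  list(
    nsng = flag_above_average(centrality_table_from_values(
      t3$factor, t3$bc_nsng, t3$cc_nsng, subgroup = "NSNG")),
    sng = flag_above_average(centrality_table_from_values(
      t3$factor, t3$bc_sng, t3$cc_sng, subgroup = "SNG")))
}
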