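#' Erdős–Rényi G(n, m) null ensemble statistics
#'
#' Draws `reps` uniform simple graphs with exactly `n` nodes and `m` edges
#' (the G(n, m) variant: a G(n, p) graph matches the empirical edge count
#' only in expectation) and computes the clustering coefficient and
#' characteristic path length of each replicate under the [global_stats()]
#' conventions. Replicates that come out disconnected still contribute their
#' path length over connected pairs. Both the ensemble standard deviation and
#' the standard error of the mean are reported: at small n the per-replicate
#' sd of the clustering coefficient is an order of magnitude larger than the
#' +/- figures quoted alongside published ensemble means, which are standard
#' errors.
#'
#' @param n Number of nodes.
#' @param m Number of edges, 0 <= m <= n(n-1)/2.
#' @param reps Number of replicates (>= 1).
#' @param seed RNG seed; runs are bit-reproducible.
#' @return Object of class `null_ensemble`: list with `n_nodes`, `n_edges`,
#'   `n_reps`, `seed`, `clustering_mean`, `clustering_sd`, `clustering_sem`,
#'   `path_length_mean`, `path_length_sd`, `path_length_sem`, and the
#'   per-replicate vectors `clustering_reps`, `path_length_reps`.
#' @export
er_ensemble_stats <- function(n, m, reps = 1000L, seed = 1L) {
  stopifnot(n >= 2, reps >= 1)
  if (m < 0 || m > n * (n - 1) / 2)
    stop("impossible (n, m) combination: n = ", n, ", m = ", m, call. = FALSE)
  cl <- numeric(reps); pl <- numeric(reps)
  with_seed(seed, {
    for (i in seq_len(reps)) {
      s <- global_stats(igraph::sample_gnm(n, m))
      cl[i] <- s$clustering_coefficient
      pl[i] <- s$characteristic_path_length
    }
  })
  summ <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)))
  }
  scl <- summ(cl); spl <- summ(pl)
  structure(list(n_nodes = as.integer(n), n_edges = as.integer(m),
                 n_reps = as.integer(reps), seed = as.integer(seed),
                 clustering_mean = scl[["mean"]], clustering_sd = scl[["sd"]],
                 clustering_sem = scl[["sem"]],
                 path_length_mean = spl[["mean"]], path_length_sd = spl[["sd"]],
                 path_length_sem = spl[["sem"]],
                 clustering_reps = cl, path_length_reps = pl),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Erdos-Renyi G(%d, %d) ensemble, %d replicates (seed %d)\n",
                     "  clustering: %.3f (sd %.3f, sem %.4f)\n",
                     "  path length: %.3f (sd %.3f, sem %.4f)\n"),
              x$n_nodes, x$n_edges, x$n_reps, x$seed,
              x$clustering_mean, x$clustering_sd, x$clustering_sem,
              x$path_length_mean, x$path_length_sd, x$path_length_sem))
  invisible(x)
}

#' Compare observed network statistics with a null ensemble
#'
#' One-sided empirical p-values with the add-one formulation,
#' p = (1 + #\{replicates >= observed\}) / (reps + 1), for the clustering
#' coefficient and the characteristic path length. A statistic is judged
#' "non-random" when its empirical p is below `alpha`.
#'
#' @param observed A `network_stats` object for the empirical network.
#' @param null A `null_ensemble` with matching node and edge counts.
#' @param alpha Verdict threshold (default 0.01).
#' @return Data frame with one row per statistic: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `empirical_p`, `verdict`.
#' @export
compare_to_null <- function(observed, null, alpha = 0.01) {
  stopifnot(inherits(observed, "network_stats"), inherits(null, "null_ensemble"))
  if (observed$n_nodes != null$n_nodes || observed$n_edges != null$n_edges)
    stop("observed (n = ", observed$n_nodes, ", m = ", observed$n_edges,
         ") and ensemble (n = ", null$n_nodes, ", m = ", null$n_edges,
         ") do not match", call. = FALSE)
  emp_p <- function(reps, obs) {
    reps <- reps[!is.na(reps)]
    (1 + sum(reps >= obs)) / (length(reps) + 1)
  }
  p_cl <- emp_p(null$clustering_reps, observed$clustering_coefficient)
  p_pl <- emp_p(null$path_length_reps, observed$characteristic_path_length)
  data.frame(
    statistic = c("clustering_coefficient", "characteristic_path_length"),
    observed = c(observed$clustering_coefficient,
                 observed$characteristic_path_length),
    null_mean = c(null$clustering_mean, null$path_length_mean),
    null_sd = c(null$clustering_sd, null$path_length_sd),
    empirical_p = c(p_cl, p_pl),
    verdict = ifelse(c(p_cl, p_pl) < alpha, "non-random", "consistent with random"),
    stringsAsFactors = FALSE)
}
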