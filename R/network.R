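#' Encode factor categories as ordinal integer codes
#'
#' Each factor value is replaced by the 0-based index of its category in the
#' codebook's printed order. Nominal factors without a natural order are coded
#' in printed order as an explicit convention (any rank coding of a nominal
#' factor is arbitrary). The outcome is excluded.
#'
#' @param data A `survey_dataset`.
#' @return Object of class `encoded_matrix`: list with `codes` (subjects x
#'   factors integer matrix, values 0..K-1) and `codebook`.
#' @export
encode_factors <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  fn <- factor_names(data$codebook)
  codes <- vapply(fn, function(f) {
    match(data$records[[f]], data$codebook$factors[[f]]$categories) - 1L
  }, integer(n_subjects(data)))
  codes <- matrix(codes, nrow = n_subjects(data),
                  dimnames = list(NULL, fn))
  structure(list(codes = codes, codebook = data$codebook),
            class = "encoded_matrix")
}

#' Decode an encoded matrix back to category labels
#'
#' @param m An `encoded_matrix`.
#' @return Data frame of category labels (no outcome column).
#' @export
decode_factors <- function(m) {
  stopifnot(inherits(m, "encoded_matrix"))
  fn <- colnames(m$codes)
  out <- as.data.frame(lapply(fn, function(f)
    m$codebook$factors[[f]]$categories[m$codes[, f] + 1L]),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- fn
  out
}

#' Pairwise factor correlations with p-values
#'
#' Spearman (default) or Pearson correlation between every pair of encoded
#' factors, with two-sided p-values from the t approximation on n - 2 degrees
#' of freedom. Constant columns yield undefined correlations, flagged as NA
#' (treated as no-edge downstream).
#'
#' @param m An `encoded_matrix` (or plain numeric matrix with column names).
#' @param method `"spearman"` or `"pearson"`.
#' @return Object of class `corr_matrix`: list with symmetric matrices `r`
#'   and `p`, `n` (subjects), and `method`.
#' @export
correlation_matrix <- function(m, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- if (inherits(m, "encoded_matrix")) m$codes else as.matrix(m)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects to correlate", call. = FALSE)
  r <- suppressWarnings(stats::cor(x, method = method))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1; diag(p) <- 0
  structure(list(r = r, p = p, n = n, method = method), class = "corr_matrix")
}

#' Build a correlation network from thresholded pairwise correlations
#'
#' An edge joins two factors iff |r| strictly exceeds `r_threshold` and the
#' p-value is strictly below `p_threshold`. The edge keeps the signed
#' correlation as weight. Factors with no surviving edge are excluded from
#' the node set (the full factor universe is retained as an attribute so
#' centrality tables can mark them "not included").
#'
#' @param corr A `corr_matrix`.
#' @param r_threshold Absolute-correlation threshold (default 0.1).
#' @param p_threshold P-value threshold (default 0.05).
#' @param subgroup Label carried by the network (e.g. "NSNG", "SNG").
#' @param roles Optional named character vector of node roles (factor ->
#'   role), attached as a vertex attribute for exports.
#' @return Object of class `corr_network`: list with `graph` (igraph, vertex
#'   attribute `role`; edge attributes `r`, `p`, `sign`), `subgroup`, and
#'   `universe` (all candidate factor names).
#' @export
build_network <- function(corr, r_threshold = 0.1, p_threshold = 0.05,
                          subgroup = "all", roles = NULL) {
  stopifnot(inherits(corr, "corr_matrix"),
            r_threshold > 0, r_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  fn <- colnames(corr$r)
  pairs <- which(upper.tri(corr$r), arr.ind = TRUE)
  ok <- !is.na(corr$r[pairs]) & abs(corr$r[pairs]) > r_threshold &
    corr$p[pairs] < p_threshold
  pairs <- pairs[ok, , drop = FALSE]
  el <- cbind(fn[pairs[, 1]], fn[pairs[, 2]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (nrow(pairs)) {
    igraph::E(g)$r <- corr$r[pairs]
    igraph::E(g)$p <- corr$p[pairs]
    igraph::E(g)$sign <- ifelse(corr$r[pairs] > 0, "positive", "negative")
  }
  if (!is.null(roles))
    igraph::V(g)$role <- unname(roles[igraph::V(g)$name])
  structure(list(graph = g, subgroup = subgroup, universe = fn),
            class = "corr_network")
}

#' Derive both subgroup correlation networks from a dataset
#'
#' Convenience wrapper: split by outcome, encode, correlate, threshold.
#'
#' @param data A `survey_dataset`.
#' @inheritParams build_network
#' @inheritParams correlation_matrix
#' @return List with `corr_network` elements `NSNG` and `SNG`.
#' @export
subgroup_networks <- function(data, method = "spearman",
                              r_threshold = 0.1, p_threshold = 0.05) {
  groups <- split_by_outcome(data)
  roles <- vapply(data$codebook$factors, `[[`, character(1), "role")
  lapply(stats::setNames(names(groups), names(groups)), function(gname) {
    cm <- correlation_matrix(encode_factors(groups[[gname]]), method = method)
    build_network(cm, r_threshold, p_threshold, subgroup = gname, roles = roles)
  })
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("Correlation network [%s]: %d nodes, %d edges (of %d candidate factors)\n",
              x$subgroup, igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$universe)))
  invisible(x)
}

#' Global topology statistics of a correlation network
#'
#' Conventions (matching common network-analyzer behaviour): the clustering
#' coefficient is the mean local clustering over nodes of degree >= 2; the
#' characteristic path length is the mean shortest-path length over connected
#' ordered pairs (infinite distances excluded); heterogeneity is the
#' coefficient of variation of the degree sequence (population variance);
#' centralization is Freeman degree centralization,
#' (N/(N-2)) (max_degree/(N-1) - density).
#'
#' @param net A `corr_network`, or a bare igraph graph.
#' @return Object of class `network_stats`: named list with `n_nodes`,
#'   `n_edges`, `avg_neighbours`, `density`, `diameter`, `heterogeneity`,
#'   `centralization`, `clustering_coefficient`,
#'   `characteristic_path_length`.
#' @export
global_stats <- function(net) {
  g <- if (inherits(net, "corr_network")) net$graph else net
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (N < 2) stop("need at least 2 nodes", call. = FALSE)
  deg <- igraph::degree(g)
  density <- 2 * E / (N * (N - 1))
  d <- igraph::distances(g)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  diam <- if (length(finite)) max(finite) else NA_real_
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc_nodes <- loc[deg >= 2]
  clustering <- if (length(cc_nodes)) mean(cc_nodes) else NA_real_
  heterogeneity <- if (mean(deg) > 0)
    sqrt(mean((deg - mean(deg))^2)) / mean(deg) else NA_real_
  centralization <- if (N > 2)
    (N / (N - 2)) * (max(deg) / (N - 1) - density) else NA_real_
  structure(list(n_nodes = N, n_edges = E,
                 avg_neighbours = 2 * E / N, density = density,
                 diameter = diam, heterogeneity = heterogeneity,
                 centralization = centralization,
                 clustering_coefficient = clustering,
                 characteristic_path_length = cpl),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Network statistics:\n")
  for (nm in names(x)) cat(sprintf("  %-27s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.network_stats <- function(x, ...) as.data.frame(unclass(x), ...)

#' Export a network in SIF format
#'
#' Simple interaction format: one `node1 <sign> node2` line per edge, plus
#' bare lines for isolated nodes (none occur in thresholded networks).
#'
#' @param net A `corr_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "corr_network"))
  g <- net$graph
  el <- igraph::as_edgelist(g)
  rel <- if (igraph::ecount(g)) igraph::E(g)$sign else character(0)
  lines <- if (nrow(el)) paste(el[, 1], rel, el[, 2], sep = "\t") else character(0)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' Node attribute `role` and edge attributes `r`, `p`, `sign` are carried.
#'
#' @param net A `corr_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "corr_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
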