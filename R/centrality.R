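#' Betweenness and closeness centralities of every network node
#'
#' Centralities are computed on the unweighted skeleton (edge presence only;
#' correlation magnitudes are not used as distances). Betweenness counts
#' shortest-path intermediaries per ordered pair, normalized by
#' (N-1)(N-2)/2. Closeness is (n_c - 1) / sum of distances within the node's
#' connected component, scaled by (n_c - 1)/(N - 1) when the graph is
#' disconnected (n_c = component size), so values degrade gracefully instead
#' of vanishing. Ties share a rank (min convention). Factors in the network's
#' candidate universe that carry no surviving edge appear with
#' `included = FALSE` and NA centralities, not zeros.
#'
#' @param net A `corr_network` (or bare igraph graph) with at least 3 nodes.
#' @return Data frame of class `centrality_table`: columns `factor`,
#'   `included`, `bc`, `cc`, `bc_rank`, `cc_rank`, `subgroup`.
#' @export
node_centralities <- function(net) {
  g <- if (inherits(net, "corr_network")) net$graph else net
  universe <- if (inherits(net, "corr_network")) net$universe else igraph::V(g)$name
  subgroup <- if (inherits(net, "corr_network")) net$subgroup else "all"
  N <- igraph::vcount(g)
  if (N < 3) stop("need at least 3 nodes for centralities", call. = FALSE)
  bc <- igraph::betweenness(g) / ((N - 1) * (N - 2) / 2)
  d <- igraph::distances(g)
  cc <- vapply(seq_len(N), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    if (!length(reach)) return(0)
    nc <- length(reach) + 1
    ((nc - 1) / sum(reach)) * ((nc - 1) / (N - 1))
  }, numeric(1))
  nm <- igraph::V(g)$name
  out <- data.frame(factor = universe,
                    included = universe %in% nm,
                    bc = NA_real_, cc = NA_real_,
                    bc_rank = NA_integer_, cc_rank = NA_integer_,
                    subgroup = subgroup, stringsAsFactors = FALSE)
  idx <- match(nm, universe)
  out$bc[idx] <- bc
  out$cc[idx] <- cc
  out$bc_rank[idx] <- rank(-bc, ties.method = "min")
  out$cc_rank[idx] <- rank(-cc, ties.method = "min")
  structure(out, class = c("centrality_table", "data.frame"))
}

#' Flag nodes above the average centrality
#'
#' A node is "above average" for a centrality when its value strictly exceeds
#' the arithmetic mean of that centrality over the nodes included in the
#' network (excluded nodes enter neither the mean nor the flag sets).
#'
#' @param table A `centrality_table` (from [node_centralities()], or built
#'   from printed values via [centrality_table_from_values()]).
#' @return Object of class `centrality_flags`: list with `above_bc`,
#'   `above_cc`, `above_both` (character vectors), `universe`, `subgroup`.
#' @export
flag_above_average <- function(table) {
  stopifnot(inherits(table, "centrality_table"), nrow(table) > 0)
  inc <- table[table$included, , drop = FALSE]
  above_bc <- inc$factor[inc$bc > mean(inc$bc)]
  above_cc <- inc$factor[inc$cc > mean(inc$cc)]
  structure(list(above_bc = above_bc, above_cc = above_cc,
                 above_both = intersect(above_bc, above_cc),
                 universe = table$factor,
                 subgroup = table$subgroup[1]),
            class = "centrality_flags")
}

#' @export
print.centrality_flags <- function(x, ...) {
  cat(sprintf("Above-average centralities [%s]: %d BC, %d CC, %d both\n",
              x$subgroup, length(x$above_bc), length(x$above_cc),
              length(x$above_both)))
  if (length(x$above_both))
    cat("  both:", paste(x$above_both, collapse = ", "), "\n")
  invisible(x)
}

#' Build a centrality table from published values
#'
#' @param factor Factor names (the candidate universe).
#' @param bc,cc Numeric centralities; NA marks factors not included in the
#'   network.
#' @param subgroup Subgroup label.
#' @return A `centrality_table`.
#' @export
centrality_table_from_values <- function(factor, bc, cc, subgroup = "all") {
  stopifnot(length(bc) == length(factor), length(cc) == length(factor))
  included <- !is.na(bc) & !is.na(cc)
  out <- data.frame(factor = factor, included = included, bc = bc, cc = cc,
                    bc_rank = NA_integer_, cc_rank = NA_integer_,
                    subgroup = subgroup, stringsAsFactors = FALSE)
  out$bc_rank[included] <- rank(-bc[included], ties.method = "min")
  out$cc_rank[included] <- rank(-cc[included], ties.method = "min")
  structure(out, class = c("centrality_table", "data.frame"))
}
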