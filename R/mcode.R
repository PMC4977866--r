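#' MCODE module (molecular-complex) detection
#'
#' An implementation of the MCODE seeded greedy algorithm. Stage 1 weights
#' each vertex by its core-clustering coefficient: the density of the highest
#' k-core of the induced subgraph on the vertex's closed neighbourhood,
#' multiplied by that core's k. Vertices below `degree_cutoff` get weight 0.
#' Stage 2 grows complexes outward from the highest-weight unused seed,
#' admitting neighbours whose weight is at least
#' `seed weight * (1 - node_score_cutoff)`; a vertex already assigned to a
#' complex is never reused, and a vertex that fails one seed's threshold may
#' still seed or join a later complex. Complexes that do not contain a
#' `k_core`-core are discarded. Optional post-processing (both disabled by
#' default, matching the plugin defaults used): `haircut` removes
#' singly-connected vertices from a complex; `fluff` adds unassigned
#' neighbours whose closed-neighbourhood density exceeds `fluff_density`.
#' Ties in seed order are broken by lexicographic vertex name, making the
#' output deterministic.
#'
#' Each complex is scored by its density times its vertex count; the members
#' of the top-scoring module are reported as hub nodes.
#'
#' @param net A `corr_network` or igraph graph with >= 3 vertices.
#' @param node_score_cutoff Allowed fractional drop from the seed weight
#'   (default 0.2).
#' @param degree_cutoff Minimum degree for a vertex to receive a weight
#'   (default 2).
#' @param k_core Complexes must contain a core of at least this order
#'   (default 2).
#' @param max_depth Maximum breadth-first expansion depth from the seed
#'   (default 100).
#' @param haircut Remove singly-connected vertices from finished complexes.
#' @param fluff Add unassigned neighbours of complex members whose
#'   closed-neighbourhood density exceeds `fluff_density`.
#' @param fluff_density Density threshold for `fluff` (default 0.1).
#' @return Object of class `mcode_result`: list with `modules` (list of
#'   data frames: `members`, plus attributes), `scores`, `hub_nodes`, and
#'   `weights` (the stage-1 vertex weights).
#' @export
mcode_modules <- function(net, node_score_cutoff = 0.2, degree_cutoff = 2,
                          k_core = 2, max_depth = 100, haircut = FALSE,
                          fluff = FALSE, fluff_density = 0.1) {
  g <- if (inherits(net, "corr_network")) net$graph else net
  N <- igraph::vcount(g)
  if (N < 3) stop("need at least 3 nodes", call. = FALSE)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(N))
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))

  weights <- numeric(N)
  for (v in seq_len(N)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_g <- igraph::induced_subgraph(sub, which(core >= kmax))
    nc <- igraph::vcount(core_g)
    dens <- if (nc > 1) 2 * igraph::ecount(core_g) / (nc * (nc - 1)) else 0
    weights[v] <- kmax * dens
  }
  names(weights) <- nm

  assigned <- logical(N)
  seed_order <- order(-weights, nm)
  modules <- list()
  for (s in seed_order) {
    if (assigned[s] || weights[s] <= 0) next
    threshold <- weights[s] * (1 - node_score_cutoff)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in as.integer(adj[[u]])) {
          if (!assigned[w] && weights[w] >= threshold) {
            assigned[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (fluff) {
      cand <- setdiff(unique(unlist(lapply(members, function(u)
        as.integer(adj[[u]])))), members)
      cand <- cand[!assigned[cand]]
      ok <- vapply(cand, function(v) {
        nb <- c(v, as.integer(adj[[v]]))
        nn <- length(nb)
        2 * igraph::ecount(igraph::induced_subgraph(g, nb)) /
          (nn * (nn - 1)) > fluff_density
      }, logical(1))
      members <- c(members, cand[ok])  # fluffed nodes stay unassigned (may overlap)
    }
    sub <- igraph::induced_subgraph(g, members)
    if (haircut) {
      keep <- igraph::degree(sub) >= 2
      if (any(keep) && !all(keep)) {
        members <- members[keep]
        sub <- igraph::induced_subgraph(g, members)
      }
    }
    if (igraph::vcount(sub) < 2 || max(igraph::coreness(sub)) < k_core) next
    ns <- igraph::vcount(sub)
    dens <- 2 * igraph::ecount(sub) / (ns * (ns - 1))
    modules[[length(modules) + 1]] <- list(members = sort(nm[members]),
                                           score = dens * ns,
                                           density = dens, size = ns)
  }
  ord <- order(-vapply(modules, `[[`, numeric(1), "score"))
  modules <- modules[ord]
  hub <- if (length(modules)) modules[[1]]$members else character(0)
  structure(list(modules = modules,
                 scores = vapply(modules, `[[`, numeric(1), "score"),
                 hub_nodes = hub, weights = weights),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat("MCODE modules:", length(x$modules), "\n")
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  %d. score %.2f, %d nodes: %s\n", i, m$score, m$size,
                paste(m$members, collapse = ", ")))
  }
  if (length(x$hub_nodes))
    cat("Hub nodes (top module):", paste(x$hub_nodes, collapse = ", "), "\n")
  invisible(x)
}
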