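test_that("centralities take closed-form values on stars and paths", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- LETTERS[1:6]
  ct <- node_centralities(star)
  expect_equal(ct$bc[ct$factor == "A"], 1)
  expect_true(all(ct$bc[ct$factor != "A"] == 0))
  expect_equal(ct$cc[ct$factor == "A"], 1)

  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- LETTERS[1:4]
  ct <- node_centralities(p4)
  expect_equal(ct$cc[ct$factor == "A"], 3 / 6)  # end node: distances 1+2+3
  expect_equal(ct$cc[ct$factor == "B"], 3 / 4)
})

test_that("centralities match exhaustive shortest-path enumeration", {
  set.seed(801)
  reps <- 0
  while (reps < 3) {
    g <- random_graph(8, 0.35)
    if (igraph::ecount(g) < 5) next
    reps <- reps + 1
    ct <- node_centralities(g)
    A <- graph_adjacency(g)
    expect_equal(ct$bc, unname(bf_betweenness(A)), tolerance = 1e-12)
    expect_equal(ct$cc, unname(bf_closeness(A)), tolerance = 1e-12)
    # conservation: total betweenness equals total interior traversals
    paths_total <- 0
    D <- bf_distances(A)
    for (s in 1:7) for (t in (s + 1):8) {
      ps <- bf_shortest_paths(A, D, s, t)
      if (length(ps))
        paths_total <- paths_total + mean(lengths(ps) - 2)
    }
    expect_equal(sum(ct$bc) * (7 * 6 / 2), paths_total, tolerance = 1e-9)
  }
})

test_that("excluded factors are marked not-included, never zero", {
  r <- diag(4); r[1, 2] <- r[2, 1] <- r[1, 3] <- r[3, 1] <- r[2, 3] <- r[3, 2] <- 0.5
  p <- matrix(0, 4, 4)
  dimnames(r) <- dimnames(p) <- list(letters[1:4], letters[1:4])
  net <- build_network(manual_corr(r, p), subgroup = "t")
  ct <- node_centralities(net)
  expect_equal(nrow(ct), 4)
  expect_false(ct$included[ct$factor == "d"])
  expect_true(is.na(ct$bc[ct$factor == "d"]))
  expect_true(is.na(ct$cc[ct$factor == "d"]))
})

test_that("adding an edge never decreases degree or closeness of its endpoints", {
  set.seed(802)
  for (rep in 1:5) {
    g <- random_graph(8, 0.3)
    miss <- which(graph_adjacency(g) == 0 & upper.tri(diag(8)), arr.ind = TRUE)
    if (!nrow(miss)) next
    pick <- miss[sample(nrow(miss), 1), ]
    g2 <- igraph::add_edges(g, pick)
    cc1 <- bf_closeness(graph_adjacency(g))
    cc2 <- bf_closeness(graph_adjacency(g2))
    expect_true(all(cc2[pick] >= cc1[pick] - 1e-12))
    expect_true(all(igraph::degree(g2)[pick] == igraph::degree(g)[pick] + 1))
  }
})

test_that("printed centrality values yield the published above-average sets", {
  fl <- yunnan_printed_flags()
  expect_length(fl$nsng$above_both, 8)
  expect_length(fl$sng$above_both, 7)
  core <- c("Residence", "Duration of drug injection", "Other drug use",
            "Age", "Ethnicity")
  expect_true(all(core %in% fl$nsng$above_both))
  expect_true(all(core %in% fl$sng$above_both))
  expect_true(all(c("HIV serostatus", "Marital status") %in% fl$sng$above_both))
  expect_false(any(c("HIV serostatus", "Marital status") %in% fl$nsng$above_both))
  only_nsng <- setdiff(fl$nsng$above_both, fl$sng$above_both)
  expect_setequal(only_nsng, c("Method of drug intake", "Drug use frequency",
                               "Source of syringe"))
})

test_that("above-average flags use a strict mean and ignore node order", {
  ct <- centrality_table_from_values(letters[1:4], rep(0.3, 4), rep(0.3, 4))
  fl <- flag_above_average(ct)
  expect_length(fl$above_bc, 0)  # all-equal column: strictly greater fails
  set.seed(803)
  vals <- runif(6)
  ct1 <- centrality_table_from_values(letters[1:6], vals, rev(vals))
  perm <- sample(6)
  ct2 <- centrality_table_from_values(letters[1:6][perm], vals[perm], rev(vals)[perm])
  f1 <- flag_above_average(ct1); f2 <- flag_above_average(ct2)
  expect_setequal(f1$above_both, f2$above_both)
})

test_that("rank recomputation reproduces printed ties", {
  t3 <- yunnan_table3()
  ct <- centrality_table_from_values(t3$factor, t3$bc_sng, t3$cc_sng, "SNG")
  expect_equal(ct$cc_rank[ct$factor == "Residence"], 1)
  expect_equal(ct$cc_rank[ct$factor == "Other drug use"], 1)  # shared rank
  expect_equal(ct$cc_rank[ct$factor == "HIV serostatus"], 3)
  expect_equal(ct$bc_rank[ct$factor == "Marital status"], 2)
})

test_that("MCODE keeps a clique and excludes a low-weight pendant", {
  g <- igraph::make_full_graph(5)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- LETTERS[1:6]
  res <- mcode_modules(g)
  expect_length(res$modules, 1)
  expect_setequal(res$modules[[1]]$members, LETTERS[1:5])
  expect_setequal(res$hub_nodes, LETTERS[1:5])
  expect_equal(unname(res$weights["F"]), 0)  # degree 1 < degree cutoff
})

test_that("MCODE expansion crosses a single bridge between equal-weight cliques", {
  # Two K4s joined by one edge (D-E). Hand trace: every vertex's closed
  # neighbourhood contains its K4 as the highest (3-)core with density 1, so
  # all eight weights equal 3; with node_score_cutoff 0.2 the admission
  # threshold from any seed is 2.4, every neighbour passes, and the greedy
  # expansion walks across the bridge: one complex holding all eight nodes.
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(4, 5))
  igraph::V(g)$name <- LETTERS[1:8]
  res <- mcode_modules(g)
  expect_equal(unname(res$weights), rep(3, 8))
  expect_length(res$modules, 1)
  expect_setequal(res$modules[[1]]$members, LETTERS[1:8])
  # with a higher cutoff the bridge still passes (weights are all equal);
  # deleting the bridge separates the cliques into two modules of four
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(4, 5)))
  res2 <- mcode_modules(g2)
  expect_length(res2$modules, 2)
  expect_setequal(res2$modules[[1]]$members, LETTERS[1:4])
  expect_setequal(res2$modules[[2]]$members, LETTERS[5:8])
})

test_that("a dense seven-clique core is reported as seven hub nodes", {
  g <- igraph::make_full_graph(7)  # the core
  g <- igraph::add_vertices(g, 5)
  # periphery: each extra node tied to two clique members only
  g <- igraph::add_edges(g, c(8, 1, 8, 2, 9, 2, 9, 3, 10, 3, 10, 4,
                              11, 4, 11, 5, 12, 5, 12, 6))
  igraph::V(g)$name <- sprintf("N%02d", 1:12)
  res <- mcode_modules(g)
  expect_length(res$hub_nodes, 7)
  expect_setequal(res$hub_nodes, sprintf("N%02d", 1:7))
})

test_that("MCODE output is deterministic with lexicographic tie-breaks", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::V(g)$name <- c("b1", "b2", "b3", "a1", "a2", "a3")
  r1 <- mcode_modules(g)
  r2 <- mcode_modules(g)
  expect_identical(r1$modules, r2$modules)
  expect_length(r1$modules, 2)
  # equal scores: the module seeded at the lexicographically first name leads
  expect_setequal(r1$modules[[1]]$members, c("a1", "a2", "a3"))
})
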