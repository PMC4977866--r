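test_that("encoding uses printed category order and decodes back exactly", {
  cb <- toy_codebook()
  rec <- data.frame(Ethnicity = c("Han", "Minority"),
                    Education = c("6-9 years", ">10 years"),
                    Reuse = c("1", ">3"), Shared = c(0, 1), check.names = FALSE)
  m <- encode_factors(survey_dataset(rec, cb))
  expect_equal(unname(m$codes[, "Ethnicity"]), c(0L, 1L))
  expect_equal(unname(m$codes[, "Education"]), c(2L, 3L))
  expect_equal(unname(m$codes[, "Reuse"]), c(0L, 2L))
  expect_false("Shared" %in% colnames(m$codes))

  set.seed(601)
  for (rep in 1:5) {
    d <- random_dataset(cb, 40)
    m <- encode_factors(d)
    expect_identical(decode_factors(m),
                     d$records[, names(cb$factors)])
  }
})

test_that("correlations match a from-scratch rank/product-moment oracle", {
  set.seed(602)
  x <- matrix(sample(0:3, 20 * 5, replace = TRUE), 20, 5,
              dimnames = list(NULL, paste0("F", 1:5)))
  cm <- correlation_matrix(structure(list(codes = x, codebook = NULL),
                                     class = "encoded_matrix"))
  for (i in 1:4) for (j in (i + 1):5) {
    rx <- rank(x[, i]); ry <- rank(x[, j])
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(cm$r[i, j], oracle, tolerance = 1e-12)
    # t-approximation p equals a Pearson test on the ranks
    expect_equal(cm$p[i, j], cor.test(rx, ry)$p.value, tolerance = 1e-9)
  }
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  expect_true(isSymmetric(cm$r))
})

test_that("degenerate columns behave: self, anti-ordered, constant", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1), c = rep(2, 5),
             d = c(1, 2, 3, 4, 5))
  cm <- correlation_matrix(m, method = "spearman")
  expect_equal(cm$r["a", "d"], 1)       # perfectly co-ordered
  expect_equal(cm$r["a", "b"], -1)      # perfectly anti-ordered
  expect_true(is.na(cm$r["a", "c"]))    # constant column flagged undefined
  net <- build_network(cm, subgroup = "t")
  expect_false("c" %in% igraph::V(net$graph)$name)
  expect_error(correlation_matrix(m[1:2, ]), "at least 3")
})

test_that("network construction applies both thresholds and drops isolates", {
  # all pairs below threshold -> empty network
  r <- diag(3); r[upper.tri(r)] <- r[lower.tri(r)] <- 0.05
  p <- matrix(0, 3, 3)
  dimnames(r) <- dimnames(p) <- list(letters[1:3], letters[1:3])
  expect_equal(igraph::vcount(build_network(manual_corr(r, p))$graph), 0)

  # brute-force double-loop oracle on a random matrix
  set.seed(603)
  n <- 8
  r <- matrix(runif(n * n, -0.4, 0.4), n); r <- (r + t(r)) / 2; diag(r) <- 1
  p <- matrix(runif(n * n), n); p <- (p + t(p)) / 2; diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(LETTERS[1:n], LETTERS[1:n])
  net <- build_network(manual_corr(r, p), 0.1, 0.05)
  got <- igraph::as_edgelist(net$graph)
  got <- paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2]))
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (abs(r[i, j]) > 0.1 && p[i, j] < 0.05)
      want <- c(want, paste(LETTERS[i], LETTERS[j]))
  expect_setequal(got, want)
  if (igraph::ecount(net$graph) > 0)
    expect_setequal(unique(igraph::E(net$graph)$sign),
                    unique(ifelse(r[abs(r) > 0.1 & p < 0.05 & row(r) < col(r)] > 0,
                                  "positive", "negative")))
})

test_that("an engineered 19-node/38-edge network reproduces the printed identities", {
  set.seed(604)
  n <- 20
  fn <- paste0("F", sprintf("%02d", 1:n))
  # ring over the first 19 nodes (19 edges) + 19 extra distinct chords
  edges <- cbind(1:19, c(2:19, 1))
  chords <- t(combn(19, 2))
  chords <- chords[!(paste(chords[, 1], chords[, 2]) %in%
                     paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))), ]
  chords <- chords[sample(nrow(chords), 19), ]
  all_edges <- rbind(edges, chords)
  r <- diag(n); p <- matrix(0.5, n, n); diag(p) <- 0
  for (k in seq_len(nrow(all_edges))) {
    i <- all_edges[k, 1]; j <- all_edges[k, 2]
    r[i, j] <- r[j, i] <- 0.5
    p[i, j] <- p[j, i] <- 1e-6
  }
  dimnames(r) <- dimnames(p) <- list(fn, fn)
  net <- build_network(manual_corr(r, p), subgroup = "NSNG")
  s <- global_stats(net)
  expect_equal(s$n_nodes, 19)   # node 20 isolated, dropped
  expect_equal(s$n_edges, 38)
  expect_equal(round(s$density, 3), 0.222)
  expect_equal(s$avg_neighbours, 4.0)
  expect_length(net$universe, 20)
})

test_that("global statistics take closed-form values on the complete graph", {
  s <- global_stats(igraph::make_full_graph(5))
  expect_equal(s$density, 1)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$characteristic_path_length, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$heterogeneity, 0)
  expect_equal(s$centralization, 0)
})

test_that("global statistics match per-definition recomputation on random graphs", {
  set.seed(605)
  for (rep in 1:5) {
    g <- random_graph(10, 0.35)
    if (igraph::ecount(g) < 2) next
    s <- global_stats(g)
    o <- bf_global_stats(graph_adjacency(g))
    for (nm in names(o))
      expect_equal(s[[nm]], o[[nm]], tolerance = 1e-12, label = nm)
    # integer identity: density * N(N-1)/2 = E exactly
    expect_equal(round(s$density * s$n_nodes * (s$n_nodes - 1) / 2), s$n_edges)
  }
})

test_that("regular graphs have zero heterogeneity and centralization", {
  s <- global_stats(igraph::make_ring(8))
  expect_equal(s$heterogeneity, 0)
  expect_equal(s$centralization, 0)
})

test_that("spearman correlation is invariant to increasing recoding", {
  set.seed(606)
  x <- sample(0:3, 50, replace = TRUE)
  y <- sample(0:2, 50, replace = TRUE)
  base <- correlation_matrix(cbind(a = x, b = y))$r["a", "b"]
  recoded <- correlation_matrix(cbind(a = c(0, 5, 7, 20)[x + 1], b = y))$r["a", "b"]
  expect_equal(recoded, base, tolerance = 1e-12)
})

test_that("network exports carry edge signs and node roles", {
  cb <- toy_codebook()
  set.seed(607)
  d <- random_dataset(cb, 60)
  # force a correlation by copying a column with noise
  cm <- correlation_matrix(encode_factors(d))
  roles <- vapply(cb$factors, `[[`, character(1), "role")
  net <- build_network(cm, r_threshold = 0.01, p_threshold = 0.99, roles = roles)
  dir <- withr::local_tempdir()
  write_sif(net, file.path(dir, "net.sif"))
  sif <- readLines(file.path(dir, "net.sif"))
  expect_length(sif, igraph::ecount(net$graph))
  expect_true(all(grepl("\t(positive|negative)\t", sif)))
  write_graphml(net, file.path(dir, "net.graphml"))
  g2 <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(net$graph)$name)
  expect_setequal(igraph::V(g2)$role, igraph::V(net$graph)$role)
})
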