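test_that("gene_network enforces the simple-graph contract", {
  ok <- data.frame(from = "a", to = "b", combined_score = 500)
  expect_s3_class(gene_network(ok), "gene_network")
  expect_error(gene_network(data.frame(from = "a", to = "a",
                                       combined_score = 1)), "self-loops")
  dup <- data.frame(from = c("a", "b"), to = c("b", "a"),
                    combined_score = c(1, 2))
  expect_error(gene_network(dup), "duplicate")
  expect_error(gene_network(data.frame(from = "a", to = "b",
                                       combined_score = -1)), "positive")
})

test_that("build_network applies the median combined-score threshold", {
  edges <- data.frame(from = c("a", "a", "b", "c", "x"),
                      to = c("b", "c", "c", "d", "y"),
                      combined_score = c(1, 2, 3, 4, 999))
  net <- build_network(c("a", "b", "c", "d"), edges)
  expect_equal(attr(net, "score_threshold"), 2.5)
  expect_equal(n_edges(net), 2)              # scores 3 and 4 survive
  expect_setequal(net$nodes, c("b", "c", "d"))

  # degenerate: all scores equal, everything kept
  eq <- data.frame(from = c("a", "b"), to = c("b", "c"),
                   combined_score = c(7, 7))
  net_eq <- build_network(c("a", "b", "c"), eq)
  expect_equal(n_edges(net_eq), 2)

  # disjoint candidate set: empty network with warning, not an error
  expect_warning(empty <- build_network(c("q", "r"), edges), "empty")
  expect_equal(n_nodes(empty), 0)
})

test_that("induce_subnetwork keeps internal edges and drops unknown ids", {
  tri <- gene_network(data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c"),
                                 combined_score = c(1, 2, 3)))
  expect_equal(n_edges(induce_subnetwork(tri, c("a", "b", "c"))), 3)
  expect_equal(n_edges(induce_subnetwork(tri, character())), 0)
  two <- induce_subnetwork(tri, c("a", "b"))
  expect_equal(n_edges(two), 1)
  expect_warning(w <- induce_subnetwork(tri, c("a", "b", "zz")), "dropped")
  expect_setequal(w$nodes, c("a", "b"))
})

test_that("assemble_candidate_network tags provenance and filters edges", {
  edges <- data.frame(from = c("h1", "h1", "k1", "t1"),
                      to = c("k1", "t1", "p1", "p1"),
                      combined_score = c(500, 500, 500, 500))
  net <- assemble_candidate_network("h1", "k1", "t1", "p1", edges)
  expect_equal(n_edges(net), 4)              # equal scores: all kept
  prov <- net$provenance
  expect_setequal(prov$gene_id, c("h1", "k1", "t1", "p1"))
  expect_true(prov$hub_disease[prov$gene_id == "h1"])
  expect_true(prov$known[prov$gene_id == "k1"])
  expect_true(prov$drug_regulating[prov$gene_id == "t1"])
  expect_true(prov$putative_target[prov$gene_id == "p1"])

  # overlapping singleton sets with no edges: empty network, all four tags
  expect_warning(
    solo <- assemble_candidate_network("g", "g", "g", "g",
                                       edges[0, , drop = FALSE]))
  expect_equal(n_nodes(solo), 0)
  expect_error(assemble_candidate_network(character(), character(),
                                          character(), character(), edges),
               "empty")
})

test_that("topology matches hand-derived values on canonical fixtures", {
  # path a-b-c
  path3 <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                   combined_score = c(5, 5)))
  tp <- compute_topology(path3)
  expect_equal(tp$betweenness[tp$gene_id == "b"], 1)
  expect_equal(tp$betweenness[tp$gene_id != "b"], c(0, 0))

  # triangle with a pendant node
  tri_p <- gene_network(data.frame(from = c("a", "a", "b", "c"),
                                   to = c("b", "c", "c", "d"),
                                   combined_score = rep(5, 4)))
  tp2 <- compute_topology(tri_p)
  expect_equal(tp2$kcoreness[match(c("a", "b", "c", "d"), tp2$gene_id)],
               c(2L, 2L, 2L, 1L))

  # star K1,5: center degree 5, closeness 1, leaves degree 1
  star <- gene_network(data.frame(from = "c0", to = paste0("l", 1:5),
                                  combined_score = rep(5, 5)))
  tp3 <- compute_topology(star)
  expect_equal(tp3$degree[tp3$gene_id == "c0"], 5L)
  expect_equal(tp3$closeness[tp3$gene_id == "c0"], 1)
  expect_equal(tp3$degree[tp3$gene_id != "c0"], rep(1L, 5))

  # isolated node: zero everywhere
  iso <- gene_network(data.frame(from = "a", to = "b", combined_score = 5),
                      nodes = c("a", "b", "z"))
  tp4 <- compute_topology(iso)
  z <- tp4[tp4$gene_id == "z", ]
  expect_equal(unlist(z[c("degree", "betweenness", "closeness", "kcoreness")]),
               c(degree = 0, betweenness = 0, closeness = 0, kcoreness = 0))
})

test_that("all four metrics equal the brute-force oracle on random small graphs", {
  set.seed(20)
  for (i in 1:30) {
    g <- random_small_graph(sample(4:12, 1))
    if (nrow(g$edges) == 0) next
    net <- gene_network(g$edges, nodes = g$nodes)
    got <- compute_topology(net)
    want <- oracle_topology(g$edges, g$nodes)
    expect_identical(got$degree, want$degree)
    expect_identical(got$kcoreness, want$kcoreness)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
  }
})

test_that("classic closeness dialect drops the component adjustment", {
  # two components: a-b edge and isolated pair c-d
  net <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d"),
                                 combined_score = c(5, 5)))
  wf <- compute_topology(net)
  cl <- compute_topology(net, closeness = "classic")
  expect_equal(cl$closeness, rep(1, 4))       # within-component
  expect_equal(wf$closeness, rep(1 / 3, 4))   # scaled by (r-1)/(n-1)
})

test_that("degree hub rule is strict and monotone in the multiplier", {
  star <- compute_topology(gene_network(
    data.frame(from = "c0", to = paste0("l", 1:5), combined_score = rep(5, 5))))
  hubs <- select_hubs(star)
  expect_identical(hubs$hub_ids, "c0")
  expect_equal(hubs$criterion$median_degree, 1)

  path3 <- compute_topology(gene_network(
    data.frame(from = c("a", "b"), to = c("b", "c"), combined_score = c(5, 5))))
  expect_length(select_hubs(path3)$hub_ids, 0)  # 2 > 2*1 is false

  cyc <- compute_topology(gene_network(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
               combined_score = rep(5, 3))))
  for (mult in c(1, 1.5, 2, 3)) {
    expect_length(select_hubs(cyc, mult)$hub_ids, 0)  # regular graph
  }

  set.seed(21)
  g <- random_small_graph(12)
  profile <- compute_topology(gene_network(g$edges, nodes = g$nodes))
  prev <- NULL
  for (mult in c(0.5, 1, 1.5, 2, 3)) {
    cur <- select_hubs(profile, mult)$hub_ids
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(select_hubs(profile[0, ]), "empty")
})

test_that("major-hub rule needs strict dominance in all four features", {
  # K4 core around the hub plus leaves: the hub alone beats every median
  # (core mates have zero betweenness, leaves low degree and coreness)
  edges <- data.frame(
    from = c("hub", "hub", "hub", "x", "x", "y", "hub", "hub", "hub", "hub"),
    to = c("x", "y", "z", "y", "z", "z", "l1", "l2", "l3", "l4"),
    combined_score = rep(5, 10))
  profile <- compute_topology(gene_network(edges))
  sel <- select_major_hubs(profile)
  expect_identical(sel$hub_ids, "hub")
  expect_named(sel$criterion$medians,
               c("degree", "betweenness", "closeness", "kcoreness"))

  # vertex-transitive cycle: every metric sits at its median, empty selection
  cyc <- compute_topology(gene_network(
    data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"),
               combined_score = rep(5, 4))))
  expect_length(select_major_hubs(cyc)$hub_ids, 0)
  expect_error(select_major_hubs(cyc[0, ]), "empty")
})

test_that("major hubs are a subset of degree hubs at multiplier 1", {
  set.seed(22)
  for (i in 1:10) {
    g <- random_small_graph(10)
    if (nrow(g$edges) < 3) next
    profile <- compute_topology(gene_network(g$edges, nodes = g$nodes))
    expect_true(all(select_major_hubs(profile)$hub_ids %in%
                      select_hubs(profile, 1)$hub_ids))
  }
})

test_that("hub selections re-evaluate under their recorded criterion", {
  sc <- simulate_scenario(small_config(seed = 13))
  profile <- compute_topology(sc$network)
  hubs <- select_hubs(profile)
  re <- profile$gene_id[profile$degree >
                          hubs$criterion$multiplier * hubs$criterion$median_degree]
  expect_identical(hubs$hub_ids, sort(re))
})
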