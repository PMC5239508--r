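test_that("scenario_config validates its fields", {
  expect_s3_class(small_config(), "scenario_config")
  expect_error(small_config(n_disease_genes = 400), "n_disease_genes")
  expect_error(small_config(noise_sd = 0), "noise_sd")
  expect_error(small_config(reversal_fraction_full = 1.2), "\\[0, 1\\]")
  expect_error(small_config(similarity_planted = -0.1), "\\[0, 1\\]")
  expect_error(scenario_config(attachment_parameter = 600,
                               n_network_nodes = 600), "attachment_parameter")
  expect_error(small_config(pathway_size_range = c(5, 500)), "pathway_size_range")
  expect_error(small_config(fingerprint_length = 32), "fingerprint_length")
})

test_that("identical seeds give byte-identical scenarios, different seeds differ", {
  a <- simulate_scenario(small_config(seed = 11))
  b <- simulate_scenario(small_config(seed = 11))
  c <- simulate_scenario(small_config(seed = 12))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$pathways$pathways, b$pathways$pathways)
  expect_identical(a$fingerprints, b$fingerprints)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("ground-truth containment chain holds across seeds", {
  for (seed in 1:8) {
    tr <- simulate_expression(small_config(seed = seed))$truth
    expect_true(all(tr$reversed_by_minus_herb %in% tr$reversed_by_full))
    expect_true(all(tr$reversed_by_full %in% tr$disease_genes))
    expect_true(all(tr$planted_hub_genes %in% tr$disease_genes))
  }
})

test_that("expression arms carry the planted shifts and reversals", {
  # noise-free limit: planted contrasts are exact
  cfg <- small_config(seed = 3, noise_sd = 1e-9, effect_size = 2)
  sim <- simulate_expression(cfg)
  expr <- sim$expression; tr <- sim$truth
  st <- compute_gene_stats(expr, "model", "control")
  up <- tr$disease_genes[seq_len(ceiling(length(tr$disease_genes) / 2))]
  expect_equal(st$log2fc[st$gene_id %in% up],
               rep(2, length(up)), tolerance = 1e-6)
  down <- setdiff(tr$disease_genes, up)
  expect_equal(st$log2fc[st$gene_id %in% down],
               rep(-2, length(down)), tolerance = 1e-6)
  # genes reversed by the full formula return exactly to baseline
  stf <- compute_gene_stats(expr, "full", "control")
  expect_equal(max(abs(stf$log2fc[stf$gene_id %in% tr$reversed_by_full])), 0,
               tolerance = 1e-6)
  # zero effect: every expected contrast is zero
  cfg0 <- small_config(seed = 3, noise_sd = 1e-9, effect_size = 0)
  st0 <- compute_gene_stats(simulate_expression(cfg0)$expression,
                            "model", "control")
  expect_equal(max(abs(st0$log2fc)), 0, tolerance = 1e-6)
})

test_that("non-disease genes are identically distributed across arms", {
  sim <- simulate_expression(small_config(seed = 5))
  expr <- sim$expression
  null_genes <- setdiff(gene_ids(expr), sim$truth$disease_genes)
  st <- screen_degs(compute_gene_stats(expr, "model", "control"))
  fp <- mean(st$pvalue[st$gene_id %in% null_genes] < 0.05)
  expect_lt(fp, 0.12)  # nominal 5%, loose bound for one seed
})

test_that("network generator reduces to plain preferential attachment without a module", {
  cfg <- small_config(seed = 2, n_network_nodes = 10, attachment_parameter = 1,
                      n_disease_genes = 5, n_hub_genes = 0)
  sim <- simulate_expression(cfg)
  net <- simulate_network(cfg, sim$truth)
  expect_equal(n_edges(net), 9)           # tree on 10 nodes
  expect_equal(n_nodes(net), 10)

  # degree distribution indistinguishable from the reference generator
  cfg2 <- small_config(seed = 2, n_hub_genes = 0)
  degs_pkg <- unlist(lapply(1:40, function(s) {
    c2 <- small_config(seed = s, n_hub_genes = 0)
    tr <- simulate_expression(c2)$truth
    profile <- compute_topology(simulate_network(c2, tr))
    profile$degree
  }))
  set.seed(999)
  degs_ref <- unlist(lapply(1:40, function(s) {
    igraph::degree(igraph::sample_pa(cfg2$n_network_nodes,
                                     power = cfg2$attachment_power,
                                     m = cfg2$attachment_parameter,
                                     directed = FALSE))
  }))
  ks <- suppressWarnings(ks.test(degs_pkg, degs_ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("network scores are integers in range and module edges are lifted", {
  sc <- simulate_scenario(small_config(seed = 4))
  sc_scores <- sc$network$edges$combined_score
  expect_true(all(sc_scores >= 150 & sc_scores <= 999))
  expect_true(all(sc_scores == floor(sc_scores)))
  hub <- sc$truth$planted_hub_genes
  in_mod <- sc$network$edges$from %in% hub & sc$network$edges$to %in% hub
  expect_gt(length(which(in_mod)), 0)
  expect_gt(median(sc_scores[in_mod]), median(sc_scores[!in_mod]))
})

test_that("planted pathway overlaps disease genes far above chance", {
  sc <- simulate_scenario(small_config(seed = 6))
  planted <- sc$pathways$pathways[[sc$truth$enriched_pathway_id]]
  frac_planted <- mean(planted %in% sc$truth$disease_genes)
  chance <- length(sc$truth$disease_genes) / sc$config$n_genes
  expect_gt(frac_planted, 3 * chance)
})

test_that("planted compound-reference similarity follows s/(2-s)", {
  # exact-sharing construction at s = 1 gives identical fingerprints
  cfg1 <- small_config(seed = 7, similarity_planted = 1)
  sim <- simulate_expression(cfg1)
  lib1 <- simulate_compound_library(cfg1, sim$truth)
  fp <- hex_to_fp(lib1$fingerprints$fingerprint[1])
  ref <- hex_to_fp(lib1$reference_drugs$fingerprint[1])
  expect_equal(tanimoto(fp, ref), 1.0)

  # general s: shared = round(s*b), disjoint remainder ->
  # tanimoto = shared / (2b - shared), approx s/(2-s)
  cfg <- small_config(seed = 7, similarity_planted = 0.8)
  lib <- simulate_compound_library(cfg, sim$truth)
  n_planted <- ceiling(cfg$n_compounds / 2)
  sims <- vapply(seq_len(n_planted), function(i) {
    tanimoto(hex_to_fp(lib$fingerprints$fingerprint[i]),
             hex_to_fp(lib$reference_drugs$fingerprint[i]))
  }, numeric(1))
  b <- vapply(seq_len(n_planted), function(i) {
    sum(hex_to_fp(lib$fingerprints$fingerprint[i]))
  }, numeric(1))
  expected <- round(0.8 * b) / (2 * b - round(0.8 * b))
  expect_equal(sims, expected, tolerance = 1e-12)
  expect_equal(mean(sims), 0.8 / (2 - 0.8), tolerance = 0.02)
})

test_that("decoy fingerprint pairs have the independent-bits expected Tanimoto", {
  # two independent density-q fingerprints: E|and| = Lq^2, E|or| = L(2q - q^2)
  set.seed(42)
  L <- 1024; q <- 0.1
  sims <- replicate(1000, {
    a <- runif(L) < q; b <- runif(L) < q
    sum(a & b) / sum(a | b)
  })
  expect_equal(mean(sims), q^2 / (2 * q - q^2), tolerance = 0.02)
})

test_that("scenario files round-trip through the writers", {
  sc <- simulate_scenario(small_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  expr2 <- read_expression_tsv(paths["expression"], paths["arm_map"])
  expect_equal(expr2$values, sc$expression$values, tolerance = 1e-6)
  expect_identical(unname(expr2$arms), unname(sc$expression$arms))
  edges2 <- read_edge_tsv(paths["edges"])
  expect_identical(edges2$combined_score, sc$network$edges$combined_score)
  coll2 <- read_gmt(paths["pathways"], universe = sc$pathways$universe)
  expect_identical(coll2$pathways, sc$pathways$pathways)
  tr2 <- read_ground_truth(paths["ground_truth"])
  expect_identical(tr2$disease_genes, sc$truth$disease_genes)
  expect_identical(tr2$compound_true_targets, sc$truth$compound_true_targets)
})
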