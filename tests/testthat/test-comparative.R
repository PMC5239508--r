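screened_table <- function(genes, lfc, p) {
  st <- data.frame(gene_id = genes, log2fc = lfc, pvalue = p,
                   direction = NA_character_, stringsAsFactors = FALSE)
  class(st) <- c("deg_table", "data.frame")
  screen_degs(st)
}

test_that("reversal categories follow the direction-crossing rule", {
  genes <- c("adcy2_like", "gsr_like", "quiet", "pushed_further")
  model <- screened_table(genes,
                          lfc = c(-2, 2, 0.1, 2),
                          p = c(0.001, 0.001, 0.9, 0.001))
  treat <- screened_table(genes,
                          lfc = c(2, 0.1, 2, 2),
                          p = c(0.001, 0.9, 0.001, 0.001))
  tab <- classify_reversal(model, treat)
  # down in the model, up under treatment -> reversed
  expect_equal(tab$category[tab$gene_id == "adcy2_like"], "reversed")
  # up in the model, unchanged by treatment -> not reversed
  expect_equal(tab$category[tab$gene_id == "gsr_like"], "not_reversed")
  # not dysregulated in the model -> unaffected regardless of treatment
  expect_equal(tab$category[tab$gene_id == "quiet"], "unaffected")
  # same-direction further dysregulation is not a reversal
  expect_equal(tab$category[tab$gene_id == "pushed_further"], "not_reversed")
})

test_that("reversal categories partition the gene universe", {
  sim <- simulate_expression(small_config(seed = 23))
  model <- screen_degs(compute_gene_stats(sim$expression, "model", "control"))
  treat <- screen_degs(compute_gene_stats(sim$expression, "full", "model"))
  tab <- classify_reversal(model, treat)
  expect_equal(nrow(tab), length(gene_ids(sim$expression)))
  expect_true(all(tab$category %in% c("reversed", "not_reversed", "unaffected")))
  expect_equal(sum(table(tab$category)), nrow(tab))
})

test_that("universe mismatches are rejected with the missing ids", {
  a <- screened_table(c("g1", "g2"), c(1, 1), c(0.01, 0.01))
  b <- screened_table(c("g1", "g3"), c(1, 1), c(0.01, 0.01))
  expect_error(classify_reversal(a, b), "g2")
})

test_that("herb-pair core genes intersect the dysregulated sets symmetrically", {
  a <- screened_table(c("g1", "g2", "g3", "g4"),
                      c(1, -1, 1, 0.1), c(0.01, 0.01, 0.01, 0.9))
  b <- screened_table(c("g1", "g2", "g3", "g4"),
                      c(0.1, -1, 1, 1), c(0.9, 0.01, 0.01, 0.01))
  expect_identical(herb_pair_core_genes(a, b), c("g2", "g3"))
  expect_identical(herb_pair_core_genes(a, b), herb_pair_core_genes(b, a))
  none <- screened_table(c("g1", "g2", "g3", "g4"),
                         rep(0.1, 4), rep(0.9, 4))
  expect_length(herb_pair_core_genes(a, none), 0)
})

test_that("herb-pair core genes recover the planted difference set", {
  hits <- 0L
  for (seed in 1:10) {
    sc <- simulate_expression(small_config(seed = seed))
    ma <- screen_degs(compute_gene_stats(sc$expression, "minus_a", "full"))
    mb <- screen_degs(compute_gene_stats(sc$expression, "minus_b", "full"))
    core <- herb_pair_core_genes(ma, mb)
    want <- setdiff(sc$truth$reversed_by_full, sc$truth$reversed_by_minus_herb)
    hits <- hits + (jaccard(core, want) >= 0.5)
  }
  expect_gte(hits, 8)
})

test_that("known-gene merging unions with provenance", {
  ks <- merge_known_genes(list(A = c("TPO", "THRA"), B = c("TPO", "TG")))
  expect_identical(ks$gene_ids, c("TG", "THRA", "TPO"))
  expect_identical(ks$source_of$TPO, c("A", "B"))
  expect_identical(ks$source_of$TG, "B")

  # idempotent union: identical lists double-tag without growing
  twice <- merge_known_genes(list(A = c("x", "y"), B = c("x", "y")))
  expect_length(twice$gene_ids, 2)
  expect_true(all(lengths(twice$source_of) == 2))

  # single source is the identity
  one <- merge_known_genes(list(only = c("b", "a")))
  expect_identical(one$gene_ids, c("a", "b"))
  expect_error(merge_known_genes(list()), "non-empty")
  expect_error(merge_known_genes(list(A = character())), "empty")
})

test_that("merged size is bounded by the sum of sources, equal iff disjoint", {
  disjoint <- merge_known_genes(list(A = c("a", "b"), B = c("c")))
  expect_length(disjoint$gene_ids, 3)
  overlapping <- merge_known_genes(list(A = c("a", "b"), B = c("b", "c")))
  expect_lt(length(overlapping$gene_ids), 4)
})

test_that("plain-text gene lists carry their source label", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# MySource", "TPO", "TG", ""), path)
  gl <- read_gene_list(path)
  expect_identical(as.character(gl), c("TPO", "TG"))
  expect_equal(attr(gl, "label"), "MySource")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A1", "A2"), path2)
  expect_equal(attr(read_gene_list(path2), "label"),
               sub("\\.txt$", "", basename(path2)))
})

test_that("the shipped disease gene lists merge to ten genes with TPO double-tagged", {
  files <- system.file("extdata",
                       c("known_genes_drugbank_goiter.txt",
                         "known_genes_kegg_H00251.txt"),
                       package = "herbnet")
  lists <- lapply(files, read_gene_list)
  names(lists) <- vapply(lists, attr, character(1), "label")
  ks <- merge_known_genes(lists)
  expect_length(ks$gene_ids, 10)
  expect_identical(ks$source_of$TPO, c("DrugBank", "KEGG_H00251"))
})
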