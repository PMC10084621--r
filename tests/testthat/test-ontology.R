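mk_ref <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(species = r[[1]], gene_name = r[[2]],
               function_desc = "desc", stringsAsFactors = FALSE)))
  df$go_terms <- lapply(rows, function(r) sort(r[[3]]))
  class(df) <- c("reference_annotation", "data.frame")
  df
}

test_that("transfer requires identical GO sets in >= 3 distinct species", {
  go <- c("GO:0000001", "GO:0000002")
  ref <- mk_ref(list("sp1", "catalase", go),
                list("sp2", "catalase", go),
                list("sp3", "catalase", go),
                list("sp1", "nibrin", go),
                list("sp2", "nibrin", go))
  tg <- data.frame(gene = c("LOC1", "LOC2"),
                   name = c("Catalase", "NIBRIN"), stringsAsFactors = FALSE)
  ann <- transfer_annotations(tg, ref)
  expect_equal(ann$LOC1, go)        # 3 species, identical sets
  expect_null(ann$LOC2)             # only 2 species
})

test_that("a divergent species does not spoil a 3-species consensus", {
  go <- c("GO:0000001", "GO:0000002")
  ref4 <- mk_ref(list("sp1", "trehalase", go), list("sp2", "trehalase", go),
                 list("sp3", "trehalase", go),
                 list("sp4", "trehalase", c("GO:0000009")))
  tg <- data.frame(gene = "LOC9", name = "trehalase-like",
                   stringsAsFactors = FALSE)
  ann <- transfer_annotations(tg, ref4)
  expect_equal(ann$LOC9, go)        # the identical-set trio still qualifies

  # but 3 species where one set differs leaves only a 2-species consensus
  ref3 <- mk_ref(list("sp1", "trehalase", go), list("sp2", "trehalase", go),
                 list("sp3", "trehalase", c("GO:0000009")))
  expect_null(transfer_annotations(tg, ref3)$LOC9)

  # duplicate rows from the same species count once
  ref_dup <- mk_ref(list("sp1", "trehalase", go), list("sp1", "trehalase", go),
                    list("sp2", "trehalase", go))
  expect_null(transfer_annotations(tg, ref_dup)$LOC9)
})

test_that("transfer is independent of reference row order and name case", {
  go <- c("GO:0000005")
  ref <- mk_ref(list("sp1", "Hsp70", go), list("sp2", "HSP-70", go),
                list("sp3", "hsp70-like", go))
  tg <- data.frame(gene = "LOC1", name = "HSP70", stringsAsFactors = FALSE)
  a1 <- transfer_annotations(tg, ref)
  a2 <- transfer_annotations(tg, ref[c(3, 1, 2), ])
  expect_equal(a1, a2)
  expect_equal(a1$LOC1, go)         # "-like" suffix and punctuation stripped
})

test_that("propagation closes annotations over is_a chains and is idempotent", {
  f <- withr::local_tempfile(fileext = ".obo")
  ids <- chain_obo(f, n = 3)          # a <- b <- c
  onto <- read_ontology(f)
  ann <- structure(list(g1 = ids[3], g2 = ids[1]),
                   propagated = FALSE, class = "annotation_set")
  p1 <- propagate(ann, onto)
  expect_setequal(p1$g1, ids)         # leaf pulls in b and the root a
  expect_equal(p1$g2, ids[1])         # root term is a fixed point
  expect_equal(propagate(p1, onto), p1)
})

test_that("enrichment matches closed forms and the summation oracle", {
  fx <- generate_ontology_fixture(n_terms = 10, n_genes = 20, seed = 31)
  onto <- fx$ontology
  # saturated candidate set: every p-value is 1
  ann <- propagate(fx$annotation, onto)
  sat <- enrich(names(ann), names(ann), ann, onto, min_term_size = 1)
  expect_true(all(sat$p_value == 1))

  # closed form: all 5 candidates carry the term, 5 of 20 background do
  expect_equal(hyper_upper_oracle(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(stats::phyper(4, 5, 15, 5, lower.tail = FALSE),
               1 / 15504, tolerance = 1e-12)

  # randomized instances against the brute-force oracle
  set.seed(32)
  for (i in 1:50) {
    N <- sample(20:200, 1); K <- sample(3:(N - 1), 1)
    n <- sample(2:(N - 1), 1); k <- sample(0:min(K, n), 1)
    if (k < 1) k <- 1
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_upper_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("a term concentrated in the candidates is flagged at FDR < 0.05", {
  f <- withr::local_tempfile(fileext = ".obo")
  ids <- chain_obo(f, n = 6)
  onto <- read_ontology(f)
  genes <- sprintf("g%02d", 1:20)
  terms <- c(rep(ids[6], 5), sample(ids[2:5], 15, replace = TRUE))
  ann <- structure(stats::setNames(as.list(terms), genes),
                   propagated = FALSE, class = "annotation_set")
  ann <- propagate(ann, onto)
  res <- enrich(genes[1:5], genes, ann, onto)
  row <- res[res$term == ids[6], ]
  expect_equal(row$k, 5); expect_equal(row$K, 5)
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(row$significant)
  # adding a gene with no annotation changes nothing
  res2 <- enrich(c(genes[1:5], "unannotated"), c(genes, "unannotated"),
                 ann, onto)
  expect_equal(as.data.frame(res2), as.data.frame(res))
})

test_that("categorization counts genes under their depth-level ancestors", {
  terms <- data.frame(
    id = sprintf("GO:%07d", 1:6),
    name = c("root", "d1a", "d1b", "d2a", "d2b", "deep"),
    namespace = "biological_process", stringsAsFactors = FALSE)
  edges <- data.frame(
    child = sprintf("GO:%07d", c(2, 3, 4, 5, 5, 6)),
    parent = sprintf("GO:%07d", c(1, 1, 2, 2, 3, 4)), stringsAsFactors = FALSE)
  onto <- as_ontology_graph(terms, edges)
  # gene annotated to the depth-3 term "deep" is counted under depth-2 d2a;
  # a gene on d2b (two depth-2 parents? d2b has parents d1a,d1b -> depth 2)
  ann <- propagate(structure(list(gA = "GO:0000006", gB = "GO:0000005"),
                             propagated = FALSE, class = "annotation_set"),
                   onto)
  tab <- categorize(c("gA", "gB"), ann, onto, level = 2)
  expect_equal(tab$count[tab$term == "GO:0000004"], 1)   # gA via deep
  expect_equal(tab$count[tab$term == "GO:0000005"], 1)   # gB itself
  empty <- categorize(character(0), ann, onto, level = 2)
  expect_true(all(empty$count == 0))
})
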