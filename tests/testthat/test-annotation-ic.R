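gaf_line <- function(go) {
  paste("UniProtKB", "P00001", "G1", "enables", go, "GO_REF:0000001", "IEA",
        "", "P", "d", "", "protein", "taxon:9606", "20200710", "DB", "", "",
        sep = "\t")
}

test_that("GAF lines are counted per term, comments and bad rows skipped", {
  gaf <- write_tmp(c("!gaf-version: 2.2",
                     gaf_line("GO:A"), gaf_line("GO:A"), gaf_line("GO:B")))
  raw <- parse_gaf(gaf)
  expect_mapequal(as.list(raw$counts), list(`GO:A` = 2L, `GO:B` = 1L))
  expect_equal(raw$total, 3L)

  only_comments <- write_tmp(c("!gaf-version: 2.2", "!generated: test"))
  raw0 <- parse_gaf(only_comments)
  expect_equal(raw0$total, 0L)
  expect_length(raw0$counts, 0)
  expect_error(information_content(raw0$counts, raw0$total), "positive")

  with_bad <- write_tmp(c(gaf_line("GO:A"), "only\ttwo"))
  rawb <- parse_gaf(with_bad)
  expect_equal(rawb$total, 1L)
  expect_equal(rawb$malformed, 1L)
})

test_that("fixture GAF counts match the generator's sampling record", {
  fx <- make_test_ontology(seed = 5, n_terms = 40)
  ann <- generate_annotations(fx$graph, total = 500, skew = 1.0, seed = 9)
  raw <- parse_gaf(write_tmp(ann$gaf))
  expect_equal(raw$total, 500L)
  expect_mapequal(as.list(raw$counts), as.list(ann$truth_counts))
})

test_that("count propagation follows ancestor sets without double counting", {
  chain <- parse_hand_obo(list(root = list(), A = list(is_a = "root"),
                               B = list(is_a = "A")))
  prop <- propagate_counts(chain, list(counts = c(B = 1), total = 1))
  expect_mapequal(as.list(prop$counts), list(B = 1, A = 1, root = 1))

  diamond <- parse_hand_obo(list(root = list(), A = list(is_a = "root"),
                                 B = list(is_a = "root"),
                                 C = list(is_a = "A", part_of = "B")))
  propd <- propagate_counts(diamond, list(counts = c(C = 1), total = 1))
  expect_equal(propd$counts[["root"]], 1)

  # random fixture vs explicit per-annotation ancestor summation
  fx <- make_test_corpus(seed = 8, n_terms = 30, total = 400)
  raw <- parse_gaf(fx$gaf)
  prop <- propagate_counts(fx$graph, raw)
  want <- oracle_propagate(fx$graph$parents, raw$counts)
  expect_mapequal(as.list(prop$counts), as.list(want))
})

test_that("information content is the negative log relative frequency", {
  ic <- information_content(c(X = 10), 1000)
  expect_equal(ic["X", "ic"], -log(0.01), tolerance = 1e-12)
  expect_equal(ic["X", "ic"], 4.6052, tolerance = 1e-4)
  ic0 <- information_content(c(Y = 500), 500)
  expect_equal(ic0["Y", "ic"], 0)

  # end-to-end recomputation from the raw GAF
  fx <- make_test_corpus(seed = 12, n_terms = 25, total = 300)
  raw <- parse_gaf(fx$gaf)
  want <- oracle_propagate(fx$graph$parents, raw$counts)
  for (t in rownames(fx$ic)) {
    expect_equal(fx$ic[t, "ic"], -log(want[[t]] / raw$total),
                 tolerance = 1e-12)
  }
})

test_that("propagated frequency is monotone: parents at least as frequent", {
  for (seed in c(2, 9, 31)) {
    fx <- make_test_corpus(seed = seed, n_terms = 30, total = 500)
    g <- fx$graph
    live <- g$terms$id[!g$terms$obsolete]
    for (child in intersect(live, rownames(fx$ic))) {
      for (p in g$parents[[child]]$parent) {
        expect_gte(fx$ic[p, "frequency"], fx$ic[child, "frequency"])
        expect_lte(fx$ic[p, "ic"], fx$ic[child, "ic"])
      }
    }
  }
})

test_that("IC tables round-trip losslessly and validate their header", {
  fx <- make_test_corpus(seed = 4, n_terms = 20, total = 200)
  path <- tempfile(fileext = ".tsv")
  write_ic_table(fx$ic, path)
  back <- read_ic_table(path)
  expect_equal(back$term_id, fx$ic$term_id)
  expect_equal(back$count, fx$ic$count, tolerance = 1e-14)
  expect_equal(back$frequency, fx$ic$frequency, tolerance = 1e-14)
  expect_equal(back$ic, fx$ic$ic, tolerance = 1e-14)
  expect_equal(attr(back, "total"), attr(fx$ic, "total"))

  headerless <- write_tmp(c("term_id\tcount\tfrequency\tic",
                            "GO:A\t10\t0.5\t0.693"))
  expect_error(read_ic_table(headerless), "total-annotations")

  hand <- write_tmp(c("# ontology-version: v1", "# corpus-version: v2",
                      "# total-annotations: 20",
                      "term_id\tcount\tfrequency\tic",
                      "GO:A\t10\t0.5\t0.6931",
                      "GO:B\t5\t0.25\t1.3863",
                      "GO:C\t1\t0.05\t2.9957"))
  tab <- read_ic_table(hand)
  expect_equal(tab$frequency, c(0.5, 0.25, 0.05))

  other <- parse_hand_obo(list(A = list()), data_version = "hand/other")
  expect_warning(read_ic_table(path, other), "ontology version")
})

test_that("Lin similarity is invariant to the IC logarithm base", {
  fx <- make_test_corpus(seed = 6, n_terms = 25, total = 400)
  terms <- sample_terms_with_ic(fx, 10)
  m_ln <- similarity_matrix(terms, fx$ic, fx$graph)
  ic10 <- fx$ic
  ic10$ic <- ic10$ic / log(10)  # same table expressed in log10 units
  m_10 <- similarity_matrix(terms, ic10, fx$graph)
  expect_equal(m_ln, m_10, tolerance = 1e-12)
})
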