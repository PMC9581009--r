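test_that("OBO stanzas map onto term records and is_a/part_of edges", {
  g <- parse_hand_obo(list(
    A = list(),
    B = list(is_a = "A")
  ))
  expect_equal(nrow(g$terms), 2)
  expect_equal(g$parents$B$parent, "A")
  expect_equal(g$parents$B$relation, "is_a")
  expect_equal(nrow(g$parents$A), 0)
  expect_equal(g$data_version, "hand/1")

  g2 <- parse_hand_obo(list(
    A = list(),
    X = list(obsolete = TRUE, replaced_by = "A")
  ))
  expect_true(g2$terms["X", "obsolete"])
  expect_equal(g2$terms["X", "replacement"], "A")

  # unknown relationship types are silently skipped
  g3 <- parse_hand_obo(list(
    A = list(),
    B = list(is_a = "A", other_rel = "A")
  ))
  expect_equal(nrow(g3$parents$B), 1)
})

test_that("malformed and cyclic OBO input is rejected", {
  expect_error(parse_obo(tempfile()), "cannot read")
  no_id <- c("format-version: 1.2", "", "[Term]", "name: nameless")
  expect_error(parse_obo(write_tmp(no_id)), "line 3")
  cyc <- hand_obo(list(A = list(is_a = "B"), B = list(is_a = "A")))
  expect_error(parse_obo(write_tmp(cyc)), "cycle")
  dangling <- hand_obo(list(B = list(is_a = "A")))
  expect_error(parse_obo(write_tmp(dangling)), "unknown term ids")
})

test_that("generated ontologies survive a write/parse round trip", {
  for (seed in c(3, 17)) {
    fx <- make_test_ontology(seed = seed, n_terms = 50,
                             namespaces = c("biological_process",
                                            "molecular_function"))
    tr <- fx$truth
    g <- fx$graph
    expect_setequal(g$terms$id, tr$ids)
    expect_equal(g$data_version, tr$data_version)
    for (id in tr$ids) {
      expect_equal(g$terms[id, "namespace"], unname(tr$namespace[id]))
      expect_equal(g$terms[id, "obsolete"], id %in% tr$obsolete)
      if (!id %in% tr$obsolete) {
        got <- g$parents[[id]][order(g$parents[[id]]$parent), ]
        want <- tr$parents[[id]][order(tr$parents[[id]]$parent), ]
        expect_equal(got$parent, want$parent)
        expect_equal(got$relation, want$relation)
      }
    }
    expect_mapequal(as.list(g$alt_ids), as.list(tr$alt_ids))
    expect_mapequal(as.list(g$replaced_by), as.list(tr$replacement))
  }
})

test_that("ancestor closure is reflexive and traverses both relation types", {
  g <- parse_hand_obo(list(
    root = list(),
    A = list(is_a = "root"),
    B = list(is_a = "A")
  ))
  expect_setequal(ancestors(g, "B"), c("B", "A", "root"))

  gd <- parse_hand_obo(list(
    root = list(),
    A = list(is_a = "root"),
    B = list(is_a = "root"),
    C = list(is_a = "A", part_of = "B")
  ))
  expect_setequal(ancestors(gd, "C"), c("C", "A", "B", "root"))
  expect_error(ancestors(gd, "nope"), "unknown term id: nope")
})

test_that("ancestor closure matches brute-force DFS on random fixtures", {
  fx <- make_test_ontology(seed = 11, n_terms = 50)
  live <- fx$graph$terms$id[!fx$graph$terms$obsolete]
  for (t in live) {
    expect_setequal(ancestors(fx$graph, t),
                    oracle_ancestors(fx$graph$parents, t))
  }
})

test_that("ancestors are monotone along every edge", {
  fx <- make_test_ontology(seed = 23, n_terms = 40)
  g <- fx$graph
  live <- g$terms$id[!g$terms$obsolete]
  for (child in live) {
    a_child <- ancestors(g, child)
    for (p in g$parents[[child]]$parent) {
      expect_true(all(ancestors(g, p) %in% a_child))
    }
  }
})

test_that("term resolution updates, discards, or keeps identifiers", {
  g <- parse_hand_obo(list(
    A = list(alt_id = "GO:ALT1"),
    B = list(is_a = "A"),
    X = list(obsolete = TRUE, replaced_by = "B"),
    Y = list(obsolete = TRUE),
    Z = list(obsolete = TRUE, replaced_by = "X")  # chained
  ))
  expect_equal(resolve_term(g, "A")$status, "kept")
  up <- resolve_term(g, "X")
  expect_equal(up$status, "updated")
  expect_equal(up$id, "B")
  expect_match(up$log, "updated")
  disc <- resolve_term(g, "Y")
  expect_equal(disc$status, "discarded")
  expect_match(disc$log, "no replacement")
  expect_equal(resolve_term(g, "nope")$status, "unknown")

  # alt_id canonicalization happens first, then obsolete handling
  expect_equal(resolve_term(g, "GO:ALT1")$status, "updated")
  expect_equal(resolve_term(g, "GO:ALT1")$id, "A")

  # chained replaced_by is followed to a live term
  expect_equal(resolve_term(g, "Z")$id, "B")

  # idempotence: resolving an updated id returns kept
  expect_equal(resolve_term(g, up$id)$status, "kept")
})

test_that("replaced_by chains beyond 5 hops are discarded", {
  chain <- list(live = list())
  for (i in 7:1) {
    chain[[paste0("O", i)]] <- list(
      obsolete = TRUE,
      replaced_by = if (i == 7) "live" else paste0("O", i + 1))
  }
  g <- parse_hand_obo(chain)
  expect_equal(resolve_term(g, "O3")$id, "live")   # exactly 5 hops
  deep <- resolve_term(g, "O1")                    # 7 hops: too deep
  expect_equal(deep$status, "discarded")
  expect_match(deep$log, "5 hops")
})
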