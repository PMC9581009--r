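# reduce a fixture term list at one threshold; returns everything the
# assertions need
reduce_fixture <- function(fx, n = 20, threshold = 0.5, seed = 1) {
  terms <- sample_terms_with_ic(fx, n)
  pv <- with_seed(seed, stats::setNames(
    10^stats::runif(length(terms), -8, log10(0.05)), terms))
  m <- similarity_matrix(terms, fx$ic, fx$graph)
  list(terms = terms, pvals = pv, m = m,
       groups = reduce_terms(terms, m, threshold, fx$ic, pv, fx$graph))
}

test_that("thresholds above every similarity leave all terms singleton", {
  fx <- make_test_corpus(seed = 21, n_terms = 40, total = 600)
  r <- reduce_fixture(fx, n = 15, threshold = 1.0)
  off_diag <- r$m - diag(diag(r$m))
  if (max(off_diag) < 1.0) {
    expect_length(r$groups$groups, 15)
    expect_true(all(vapply(r$groups$groups,
                           function(g) length(g$members) == 1L, TRUE)))
  } else {
    succeed("fixture contained an exact tie at 1.0; covered elsewhere")
  }
})

test_that("a single pair above threshold forms one group of two", {
  g <- parse_hand_obo(list(root = list(), anc = list(is_a = "root"),
                           a = list(is_a = "anc"), b = list(is_a = "anc")))
  ic <- make_ic(c(root = 0, anc = 2.0, a = 2.2, b = 2.3))
  m <- similarity_matrix(c("a", "b"), ic, g)
  expect_gt(m["a", "b"], 0.7)  # 2*2 / 4.5 = 0.889
  pv <- c(a = 0.01, b = 0.02)
  grp <- reduce_terms(c("a", "b"), m, 0.7, ic, pv, g)
  expect_length(grp$groups, 1)
  expect_setequal(grp$groups[[1]]$members, c("a", "b"))
  expect_true(grp$groups[[1]]$representative %in% c("a", "b"))
})

test_that("grouping equals the functional-graph components oracle", {
  fx <- make_test_corpus(seed = 33, n_terms = 60, total = 1000)
  r <- reduce_fixture(fx, n = 30, threshold = 0.5)
  want <- oracle_components(r$m, 0.5)
  names(want) <- r$terms
  expect_true(same_partition(membership_of(r$groups, r$terms), want))
})

test_that("groups partition the input at every threshold", {
  fx <- make_test_corpus(seed = 44, n_terms = 50, total = 800)
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)) {
    r <- reduce_fixture(fx, n = 25, threshold = thr)
    members <- unlist(lapply(r$groups$groups, `[[`, "members"))
    expect_setequal(members, r$terms)        # covering
    expect_equal(anyDuplicated(members), 0L) # disjoint
    for (g in r$groups$groups) {
      expect_true(g$representative %in% g$members)
    }
  }
})

test_that("the number of groups is non-decreasing in the threshold", {
  fx <- make_test_corpus(seed = 55, n_terms = 50, total = 800)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(thr) {
    length(reduce_fixture(fx, n = 25, threshold = thr)$groups$groups)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("reduction is deterministic across repeated runs", {
  fx <- make_test_corpus(seed = 66, n_terms = 40, total = 600)
  r1 <- reduce_fixture(fx, n = 20, threshold = 0.4)
  r2 <- reduce_fixture(fx, n = 20, threshold = 0.4)
  expect_identical(r1$groups, r2$groups)
})

test_that("threshold and p-value arguments are validated", {
  fx <- make_test_corpus(seed = 21, n_terms = 20, total = 300)
  terms <- sample_terms_with_ic(fx, 5)
  m <- similarity_matrix(terms, fx$ic, fx$graph)
  pv <- stats::setNames(rep(0.01, 5), terms)
  expect_error(reduce_terms(terms, m, 1.5, fx$ic, pv, fx$graph), "\\[0, 1\\]")
  expect_error(reduce_terms(terms, m, -0.1, fx$ic, pv, fx$graph), "\\[0, 1\\]")
  expect_error(select_representative(terms[1], terms[2], fx$ic,
                                     pv[-1], fx$graph),
               paste0("no p-value available for term ", terms[1]))
})

test_that("representative contest reproduces all four rule branches", {
  g <- parse_hand_obo(list(root = list(), parent = list(is_a = "root"),
                           child = list(is_a = "parent"),
                           other = list(is_a = "root")))
  narrow <- make_ic(c(root = 0, parent = -log(0.01), child = -log(0.005),
                      other = -log(0.02)))
  broad_parent <- make_ic(c(root = 0, parent = -log(0.06),
                            child = -log(0.005), other = -log(0.02)))
  both_broad <- make_ic(c(root = 0, parent = -log(0.30),
                          child = -log(0.06), other = -log(0.10)))

  # 1: exactly one broad term (freq >= 5%): the other, more specific wins
  pv <- c(parent = 0.0001, child = 0.04, other = 0.03)
  expect_equal(select_representative("parent", "child", broad_parent, pv, g),
               "child")
  expect_equal(select_representative("child", "parent", broad_parent, pv, g),
               "child")

  # 2: one p-value at least 50% higher: lower p wins
  pv2 <- c(parent = 0.04, child = 0.01, other = 0.01)
  expect_equal(select_representative("parent", "other", narrow, pv2, g),
               "other")
  expect_equal(select_representative("other", "parent", narrow, pv2, g),
               "other")

  # 3: equal p-values fall through to the ancestor rule
  pv3 <- c(parent = 0.01, child = 0.01, other = 0.01)
  expect_equal(select_representative("parent", "child", narrow, pv3, g),
               "parent")
  expect_equal(select_representative("child", "parent", narrow, pv3, g),
               "parent")

  # 3: p-values differing by less than 50% also reach the ancestor rule
  pv3b <- c(parent = 0.011, child = 0.010, other = 0.010)
  expect_equal(select_representative("child", "parent", narrow, pv3b, g),
               "parent")

  # 4 via rule 1: both terms broad skips the p-value and ancestor rules
  pv4 <- c(parent = 0.04, child = 0.01, other = 0.01)
  expect_equal(select_representative("parent", "child", both_broad, pv4, g),
               "parent")

  # 4: nothing decisive: the first argument (incumbent representative) wins
  pv5 <- c(parent = 0.01, child = 0.012, other = 0.010)
  expect_equal(select_representative("other", "child", narrow, pv5, g),
               "other")
  expect_equal(select_representative("child", "other", narrow, pv5, g),
               "child")
})

test_that("group membership files carry one row per member", {
  fx <- make_test_corpus(seed = 77, n_terms = 40, total = 600)
  r <- reduce_fixture(fx, n = 15, threshold = 0.5)
  path <- tempfile(fileext = ".tsv")
  write_groups(r$groups, r$m, r$pvals, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 15)
  expect_setequal(tab$member, r$terms)
  expect_true(all(tab$representative %in% r$terms))
  # representatives sit at similarity 1 to themselves
  self_rows <- tab$member == tab$representative
  expect_true(all(abs(tab$similarity_to_representative[self_rows] - 1) <
                    1e-12))
})
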