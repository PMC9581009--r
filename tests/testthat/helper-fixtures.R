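# Shared fixture builders and independent oracles.
# Oracles are deliberately naive re-implementations (recursive DFS, explicit
# per-annotation summation, igraph components) kept separate from the package
# code paths they check.

write_tmp <- function(lines, ext = "") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# generate + parse a synthetic ontology; returns graph, truth, and file path
make_test_ontology <- function(seed = 1, n_terms = 50, ...) {
  ont <- generate_ontology(n_terms = n_terms, seed = seed, ...)
  path <- write_tmp(ont$obo, ".obo")
  list(graph = parse_obo(path), truth = ont$truth, path = path)
}

# ontology + annotation corpus + IC table in one go
make_test_corpus <- function(seed = 1, n_terms = 50, total = 2000,
                             skew = 1.0, ...) {
  fx <- make_test_ontology(seed = seed, n_terms = n_terms, ...)
  ann <- generate_annotations(fx$graph, total = total, skew = skew,
                              seed = seed + 1000)
  gaf <- write_tmp(ann$gaf, ".gaf")
  fx$gaf <- gaf
  fx$truth_counts <- ann$truth_counts
  fx$ic <- compute_ic(fx$graph, gaf)
  fx
}

# hand-written OBO for targeted topologies; parents = named list of
# character vectors "parent_id:relation"
hand_obo <- function(terms, namespace = "biological_process",
                     data_version = "hand/1") {
  lines <- c("format-version: 1.2",
             paste0("data-version: ", data_version), "")
  for (id in names(terms)) {
    t <- terms[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", if (!is.null(t$name)) t$name else id),
               paste0("namespace: ",
                      if (!is.null(t$namespace)) t$namespace else namespace))
    for (a in t$alt_id) lines <- c(lines, paste0("alt_id: ", a))
    for (p in t$is_a) lines <- c(lines, paste0("is_a: ", p))
    for (p in t$part_of) lines <- c(lines,
                                    paste0("relationship: part_of ", p))
    for (p in t$other_rel) lines <- c(lines,
                                      paste0("relationship: regulates ", p))
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    for (r in t$replaced_by) lines <- c(lines, paste0("replaced_by: ", r))
    lines <- c(lines, "")
  }
  lines
}

parse_hand_obo <- function(terms, ...) {
  parse_obo(write_tmp(hand_obo(terms, ...), ".obo"))
}

# a bare IC table from a named vector of IC values (frequencies implied)
make_ic <- function(ic_values, total = 1000) {
  freq <- exp(-ic_values)
  tab <- data.frame(term_id = names(ic_values),
                    count = freq * total,
                    frequency = freq,
                    ic = unname(ic_values),
                    stringsAsFactors = FALSE)
  rownames(tab) <- tab$term_id
  structure(tab, total = total, ontology_version = "hand/1",
            corpus_version = "hand/1",
            class = c("go_ic_table", "data.frame"))
}

# first n live single-namespace terms with defined positive IC
# (deterministic); zero-IC corpus-saturated roots have dedicated tests
sample_terms_with_ic <- function(fx, n,
                                 namespace = "biological_process") {
  g <- fx$graph
  cand <- g$terms$id[!g$terms$obsolete & g$terms$namespace == namespace]
  cand <- intersect(cand, rownames(fx$ic)[fx$ic$ic > 0])
  stopifnot(length(cand) >= n)
  sort(cand)[seq_len(n)]
}

with_seed <- goscatter:::with_seed

## ---- oracles ----

# recursive DFS reflexive ancestor closure over a parents list
oracle_ancestors <- function(parents, term) {
  out <- term
  for (p in parents[[term]]$parent) {
    out <- union(out, oracle_ancestors(parents, p))
  }
  unique(out)
}

# brute-force per-annotation propagation: every raw count contributes to the
# full ancestor set of its term
oracle_propagate <- function(parents, raw_counts) {
  acc <- numeric(0)
  for (term in names(raw_counts)) {
    for (a in oracle_ancestors(parents, term)) {
      acc[a] <- (if (a %in% names(acc)) acc[[a]] else 0) + raw_counts[[term]]
    }
  }
  acc
}

# brute-force Lin from first principles
oracle_lin <- function(a, b, parents, ic_vec) {
  if (!(a %in% names(ic_vec)) || !(b %in% names(ic_vec))) return(0)
  shared <- intersect(oracle_ancestors(parents, a),
                      oracle_ancestors(parents, b))
  shared <- intersect(shared, names(ic_vec))
  if (length(shared) == 0) return(0)
  denom <- ic_vec[[a]] + ic_vec[[b]]
  if (denom <= 0) return(0)
  max(0, 2 * max(ic_vec[shared]) / denom)
}

# grouping oracle: connected components of the functional graph
# {i -> argmax-partner(i) : max off-diagonal sim(i) >= threshold}
oracle_components <- function(m, threshold) {
  n <- nrow(m)
  edges <- NULL
  for (i in seq_len(n)) {
    sims <- m[i, ]
    sims[i] <- -Inf
    if (max(sims) >= threshold) {
      j <- which(sims == max(sims))[1]
      edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# turn a go_term_groups partition into a membership vector over `terms`
membership_of <- function(groups, terms) {
  mem <- integer(length(terms))
  names(mem) <- terms
  for (k in seq_along(groups$groups)) {
    mem[groups$groups[[k]]$members] <- k
  }
  mem
}

# do two membership vectors describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
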