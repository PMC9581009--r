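#' Lin semantic similarity between two GO terms
#'
#' Computes `2 * IC(MICA) / (IC(a) + IC(b))`, where the MICA is the most
#' informative common ancestor: the shared term of highest information content
#' after propagating both terms up the DAG via is_a/part_of. Scores lie in
#' `[0, 1]`; identical terms with positive IC score exactly 1. When the
#' denominator is 0 (both terms are corpus-saturated roots) the score is
#' defined as 0. Terms absent from the annotation corpus have undefined IC and
#' score 0 against everything.
#'
#' @param a,b Canonical non-obsolete term ids.
#' @param ic A `go_ic_table`.
#' @param graph A `go_ontology`.
#' @return A similarity score in `[0, 1]`.
#' @export
lin_similarity <- function(a, b, ic, graph) {
  for (t in c(a, b)) {
    if (!t %in% graph$terms$id) stop("term not in ontology: ", t, call. = FALSE)
  }
  ica <- ic_of(ic, a)
  icb <- ic_of(ic, b)
  if (is.na(ica) || is.na(icb)) return(0)
  shared <- intersect(anc_memo(graph, a), anc_memo(graph, b))
  shared_ic <- ic[intersect(shared, rownames(ic)), "ic"]
  if (length(shared_ic) == 0) return(0)
  denom <- ica + icb
  if (denom <= 0) return(0)
  max(0, 2 * max(shared_ic) / denom)
}

#' Pairwise Lin similarity matrix for a term list
#'
#' Computes the full symmetric matrix of Lin similarities for a deduplicated
#' list of terms from a single namespace. Cross-namespace pairs are never
#' meaningful (they share no informative ancestor) and the pipeline splits
#' input lists by namespace before calling this; mixing namespaces here is an
#' error.
#'
#' @param terms Character vector of canonical term ids (duplicates collapsed).
#' @param ic A `go_ic_table`.
#' @param graph A `go_ontology`.
#' @return A symmetric numeric matrix with `terms` as dimnames, entries in
#'   `[0, 1]`.
#' @export
similarity_matrix <- function(terms, ic, graph) {
  terms <- unique(terms)
  ns <- unique(graph$terms[terms, "namespace"])
  if (length(ns) > 1) {
    stop("similarity_matrix() requires a single namespace; got: ",
         paste(ns, collapse = ", "), call. = FALSE)
  }
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- lin_similarity(terms[i], terms[j], ic, graph)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Dump a similarity matrix as TSV (debugging aid)
#'
#' @param m Similarity matrix from [similarity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
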