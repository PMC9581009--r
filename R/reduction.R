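#' Group similar terms and pick one representative per group
#'
#' Walks the cleaned input list in order. Each term whose highest pairwise Lin
#' similarity is at or above `threshold` is unioned with its most similar
#' term's group (ties for "most similar" broken by earlier input position);
#' terms with no partner at or above the threshold remain singletons. After
#' every union a representative contest ([select_representative()]) runs
#' between the current representative of the group being joined (first
#' argument) and the representative of the incoming term's set. When a later
#' term bridges two existing multi-term groups, the two current
#' representatives contest. The result is a partition of the input list.
#'
#' @param terms Character vector of canonical term ids, in cleaned input
#'   order.
#' @param matrix Similarity matrix covering `terms` (from
#'   [similarity_matrix()]).
#' @param threshold Similarity cutoff in `[0, 1]`; pairs at or above it merge.
#' @param ic A `go_ic_table` (for the broad-term frequency rule).
#' @param pvals Named numeric vector: term id -> p-value.
#' @param graph A `go_ontology` (for the ancestor rule).
#' @return A `go_term_groups` object: list with `groups` (list of
#'   `list(representative, members)` in order of first appearance, members in
#'   input order and including the representative) and `threshold`.
#' @export
reduce_terms <- function(terms, matrix, threshold, ic, pvals, graph) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("similarity threshold must be a number in [0, 1]; got ", threshold,
         call. = FALSE)
  }
  stopifnot(all(terms %in% rownames(matrix)))
  n <- length(terms)
  m <- matrix[terms, terms, drop = FALSE]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  rep_of <- terms  # representative of the set rooted at each index

  if (n > 1) {
    for (i in seq_len(n)) {
      sims <- m[i, ]
      sims[i] <- -Inf
      mx <- max(sims)
      if (mx < threshold) next
      j <- which(sims == mx)[1]  # earliest input position wins ties
      ri <- find(i)
      rj <- find(j)
      if (ri == rj) next
      winner <- select_representative(rep_of[rj], rep_of[ri], ic, pvals, graph)
      parent[ri] <- rj
      rep_of[rj] <- winner
    }
  }

  roots <- vapply(seq_len(n), find, 0L)
  groups <- list()
  seen <- integer(0)
  for (i in seq_len(n)) {
    r <- roots[i]
    if (!r %in% seen) {
      seen <- c(seen, r)
      groups[[length(groups) + 1L]] <- list(
        representative = rep_of[r],
        members = terms[roots == r]
      )
    }
  }
  structure(list(groups = groups, threshold = threshold),
            class = "go_term_groups")
}

#' @export
print.go_term_groups <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$members), 0L)
  cat("go_term_groups:", length(x$groups), "groups covering", sum(sizes),
      "terms at threshold", x$threshold, "(", sum(sizes == 1L),
      "singletons )\n")
  invisible(x)
}

#' Representative contest between two terms
#'
#' Stepwise rule deciding which of two terms represents their group:
#' \enumerate{
#'   \item If exactly one term is annotated to 5\% or more of the annotation
#'     corpus (a broad term), select the other, more specific term. If both
#'     are, jump to step 4.
#'   \item If one p-value is at least 50\% higher than the other
#'     (`p_hi >= 1.5 * p_lo`), select the term with the lower p-value. Equal
#'     p-values fall through.
#'   \item If one term is an ancestor (via is_a/part_of) of the other, select
#'     the ancestor.
#'   \item Otherwise select the first argument — during [reduce_terms()] that
#'     is the group's current representative, which makes the outcome
#'     deterministic.
#' }
#'
#' @param a,b Term ids; `a` is the incumbent (current group representative).
#' @param ic A `go_ic_table`; terms absent from the corpus count as frequency
#'   0.
#' @param pvals Named numeric vector of p-values; missing entries are an
#'   error.
#' @param graph A `go_ontology`.
#' @return The winning term id.
#' @export
select_representative <- function(a, b, ic, pvals, graph) {
  stopifnot(a != b)
  for (t in c(a, b)) {
    if (!t %in% names(pvals) || is.na(pvals[[t]])) {
      stop("no p-value available for term ", t, call. = FALSE)
    }
  }
  broad_a <- freq_of(ic, a) >= 0.05
  broad_b <- freq_of(ic, b) >= 0.05
  if (xor(broad_a, broad_b)) return(if (broad_a) b else a)
  if (!(broad_a && broad_b)) {
    pa <- pvals[[a]]
    pb <- pvals[[b]]
    if (pa != pb) {
      p_hi <- max(pa, pb)
      p_lo <- min(pa, pb)
      if (p_hi >= 1.5 * p_lo) return(if (pa < pb) a else b)
    }
    if (a %in% anc_memo(graph, b)) return(a)
    if (b %in% anc_memo(graph, a)) return(b)
  }
  a
}

#' Write group membership as a tab-delimited file
#'
#' One row per member term: representative id, member id, Lin similarity of
#' the member to its representative, and the member's p-value.
#'
#' @param groups A `go_term_groups` object.
#' @param matrix The similarity matrix used for grouping.
#' @param pvals Named numeric vector of p-values.
#' @param path Output path.
#' @param names Optional named character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, matrix, pvals, path, names = NULL) {
  stopifnot(inherits(groups, "go_term_groups"))
  rows <- lapply(groups$groups, function(g) {
    data.frame(
      representative = g$representative,
      member = g$members,
      similarity_to_representative = matrix[g$members, g$representative],
      p_value = unname(pvals[g$members]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(names)) {
    out$member_description <- unname(names[out$member])
  }
  utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
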