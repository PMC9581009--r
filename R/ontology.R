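#' Parse a Gene Ontology OBO file into a term DAG
#'
#' Reads an OBO 1.2/1.4 flat file and builds the directed acyclic graph of GO
#' terms connected by `is_a` and `relationship: part_of` parent links. All
#' other relationship types (e.g. `regulates`) are ignored. Obsolete terms are
#' retained in the term table, flagged, and mapped to their `replaced_by`
#' target when one is given; `alt_id` identifiers are collected into a map to
#' their canonical term.
#'
#' @param path Path to a `go.obo`-style flat file.
#' @return An object of class `go_ontology`: a list with elements
#'   \describe{
#'     \item{terms}{data.frame with columns `id`, `name`, `namespace`,
#'       `obsolete` (logical), `replacement` (id or `NA`).}
#'     \item{parents}{named list: term id -> data.frame(parent, relation).}
#'     \item{children}{named list: term id -> character vector of child ids
#'       (is_a/part_of inverses), used for descendant queries.}
#'     \item{replaced_by}{named character vector: obsolete id -> replacement.}
#'     \item{alt_ids}{named character vector: alternative id -> canonical id.}
#'     \item{data_version}{the `data-version` header line, or `NA`.}
#'   }
#'   Ancestor closures are memoised inside the object (environment `cache`).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)

  data_version <- NA_character_
  header_end <- length(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) > 0) header_end <- stanza_starts[1] - 1L
  dv <- grep("^data-version:", lines[seq_len(header_end)], value = TRUE)
  if (length(dv) > 0) data_version <- trimws(sub("^data-version:", "", dv[1]))

  # stanza boundaries: every "[...]" line starts a stanza; [Term] ones matter
  all_stanzas <- grep("^\\[.*\\]$", lines)
  ends <- c(all_stanzas[-1] - 1L, length(lines))
  keep <- lines[all_stanzas] == "[Term]"
  starts <- all_stanzas[keep]
  ends <- ends[keep]

  n <- length(starts)
  ids <- character(n)
  names_ <- character(n)
  namespaces <- character(n)
  obsolete <- logical(n)
  replacement <- rep(NA_character_, n)
  parents <- vector("list", n)
  alt_pairs <- list()

  for (k in seq_len(n)) {
    block <- lines[seq.int(starts[k] + 1L, ends[k])]
    block <- block[nzchar(block)]
    key <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]+:", "", block))
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments

    id <- val[key == "id"]
    if (length(id) == 0 || !nzchar(id[1])) {
      stop("OBO [Term] stanza starting at line ", starts[k], " has no id",
           call. = FALSE)
    }
    ids[k] <- id[1]
    nm <- val[key == "name"]
    names_[k] <- if (length(nm)) nm[1] else NA_character_
    ns <- val[key == "namespace"]
    namespaces[k] <- if (length(ns)) ns[1] else NA_character_
    obsolete[k] <- any(key == "is_obsolete" & val == "true")
    rb <- val[key == "replaced_by"]
    if (length(rb)) replacement[k] <- rb[1]

    isa <- val[key == "is_a"]
    rel <- val[key == "relationship"]
    po <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    pr <- data.frame(
      parent = c(isa, po),
      relation = c(rep("is_a", length(isa)), rep("part_of", length(po))),
      stringsAsFactors = FALSE
    )
    parents[[k]] <- pr

    alts <- val[key == "alt_id"]
    if (length(alts)) alt_pairs[[length(alt_pairs) + 1L]] <-
      stats::setNames(rep(ids[k], length(alts)), alts)
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  terms <- data.frame(
    id = ids, name = names_, namespace = namespaces,
    obsolete = obsolete, replacement = replacement,
    stringsAsFactors = FALSE
  )
  rownames(terms) <- ids
  names(parents) <- ids

  # obsolete terms keep no parent links: they play no role in similarity
  for (i in which(obsolete)) parents[[i]] <- parents[[i]][0, , drop = FALSE]

  alt_ids <- if (length(alt_pairs)) do.call(c, alt_pairs) else
    stats::setNames(character(0), character(0))
  alt_ids <- alt_ids[!(names(alt_ids) %in% ids)]  # canonical ids win

  # edge endpoints must be known terms
  all_parents <- unique(unlist(lapply(parents, function(p) p$parent)))
  missing <- setdiff(all_parents, ids)
  if (length(missing) > 0) {
    stop("OBO edges reference unknown term ids: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  children <- vector("list", n)
  names(children) <- ids
  for (k in seq_len(n)) {
    for (p in parents[[k]]$parent) children[[p]] <- c(children[[p]], ids[k])
  }

  g <- structure(
    list(
      terms = terms, parents = parents, children = children,
      replaced_by = stats::setNames(replacement[obsolete & !is.na(replacement)],
                                    ids[obsolete & !is.na(replacement)]),
      alt_ids = alt_ids, data_version = data_version,
      cache = new.env(parent = emptyenv())
    ),
    class = "go_ontology"
  )
  check_acyclic(g)
  g
}

#' @export
print.go_ontology <- function(x, ...) {
  live <- sum(!x$terms$obsolete)
  cat("go_ontology:", nrow(x$terms), "terms (", live, "live,",
      nrow(x$terms) - live, "obsolete ),",
      sum(vapply(x$parents, nrow, 0L)), "is_a/part_of edges\n")
  cat("data-version:", x$data_version, "\n")
  invisible(x)
}

# is_a/part_of graph over live terms must be acyclic
check_acyclic <- function(graph) {
  edges <- ontology_edges(graph)
  if (nrow(edges) == 0) return(invisible(TRUE))
  ig <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                      directed = TRUE)
  if (!igraph::is_dag(ig)) {
    stop("ontology is_a/part_of graph contains a cycle", call. = FALSE)
  }
  invisible(TRUE)
}

# all live-term edges as a data.frame(child, parent, relation)
ontology_edges <- function(graph) {
  live <- graph$terms$id[!graph$terms$obsolete]
  ps <- graph$parents[live]
  nper <- vapply(ps, nrow, 0L)
  data.frame(
    child = rep(live, nper),
    parent = unlist(lapply(ps, function(p) p$parent), use.names = FALSE),
    relation = unlist(lapply(ps, function(p) p$relation), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Ancestors of a term (reflexive closure over is_a/part_of)
#'
#' Returns the reflexive transitive closure of the `is_a` and `part_of` parent
#' relations: the term itself plus every term reachable by propagating up the
#' GO DAG. Reflexivity makes the Lin self-similarity of a term equal to 1.
#' Closures are memoised on the ontology object, so repeated queries are cheap.
#'
#' @param graph A `go_ontology` object from [parse_obo()].
#' @param term A canonical, non-obsolete term id.
#' @return Character vector of term ids, including `term` itself.
#' @export
ancestors <- function(graph, term) {
  stopifnot(inherits(graph, "go_ontology"))
  if (!term %in% graph$terms$id) {
    stop("unknown term id: ", term, call. = FALSE)
  }
  if (isTRUE(graph$terms[term, "obsolete"])) {
    stop("term is obsolete and has no ancestor closure: ", term, call. = FALSE)
  }
  anc_memo(graph, term)
}

anc_memo <- function(graph, term) {
  cache <- graph$cache
  hit <- get0(term, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  # iterative worklist; memoised sets are reused when encountered
  out <- term
  frontier <- graph$parents[[term]]$parent
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (p in frontier) {
      if (p %in% out) next
      hit <- get0(p, envir = cache, inherits = FALSE)
      if (!is.null(hit)) {
        out <- union(out, hit)
      } else {
        out <- c(out, p)
        nxt <- c(nxt, graph$parents[[p]]$parent)
      }
    }
    frontier <- unique(nxt)
  }
  out <- unique(out)
  assign(term, out, envir = cache)
  out
}

#' Resolve a raw term identifier against the loaded ontology
#'
#' Applies the cleaning rules for user-supplied identifiers: alternative ids
#' are first mapped to their canonical term; obsolete terms are then updated
#' through their `replaced_by` chain (followed to a fixed point, at most 5
#' hops) or discarded when no replacement is defined; identifiers absent from
#' the ontology are reported as unknown. Every non-kept outcome carries a
#' human-readable log message.
#'
#' @param graph A `go_ontology` object.
#' @param raw_id The identifier as found in the input.
#' @return A list with elements `status` (one of `"kept"`, `"updated"`,
#'   `"discarded"`, `"unknown"`), `id` (the canonical id, or `NA` for
#'   discarded/unknown), and `log` (a message, or `NA` when kept).
#' @export
resolve_term <- function(graph, raw_id) {
  stopifnot(inherits(graph, "go_ontology"))
  id <- raw_id
  notes <- character(0)

  # alt_id resolution happens before obsolete resolution
  if (id %in% names(graph$alt_ids)) {
    id <- unname(graph$alt_ids[[id]])
    notes <- c(notes, paste0("alt_id ", raw_id, " canonicalized to ", id))
  }
  if (!id %in% graph$terms$id) {
    return(list(status = "unknown", id = NA_character_,
                log = paste0(raw_id, " not found in ontology; term ignored")))
  }

  hops <- 0L
  while (isTRUE(graph$terms[id, "obsolete"])) {
    rep_id <- graph$terms[id, "replacement"]
    if (is.na(rep_id)) {
      return(list(status = "discarded", id = NA_character_,
                  log = paste0(raw_id,
                               " is obsolete with no replacement; discarded")))
    }
    hops <- hops + 1L
    if (hops > 5L) {
      return(list(status = "discarded", id = NA_character_,
                  log = paste0(raw_id,
                               " replaced_by chain exceeds 5 hops; discarded")))
    }
    if (rep_id %in% names(graph$alt_ids)) rep_id <- unname(graph$alt_ids[[rep_id]])
    if (!rep_id %in% graph$terms$id) {
      return(list(status = "discarded", id = NA_character_,
                  log = paste0(raw_id, " replacement ", rep_id,
                               " not in ontology; discarded")))
    }
    id <- rep_id
  }

  if (id != raw_id) {
    status <- if (hops > 0) "updated" else "updated"
    return(list(status = "updated", id = id,
                log = paste0(raw_id, " updated to ", id,
                             if (length(notes)) paste0(" (", paste(notes, collapse = "; "), ")")
                             else "")))
  }
  list(status = "kept", id = id, log = NA_character_)
}
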