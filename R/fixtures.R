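#' Generate a miniature synthetic ontology in OBO format
#'
#' Builds a rooted DAG per namespace: the first term of each namespace is its
#' root, and every later term draws 1..`max_parents` parents uniformly from
#' the earlier terms of the same namespace, which guarantees acyclicity. A
#' fraction of edges are `part_of` relationships, the rest `is_a`. Obsolete
#' stanzas are appended, a fraction of which carry a `replaced_by` pointer to
#' a random live term; a few live terms receive `alt_id` aliases. Identical
#' arguments (including `seed`) yield byte-identical OBO text.
#'
#' @param n_terms Live terms per namespace (>= 1).
#' @param namespaces Character vector of namespace names.
#' @param max_parents Maximum parents per non-root term (>= 1).
#' @param part_of_prob Probability that an edge is `part_of` rather than
#'   `is_a`.
#' @param obsolete_frac Obsolete stanzas as a fraction of `n_terms`, per
#'   namespace.
#' @param replaced_frac Fraction of obsolete stanzas given a `replaced_by`.
#' @param alt_id_frac Fraction of live terms given an `alt_id` alias.
#' @param seed Integer seed.
#' @return A list with `obo` (character vector of OBO lines) and `truth`
#'   (list: `ids`, `namespace`, `parents` — named list of
#'   data.frame(parent, relation) —, `obsolete` ids, `replacement` named map,
#'   `alt_ids` named map, `data_version`).
#' @export
generate_ontology <- function(n_terms = 50L,
                              namespaces = "biological_process",
                              max_parents = 3L,
                              part_of_prob = 0.25,
                              obsolete_frac = 0.1,
                              replaced_frac = 0.5,
                              alt_id_frac = 0.05,
                              seed = 1L) {
  stopifnot(n_terms >= 1, max_parents >= 1)
  for (f in c(part_of_prob, obsolete_frac, replaced_frac, alt_id_frac)) {
    if (is.na(f) || f < 0 || f > 1) {
      stop("fractions must lie in [0, 1]; got ", f, call. = FALSE)
    }
  }
  with_seed(seed, {
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    ids <- character(0)
    ns_of <- character(0)
    parents <- list()
    obsolete <- character(0)
    replacement <- character(0)
    alt_ids <- character(0)

    for (ns in namespaces) {
      ns_ids <- vapply(seq_len(n_terms), function(i) next_id(), "")
      for (i in seq_len(n_terms)) {
        id <- ns_ids[i]
        ids <- c(ids, id)
        ns_of[id] <- ns
        if (i == 1L) {
          parents[[id]] <- data.frame(parent = character(0),
                                      relation = character(0),
                                      stringsAsFactors = FALSE)
        } else {
          k <- sample.int(min(max_parents, i - 1L), 1L)
          ps <- sample(ns_ids[seq_len(i - 1L)], k)
          rel <- ifelse(stats::runif(k) < part_of_prob, "part_of", "is_a")
          parents[[id]] <- data.frame(parent = ps, relation = rel,
                                      stringsAsFactors = FALSE)
        }
      }
      n_obs <- round(obsolete_frac * n_terms)
      for (j in seq_len(n_obs)) {
        id <- next_id()
        ids <- c(ids, id)
        ns_of[id] <- ns
        parents[[id]] <- data.frame(parent = character(0),
                                    relation = character(0),
                                    stringsAsFactors = FALSE)
        obsolete <- c(obsolete, id)
        if (stats::runif(1) < replaced_frac) {
          replacement[id] <- sample(ns_ids, 1L)
        }
      }
      n_alt <- round(alt_id_frac * n_terms)
      if (n_alt > 0) {
        targets <- sample(ns_ids, n_alt)
        for (t in targets) alt_ids[next_id()] <- t
      }
    }

    data_version <- paste0("synthetic/seed-", seed)
    lines <- c(
      "format-version: 1.2",
      paste0("data-version: ", data_version),
      ""
    )
    for (id in ids) {
      lines <- c(lines, "[Term]", paste0("id: ", id),
                 paste0("name: synthetic term ", sub("GO:0*", "", id)),
                 paste0("namespace: ", ns_of[id]))
      aliases <- names(alt_ids)[alt_ids == id]
      for (a in aliases) lines <- c(lines, paste0("alt_id: ", a))
      pr <- parents[[id]]
      if (nrow(pr) > 0) {
        for (r in seq_len(nrow(pr))) {
          lines <- c(lines, if (pr$relation[r] == "is_a")
            paste0("is_a: ", pr$parent[r], " ! synthetic")
          else paste0("relationship: part_of ", pr$parent[r], " ! synthetic"))
        }
      }
      if (id %in% obsolete) {
        lines <- c(lines, "is_obsolete: true")
        if (id %in% names(replacement)) {
          lines <- c(lines, paste0("replaced_by: ", replacement[id]))
        }
      }
      lines <- c(lines, "")
    }

    list(
      obo = lines,
      truth = list(ids = ids, namespace = ns_of, parents = parents,
                   obsolete = obsolete, replacement = replacement,
                   alt_ids = alt_ids, data_version = data_version)
    )
  })
}

#' Generate a synthetic GAF annotation corpus
#'
#' Samples annotation lines from the live terms of an ontology with a
#' Zipf-like, leaf-biased weighting: terms are ranked by specificity (number
#' of ancestors, descending) and term rank `r` receives weight `r^-skew`.
#' `skew = 0` gives uniform sampling; large `skew` concentrates all lines on
#' the most specific term. This mimics real annotation corpora where root
#' terms accumulate huge propagated counts and leaves stay rare, which is
#' what gives the information-content gradient its meaning.
#'
#' @param graph A `go_ontology` (typically parsed from
#'   [generate_ontology()] output).
#' @param total Number of annotation lines to draw.
#' @param skew Zipf exponent (>= 0, may be `Inf`).
#' @param seed Integer seed.
#' @return A list with `gaf` (character vector of GAF 2.2 lines, comments
#'   included) and `truth_counts` (named integer vector of drawn lines per
#'   term).
#' @export
generate_annotations <- function(graph, total = 5000L, skew = 1.0,
                                 seed = 1L) {
  stopifnot(inherits(graph, "go_ontology"))
  with_seed(seed, {
    header <- c("!gaf-version: 2.2",
                paste0("!date-generated: synthetic/seed-", seed))
    if (total == 0) {
      list(gaf = header,
           truth_counts = stats::setNames(integer(0), character(0)))
    } else {
    live <- graph$terms$id[!graph$terms$obsolete]
    n_anc <- vapply(live, function(t) length(anc_memo(graph, t)), 0L)
    ord <- order(-n_anc, live)  # most specific first
    ranked <- live[ord]
    w <- seq_along(ranked)^(-skew)
    w <- w / sum(w)
    draws <- sample(ranked, total, replace = TRUE, prob = w)
    aspect <- c(biological_process = "P", molecular_function = "F",
                cellular_component = "C")
    ns <- graph$terms[draws, "namespace"]
    lines <- vapply(seq_along(draws), function(i) {
      paste(
        "UniProtKB", sprintf("P%05d", i), sprintf("GENE%d", i), "enables",
        draws[i], "GO_REF:0000001", "IEA", "", unname(aspect[ns[i]]),
        "synthetic protein", "", "protein", "taxon:9606", "20200710",
        "SynDB", "", "",
        sep = "\t")
    }, "")
    tab <- table(draws)
    list(gaf = c(header, lines),
         truth_counts = stats::setNames(as.integer(tab), names(tab)))
    }
  })
}

#' Generate a synthetic enrichment-result input list
#'
#' Samples live terms of one namespace without replacement, draws p-values
#' log-uniformly from `p_range`, and writes the list in any of the four input
#' dialects. Obsolete identifiers and duplicate rows can be injected to
#' exercise the cleaning stage; the returned `truth` data.frame is the
#' expected cleaned result (obsolete ids replaced where the ontology defines
#' a replacement, duplicates collapsed onto the smaller p-value, input order
#' preserved).
#'
#' @param graph A `go_ontology`.
#' @param size Number of distinct live terms to sample.
#' @param namespace Namespace to sample from.
#' @param dialect Output dialect (see [input_dialects()]).
#' @param p_range Length-2 numeric: log-uniform p-value range.
#' @param n_obsolete_inject Number of obsolete ids appended to the list.
#' @param n_duplicate_inject Number of duplicated rows appended (fresh
#'   p-values).
#' @param seed Integer seed.
#' @return A list with `text` (lines of the dialect file), `truth`
#'   (data.frame `term_id`, `p_value` of the expected cleaned list), and
#'   `n_updates`/`n_discards` bookkeeping for the injected obsolete ids.
#' @export
generate_input_list <- function(graph, size = 60L,
                                namespace = "biological_process",
                                dialect = "standard",
                                p_range = c(1e-8, 0.05),
                                n_obsolete_inject = 0L,
                                n_duplicate_inject = 0L,
                                seed = 1L) {
  stopifnot(inherits(graph, "go_ontology"))
  cols <- dialect_columns(dialect)
  with_seed(seed, {
    live <- graph$terms$id[!graph$terms$obsolete &
                             graph$terms$namespace == namespace]
    if (size > length(live)) {
      stop("requested list size ", size, " exceeds the ", length(live),
           " live terms of ", namespace, call. = FALSE)
    }
    terms <- sample(live, size)
    draw_p <- function(k) {
      10^stats::runif(k, log10(p_range[1]), log10(p_range[2]))
    }
    p <- signif(draw_p(size), 6)
    raw <- data.frame(id = terms, p = p, stringsAsFactors = FALSE)

    obs_pool <- graph$terms$id[graph$terms$obsolete &
                                 graph$terms$namespace == namespace]
    n_obs <- min(n_obsolete_inject, length(obs_pool))
    n_updates <- 0L
    n_discards <- 0L
    if (n_obs > 0) {
      inj <- sample(obs_pool, n_obs)
      raw <- rbind(raw, data.frame(id = inj, p = signif(draw_p(n_obs), 6)))
    }
    if (n_duplicate_inject > 0) {
      dup_ids <- sample(terms, min(n_duplicate_inject, size))
      raw <- rbind(raw, data.frame(id = dup_ids,
                                   p = signif(draw_p(length(dup_ids)), 6)))
    }

    # expected cleaned list: resolve injected obsolete ids from the truth
    # maps, collapse duplicates onto the smaller p, keep input order
    resolved <- raw
    keep <- rep(TRUE, nrow(resolved))
    for (i in seq_len(nrow(resolved))) {
      id <- resolved$id[i]
      if (id %in% graph$terms$id && graph$terms[id, "obsolete"]) {
        rep_id <- graph$terms[id, "replacement"]
        if (is.na(rep_id)) {
          keep[i] <- FALSE
          n_discards <- n_discards + 1L
        } else {
          resolved$id[i] <- rep_id
          n_updates <- n_updates + 1L
        }
      }
    }
    resolved <- resolved[keep, , drop = FALSE]
    truth <- resolved[!duplicated(resolved$id), , drop = FALSE]
    for (id in unique(resolved$id)) {
      truth$p[truth$id == id] <- min(resolved$p[resolved$id == id])
    }
    truth <- data.frame(term_id = truth$id, p_value = truth$p,
                        stringsAsFactors = FALSE)

    fmt_p <- function(x) format(x, scientific = TRUE, digits = 6)
    text <- switch(dialect,
      "standard" = paste(raw$id, fmt_p(raw$p), sep = "\t"),
      "standard-plus" = paste(raw$id, fmt_p(raw$p),
                              signif(stats::runif(nrow(raw), 1, 100), 4),
                              sep = "\t"),
      "topgo" = c(
        paste("GO.ID", "Term", "Annotated", "Significant", "Expected",
              "Rank in classicFisher", "classicFisher", sep = "\t"),
        paste(raw$id, paste0("synthetic term ", seq_len(nrow(raw))),
              sample(20:400, nrow(raw), replace = TRUE),
              sample(1:50, nrow(raw), replace = TRUE),
              signif(stats::runif(nrow(raw), 0.5, 30), 3),
              seq_len(nrow(raw)), fmt_p(raw$p), sep = "\t")),
      "gostats" = c(
        paste("GOBPID", "Pvalue", "OddsRatio", "ExpCount", "Count", "Size",
              "Term", sep = "\t"),
        paste(raw$id, fmt_p(raw$p),
              signif(stats::runif(nrow(raw), 1, 10), 3),
              signif(stats::runif(nrow(raw), 0.5, 30), 3),
              sample(1:50, nrow(raw), replace = TRUE),
              sample(20:400, nrow(raw), replace = TRUE),
              paste0("synthetic term ", seq_len(nrow(raw))), sep = "\t"))
    )
    list(text = text, truth = truth, n_updates = n_updates,
         n_discards = n_discards)
  })
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
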