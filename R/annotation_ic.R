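#' Count term annotations in a GAF file
#'
#' Reads a GAF 2.x gene association file and counts how many annotation lines
#' mention each GO term (column 5). Comment lines start with `!` and are
#' ignored; lines that do not have the 17 GAF columns are skipped and counted
#' as malformed.
#'
#' @param path Path to an (uncompressed) GAF file.
#' @return A list with `counts` (named integer vector, term id -> annotation
#'   lines), `total` (number of counted lines), `malformed` (number of skipped
#'   lines), and `corpus_version` (first `!gaf-version`/`!date-generated`-style
#'   header worth recording, or `NA`).
#' @export
parse_gaf <- function(path) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "!")
  corpus_version <- NA_character_
  ver <- grep("^!(gaf-version|date-generated|Generated):", lines[is_comment],
              value = TRUE)
  if (length(ver) > 0) corpus_version <- trimws(sub("^![^:]+:", "", ver[1]))

  body <- lines[!is_comment & nzchar(lines)]
  if (length(body) == 0) {
    return(list(counts = stats::setNames(integer(0), character(0)),
                total = 0L, malformed = 0L, corpus_version = corpus_version))
  }
  # count separators directly: strsplit drops trailing empty fields, and the
  # last GAF columns are routinely empty
  ntabs <- nchar(body) - nchar(gsub("\t", "", body, fixed = TRUE))
  ncol_ok <- ntabs == 16L
  malformed <- sum(!ncol_ok)
  fields <- strsplit(body[ncol_ok], "\t", fixed = TRUE)
  go_ids <- vapply(fields, `[[`, character(1), 5L)
  tab <- table(go_ids)
  list(
    counts = stats::setNames(as.integer(tab), names(tab)),
    total = length(go_ids),
    malformed = malformed,
    corpus_version = corpus_version
  )
}

#' Propagate raw annotation counts up the ontology
#'
#' Each annotation line contributes once to the annotated term and once to
#' every ancestor of that term (is_a/part_of closure). Because the ancestor
#' closure is a set, diamond paths in the DAG never double-count. Term ids are
#' first resolved against the ontology (alt_id and replaced_by handling); ids
#' that cannot be resolved are dropped with a warning.
#'
#' @param graph A `go_ontology` object.
#' @param raw Output of [parse_gaf()], or any list with `counts` and `total`.
#' @return A list with `counts` (named numeric, propagated), `total` (number
#'   of annotation lines that resolved into the graph), and `dropped` (lines
#'   lost to unresolvable ids).
#' @export
propagate_counts <- function(graph, raw) {
  stopifnot(inherits(graph, "go_ontology"))
  acc <- new.env(parent = emptyenv())
  dropped <- 0L
  resolved_total <- 0L
  for (term in names(raw$counts)) {
    k <- raw$counts[[term]]
    res <- resolve_term(graph, term)
    if (!res$status %in% c("kept", "updated")) {
      dropped <- dropped + k
      next
    }
    resolved_total <- resolved_total + k
    for (a in anc_memo(graph, res$id)) {
      prev <- get0(a, envir = acc, inherits = FALSE)
      assign(a, if (is.null(prev)) k else prev + k, envir = acc)
    }
  }
  if (dropped > 0) {
    warning(dropped, " annotation line(s) referenced unresolvable term ids ",
            "and were dropped", call. = FALSE)
  }
  ids <- ls(acc)
  list(
    counts = stats::setNames(vapply(ids, get, 0, envir = acc), ids),
    total = resolved_total,
    dropped = dropped
  )
}

#' Information content table from propagated counts
#'
#' The information content of a term is the negative natural logarithm of its
#' relative annotation frequency in the corpus: `ic = -ln(count / total)`.
#' Frequent, broad terms score near 0; rare, specific terms score high. Lin
#' similarity downstream is a ratio of ICs and therefore invariant to the
#' logarithm base used here.
#'
#' @param counts Named numeric vector of propagated counts.
#' @param total Total number of annotation lines in the corpus (> 0).
#' @param ontology_version,corpus_version Version strings stored for
#'   provenance (written into the table header by [write_ic_table()]).
#' @return A `go_ic_table`: data.frame with columns `term_id`, `count`,
#'   `frequency`, `ic`, plus attributes `total`, `ontology_version`,
#'   `corpus_version`.
#' @export
information_content <- function(counts, total,
                                ontology_version = NA_character_,
                                corpus_version = NA_character_) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) || total <= 0) {
    stop("total annotation count must be positive; got ", total,
         " (empty or comment-only corpus?)", call. = FALSE)
  }
  counts <- counts[counts > 0]
  freq <- as.numeric(counts) / total
  tab <- data.frame(
    term_id = names(counts),
    count = as.numeric(counts),
    frequency = freq,
    ic = -log(freq),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$term_id
  structure(tab,
            total = total,
            ontology_version = ontology_version,
            corpus_version = corpus_version,
            class = c("go_ic_table", "data.frame"))
}

#' Build an IC table straight from ontology + GAF
#'
#' Convenience wrapper: [parse_gaf()], [propagate_counts()], then
#' [information_content()].
#'
#' @inheritParams propagate_counts
#' @param gaf_path Path to the GAF file.
#' @return A `go_ic_table`.
#' @export
compute_ic <- function(graph, gaf_path) {
  raw <- parse_gaf(gaf_path)
  prop <- propagate_counts(graph, raw)
  information_content(prop$counts, prop$total,
                      ontology_version = graph$data_version,
                      corpus_version = raw$corpus_version)
}

# look up helpers; terms absent from the corpus have undefined IC
ic_of <- function(ic, term) {
  if (term %in% rownames(ic)) ic[term, "ic"] else NA_real_
}
freq_of <- function(ic, term) {
  if (term %in% rownames(ic)) ic[term, "frequency"] else 0
}

#' Write / read a precomputed IC table
#'
#' The table is a lossless tab-delimited round trip of term id, propagated
#' count, frequency and information content, preceded by `#`-prefixed header
#' lines recording the ontology and annotation-corpus versions and the total
#' annotation count. Precomputing lets users avoid re-reading the full GAF
#' corpus on every run.
#'
#' @param ic A `go_ic_table`.
#' @param path File path for the tab-delimited table.
#' @return `write_ic_table()` returns `path` invisibly; `read_ic_table()`
#'   returns a `go_ic_table`.
#' @export
write_ic_table <- function(ic, path) {
  stopifnot(inherits(ic, "go_ic_table"))
  hdr <- c(
    paste0("# ontology-version: ", attr(ic, "ontology_version")),
    paste0("# corpus-version: ", attr(ic, "corpus_version")),
    paste0("# total-annotations: ", format(attr(ic, "total"), scientific = FALSE)),
    paste("term_id", "count", "frequency", "ic", sep = "\t")
  )
  body <- paste(ic$term_id,
                format(ic$count, scientific = FALSE, trim = TRUE),
                sprintf("%.17g", ic$frequency),
                sprintf("%.17g", ic$ic), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ic_table
#' @param graph Optional `go_ontology`; when given, its `data_version` is
#'   compared with the table header and a mismatch raises a warning (not an
#'   error), since off-version tables silently shift IC values.
#' @export
read_ic_table <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("cannot read IC table: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(hit) == 0) NA_character_ else
      trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  ontology_version <- get_hdr("ontology-version")
  corpus_version <- get_hdr("corpus-version")
  total_chr <- get_hdr("total-annotations")
  if (is.na(total_chr)) {
    stop("IC table ", path, " is missing its '# total-annotations:' header; ",
         "was it produced by write_ic_table()?", call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) > 0 && startsWith(body[1], "term_id")) body <- body[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("IC table ", path, " has rows without 4 tab-delimited columns",
         call. = FALSE)
  }
  tab <- data.frame(
    term_id = vapply(fields, `[[`, "", 1L),
    count = as.numeric(vapply(fields, `[[`, "", 2L)),
    frequency = as.numeric(vapply(fields, `[[`, "", 3L)),
    ic = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$term_id
  out <- structure(tab,
                   total = as.numeric(total_chr),
                   ontology_version = ontology_version,
                   corpus_version = corpus_version,
                   class = c("go_ic_table", "data.frame"))
  if (!is.null(graph) && !is.na(ontology_version) &&
      !identical(ontology_version, graph$data_version)) {
    warning("IC table was computed against ontology version '",
            ontology_version, "' but the loaded ontology is '",
            graph$data_version, "'", call. = FALSE)
  }
  out
}
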