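#' Supported enrichment-result input dialects
#'
#' Four tab-delimited layouts are accepted:
#' \describe{
#'   \item{standard}{2 columns: term id, p-value.}
#'   \item{standard-plus}{3 columns: term id, p-value, user-defined metric
#'     (usable for plot colors/sizes).}
#'   \item{topgo}{7 columns: term id, term name, Annotated, Significant,
#'     Expected, rank, p-value. The Significant column is captured as the
#'     foreground gene count.}
#'   \item{gostats}{7 columns: term id, p-value, OddsRatio, ExpCount, Count,
#'     Size, term name. The Count column is captured as the foreground gene
#'     count.}
#' }
#' These layouts are this package's documented contract for the two 7-column
#' shapes; no auto-detection is attempted.
#'
#' @return Character vector of dialect names.
#' @export
input_dialects <- function() c("standard", "standard-plus", "topgo", "gostats")

dialect_columns <- function(dialect) {
  switch(dialect,
    "standard"      = list(ncol = 2L, id = 1L, p = 2L, metric = NA, fg = NA),
    "standard-plus" = list(ncol = 3L, id = 1L, p = 2L, metric = 3L, fg = NA),
    "topgo"         = list(ncol = 7L, id = 1L, p = 7L, metric = NA, fg = 4L),
    "gostats"       = list(ncol = 7L, id = 1L, p = 2L, metric = NA, fg = 5L),
    stop("unknown input dialect '", dialect, "'; valid dialects: ",
         paste(input_dialects(), collapse = ", "), call. = FALSE)
  )
}

#' Parse and clean an enrichment-result term list
#'
#' Reads one of the four tab-delimited dialects (see [input_dialects()]),
#' resolves every term id against the ontology ([resolve_term()]: alt_id
#' canonicalization, obsolete update or discard), collapses duplicate ids
#' (keeping the smaller p-value, with a warning), and clamps p-values of 0 to
#' the smallest positive p-value in the list so downstream ratio tests and
#' log-scaling stay defined. Input order is preserved.
#'
#' @param path Path to the tab-delimited list.
#' @param dialect One of [input_dialects()].
#' @param graph A `go_ontology`.
#' @param header `TRUE`, `FALSE`, or `NA` (default) to auto-detect: the first
#'   row is treated as a header when its p-value column is not numeric.
#' @return A `go_term_list`: data.frame with columns `term_id`, `p_value`,
#'   `user_metric`, `fg_count` (NA where the dialect has none), carrying
#'   attributes `dialect`, `report` (cleaning counts: `rows`, `kept`,
#'   `updated`, `discarded`, `unknown`, `duplicate`) and `log` (character
#'   vector of per-term notices).
#' @export
parse_input <- function(path, dialect = "standard", graph, header = NA) {
  cols <- dialect_columns(dialect)
  if (!file.exists(path)) stop("cannot read input list: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (length(fields) > 0) {
    first_p <- suppressWarnings(
      as.numeric(fields[[1]][min(cols$p, length(fields[[1]]))]))
    drop_first <- isTRUE(header) || (is.na(header) && is.na(first_p))
    if (drop_first) fields <- fields[-1]
  }
  if (length(fields) == 0) {
    stop("input list ", path, " contains no data rows", call. = FALSE)
  }

  bad <- which(lengths(fields) != cols$ncol)
  if (length(bad) > 0) {
    stop("input row ", bad[1], " has ", lengths(fields)[bad[1]],
         " columns; dialect '", dialect, "' requires ", cols$ncol,
         call. = FALSE)
  }

  raw_id <- vapply(fields, `[[`, "", cols$id)
  p_chr <- vapply(fields, `[[`, "", cols$p)
  p <- suppressWarnings(as.numeric(p_chr))
  if (anyNA(p)) {
    r <- which(is.na(p))[1]
    stop("non-numeric p-value '", p_chr[r], "' in input row ", r,
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    r <- which(p < 0 | p > 1)[1]
    stop("p-value out of range in input row ", r, ": ", p[r], call. = FALSE)
  }
  metric <- if (is.na(cols$metric)) rep(NA_real_, length(fields)) else
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", cols$metric)))
  fg <- if (is.na(cols$fg)) rep(NA_real_, length(fields)) else
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", cols$fg)))

  n <- length(raw_id)
  log_lines <- character(0)
  status <- character(n)
  canon <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- resolve_term(graph, raw_id[i])
    status[i] <- res$status
    canon[i] <- res$id
    if (!is.na(res$log)) log_lines <- c(log_lines, res$log)
  }

  keep <- status %in% c("kept", "updated")
  seen <- character(0)
  dup <- logical(n)
  best <- list()  # canonical id -> row index of current best (smallest p)
  for (i in which(keep)) {
    id <- canon[i]
    if (id %in% seen) {
      dup[i] <- TRUE
      j <- best[[id]]
      if (p[i] < p[j]) {
        # later duplicate wins on p: swap roles so the kept row carries its p
        dup[i] <- FALSE
        dup[j] <- TRUE
        best[[id]] <- i
      }
      log_lines <- c(log_lines, paste0(
        "duplicate entry for ", id, " collapsed; keeping p = ",
        format(min(p[i], p[j]))))
      warning("duplicate term ", id, " in input; keeping the smaller p-value",
              call. = FALSE)
    } else {
      seen <- c(seen, id)
      best[[id]] <- i
    }
  }
  sel <- keep & !dup
  # duplicates logged under their surviving row position keep input order:
  # reorder by first appearance of each canonical id
  first_pos <- vapply(seen, function(id) min(which(keep & canon == id)), 0L)
  ord <- order(first_pos)
  rows <- vapply(seen[ord], function(id) best[[id]], 0L)

  out <- data.frame(
    term_id = canon[rows],
    p_value = p[rows],
    user_metric = metric[rows],
    fg_count = fg[rows],
    stringsAsFactors = FALSE
  )

  if (any(out$p_value == 0)) {
    pos <- out$p_value[out$p_value > 0]
    if (length(pos) == 0) {
      stop("all p-values in the input are 0; cannot rescale", call. = FALSE)
    }
    clamp <- min(pos)
    nz <- sum(out$p_value == 0)
    out$p_value[out$p_value == 0] <- clamp
    log_lines <- c(log_lines, paste0(
      nz, " p-value(s) of 0 clamped to the smallest positive p-value ",
      format(clamp)))
    warning("p-value(s) of 0 clamped to ", format(clamp), call. = FALSE)
  }

  report <- list(
    rows = n,
    kept = sum(status == "kept" & !dup),
    updated = sum(status == "updated" & !dup),
    discarded = sum(status == "discarded"),
    unknown = sum(status == "unknown"),
    duplicate = sum(dup)
  )
  structure(out, dialect = dialect, report = report, log = log_lines,
            class = c("go_term_list", "data.frame"))
}

#' @export
print.go_term_list <- function(x, ...) {
  rep <- attr(x, "report")
  cat("go_term_list:", nrow(x), "cleaned terms (dialect ",
      attr(x, "dialect"), ")\n", sep = "")
  cat("  rows:", rep$rows, "| kept:", rep$kept, "| updated:", rep$updated,
      "| discarded:", rep$discarded, "| unknown:", rep$unknown,
      "| duplicates collapsed:", rep$duplicate, "\n")
  invisible(x)
}
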