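#' Run the full summarization pipeline
#'
#' Orchestrates the whole method: load the ontology and the information
#' content table (precomputed, or computed from a GAF corpus), parse and
#' clean the input term list, split it by GO namespace, and for each
#' requested namespace compute the Lin similarity matrix, group terms under
#' the similarity cutoff, select representatives, embed them in 2D semantic
#' space by MDS, and render the scatterplot. Per namespace it writes a figure,
#' a group-membership TSV and a plot-dataframe TSV; one provenance log
#' records versions, parameters, every term update/discard notice, the MDS
#' seed and stress, and the output file names.
#'
#' @param input Path to the enrichment-result list.
#' @param input_type One of [input_dialects()].
#' @param go_obo Path to the core ontology in OBO format.
#' @param ic_table Path to a precomputed IC table ([write_ic_table()]), or
#'   `NULL` to compute from `gaf`.
#' @param gaf Path to a GAF annotation corpus (used when `ic_table` is
#'   `NULL`).
#' @param ontology Which namespaces to process: `"bp"`, `"mf"`, `"cc"`, or
#'   `"all"`.
#' @param similarity_cutoff Lin similarity threshold for grouping (default
#'   0.5).
#' @param seed Integer seed recorded with the embedding.
#' @param outdir Output directory (created if missing).
#' @param name Prefix for all output files.
#' @param spec A `go_plot_spec`; defaults to [plot_spec()] defaults.
#' @param write_similarity Also dump the per-namespace similarity matrix as
#'   TSV (debugging aid)?
#' @return Invisibly, a list with one element per rendered namespace
#'   (`figure`, `groups`, `dataframe` paths plus the in-memory objects) and
#'   `log` (the log file path).
#' @export
run_goscatter <- function(input,
                          input_type = "standard",
                          go_obo,
                          ic_table = NULL,
                          gaf = NULL,
                          ontology = c("all", "bp", "mf", "cc"),
                          similarity_cutoff = 0.5,
                          seed = 42L,
                          outdir = ".",
                          name = "goscatter",
                          spec = plot_spec(),
                          write_similarity = FALSE) {
  ontology <- match.arg(ontology)
  if (is.null(ic_table) && is.null(gaf)) {
    stop("either a precomputed IC table or a GAF corpus is required",
         call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  log_lines <- c(
    paste0("tool: goscatter ", as.character(utils::packageVersion("goscatter"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  graph <- parse_obo(go_obo)
  log_lines <- c(log_lines, paste0("ontology: ", go_obo,
                                   " (data-version: ", graph$data_version, ")"))
  ic <- if (!is.null(ic_table)) {
    log_lines <- c(log_lines, paste0("ic-table: ", ic_table))
    read_ic_table(ic_table, graph)
  } else {
    log_lines <- c(log_lines, paste0("annotation-corpus: ", gaf))
    compute_ic(graph, gaf)
  }
  log_lines <- c(log_lines,
                 paste0("corpus-version: ", attr(ic, "corpus_version")),
                 paste0("total-annotations: ", attr(ic, "total")))

  params <- c(input = input, input_type = input_type, ontology = ontology,
              similarity_cutoff = similarity_cutoff, seed = seed,
              palette = spec$palette, color_by = spec$color_by,
              size_by = spec$size_by, max_labels = spec$max_labels,
              label_style = spec$label_style,
              description_limit = spec$description_limit,
              legend_columns = spec$legend_columns, legend = spec$legend,
              file_type = spec$file_type, dpi = spec$dpi, outdir = outdir,
              name = name)
  log_lines <- c(log_lines,
                 paste0("parameter ", names(params), ": ", unname(params)))

  term_list <- parse_input(input, input_type, graph)
  rep_counts <- attr(term_list, "report")
  log_lines <- c(log_lines, attr(term_list, "log"),
                 paste0("input rows: ", rep_counts$rows,
                        " | kept: ", rep_counts$kept,
                        " | updated: ", rep_counts$updated,
                        " | discarded: ", rep_counts$discarded,
                        " | unknown: ", rep_counts$unknown,
                        " | duplicates collapsed: ", rep_counts$duplicate))

  ns_map <- c(bp = "biological_process", mf = "molecular_function",
              cc = "cellular_component")
  wanted <- if (ontology == "all") ns_map else ns_map[ontology]

  results <- list()
  for (i in seq_along(wanted)) {
    suffix <- names(wanted)[i]
    ns <- wanted[[i]]
    sub <- term_list[graph$terms[term_list$term_id, "namespace"] == ns, ,
                     drop = FALSE]
    if (nrow(sub) == 0) {
      log_lines <- c(log_lines, paste0("namespace ", ns,
                                       ": 0 surviving terms, skipped"))
      next
    }
    no_ic <- sub$term_id[!sub$term_id %in% rownames(ic)]
    if (length(no_ic) > 0) {
      log_lines <- c(log_lines, paste0(
        "namespace ", ns, ": term(s) absent from the annotation corpus, ",
        "kept as singletons with undefined IC: ",
        paste(no_ic, collapse = ", ")))
    }
    pvals <- stats::setNames(sub$p_value, sub$term_id)
    m <- similarity_matrix(sub$term_id, ic, graph)
    groups <- reduce_terms(sub$term_id, m, similarity_cutoff, ic, pvals,
                           graph)
    reps <- vapply(groups$groups, `[[`, "", "representative")
    emb <- embed_terms(reps, m, seed = seed)
    prefix <- file.path(outdir, paste0(name, "_", suffix))

    rendered <- render_scatterplot(emb, groups, sub, ic, graph, spec,
                                   prefix)
    groups_path <- paste0(prefix, "_groups.tsv")
    write_groups(groups, m, pvals, groups_path,
                 names = stats::setNames(graph$terms[sub$term_id, "name"],
                                         sub$term_id))
    if (write_similarity) {
      write_similarity_matrix(m, paste0(prefix, "_similarity.tsv"))
    }
    log_lines <- c(log_lines,
                   paste0("namespace ", ns, ": ", nrow(sub), " terms, ",
                          length(groups$groups), " groups (",
                          sum(vapply(groups$groups,
                                     function(g) length(g$members) == 1L,
                                     TRUE)), " singletons) at threshold ",
                          similarity_cutoff),
                   paste0("namespace ", ns, ": MDS seed ", seed, ", stress ",
                          format(emb$stress, digits = 6)),
                   paste0("output: ", rendered$figure),
                   paste0("output: ", groups_path),
                   paste0("output: ", rendered$dataframe))
    results[[suffix]] <- list(
      figure = rendered$figure, groups = groups_path,
      dataframe = rendered$dataframe, data = rendered$data,
      term_groups = groups, embedding = emb, similarity = m
    )
  }

  if (length(results) == 0) {
    stop("no terms survived cleaning in any requested namespace",
         call. = FALSE)
  }

  log_path <- file.path(outdir, paste0(name, "_log.txt"))
  writeLines(log_lines, log_path)
  results$log <- log_path
  invisible(results)
}
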