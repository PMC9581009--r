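#' Plotting options for the summary scatterplot
#'
#' Bundles the user-facing graphical options. Defaults follow the tool's
#' standard look: circles colored by log10 p-value on a gradient palette,
#' sized by the number of terms each representative stands for, and the 10
#' most significant representatives labeled with numbers whose descriptions
#' are printed below the plot.
#'
#' @param palette Named palette; any name in [grDevices::hcl.pals()] or an
#'   RColorBrewer palette name is accepted.
#' @param color_by One of `"pvalue"` (log10-scaled), `"members"`,
#'   `"frequency"`, `"unique"`, `"user"`.
#' @param size_by One of `"members"`, `"pvalue"`, `"frequency"`, `"fixed"`,
#'   `"user"`.
#' @param max_labels Number of most-significant representatives to label
#'   (>= 0).
#' @param label_style `"numbered"` (numbers on the plot, descriptions below),
#'   `"goid"` (term identifiers in-plot with automatic label placement), or
#'   `"description"` (descriptors in-plot with automatic label placement).
#' @param description_limit Maximum characters of a description before
#'   truncation.
#' @param legend_columns Number of columns for the description block /
#'   discrete legend.
#' @param legend Show the legend?
#' @param font_size Base font size in points.
#' @param file_type One of `"png"`, `"pdf"`, `"svg"`, `"tiff"`.
#' @param dpi Raster resolution in dots per inch.
#' @param point_size_range Numeric length-2: point sizes (mm) that the size
#'   encoding is rescaled into; `"fixed"` uses its mean.
#' @return A `go_plot_spec` list.
#' @export
plot_spec <- function(palette = "viridis",
                      color_by = c("pvalue", "members", "frequency", "unique",
                                   "user"),
                      size_by = c("members", "pvalue", "frequency", "fixed",
                                  "user"),
                      max_labels = 10L,
                      label_style = c("numbered", "goid", "description"),
                      description_limit = 50L,
                      legend_columns = 1L,
                      legend = TRUE,
                      font_size = 11,
                      file_type = c("png", "pdf", "svg", "tiff"),
                      dpi = 300,
                      point_size_range = c(3, 12)) {
  color_by <- match.arg(color_by)
  size_by <- match.arg(size_by)
  label_style <- match.arg(label_style)
  file_type <- match.arg(file_type)
  stopifnot(is.numeric(max_labels), max_labels >= 0)
  palette <- resolve_palette(palette)
  structure(
    list(palette = palette, color_by = color_by, size_by = size_by,
         max_labels = as.integer(max_labels), label_style = label_style,
         description_limit = as.integer(description_limit),
         legend_columns = as.integer(legend_columns), legend = legend,
         font_size = font_size, file_type = file_type, dpi = dpi,
         point_size_range = point_size_range),
    class = "go_plot_spec"
  )
}

#' @rdname plot_spec
#' @export
valid_palettes <- function() {
  unique(c(grDevices::hcl.pals(),
           rownames(RColorBrewer::brewer.pal.info)))
}

# case-insensitive lookup so matplotlib-style lowercase names ("viridis",
# "plasma") hit the corresponding registry entries
resolve_palette <- function(palette) {
  valid <- valid_palettes()
  hit <- valid[tolower(valid) == tolower(palette)]
  if (length(hit) == 0) {
    stop("unknown palette '", palette, "'; valid palette names are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  hit[1]
}

palette_colors <- function(palette, n) {
  if (palette %in% grDevices::hcl.pals()) {
    grDevices::hcl.colors(max(n, 2L), palette)[seq_len(n)]
  } else {
    info <- RColorBrewer::brewer.pal.info[palette, ]
    k <- min(max(n, 3L), info$maxcolors)
    cols <- RColorBrewer::brewer.pal(k, palette)
    if (n <= k) cols[seq_len(n)] else
      grDevices::colorRampPalette(cols)(n)
  }
}

#' Build the per-representative plot dataframe
#'
#' One row per representative: id, description, semantic-space coordinates,
#' p-value and its log10, member count, corpus frequency, and the optional
#' user metric / foreground count. This is the exact dataframe the
#' scatterplot is drawn from, and it is what [render_scatterplot()] saves as
#' TSV so users can rebuild or restyle the figure.
#'
#' @param embedding A `go_embedding`.
#' @param groups A `go_term_groups`.
#' @param term_list A `go_term_list` (cleaned entries).
#' @param ic A `go_ic_table`.
#' @param graph A `go_ontology` (for descriptions).
#' @return A data.frame ordered by group appearance.
#' @export
plot_dataframe <- function(embedding, groups, term_list, ic, graph) {
  reps <- vapply(groups$groups, `[[`, "", "representative")
  stopifnot(setequal(reps, rownames(embedding$coordinates)))
  members <- vapply(groups$groups, function(g) length(g$members), 0L)
  pv <- stats::setNames(term_list$p_value, term_list$term_id)
  um <- stats::setNames(term_list$user_metric, term_list$term_id)
  fg <- stats::setNames(term_list$fg_count, term_list$term_id)
  data.frame(
    representative = reps,
    description = graph$terms[reps, "name"],
    x = embedding$coordinates[reps, "x"],
    y = embedding$coordinates[reps, "y"],
    p_value = unname(pv[reps]),
    log10_p_value = log10(unname(pv[reps])),
    members = members,
    frequency = vapply(reps, function(t) freq_of(ic, t), 0),
    user_metric = unname(um[reps]),
    fg_count = unname(fg[reps]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

user_values <- function(df) {
  if (!all(is.na(df$user_metric))) return(df$user_metric)
  if (!all(is.na(df$fg_count))) return(df$fg_count)
  stop("a 'user' color/size encoding was requested but the input dialect ",
       "carried no user metric or foreground count column", call. = FALSE)
}

#' Render the semantic-space scatterplot
#'
#' Draws one circle per representative at its MDS coordinates, applies the
#' color and size encodings from the `go_plot_spec`, labels the most
#' significant representatives (ascending p-value, ties broken by group
#' order), and writes both the figure and the plot dataframe
#' (`<out_prefix>_dataframe.tsv`). In-plot identifier/description labels are
#' placed with ggrepel's automatic label placement (fixed seed, with arrows).
#'
#' @param embedding A `go_embedding`.
#' @param groups A `go_term_groups`.
#' @param term_list A `go_term_list`.
#' @param ic A `go_ic_table`.
#' @param graph A `go_ontology`.
#' @param spec A `go_plot_spec` from [plot_spec()].
#' @param out_prefix Path prefix for the figure and dataframe files.
#' @return Invisibly, a list with `figure` and `dataframe` file paths, the
#'   dataframe itself (`data`), and the ggplot object (`plot`).
#' @export
render_scatterplot <- function(embedding, groups, term_list, ic, graph, spec,
                               out_prefix) {
  stopifnot(inherits(spec, "go_plot_spec"))
  df <- plot_dataframe(embedding, groups, term_list, ic, graph)
  n <- nrow(df)

  # significance ranking: ascending p, ties by group appearance order
  rank_order <- order(df$p_value, seq_len(n))
  n_lab <- min(spec$max_labels, n)
  labelled <- rank_order[seq_len(n_lab)]
  df$label_rank <- NA_integer_
  df$label_rank[labelled] <- seq_len(n_lab)

  trunc_desc <- function(s) {
    ifelse(is.na(s), "", ifelse(nchar(s) > spec$description_limit,
                                paste0(substr(s, 1, spec$description_limit - 1),
                                       "…"),
                                s))
  }
  df$short_description <- trunc_desc(df$description)

  color_vals <- switch(spec$color_by,
    pvalue = df$log10_p_value,
    members = df$members,
    frequency = df$frequency,
    unique = factor(df$representative, levels = df$representative),
    user = user_values(df))
  color_name <- switch(spec$color_by,
    pvalue = "log10 p-value", members = "members",
    frequency = "GOA frequency", unique = "term", user = "user value")
  size_vals <- switch(spec$size_by,
    members = df$members,
    pvalue = -df$log10_p_value,
    frequency = df$frequency,
    fixed = NULL,
    user = user_values(df))
  size_name <- switch(spec$size_by,
    members = "members", pvalue = "-log10 p-value",
    frequency = "GOA frequency", fixed = NULL, user = "user value")

  df$.color <- color_vals
  aes_args <- list(x = quote(x), y = quote(y), color = quote(.color))
  if (!is.null(size_vals)) {
    df$.size <- size_vals
    aes_args$size <- quote(.size)
  }

  gg <- ggplot2::ggplot(df, do.call(ggplot2::aes, aes_args))
  if (is.null(size_vals)) {
    gg <- gg + ggplot2::geom_point(size = mean(spec$point_size_range),
                                   alpha = 0.8)
  } else {
    gg <- gg + ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_size_continuous(name = size_name,
                                     range = spec$point_size_range)
  }

  if (spec$color_by == "unique") {
    gg <- gg + ggplot2::scale_color_manual(
      name = color_name,
      values = stats::setNames(palette_colors(spec$palette, n),
                               levels(color_vals)),
      labels = stats::setNames(
        if (spec$label_style == "goid") df$representative
        else paste0(df$representative, " ", df$short_description),
        levels(color_vals)),
      guide = ggplot2::guide_legend(ncol = spec$legend_columns)
    )
  } else {
    gg <- gg + ggplot2::scale_color_gradientn(
      name = color_name,
      colors = palette_colors(spec$palette, 256L))
  }

  caption <- NULL
  if (n_lab > 0) {
    lab_df <- df[!is.na(df$label_rank), , drop = FALSE]
    lab_df <- lab_df[order(lab_df$label_rank), , drop = FALSE]
    if (spec$label_style == "numbered") {
      gg <- gg + ggplot2::geom_text(
        data = lab_df,
        ggplot2::aes(x = x, y = y, label = label_rank),
        inherit.aes = FALSE, size = spec$font_size * 0.3,
        fontface = "bold", vjust = -1.1)
      entries <- paste0(lab_df$label_rank, ": ", lab_df$short_description)
      ncolumns <- max(1L, spec$legend_columns)
      rows <- split(entries, ceiling(seq_along(entries) / ncolumns))
      caption <- paste(vapply(rows, paste, "", collapse = "    "),
                       collapse = "\n")
    } else {
      lab_df$.label <- if (spec$label_style == "goid") lab_df$representative
        else lab_df$short_description
      gg <- gg + ggrepel::geom_text_repel(
        data = lab_df,
        ggplot2::aes(x = x, y = y, label = .label),
        inherit.aes = FALSE, size = spec$font_size * 0.3,
        seed = 1L, min.segment.length = 0, max.overlaps = Inf,
        arrow = grid::arrow(length = grid::unit(0.01, "npc")))
    }
  }

  gg <- gg +
    ggplot2::labs(x = "Semantic space X", y = "Semantic space Y",
                  caption = caption) +
    ggplot2::theme_bw(base_size = spec$font_size) +
    ggplot2::theme(plot.caption = ggplot2::element_text(hjust = 0))
  if (!spec$legend) gg <- gg + ggplot2::theme(legend.position = "none")

  fig_path <- paste0(out_prefix, ".", spec$file_type)
  # cairo svg: avoids an svglite dependency and embeds no timestamps
  dev <- if (spec$file_type == "svg") grDevices::svg else spec$file_type
  ggplot2::ggsave(fig_path, gg, width = 7, height = 6, dpi = spec$dpi,
                  device = dev)

  df_path <- paste0(out_prefix, "_dataframe.tsv")
  out_cols <- c("representative", "description", "x", "y", "p_value",
                "log10_p_value", "members", "frequency")
  if (!all(is.na(df$user_metric))) out_cols <- c(out_cols, "user_metric")
  if (!all(is.na(df$fg_count))) out_cols <- c(out_cols, "fg_count")
  utils::write.table(
    format(df[, out_cols], digits = 12, trim = TRUE),
    df_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(figure = fig_path, dataframe = df_path, data = df,
                 plot = gg))
}
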