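# Figures and tables: force-directed network plots and the two-cohort
# triangular matrix.

#' Figure specification for network plots
#'
#' @param layout_seed integer seed for the Fruchterman-Reingold layout.
#' @param layout_mode `"averaged_fixed"` computes one layout from the
#'   element-wise mean absolute adjacency of both cohorts and reuses it for
#'   both plots (the study's fixed average layout); `"per_cohort"` lays each
#'   network out independently.
#' @param edge_width_scale multiplier on `|rho|` for edge widths.
#' @return list of class `figure_spec`.
#' @export
figure_spec <- function(layout_seed = 1L,
                        layout_mode = c("averaged_fixed", "per_cohort"),
                        edge_width_scale = 12) {
  structure(list(layout_seed = as.integer(layout_seed),
                 layout_mode = match.arg(layout_mode),
                 edge_width_scale = edge_width_scale),
            class = "figure_spec")
}

fr_layout <- function(w, seed) {
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(substream_seed(seed, "layout"))
  igraph::layout_with_fr(g)
}

#' Plot a weighted partial-correlation network
#'
#' Nodes are coloured by block (or by a community partition if given);
#' positive edges are blue, negative red; edge width is proportional to the
#' posterior-mean |rho|. In averaged-fixed mode pass `layout_adjacency` (the
#' mean absolute adjacency of the two cohorts) so both cohort figures share
#' identical node coordinates; a precomputed `coords` matrix overrides the
#' layout entirely.
#'
#' @param adjacency symmetric weighted adjacency of supported edges (see
#'   [supported_adjacency()]).
#' @param file output file (`.png` or `.svg`).
#' @param spec a `figure_spec`.
#' @param schema variable schema (for block colours); NULL = single colour.
#' @param communities optional named membership vector for node colours.
#' @param layout_adjacency adjacency used for the layout (averaged-fixed
#'   mode); defaults to `adjacency`.
#' @param coords optional precomputed coordinate matrix.
#' @return invisibly, a list with `file` and the `coords` used.
#' @export
plot_network <- function(adjacency, file, spec = figure_spec(), schema = NULL,
                         communities = NULL, layout_adjacency = NULL,
                         coords = NULL) {
  w <- as.matrix(adjacency)
  labels <- rownames(w) %||% paste0("V", seq_len(nrow(w)))
  if (is.null(coords))
    coords <- fr_layout(layout_adjacency %||% w, spec$layout_seed)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- abs(igraph::E(g)$weight) * spec$edge_width_scale
  ec <- ifelse(igraph::E(g)$weight >= 0, "#2166ac", "#b2182b")
  vc <- if (!is.null(communities)) {
    pal <- grDevices::hcl.colors(max(communities), "Set 2")
    pal[communities[labels]]
  } else if (!is.null(schema)) {
    blk <- schema$block[match(labels, schema$name)]
    c(trait = "#80b1d3", stressor_dysregulation = "#fdb462",
      depression = "#fb8072")[blk]
  } else "#80b1d3"
  open_dev <- if (grepl("\\.svg$", file)) grDevices::svg else grDevices::png
  if (identical(open_dev, grDevices::png)) open_dev(file, width = 800, height = 800)
  else open_dev(file, width = 8, height = 8)
  graphics::par(mar = c(1, 1, 1, 1))
  igraph::plot.igraph(g, layout = coords, vertex.color = vc, vertex.size = 22,
                      vertex.label = labels, vertex.label.cex = 0.7,
                      vertex.label.color = "black",
                      edge.width = pmax(ew, 0.5), edge.color = ec)
  grDevices::dev.off()
  invisible(list(file = file, coords = coords))
}

#' Two-cohort triangular matrix of edge estimates
#'
#' 13 x 13 display with cohort A in the lower triangle and cohort B in the
#' upper: cells hold the posterior mean with its 95% CrI (3 decimals); cell
#' colours mark replication (green = replicated, orange = discordant, white =
#' ambiguous in at least one cohort).
#'
#' @param repl a `replication_summary`.
#' @param decisions_a,decisions_b the per-cohort `edge_decisions`.
#' @param labels node labels in canonical order.
#' @param file_tsv optional TSV output path for the cell text.
#' @param file_png optional PNG rendering.
#' @return list with `cells` (character matrix) and `colors`.
#' @export
triangular_matrix <- function(repl, decisions_a, decisions_b, labels,
                              file_tsv = NULL, file_png = NULL) {
  k <- length(labels)
  fmt <- function(d, r) sprintf("%.3f (%.3f, %.3f)",
                                d$rho_mean[r], d$cri_low[r], d$cri_high[r])
  cells <- matrix("", k, k, dimnames = list(labels, labels))
  colors <- matrix("white", k, k, dimnames = list(labels, labels))
  for (r in seq_len(nrow(repl))) {
    i <- repl$i[r]; j <- repl$j[r]
    cells[j, i] <- fmt(decisions_a, r)   # lower triangle: cohort A
    cells[i, j] <- fmt(decisions_b, r)   # upper triangle: cohort B
    col <- if (repl$replication[r] %in%
               c("replicated_association", "replicated_independence")) "green"
           else if (repl$replication[r] == "discordant") "orange"
           else "white"
    colors[j, i] <- colors[i, j] <- col
  }
  if (!is.null(file_tsv))
    utils::write.table(cells, file_tsv, sep = "\t", quote = FALSE,
                       col.names = NA)
  if (!is.null(file_png)) {
    grDevices::png(file_png, width = 1400, height = 1400)
    graphics::par(mar = c(1, 8, 8, 1))
    num <- matrix(match(colors, c("white", "green", "orange")), k, k)
    graphics::image(seq_len(k), seq_len(k), t(num[k:1, ]), axes = FALSE,
                    xlab = "", ylab = "",
                    col = c("white", "#a6dba0", "#fdb863"), zlim = c(1, 3))
    graphics::axis(3, at = seq_len(k), labels = labels, las = 2, cex.axis = 0.8)
    graphics::axis(2, at = seq_len(k), labels = rev(labels), las = 2, cex.axis = 0.8)
    for (i in seq_len(k)) for (j in seq_len(k))
      if (nzchar(cells[i, j]))
        graphics::text(j, k + 1 - i, cells[i, j], cex = 0.45)
    grDevices::dev.off()
  }
  list(cells = cells, colors = colors)
}
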