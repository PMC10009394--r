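#' Consensus graph from posterior edge frequencies
#'
#' A within-slice pair enters the consensus when its total orientation
#' posterior `p(i->j) + p(j->i)` reaches `include_threshold`; it is drawn
#' single-headed toward the dominant direction when that direction carries
#' at least `direction_ratio` of the pair's mass, and double-headed
#' otherwise (the data cannot resolve the direction).  Between-slice edges
#' enter at `p >= include_threshold` and always point forward in time.
#'
#' @param posteriors list with `W` and `B` edge-posterior matrices (from
#'   [edge_posteriors()] or [exhaustive_posterior()]).
#' @param include_threshold minimum total posterior for a connection.
#' @param direction_ratio minimum share of a pair's mass for a resolved
#'   direction.
#' @return A `consensus_graph`: data frame of connections with `type`
#'   (within/between), `from`, `to`, `p_forward`, `p_backward`, `class`
#'   (directed/double-headed/between-slice) and `strength`.
#' @export
build_consensus <- function(posteriors, include_threshold = 0.5,
                            direction_ratio = 0.8) {
  stopifnot(include_threshold >= 0, include_threshold <= 1,
            direction_ratio >= 0, direction_ratio <= 1)
  W <- posteriors$W; B <- posteriors$B
  items <- posteriors$items %||% rownames(W) %||% paste0("V", seq_len(nrow(W)))
  n <- nrow(W)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- W[i, j] + W[j, i]
    if (tot >= include_threshold) {
      fwd <- W[i, j] >= W[j, i]
      pf <- max(W[i, j], W[j, i]); pb <- min(W[i, j], W[j, i])
      rows[[length(rows) + 1L]] <- data.frame(
        type = "within",
        from = items[if (fwd) i else j], to = items[if (fwd) j else i],
        p_forward = pf, p_backward = pb,
        class = if (pf / tot >= direction_ratio) "directed" else "double-headed",
        strength = tot, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (B[i, j] >= include_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "between", from = items[i], to = items[j],
        p_forward = B[i, j], p_backward = 0,
        class = "between-slice", strength = B[i, j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), from = character(0), to = character(0),
               p_forward = numeric(0), p_backward = numeric(0),
               class = character(0), strength = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(edges = out, items = items,
                 include_threshold = include_threshold,
                 direction_ratio = direction_ratio),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat(sprintf("<consensus_graph> %d nodes, %d connections (threshold %.2f)\n",
              length(x$items), nrow(x$edges), x$include_threshold))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Plot the grid of per-pair effect distributions
#'
#' One cell per (source at T, target at T+1) pair: a density sketch of the
#' effect draws, a zero reference line, colour fill when the credible
#' interval excludes zero, and the posterior mean annotated (the same
#' number exported by [as.data.frame.effect_distribution()]).  The display
#' is truncated to `display_range`.
#'
#' @param effects an [effect_distribution()].
#' @param display_range x-axis limits of every cell.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param fill fill colour for significant cells.
#' @return The per-pair summary data frame, invisibly.
#' @export
plot_effect_grid <- function(effects, display_range = c(-0.1, 0.5),
                             file = NULL, fill = "#9ecae1") {
  stopifnot(inherits(effects, "effect_distribution"))
  n <- length(effects$items)
  if (!is.null(file)) {
    grDevices::png(file, width = 160 * n + 120, height = 160 * n + 120,
                   res = 96)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(n, n), mar = c(1.2, 1.2, 1.6, 0.4),
                      oma = c(2, 3, 3, 1))
  # restore par before any device teardown registered above
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    x <- effects$draws[s, t, ]
    xr <- display_range
    if (length(unique(x)) > 1L) {
      d <- stats::density(x, from = xr[1], to = xr[2])
      graphics::plot(d, main = "", xlab = "", ylab = "", xlim = xr, axes = FALSE,
                     col = NA)
      if (effects$significant[s, t])
        graphics::polygon(c(d$x, rev(d$x)), c(d$y, rep(0, length(d$y))),
                          col = fill, border = NA)
      graphics::lines(d, col = "grey30")
    } else {
      graphics::plot(NA, xlim = xr, ylim = c(0, 1), main = "", xlab = "",
                     ylab = "", axes = FALSE)
      graphics::segments(x[1], 0, x[1], 1, lwd = 2,
                         col = if (effects$significant[s, t]) fill else "grey30")
    }
    graphics::abline(v = 0, col = "red")
    graphics::box(col = "grey70")
    graphics::mtext(sprintf("%.2f", effects$mean[s, t]), side = 3, line = 0.1,
                    cex = 0.55)
    if (t == 1L) graphics::mtext(effects$items[s], side = 2, line = 0.4,
                                 cex = 0.5)
    if (s == 1L) graphics::mtext(effects$items[t], side = 3, line = 1.0,
                                 cex = 0.5)
  }
  graphics::mtext("effect of row variable at T on column variable at T+1",
                  outer = TRUE, side = 1, line = 0.5, cex = 0.7)
  invisible(as.data.frame(effects))
}

#' Plot the consensus DAG
#'
#' Within-slice connections are drawn solid (double-headed when the
#' direction is unresolved), between-slice connections dashed from a node
#' to its next-slice copy; line width increases monotonically with the
#' connection's posterior strength.
#'
#' @param graph a [build_consensus()] result.
#' @param file optional PNG path.
#' @return The edge data frame, invisibly.
#' @export
plot_consensus_dag <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "consensus_graph"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 96)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ed <- graph$edges
  g <- igraph::make_empty_graph(n = length(graph$items), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$items)
  if (nrow(ed)) {
    for (r in seq_len(nrow(ed)))
      g <- igraph::add_edges(g, c(ed$from[r], ed$to[r]))
    lty <- ifelse(ed$type == "between", 2L, 1L)
    amode <- ifelse(ed$class == "double-headed", 3L, 2L)
    width <- 0.5 + 4 * ed$strength
    curved <- ifelse(ed$from == ed$to, 1.5, 0.15)
  } else {
    lty <- amode <- width <- curved <- numeric(0)
  }
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    edge.lty = lty, edge.arrow.mode = amode, edge.width = width,
    edge.curved = curved, edge.arrow.size = 0.5,
    vertex.size = 26, vertex.color = "white", vertex.frame.color = "grey40",
    vertex.label.color = "black", vertex.label.cex = 0.8)
  graphics::legend("bottomleft", lty = c(1, 2), bty = "n", cex = 0.8,
                   legend = c("within-slice", "between-slice (T to T+1)"))
  invisible(ed)
}

#' Write a consensus graph as DOT and GraphML
#' @param graph a [build_consensus()] result.
#' @param dot_path,graphml_path output files (either may be `NULL`).
#' @return `graph`, invisibly.
#' @export
write_consensus <- function(graph, dot_path = NULL, graphml_path = NULL) {
  ed <- graph$edges
  if (!is.null(dot_path)) {
    lines <- c("digraph consensus {",
               sprintf("  \"%s\";", graph$items),
               if (nrow(ed)) sprintf(
                 "  \"%s\" -> \"%s\" [posterior=%.4f, class=\"%s\", style=%s%s];",
                 ed$from, ed$to, ed$strength, ed$class,
                 ifelse(ed$type == "between", "dashed", "solid"),
                 ifelse(ed$class == "double-headed", ", dir=both", "")),
               "}")
    writeLines(lines, dot_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::make_empty_graph(n = length(graph$items), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = graph$items)
    if (nrow(ed)) {
      for (r in seq_len(nrow(ed)))
        g <- igraph::add_edges(g, c(ed$from[r], ed$to[r]))
      g <- igraph::set_edge_attr(g, "posterior", value = ed$strength)
      g <- igraph::set_edge_attr(g, "class", value = ed$class)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(graph)
}
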