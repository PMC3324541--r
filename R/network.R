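#' Build the directed gene-predictivity network
#'
#' One edge per (input gene, target gene) pair across all fitted models,
#' pointing from the predictive input to the predicted target. The edge
#' `rank` is the iteration at which the input was selected (rank 1 = most
#' predictive); its display colour cycles red, blue, green, orange, black.
#' A gene's indegree is the number of inputs in its own model; its
#' outdegree the number of models it serves as input for.
#'
#' @param fit An `isvm_fit` (or named list of `isvm_model`s).
#' @param panel Optional [gene_panel()]; defaults to the panel stored in
#'   `fit`. Determines the node set (isolated genes are kept as nodes).
#' @return An object of class `predictive_network`: list with `nodes`
#'   (character), `edges` (tibble: `from`, `to`, `rank`, `color`) and
#'   `degrees` (tibble: `gene`, `indegree`, `outdegree`).
#' @export
build_network <- function(fit, panel = NULL) {
  if (is.null(panel)) panel <- attr(fit, "panel")
  rows <- list()
  for (model in unclass(fit)) {
    if (length(model$selected) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      from = model$selected_genes,
      to = model$target_gene,
      rank = seq_along(model$selected)
    )
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    from = character(), to = character(), rank = integer()
  )
  edges$color <- rank_color(edges$rank)
  nodes <- if (!is.null(panel)) panel$gene else sort(unique(c(edges$from,
                                                              edges$to)))
  degrees <- tibble::tibble(
    gene = nodes,
    indegree = vapply(nodes, function(g) sum(edges$to == g), integer(1),
                      USE.NAMES = FALSE),
    outdegree = vapply(nodes, function(g) sum(edges$from == g), integer(1),
                       USE.NAMES = FALSE)
  )
  structure(list(nodes = nodes, edges = edges, degrees = degrees),
            class = "predictive_network")
}

# Selection-iteration colour map; ranks beyond 5 cycle (the integer rank
# attribute stays authoritative).
rank_color <- function(rank) {
  palette <- c("red", "blue", "green", "orange", "black")
  palette[(as.integer(rank) - 1L) %% 5L + 1L]
}

#' @export
print.predictive_network <- function(x, ...) {
  cat("<predictive_network> ", length(x$nodes), " genes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param x A `predictive_network`.
#' @param ... Unused.
#' @method tidy predictive_network
#' @export
tidy.predictive_network <- function(x, ...) x$edges

#' @rdname build_network
#' @method glance predictive_network
#' @export
glance.predictive_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    max_rank = if (nrow(x$edges)) max(x$edges$rank) else 0L,
    max_indegree = max(c(0L, x$degrees$indegree)),
    max_outdegree = max(c(0L, x$degrees$outdegree))
  )
}

#' Node degree table
#'
#' @param net A `predictive_network`.
#' @return Tibble (`gene`, `indegree`, `outdegree`).
#' @export
degree_table <- function(net) net$degrees

#' Export the network for graph tools
#'
#' `sif` writes Cytoscape simple-interaction lines
#' (`source predicts target`); `graphml` (via igraph) and `dot` carry the
#' `rank` and `color` edge attributes.
#'
#' @param net A `predictive_network`.
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "dot")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    lines <- sprintf("%s\tpredicts\t%s", e$from, e$to)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
    lines <- c(
      "digraph predictive_network {",
      paste0("  ", q(net$nodes), ";"),
      sprintf("  %s -> %s [rank=%d, color=%s];",
              q(e$from), q(e$to), e$rank, q(e$color)),
      "}"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Convert a predictive network to an igraph graph
#'
#' @param net A `predictive_network`.
#' @return A directed igraph object with `rank` and `color` edge
#'   attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Plot node degrees of the predictivity network
#'
#' Side-by-side indegree/outdegree bars per gene.
#'
#' @param object A `predictive_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot predictive_network
#' @export
autoplot.predictive_network <- function(object, ...) {
  long <- tidyr::pivot_longer(object$degrees, c("indegree", "outdegree"),
                              names_to = "direction", values_to = "degree")
  long$gene <- factor(long$gene, levels = object$degrees$gene)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$degree,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "degree", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
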