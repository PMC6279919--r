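# Phase-annotated Spearman co-expression networks over rhythmic gene sets.

#' Build a Spearman co-expression network
#'
#' Computes Spearman's rank correlation for every pair of the requested
#' genes (average ranks on ties) and keeps an undirected edge where the
#' signed coefficient is at least `rho_min`. Each node carries its phase
#' call. Constant profiles have undefined correlations: their nodes are
#' kept but their edges skipped, with a warning. Pairwise correlations are
#' computed in column blocks so memory stays proportional to
#' `block_size^2` rather than the full gene count squared.
#'
#' @param expr A diel expression tibble (at least 3 time points).
#' @param genes Genes to network (default: all genes in `expr`).
#' @param rho_min Minimum signed Spearman correlation for an edge.
#' @param phases Optional tibble with `gene_id`, `phase_call_h`; by default
#'   phases are computed from `expr` with [phase_call()].
#' @param block_size Genes per correlation block.
#' @return A `diel_gcn` object with `nodes` (`gene_id`, `phase_call_h`) and
#'   `edges` (`gene_a`, `gene_b`, `rho`) tibbles; see [tidy.diel_gcn()].
#' @examples
#' sim <- simulate_diel_matrix(10, 1, noise_frac = 0, seed = 1)
#' net <- build_gcn(sim$expr)
#' glance(net)
#' @export
build_gcn <- function(expr, genes = NULL, rho_min = 0.8, phases = NULL,
                      block_size = 1000L) {
  check_expr(expr)
  grid <- diel_grid(expr)
  if (length(grid) < 3L) {
    rlang::abort("at least 3 time points are required for rank correlation.")
  }
  genes <- genes %||% expr$gene_id
  miss <- setdiff(genes, expr$gene_id)
  if (length(miss) > 0L) {
    rlang::abort(sprintf("gene(s) not in the matrix: %s",
                         paste(utils::head(miss, 5L), collapse = ", ")))
  }
  m <- expr_values(expr)[match(genes, expr$gene_id), , drop = FALSE]

  constant <- apply(m, 1L, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    rlang::warn(sprintf(
      "%d constant gene(s) kept as nodes without edges: %s",
      sum(constant), paste(utils::head(genes[constant], 5L), collapse = ", ")
    ))
  }

  if (is.null(phases)) {
    ph <- apply(m, 1L, phase_call, grid = grid)
  } else {
    ph <- stats::setNames(phases$phase_call_h, phases$gene_id)[genes]
  }
  nodes <- tibble::tibble(gene_id = genes, phase_call_h = unname(ph))

  # rank-transform once; Pearson on ranks = Spearman
  rk <- t(apply(m, 1L, rank, ties.method = "average"))
  n <- nrow(rk)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  edges <- list()
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      ii <- blocks[[bi]]; jj <- blocks[[bj]]
      rho <- suppressWarnings(stats::cor(t(rk[ii, , drop = FALSE]),
                                         t(rk[jj, , drop = FALSE])))
      hit <- which(!is.na(rho) & rho >= rho_min, arr.ind = TRUE)
      if (bi == bj) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) > 0L) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          gene_a = genes[ii[hit[, 1]]],
          gene_b = genes[jj[hit[, 2]]],
          rho = rho[hit]
        )
      }
    }
  }
  edges <- if (length(edges) > 0L) dplyr::bind_rows(edges) else {
    tibble::tibble(gene_a = character(), gene_b = character(), rho = numeric())
  }
  structure(list(nodes = nodes, edges = edges, rho_min = rho_min),
            class = "diel_gcn")
}

#' @export
print.diel_gcn <- function(x, ...) {
  cat(sprintf("<diel_gcn> %d nodes, %d edges (Spearman rho >= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$rho_min))
  invisible(x)
}

#' Tidy a co-expression network
#'
#' @param x A `diel_gcn` object.
#' @param ... Unused.
#' @return The edge tibble (`gene_a`, `gene_b`, `rho`).
#' @method tidy diel_gcn
#' @export
tidy.diel_gcn <- function(x, ...) x$edges

#' Summarise a co-expression network
#'
#' @inheritParams tidy.diel_gcn
#' @return One-row tibble with node count, edge count, and the cutoff.
#' @method glance diel_gcn
#' @export
glance.diel_gcn <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 rho_min = x$rho_min)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges,
    directed = FALSE,
    vertices = data.frame(name = net$nodes$gene_id,
                          phase_call_h = net$nodes$phase_call_h)
  )
}

#' Export / import a co-expression network
#'
#' `"edge_list"` writes two TSVs: the edges at `path` and the nodes (with
#' phase annotations) at `<path>.nodes.tsv`, so the round trip is lossless
#' including isolated nodes. `"graphml"` writes a single GraphML file with
#' the phase as a node attribute and rho as an edge attribute.
#'
#' @param net A `diel_gcn` object.
#' @param path Output path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `export_network()` returns `path` invisibly; `read_network()`
#'   returns a `diel_gcn`.
#' @export
export_network <- function(net, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    readr::write_tsv(net$edges, path, progress = FALSE)
    readr::write_tsv(net$nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @param rho_min Cutoff recorded on the re-imported network.
#' @export
read_network <- function(path, format = c("edge_list", "graphml"),
                         rho_min = 0.8) {
  format <- match.arg(format)
  if (format == "edge_list") {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      gene_id = igraph::vertex_attr(g, "name"),
      phase_call_h = igraph::vertex_attr(g, "phase_call_h")
    )
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(gene_a = el$from, gene_b = el$to,
                            rho = el$rho %||% numeric(nrow(el)))
  }
  structure(list(nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges), rho_min = rho_min),
            class = "diel_gcn")
}

#' Circular phase-coloured plot of a co-expression network
#'
#' @param object A `diel_gcn` object.
#' @param max_edges At most this many edges are drawn (sampled
#'   deterministically by rank of rho) to keep the figure readable.
#' @param ... Unused.
#' @return A ggplot with nodes on a circle ordered by phase call and
#'   coloured by phase.
#' @method autoplot diel_gcn
#' @export
autoplot.diel_gcn <- function(object, max_edges = 2000L, ...) {
  nodes <- object$nodes
  ord <- order(nodes$phase_call_h, nodes$gene_id)
  nodes <- nodes[ord, ]
  theta <- 2 * pi * (seq_len(nrow(nodes)) - 1L) / max(1L, nrow(nodes))
  nodes$x <- cos(theta)
  nodes$y <- sin(theta)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(object$edges) > 0L) {
    ed <- object$edges[order(-object$edges$rho), ]
    ed <- ed[seq_len(min(nrow(ed), max_edges)), ]
    ed <- dplyr::left_join(ed, nodes[, c("gene_id", "x", "y")],
                           by = c(gene_a = "gene_id"))
    ed <- dplyr::left_join(ed, nodes[, c("gene_id", "x", "y")],
                           by = c(gene_b = "gene_id"), suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_b, yend = .data$y_b),
      linewidth = 0.1, alpha = 0.2, colour = "grey60"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase_call_h), size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = "phase (h)") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
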