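#' Hub-centred module network
#'
#' Builds the node set of a module's hub graph: all DE proteins assigned to
#' the module, plus the `top_k` proteins most strongly connected to the hub
#' by adjacency (regardless of DE status). Nodes carry their DE-group tag
#' (`upregulated_ad`, `stepwise`, `unique`) or `background`. Edges keep
#' adjacency values at or above `edge_floor` (a quantile of the within-node
#' adjacency; 0 keeps the complete graph, matching the construction where
#' edge length is inversely proportional to adjacency); the hub stays
#' directly connected to every node.
#'
#' @param module module label (colour name).
#' @param assignment a `module_assignment`.
#' @param eigen an `eigenprotein_set` (for the hub protein).
#' @param adjacency signed adjacency matrix (dimnames = protein ids).
#' @param de_groups a `de_groups` from [venn_trichotomy] (or NULL).
#' @param top_k number of hub-correlated proteins to include.
#' @param edge_floor_quantile quantile of within-node-set adjacency below
#'   which edges are dropped (0 keeps all).
#' @return object of class `hub_network`: `module`, `hub`, `nodes`
#'   (data.frame id/group), `edges` (data.frame from/to/weight).
#' @export
hub_network <- function(module, assignment, eigen, adjacency, de_groups = NULL,
                        top_k = 30, edge_floor_quantile = 0) {
  labels <- assignment$module
  if (!module %in% labels) stop("unknown module: ", module)
  prot <- colnames(adjacency)
  if (is.null(prot)) stop("adjacency must carry protein dimnames")
  hub <- eigen$hubs[[module]]
  members <- names(labels)[labels == module]
  de_all <- if (is.null(de_groups)) character(0)
  else unlist(de_groups, use.names = FALSE)
  de_in_module <- intersect(members, de_all)
  hub_adj <- adjacency[hub, setdiff(prot, hub)]
  top <- if (top_k > 0) names(sort(hub_adj, decreasing = TRUE))[seq_len(min(top_k, length(hub_adj)))]
  else character(0)
  ids <- unique(c(hub, de_in_module, top))
  tag <- function(id) {
    if (!is.null(de_groups)) {
      if (id %in% de_groups$stepwise) return("stepwise")
      if (id %in% de_groups$unique) return("unique")
      if (id %in% de_groups$upregulated_ad) return("upregulated_ad")
    }
    "background"
  }
  nodes <- data.frame(id = ids,
                      group = vapply(ids, tag, character(1)),
                      is_hub = ids == hub, row.names = NULL)
  sub <- adjacency[ids, ids, drop = FALSE]
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                      weight = sub[pairs], row.names = NULL)
  if (edge_floor_quantile > 0 && nrow(edges)) {
    floor_val <- quantile(edges$weight, edge_floor_quantile)
    keep <- edges$weight >= floor_val | edges$from == hub | edges$to == hub
    edges <- edges[keep, , drop = FALSE]
  }
  structure(list(module = module, hub = hub, nodes = nodes, edges = edges),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("hub network '%s': hub %s, %d nodes, %d edges\n",
              x$module, x$hub, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a hub network to GraphML or an edge list
#'
#' Lossless serialisation of nodes (id, DE-group tag, hub flag) and weighted
#' edges; GraphML via igraph, edge list as TSV (with a node table alongside).
#'
#' @param net a `hub_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back an exported GraphML hub network
#'
#' @param path GraphML file written by [export_graph].
#' @return list with `nodes` and `edges` data.frames.
#' @export
import_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  names(nodes)[names(nodes) == "name"] <- "id"
  list(nodes = nodes, edges = edges)
}
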