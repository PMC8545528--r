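#' Typed ceRNA/PPI graphs
#'
#' A typed graph is an undirected [igraph::igraph] in which every node carries
#' a `type` label (`lncRNA`, `diabetes`, `DR`, `common` or `other`) and every
#' edge carries a `kind` (`ppi` or `cerna`). ceRNA edges additionally carry the
#' comma-joined ids of the miRNAs shared by the lncRNA and its coding partner.
#' The graph is simple per kind: no self-loops and no duplicated
#' (node pair, kind) edges, although the same pair may be connected by one
#' `ppi` and one `cerna` edge at once.
#'
#' @param nodes A data frame with columns `id` (character) and `type`
#'   (one of `lncRNA`, `diabetes`, `DR`, `common`, `other`).
#' @param edges A data frame with columns `from`, `to`, `kind` and optionally
#'   `shared_mirnas` (comma-joined miRNA ids, empty for `ppi` edges).
#' @return An igraph object of class `c("typed_graph", "igraph")`.
#' @examples
#' g <- typed_graph(
#'   nodes = tibble::tibble(id = c("G1", "G2", "L1"),
#'                          type = c("common", "other", "lncRNA")),
#'   edges = tibble::tibble(from = c("G1", "L1"), to = c("G2", "G1"),
#'                          kind = c("ppi", "cerna"),
#'                          shared_mirnas = c("", "miR-1"))
#' )
#' tg_nodes(g)
#' @export
typed_graph <- function(nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("id", "type") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    abort("duplicate node ids", class = "cernet_invalid_graph")
  }
  bad <- setdiff(unique(nodes$type), NODE_TYPES)
  if (length(bad) > 0) {
    abort(sprintf("unknown node type(s): %s", paste(bad, collapse = ", ")),
          class = "cernet_invalid_graph")
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(),
                    kind = character(), shared_mirnas = character())
  }
  edges <- as_tibble(edges)
  if (!"shared_mirnas" %in% names(edges)) edges$shared_mirnas <- ""
  edges$shared_mirnas[is.na(edges$shared_mirnas)] <- ""
  edges <- mutate(edges, from = as.character(.data$from),
                  to = as.character(.data$to))
  if (any(edges$from == edges$to)) {
    abort("self-loops are not allowed", class = "cernet_invalid_graph")
  }
  if (!all(edges$kind %in% EDGE_KINDS)) {
    abort("edge kind must be 'ppi' or 'cerna'", class = "cernet_invalid_graph")
  }
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing) > 0) {
    abort(sprintf("edges reference unknown nodes: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "cernet_invalid_graph")
  }
  # canonical order within a pair, then dedupe on (pair, kind)
  key_a <- pmin(edges$from, edges$to)
  key_b <- pmax(edges$from, edges$to)
  edges <- edges[!duplicated(paste(key_a, key_b, edges$kind)), , drop = FALSE]

  type_of <- setNames(nodes$type, nodes$id)
  cer <- filter(edges, .data$kind == "cerna")
  if (nrow(cer) > 0) {
    n_lnc <- (type_of[cer$from] == "lncRNA") + (type_of[cer$to] == "lncRNA")
    if (any(n_lnc != 1)) {
      abort("every cerna edge must join exactly one lncRNA and one non-lncRNA node",
            class = "cernet_invalid_graph")
    }
    if (any(cer$shared_mirnas == "")) {
      abort("cerna edges must carry at least one shared miRNA",
            class = "cernet_invalid_graph")
    }
  }

  g <- igraph::graph_from_data_frame(
    d = edges[, c("from", "to", "kind", "shared_mirnas")],
    directed = FALSE,
    vertices = nodes[, c("id", "type")]
  )
  class(g) <- c("typed_graph", class(g))
  g
}

#' Node and edge tables of a typed graph
#'
#' @param g A `typed_graph`.
#' @return `tg_nodes()`: a tibble with `id` and `type`. `tg_edges()`: a tibble
#'   with `from`, `to`, `kind`, `shared_mirnas`.
#' @export
tg_nodes <- function(g) {
  tibble(id = igraph::V(g)$name, type = igraph::V(g)$type)
}

#' @rdname tg_nodes
#' @export
tg_edges <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(tibble(from = character(), to = character(),
                  kind = character(), shared_mirnas = character()))
  }
  el <- igraph::as_edgelist(g)
  tibble(from = el[, 1], to = el[, 2],
         kind = igraph::E(g)$kind,
         shared_mirnas = igraph::E(g)$shared_mirnas %||% "")
}

#' @export
print.typed_graph <- function(x, ...) {
  nd <- tg_nodes(x)
  ed <- tg_edges(x)
  cat(sprintf("<typed_graph> %d nodes, %d edges\n",
              nrow(nd), nrow(ed)))
  tcount <- table(factor(nd$type, levels = NODE_TYPES))
  cat("  node types:",
      paste(sprintf("%s=%d", names(tcount), tcount), collapse = " "), "\n")
  kcount <- table(factor(ed$kind, levels = EDGE_KINDS))
  cat("  edge kinds:",
      paste(sprintf("%s=%d", names(kcount), kcount), collapse = " "), "\n")
  invisible(x)
}

#' Read and write typed graphs
#'
#' The TSV serialisation uses one file for edges (`node_a`, `node_b`, `kind`,
#' `shared_mirnas` comma-joined) and one for node labels (`id`, `type`).
#' GraphML output goes through [igraph::write_graph()].
#'
#' @param g A `typed_graph`.
#' @param edges_path,nodes_path Paths for the edge and node TSVs.
#' @return `write_typed_graph()` returns `g` invisibly; `read_typed_graph()`
#'   returns a `typed_graph`.
#' @export
write_typed_graph <- function(g, edges_path, nodes_path) {
  ed <- tg_edges(g)
  ed <- rename(ed, node_a = "from", node_b = "to")
  write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tg_nodes(g), nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(g)
}

#' @rdname write_typed_graph
#' @export
read_typed_graph <- function(edges_path, nodes_path) {
  ed <- as_tibble(read.delim(edges_path, colClasses = "character"))
  nd <- as_tibble(read.delim(nodes_path, colClasses = "character"))
  ed <- rename(ed, from = "node_a", to = "node_b")
  typed_graph(nd, ed)
}

#' @rdname write_typed_graph
#' @param path Path for GraphML output.
#' @export
write_typed_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' @rdname write_typed_graph
#' @export
read_typed_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  typed_graph(
    tibble(id = igraph::V(g)$name, type = igraph::V(g)$type),
    {
      el <- igraph::as_edgelist(g)
      tibble(from = el[, 1], to = el[, 2], kind = igraph::E(g)$kind,
             shared_mirnas = igraph::E(g)$shared_mirnas %||% "")
    }
  )
}

# Internal: rebuild the typed_graph class after igraph operations strip it.
as_typed_graph <- function(g) {
  if (!inherits(g, "typed_graph")) class(g) <- c("typed_graph", class(g))
  g
}
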