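#' Partition two disease gene lists into only/common sets
#'
#' Splits a diabetes gene list and a diabetic-retinopathy (DR) gene list into
#' three disjoint sets: genes unique to each disease and the common
#' intersection. Matching is exact, case-sensitive string equality unless
#' `normalize = TRUE`, which upper-cases ids first.
#'
#' @param diabetes,dr Character vectors of gene symbols.
#' @param normalize Upper-case ids before comparing (default `FALSE`).
#' @return A tibble with columns `id` and `set`
#'   (`diabetes_only`, `dr_only`, `common`).
#' @examples
#' intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D"))
#' @export
intersect_gene_sets <- function(diabetes, dr, normalize = FALSE) {
  diabetes <- unique(as.character(diabetes))
  dr <- unique(as.character(dr))
  if (normalize) {
    diabetes <- unique(toupper(diabetes))
    dr <- unique(toupper(dr))
  }
  common <- intersect(diabetes, dr)
  bind_rows(
    tibble(id = setdiff(diabetes, common), set = "diabetes_only"),
    tibble(id = setdiff(dr, common), set = "dr_only"),
    tibble(id = common, set = "common")
  )
}

#' Induce the disease subgraph of a PPI network
#'
#' Maps disease genes onto a PPI graph, labels them (`diabetes`, `DR`,
#' `common`) and returns the subgraph induced on the mapped genes. Genes
#' absent from the PPI are dropped and reported.
#'
#' @param ppi A `typed_graph` (node types are overwritten by the disease
#'   labels for mapped genes).
#' @param gene_sets A tibble as returned by [intersect_gene_sets()].
#' @return A list with `graph` (the induced `typed_graph`) and `dropped`
#'   (tibble of genes not found in the PPI). Emits a warning when no disease
#'   gene maps into the PPI.
#' @export
induce_disease_subgraph <- function(ppi, gene_sets) {
  gene_sets <- as_tibble(gene_sets)
  lab <- c(diabetes_only = "diabetes", dr_only = "DR", common = "common")
  gene_sets$type <- lab[gene_sets$set]
  present <- gene_sets$id %in% igraph::V(ppi)$name
  dropped <- gene_sets[!present, c("id", "set")]
  kept <- gene_sets[present, , drop = FALSE]
  if (nrow(kept) == 0) {
    warn("no disease gene maps into the PPI network; returning an empty graph")
    return(list(graph = typed_graph(tibble(id = character(),
                                           type = character())),
                dropped = dropped))
  }
  sub <- igraph::induced_subgraph(ppi, kept$id)
  igraph::V(sub)$type <- setNames(kept$type, kept$id)[igraph::V(sub)$name]
  list(graph = as_typed_graph(sub), dropped = dropped)
}

#' Largest connected component
#'
#' Returns the connected component with the most nodes. Ties are broken
#' deterministically: the component containing the lexicographically smallest
#' node id wins.
#'
#' @param g A `typed_graph`.
#' @return The component as a `typed_graph` (the empty graph maps to itself).
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0) return(g)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  as_typed_graph(igraph::induced_subgraph(g, comp$membership == best))
}

#' Integrate ceRNA regulations into a disease PPI graph
#'
#' Adds lncRNA nodes and `cerna` edges to a PPI-backed disease graph.
#' ceRNA edges whose coding gene is absent from the graph are dropped and
#' reported; lncRNA partners may be new nodes (added with type `lncRNA`).
#' An edge joining two lncRNAs is a validation error.
#'
#' @param g A `typed_graph` of coding genes.
#' @param cerna A tibble with columns `lncrna`, `gene`, `shared_mirnas`
#'   (comma-joined miRNA ids).
#' @return A list with `graph` (the integrated `typed_graph`) and `dropped`
#'   (tibble of ceRNA edges whose gene was absent).
#' @export
integrate_cerna <- function(g, cerna) {
  cerna <- as_tibble(cerna)
  stopifnot(all(c("lncrna", "gene", "shared_mirnas") %in% names(cerna)))
  nd <- tg_nodes(g)
  lnc_ids <- union(unique(cerna$lncrna), nd$id[nd$type == "lncRNA"])
  if (any(cerna$gene %in% lnc_ids)) {
    abort("cerna edge joins two lncRNAs", class = "cernet_invalid_graph")
  }
  present <- cerna$gene %in% nd$id
  dropped <- cerna[!present, , drop = FALSE]
  kept <- cerna[present, , drop = FALSE]
  new_lnc <- setdiff(unique(kept$lncrna), nd$id)
  nodes <- bind_rows(nd, tibble(id = new_lnc, type = "lncRNA"))
  edges <- bind_rows(
    tg_edges(g),
    tibble(from = kept$lncrna, to = kept$gene, kind = "cerna",
           shared_mirnas = kept$shared_mirnas)
  )
  list(graph = typed_graph(nodes, edges), dropped = dropped)
}

#' Build a typed ceRNA+PPI network end to end
#'
#' Convenience wrapper that runs the construction order used for
#' comprehensive lncRNA-mRNA networks: map disease genes into the PPI,
#' extract the largest component, then integrate ceRNA regulations.
#'
#' @inheritParams induce_disease_subgraph
#' @inheritParams integrate_cerna
#' @return A list with `graph`, `dropped_genes` and `dropped_cerna`.
#' @export
build_network <- function(ppi, gene_sets, cerna) {
  ind <- induce_disease_subgraph(ppi, gene_sets)
  lc <- largest_component(ind$graph)
  integ <- integrate_cerna(lc, cerna)
  list(graph = integ$graph,
       dropped_genes = ind$dropped,
       dropped_cerna = integ$dropped)
}
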