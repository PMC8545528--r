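#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @param source Optional source label stored on every set (e.g. `"GO"`,
#'   `"KEGG"`); defaults to the file name.
#' @return A tibble with columns `set`, `source`, `genes` (list-column).
#' @export
read_gmt <- function(path, source = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(sets)) {
    abort("duplicate set names in GMT", class = "cernet_invalid_input")
  }
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(lengths(genes) == 0)) {
    abort("empty gene set in GMT", class = "cernet_invalid_input")
  }
  tibble(set = sets, source = source %||% basename(path), genes = genes)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set[i], collection$source[i] %||% "na",
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the observed
#' overlap when `|query|` genes are sampled from the universe without
#' replacement and `|geneset|` of the universe genes are marked.
#'
#' @param query,geneset,universe Character vectors of gene ids; `query` and
#'   `geneset` must be subsets of `universe`.
#' @return A single p-value in (0, 1].
#' @examples
#' hypergeom_overrep(c("a", "b", "c"), c("a", "b", "c", "d"), letters[1:10])
#' # 4/120
#' @export
hypergeom_overrep <- function(query, geneset, universe) {
  query <- unique(query); geneset <- unique(geneset)
  universe <- unique(universe)
  if (length(setdiff(query, universe)) > 0) {
    abort("query contains genes outside the universe",
          class = "cernet_invalid_input")
  }
  if (length(setdiff(geneset, universe)) > 0) {
    abort("geneset contains genes outside the universe",
          class = "cernet_invalid_input")
  }
  k <- length(intersect(query, geneset))
  if (length(query) == 0 || k == 0) return(1)
  phyper(k - 1, length(geneset), length(universe) - length(geneset),
         length(query), lower.tail = FALSE)
}

#' Over-representation analysis of a query gene set
#'
#' Tests the query against every set in the collection with the upper-tail
#' hypergeometric test and applies Benjamini-Hochberg correction across all
#' sets of the collection. By default the universe is the union of all
#' collection genes; pass the analysed graph's coding genes to use the
#' documented graph-aware background. lncRNA ids are excluded from the query
#' when a graph is supplied via `exclude`.
#'
#' @param query Character vector of gene ids.
#' @param collection A tibble from [read_gmt()].
#' @param universe Optional character vector of background gene ids; defaults
#'   to the union of collection genes (plus the query).
#' @param exclude Optional ids to remove from the query (e.g. lncRNAs).
#' @return A tibble with one row per set: `set`, `source`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `p_adjust`,
#'   sorted by `p_adjust` then set name.
#' @export
enrich <- function(query, collection, universe = NULL, exclude = NULL) {
  if (nrow(collection) == 0) {
    return(tibble(set = character(), source = character(),
                  overlap = integer(), set_size = integer(),
                  query_size = integer(), universe_size = integer(),
                  p_value = numeric(), p_adjust = numeric()))
  }
  query <- unique(as.character(query))
  if (!is.null(exclude)) query <- setdiff(query, exclude)
  if (is.null(universe)) {
    universe <- union(unique(unlist(collection$genes)), query)
  }
  universe <- unique(universe)
  query <- intersect(query, universe)
  rows <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    gs <- intersect(collection$genes[[i]], universe)
    tibble(set = collection$set[i],
           source = collection$source[i] %||% NA_character_,
           overlap = length(intersect(query, gs)),
           set_size = length(gs),
           query_size = length(query),
           universe_size = length(universe),
           p_value = hypergeom_overrep(query, gs, universe))
  })
  rows$p_adjust <- p.adjust(rows$p_value, method = "BH")
  arrange(rows, .data$p_adjust, .data$set)
}
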