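#' MCODE parameters
#'
#' Parameter bundle for [predict_complexes()]. Defaults are the classic
#' molecular-complex-detection settings: K-core 2, node score cutoff 0.2,
#' maximum expansion depth 100, haircut on, fluff off.
#'
#' @param k_core Minimum core number a complex must retain (>= 2).
#' @param node_score_cutoff Expansion admits a neighbour `v` iff
#'   `w(v) > w(seed) * (1 - node_score_cutoff)`; in \[0, 1\].
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @param haircut Iteratively remove members with exactly one within-complex
#'   edge.
#' @param fluff Add neighbours whose closed-neighbourhood density exceeds
#'   `fluff_density` after the core expansion.
#' @param fluff_density Density threshold for fluff.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(k_core = 2L, node_score_cutoff = 0.2,
                         max_depth = 100L, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.1) {
  chk_count(k_core, "k_core", min = 2L)
  chk_count(max_depth, "max_depth", min = 1L)
  if (!is.numeric(node_score_cutoff) || node_score_cutoff < 0 ||
      node_score_cutoff > 1) {
    abort("`node_score_cutoff` must be in [0, 1]",
          class = "cernet_invalid_config")
  }
  structure(list(k_core = as.integer(k_core),
                 node_score_cutoff = node_score_cutoff,
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density),
            class = "mcode_params")
}

# Adjacency sets (integer indices) of the simplified graph.
adj_sets <- function(g) {
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  lapply(igraph::adjacent_vertices(gs, igraph::V(gs)), as.integer)
}

# Core numbers by iterative minimum-degree peeling on an adjacency-set list.
peel_cores <- function(adj) {
  n <- length(adj)
  deg <- lengths(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  for (i in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    nb <- adj[[v]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
  }
  core
}

#' k-core decomposition
#'
#' The core number of a node is the largest `k` such that the node belongs to
#' a maximal subgraph of minimum degree `k`. Computed by iterative
#' minimum-degree peeling on the simplified graph.
#'
#' @param g A `typed_graph`.
#' @return A named integer vector of core numbers.
#' @examples
#' g <- typed_graph(tibble::tibble(id = LETTERS[1:3], type = "other"),
#'                  tibble::tibble(from = c("A", "B"), to = c("B", "C"),
#'                                 kind = "ppi"))
#' k_core_decomposition(g)  # a path: all cores 1
#' @export
k_core_decomposition <- function(g) {
  adj <- adj_sets(g)
  setNames(peel_cores(adj), igraph::V(g)$name)
}

# Density 2E/(V(V-1)) of the subgraph induced on `idx` (indices), given
# adjacency sets of the parent graph.
sub_density <- function(adj, idx) {
  v <- length(idx)
  if (v < 2) return(0)
  in_set <- logical(length(adj))
  in_set[idx] <- TRUE
  e <- sum(vapply(idx, function(i) sum(in_set[adj[[i]]]), numeric(1))) / 2
  2 * e / (v * (v - 1))
}

# Adjacency sets restricted to `idx`, re-indexed 1..length(idx).
sub_adj <- function(adj, idx) {
  map <- integer(length(adj))
  map[idx] <- seq_along(idx)
  lapply(idx, function(i) {
    nb <- adj[[i]]
    map[nb[map[nb] > 0L]]
  })
}

#' MCODE vertex weights
#'
#' The weight of node `v` is `k_max * density` of the highest-k-core subgraph
#' of `v`'s closed neighbourhood, where `k_max` is the maximum core number in
#' that neighbourhood and density is `2E / (V (V - 1))`. Degree-0 nodes weigh
#' 0.
#'
#' @param g A `typed_graph`.
#' @return A named numeric vector of weights.
#' @export
vertex_weights <- function(g) {
  adj <- adj_sets(g)
  w <- vapply(seq_along(adj), function(v) {
    nv <- c(v, adj[[v]])
    if (length(nv) < 2) return(0)
    sadj <- sub_adj(adj, nv)
    cores <- peel_cores(sadj)
    kmax <- max(cores)
    if (kmax == 0L) return(0)
    hk <- nv[cores == kmax]
    kmax * sub_density(adj, hk)
  }, numeric(1))
  setNames(w, igraph::V(g)$name)
}

# Iterated haircut: drop members with exactly one within-complex edge.
haircut_members <- function(adj, members) {
  repeat {
    in_set <- logical(length(adj))
    in_set[members] <- TRUE
    indeg <- vapply(members, function(i) sum(in_set[adj[[i]]]), numeric(1))
    drop <- members[indeg == 1]
    if (length(drop) == 0) break
    members <- setdiff(members, drop)
  }
  members
}

#' Detect dense complexes (MCODE-style)
#'
#' Seeds are taken in descending vertex-weight order among unvisited nodes
#' (ties by node id). From each seed, breadth-first expansion up to
#' `max_depth` admits a neighbour `v` iff
#' `w(v) > w(seed) * (1 - node_score_cutoff)` and `v` has not been claimed by
#' an earlier complex. The haircut post-process iteratively removes members
#' with exactly one within-complex edge; complexes whose induced minimum core
#' number is below `k_core` are discarded. The complex score is the induced
#' density times the member count.
#'
#' @param g A `typed_graph`.
#' @param params An [mcode_params()] bundle.
#' @return A tibble of class `mcode_result`, one row per complex, ranked by
#'   score: columns `module`, `seed`, `n_members`, `density`, `score`,
#'   `members` (list-column of node ids).
#' @export
predict_complexes <- function(g, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  ids <- igraph::V(g)$name
  n <- length(ids)
  if (n == 0) {
    return(empty_mcode_result())
  }
  adj <- adj_sets(g)
  w <- unname(vertex_weights(g))
  order_seeds <- order(-w, ids)
  visited <- logical(n)
  out <- list()
  for (seed in order_seeds) {
    if (visited[seed]) next
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0 && depth < params$max_depth) {
      cand <- unique(unlist(adj[frontier]))
      cand <- cand[!visited[cand] & w[cand] > thr]
      if (length(cand) == 0) break
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    if (params$fluff) {
      cand <- setdiff(unique(unlist(adj[members])), members)
      cand <- cand[!visited[cand]]
      keep <- cand[vapply(cand, function(v) {
        sub_density(adj, c(v, adj[[v]])) > params$fluff_density
      }, logical(1))]
      visited[keep] <- TRUE
      members <- c(members, keep)
    }
    if (params$haircut) members <- haircut_members(adj, members)
    if (length(members) < 2) next
    cores <- peel_cores(sub_adj(adj, members))
    if (min(cores) < params$k_core) next
    dens <- sub_density(adj, members)
    out[[length(out) + 1]] <- tibble(
      seed = ids[seed],
      n_members = length(members),
      density = dens,
      score = dens * length(members),
      members = list(sort(ids[members]))
    )
  }
  if (length(out) == 0) return(empty_mcode_result())
  res <- bind_rows(out)
  res <- rank_modules(res, top_n = nrow(res))
  res
}

empty_mcode_result <- function() {
  structure(
    tibble(module = integer(), seed = character(), n_members = integer(),
           density = numeric(), score = numeric(), members = list()),
    class = c("mcode_result", class(tibble())))
}

#' Rank detected modules
#'
#' Orders complexes by score descending, ties broken by size descending then
#' by smallest member id, and keeps the top `top_n` (default 5).
#'
#' @param modules An `mcode_result` tibble (or compatible data frame).
#' @param top_n How many modules to keep.
#' @return An `mcode_result` tibble with a refreshed `module` rank column.
#' @export
rank_modules <- function(modules, top_n = 5) {
  if (nrow(modules) == 0 || top_n < 1) return(empty_mcode_result())
  first_member <- vapply(modules$members, function(m) min(m), character(1))
  ord <- order(-modules$score, -modules$n_members, first_member)
  res <- modules[head(ord, top_n), , drop = FALSE]
  res$module <- seq_len(nrow(res))
  res <- select(res, "module", "seed", "n_members", "density", "score",
                "members")
  structure(res, class = c("mcode_result", class(tibble())))
}

#' @method tidy mcode_result
#' @export
tidy.mcode_result <- function(x, ...) {
  tidyr::unnest(select(x, "module", "score", "members"), "members") |>
    rename(id = "members")
}

#' @method glance mcode_result
#' @export
glance.mcode_result <- function(x, ...) {
  tibble(n_modules = nrow(x),
         top_score = if (nrow(x) > 0) max(x$score) else NA_real_,
         total_members = sum(x$n_members))
}
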