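# Small graph builders and independent brute-force oracles shared by the
# suite. The oracles enumerate explicitly and never call the code paths they
# check.

# Build a typed_graph from a flat vector of edge endpoints:
# tg("A","B", "B","C") is the path A-B-C. Extra isolated nodes via `nodes`.
tg <- function(..., nodes = NULL, type = "other") {
  ep <- c(...)
  stopifnot(length(ep) %% 2 == 0)
  from <- ep[seq(1, length(ep), by = 2)]
  to <- ep[seq(2, length(ep), by = 2)]
  ids <- sort(unique(c(from, to, nodes)))
  typed_graph(tibble::tibble(id = ids, type = type),
              tibble::tibble(from = from, to = to, kind = "ppi"))
}

tg_complete <- function(ids) {
  pr <- utils::combn(ids, 2)
  typed_graph(tibble::tibble(id = ids, type = "other"),
              tibble::tibble(from = pr[1, ], to = pr[2, ], kind = "ppi"))
}

# Adjacency list (integer indices) of a typed_graph, parallel edges merged.
adj_of <- function(g) {
  gs <- igraph::simplify(g)
  lapply(igraph::adjacent_vertices(gs, igraph::V(gs)), as.integer)
}

# ---- betweenness oracle: explicit enumeration of all shortest paths -------

enumerate_paths <- function(adj, dist, t) {
  # all shortest paths ending in t, walking predecessors backwards
  if (dist[t] == 0) return(list(t))
  preds <- adj[[t]][dist[adj[[t]]] == dist[t] - 1L]
  out <- list()
  for (p in preds) {
    for (sub in enumerate_paths(adj, dist, p)) {
      out[[length(out) + 1]] <- c(sub, t)
    }
  }
  out
}

oracle_betweenness <- function(g) {
  adj <- adj_of(g)
  n <- length(adj)
  ids <- igraph::V(g)$name
  raw <- stats::setNames(numeric(n), ids)
  if (n < 3) return(raw)
  for (s in 1:(n - 1)) {
    # BFS distances from s
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; q <- c(q, u) }
      }
    }
    for (t in (s + 1):n) {
      if (is.na(dist[t])) next
      paths <- enumerate_paths(adj, dist, t)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        via <- table(inner)
        raw[as.integer(names(via))] <- raw[as.integer(names(via))] +
          as.numeric(via) / length(paths)
      }
    }
  }
  raw / ((n - 1) * (n - 2) / 2)
}

# Total intermediate-node appearances over all shortest paths (for the
# bookkeeping invariant on raw betweenness).
oracle_path_interior_mass <- function(g) {
  adj <- adj_of(g)
  n <- length(adj)
  total <- 0
  if (n < 3) return(0)
  for (s in 1:(n - 1)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; q <- c(q, u) }
      }
    }
    for (t in (s + 1):n) {
      if (is.na(dist[t])) next
      paths <- enumerate_paths(adj, dist, t)
      total <- total +
        sum(vapply(paths, function(p) length(p) - 2, numeric(1))) /
        length(paths)
    }
  }
  total
}

# ---- k-core oracle: repeated subgraph minimum-degree check ----------------

oracle_cores <- function(g) {
  adj <- adj_of(g)
  n <- length(adj)
  core <- stats::setNames(integer(n), igraph::V(g)$name)
  for (k in 1:max(1, n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- vapply(seq_len(n), function(v) {
        if (!alive[v]) return(Inf)
        sum(alive[adj[[v]]])
      }, numeric(1))
      drop <- which(alive & deg < k)
      if (length(drop) == 0) break
      alive[drop] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
  }
  core
}

# ---- Mann-Whitney oracle: full enumeration of label assignments -----------

oracle_mw_two_sided <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">"))
  obs <- u_of(x, y)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  list(u = obs, p = min(1, p))
}

# ---- hypergeometric oracle: enumeration of all draws ----------------------

oracle_hypergeom <- function(universe_n, set_n, query_n, overlap) {
  if (query_n == 0 || overlap == 0) return(1)
  universe <- seq_len(universe_n)
  marked <- seq_len(set_n)
  draws <- utils::combn(universe_n, query_n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= overlap))
}

# ---- misc -----------------------------------------------------------------

atlas_typed <- function(i) {
  g <- igraph::graph_from_atlas(i)
  n <- igraph::vcount(g)
  if (n == 0) return(NULL)
  el <- igraph::as_edgelist(g)
  ids <- sprintf("n%02d", seq_len(n))
  typed_graph(tibble::tibble(id = ids, type = "other"),
              if (nrow(el) > 0) {
                tibble::tibble(from = ids[as.integer(el[, 1])],
                               to = ids[as.integer(el[, 2])], kind = "ppi")
              } else NULL)
}

random_typed_graph <- function(n, p = 0.4) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  ids <- sprintf("r%02d", seq_len(n))
  typed_graph(tibble::tibble(id = ids, type = "other"),
              if (any(keep)) {
                tibble::tibble(from = ids[pairs[1, keep]],
                               to = ids[pairs[2, keep]], kind = "ppi")
              } else NULL)
}

edges_sorted <- function(g) {
  ed <- tg_edges(g)
  key_a <- pmin(ed$from, ed$to); key_b <- pmax(ed$from, ed$to)
  ed$from <- key_a; ed$to <- key_b
  dplyr::arrange(ed, from, to, kind)
}
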