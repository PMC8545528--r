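#' Per-node topological metrics
#'
#' Computes the three node-level metrics used to characterise typed ceRNA/PPI
#' networks: degree, betweenness centrality (BC) and topological coefficient
#' (TC).
#'
#' Degree counts every incident edge, `ppi` and `cerna` alike, so a node
#' connected to the same partner by both kinds scores 2. BC and TC are
#' structural metrics and are computed on the simplified graph (parallel
#' edges collapsed). BC follows the NetworkAnalyzer convention: for node
#' \eqn{v}, the sum over unordered pairs \eqn{(s,t)} of
#' \eqn{\sigma_{st}(v)/\sigma_{st}} normalised by \eqn{(n-1)(n-2)/2};
#' disconnected pairs contribute 0, and graphs with fewer than three nodes
#' have all BC equal to 0. TC of a node \eqn{n} with degree \eqn{k_n \ge 2}
#' averages \eqn{J(n,m)/k_n} over every node \eqn{m \ne n} sharing at least
#' one neighbour with \eqn{n}, where \eqn{J(n,m)} is the number of common
#' neighbours plus 1 if \eqn{n} and \eqn{m} are adjacent; nodes with degree
#' \eqn{\le 1} or no such partner have TC = 0.
#'
#' @param g A `typed_graph`.
#' @return A tibble with columns `id`, `type`, `degree`, `bc`, `tc`.
#' @examples
#' g <- typed_graph(tibble::tibble(id = c("A", "B", "C"), type = "other"),
#'                  tibble::tibble(from = c("A", "B"), to = c("B", "C"),
#'                                 kind = "ppi"))
#' node_metrics(g)
#' @export
node_metrics <- function(g) {
  tibble(
    id = igraph::V(g)$name,
    type = igraph::V(g)$type,
    degree = compute_degree(g),
    bc = compute_betweenness(g),
    tc = compute_topological_coefficient(g)
  )
}

#' @rdname node_metrics
#' @return `compute_degree()`, `compute_betweenness()` and
#'   `compute_topological_coefficient()` each return a numeric vector named
#'   by node id.
#' @export
compute_degree <- function(g) {
  setNames(igraph::degree(g, loops = FALSE), igraph::V(g)$name)
}

#' @rdname node_metrics
#' @export
compute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(setNames(rep(0, n), igraph::V(g)$name))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  bc <- igraph::betweenness(gs, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(bc), igraph::V(g)$name)
}

#' @rdname node_metrics
#' @export
compute_topological_coefficient <- function(g) {
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(gs)
  adj <- igraph::adjacent_vertices(gs, igraph::V(gs))
  adj <- lapply(adj, as.integer)
  deg <- lengths(adj)
  tc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] <= 1) next
    # count, for each node m, how many neighbours it shares with v
    shared <- integer(n)
    for (u in adj[[v]]) {
      shared[adj[[u]]] <- shared[adj[[u]]] + 1L
    }
    shared[v] <- 0L
    cand <- which(shared > 0L)
    if (length(cand) == 0) next
    j <- shared[cand]
    j[cand %in% adj[[v]]] <- j[cand %in% adj[[v]]] + 1L
    tc[v] <- mean(j) / deg[v]
  }
  setNames(tc, igraph::V(g)$name)
}

#' Fit a power law to a degree distribution
#'
#' Least-squares line on the log-log degree-frequency plot: for each distinct
#' positive degree \eqn{k} observed at least once, the point
#' \eqn{(\log k, \log N(k))} enters an ordinary linear fit, where \eqn{N(k)}
#' is the number of nodes with degree \eqn{k}. Degree-0 nodes are excluded
#' (log undefined). The log base cancels in both the slope and \eqn{R^2}.
#'
#' @param degrees Numeric vector of per-node degrees.
#' @return An object of class `powerlaw_fit` with elements `slope`, `r2`,
#'   `points_used` and `points` (the fitted log-log table). Use [tidy()] /
#'   [glance()] for tibble output.
#' @examples
#' fit <- fit_power_law(rep(c(1, 2, 4), c(8, 4, 2)))
#' glance(fit)   # slope -1, r2 1
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[!is.na(degrees) & degrees > 0]
  freq <- as.data.frame(table(degrees), stringsAsFactors = FALSE)
  names(freq) <- c("k", "n_k")
  freq$k <- as.numeric(freq$k)
  if (nrow(freq) < 3) {
    abort("power-law fit needs >= 3 distinct positive degree values",
          class = "cernet_undefined_fit")
  }
  pts <- tibble(log_k = log(freq$k), log_n = log(freq$n_k),
                k = freq$k, n_k = freq$n_k)
  fit <- lm(log_n ~ log_k, data = pts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pts$log_n - mean(pts$log_n))^2)
  structure(
    list(slope = unname(coef(fit)[2]),
         r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
         points_used = nrow(pts),
         points = pts),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> slope = %.4f, R2 = %.4f (%d degree values)\n",
              x$slope, x$r2, x$points_used))
  invisible(x)
}

#' Tidiers for power-law fits
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return `tidy()` returns the per-degree log-log points; `glance()` a
#'   one-row tibble with `slope`, `r2`, `points_used`.
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) x$points

#' @rdname tidy.powerlaw_fit
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(slope = x$slope, r2 = x$r2, points_used = x$points_used)
}

#' Compare a topological metric between node types
#'
#' Pairwise two-sided Mann-Whitney U tests of a node metric between every
#' pair of node-type groups. The exact null distribution is used when both
#' groups are small and tie-free (delegated to [stats::wilcox.test()], which
#' switches to the normal approximation with tie correction otherwise).
#' Groups with fewer than two members are skipped with a warning.
#'
#' @param metrics A tibble from [node_metrics()] (columns `id`, `type` and
#'   the metric).
#' @param metric Name of the metric column to compare
#'   (`"degree"`, `"bc"` or `"tc"`).
#' @return A tibble with `metric`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (the Mann-Whitney U of group1) and `p_value`.
#' @export
compare_metric_by_type <- function(metrics, metric = "degree") {
  metrics <- as_tibble(metrics)
  stopifnot(metric %in% names(metrics))
  groups <- split(metrics[[metric]], metrics$type)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small) > 0) {
    warn(sprintf("skipping group(s) with < 2 members: %s",
                 paste(small, collapse = ", ")))
    groups <- groups[lengths(groups) >= 2]
  }
  nm <- sort(names(groups))
  if (length(nm) < 2) {
    return(tibble(metric = character(), group1 = character(),
                  group2 = character(), n1 = integer(), n2 = integer(),
                  statistic = numeric(), p_value = numeric()))
  }
  pairs <- utils::combn(nm, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(wilcox.test(groups[[a]], groups[[b]],
                                       alternative = "two.sided"))
    tibble(metric = metric, group1 = a, group2 = b,
           n1 = length(groups[[a]]), n2 = length(groups[[b]]),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
}

#' Select hub nodes by degree
#'
#' Hubs are the top-`k` nodes by degree (default `k = 50`), ties broken by
#' node id ascending. An optional type filter restricts eligibility, e.g.
#' to rank hub lncRNAs and hub coding genes separately.
#'
#' @param metrics A tibble from [node_metrics()].
#' @param k Number of hubs to return (default 50).
#' @param types Optional character vector of node types to restrict to.
#' @return A tibble of `min(k, eligible)` rows ordered by rank, with columns
#'   `rank`, `id`, `type`, `degree`.
#' @export
select_hubs <- function(metrics, k = 50, types = NULL) {
  chk_count(k, "k")
  metrics <- as_tibble(metrics)
  if (!is.null(types)) metrics <- filter(metrics, .data$type %in% types)
  out <- arrange(metrics, desc(.data$degree), .data$id)
  out <- head(out, k)
  mutate(select(out, "id", "type", "degree"),
         rank = dplyr::row_number(), .before = 1)
}

#' Regulating proportions of hub lncRNAs
#'
#' For each hub lncRNA, counts its ceRNA neighbours per disease type and
#' normalises over the typed neighbours (`diabetes`, `DR`, `common`); the
#' proportions sum to 1 when defined. Neighbours typed `other` are excluded
#' from the denominator and reported separately. lncRNAs with no typed ceRNA
#' neighbour get `NA` proportions.
#'
#' @param g A `typed_graph`.
#' @param lncrnas Character vector of lncRNA node ids (e.g. hub lncRNAs).
#' @return A tibble with one row per lncRNA: counts `n_diabetes`, `n_dr`,
#'   `n_common`, `n_other` and proportions `p_diabetes`, `p_dr`, `p_common`.
#' @export
regulating_proportions <- function(g, lncrnas) {
  nd <- tg_nodes(g)
  bad <- setdiff(lncrnas, nd$id[nd$type == "lncRNA"])
  if (length(bad) > 0) {
    abort(sprintf("not lncRNA nodes of the graph: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "cernet_invalid_input")
  }
  ed <- filter(tg_edges(g), .data$kind == "cerna")
  type_of <- setNames(nd$type, nd$id)
  purrr::map_dfr(lncrnas, function(l) {
    nb <- c(ed$to[ed$from == l], ed$from[ed$to == l])
    tt <- type_of[nb]
    n_dia <- sum(tt == "diabetes"); n_dr <- sum(tt == "DR")
    n_com <- sum(tt == "common"); n_oth <- sum(tt == "other")
    tot <- n_dia + n_dr + n_com
    tibble(lncrna = l, n_diabetes = n_dia, n_dr = n_dr, n_common = n_com,
           n_other = n_oth,
           p_diabetes = if (tot > 0) n_dia / tot else NA_real_,
           p_dr = if (tot > 0) n_dr / tot else NA_real_,
           p_common = if (tot > 0) n_com / tot else NA_real_)
  })
}
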