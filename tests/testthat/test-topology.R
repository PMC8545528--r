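test_that("degree counts every incident edge, ppi and cerna alike", {
  g <- tg("A", "B", "B", "C")
  expect_equal(unname(compute_degree(g)), c(1, 2, 1))

  iso <- tg("A", "B", nodes = "Z")
  expect_equal(compute_degree(iso)[["Z"]], 0)

  mixed <- typed_graph(
    tibble::tibble(id = c("L1", "G1"), type = c("lncRNA", "other")),
    tibble::tibble(from = c("L1", "L1"), to = c("G1", "G1"),
                   kind = c("ppi", "cerna"),
                   shared_mirnas = c("", "miR-1")))
  expect_equal(compute_degree(mixed)[["G1"]], 2)
})

test_that("betweenness matches hand-derived fixtures and conventions", {
  path <- tg("A", "B", "B", "C")
  expect_equal(compute_betweenness(path)[["B"]], 1)

  star <- tg("C0", "L1", "C0", "L2", "C0", "L3")
  bc <- compute_betweenness(star)
  expect_equal(bc[["C0"]], 1)
  expect_equal(unname(bc[c("L1", "L2", "L3")]), c(0, 0, 0))

  ring4 <- tg("A", "B", "B", "C", "C", "D", "D", "A")
  expect_equal(unname(compute_betweenness(ring4)), rep(0.5 / 3, 4),
               tolerance = 1e-12)

  two <- tg("A", "B")
  expect_equal(unname(compute_betweenness(two)), c(0, 0))
})

test_that("betweenness agrees with the path-enumeration oracle", {
  withr::local_seed(42)
  for (rep in 1:25) {
    g <- random_typed_graph(sample(4:8, 1), p = runif(1, 0.25, 0.7))
    expect_equal(compute_betweenness(g), oracle_betweenness(g),
                 tolerance = 1e-9)
    # raw-mass bookkeeping: sum of unnormalised bc equals the oracle's
    # total interior appearances
    n <- igraph::vcount(g)
    raw_sum <- sum(compute_betweenness(g)) * (n - 1) * (n - 2) / 2
    expect_equal(raw_sum, oracle_path_interior_mass(g), tolerance = 1e-9)
  }
})

test_that("topological coefficient matches the shared-neighbour fixtures", {
  expect_equal(unname(compute_topological_coefficient(tg_complete(LETTERS[1:3]))),
               c(1, 1, 1))
  ring4 <- tg("A", "B", "B", "C", "C", "D", "D", "A")
  expect_equal(unname(compute_topological_coefficient(ring4)),
               c(1, 1, 1, 1))
  path <- tg("A", "B", "B", "C")
  expect_equal(compute_topological_coefficient(path)[["B"]], 0)
  # degree <= 1 forces 0
  expect_equal(unname(compute_topological_coefficient(path)[c("A", "C")]),
               c(0, 0))
})

test_that("power-law fit is exact on exact data and flags degenerate input", {
  f <- fit_power_law(rep(c(1, 2, 4), c(8, 4, 2)))
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$points_used, 3L)

  flat <- fit_power_law(rep(c(1, 2, 4), c(3, 3, 3)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(fit_power_law(rep(c(1, 2), c(5, 5))),
               class = "cernet_undefined_fit")

  g <- glance(f)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("slope", "r2", "points_used"))
  expect_equal(nrow(tidy(f)), 3)
})

test_that("Mann-Whitney comparisons agree with full enumeration", {
  m <- tibble::tibble(id = as.character(1:6),
                      type = rep(c("DR", "diabetes"), each = 3),
                      degree = c(1, 2, 3, 4, 5, 6))  # group1 = DR (sorted)
  out <- compare_metric_by_type(m, "degree")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1)

  # identical distributions give p = 1 (symmetry)
  same <- tibble::tibble(id = as.character(1:4),
                         type = rep(c("diabetes", "DR"), each = 2),
                         degree = c(1, 2, 1, 2))
  p_same <- suppressWarnings(compare_metric_by_type(same, "degree")$p_value)
  expect_equal(p_same, 1)

  # exact path equals enumeration for all group sizes with n1 + n2 <= 10
  withr::local_seed(7)
  for (n1 in 2:5) {
    for (n2 in n1:(10 - n1)) {
      x <- sample(seq(1, 100, by = 3), n1)
      y <- sample(setdiff(seq(2, 100, by = 3), x), n2)
      oracle <- oracle_mw_two_sided(x, y)
      wt <- wilcox.test(x, y, alternative = "two.sided")
      expect_equal(unname(wt$statistic), oracle$u)
      expect_equal(wt$p.value, oracle$p, tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }

  expect_warning(
    compare_metric_by_type(
      tibble::tibble(id = as.character(1:4),
                     type = c("diabetes", "DR", "DR", "DR"),
                     degree = 1:4), "degree"),
    "skipping")
})

test_that("hub selection ranks by degree with id tie-breaks", {
  m <- tibble::tibble(id = c("A", "B", "C", "D"),
                      type = "other", degree = c(5, 3, 3, 1),
                      bc = 0, tc = 0)
  expect_equal(select_hubs(m, k = 2)$id, c("A", "B"))
  expect_equal(nrow(select_hubs(m, k = 10)), 4)

  withr::local_seed(1)
  m60 <- tibble::tibble(id = sprintf("g%02d", 1:60), type = "other",
                        degree = sample(1:20, 60, replace = TRUE),
                        bc = 0, tc = 0)
  hubs <- select_hubs(m60, k = 50)
  expect_equal(nrow(hubs), 50)
  expect_gte(min(hubs$degree),
             max(m60$degree[!m60$id %in% hubs$id]))
})

test_that("regulating proportions normalise over typed ceRNA neighbours", {
  g <- typed_graph(
    tibble::tibble(id = c("L1", "C1", "C2", "D1", "R1", "O1"),
                   type = c("lncRNA", "common", "common", "diabetes",
                            "DR", "other")),
    tibble::tibble(from = "L1", to = c("C1", "C2", "D1", "R1", "O1"),
                   kind = "cerna", shared_mirnas = "miR-1"))
  pr <- regulating_proportions(g, "L1")
  expect_equal(pr$p_diabetes, 0.25)
  expect_equal(pr$p_dr, 0.25)
  expect_equal(pr$p_common, 0.5)
  expect_equal(pr$n_other, 1)
  expect_equal(pr$p_diabetes + pr$p_dr + pr$p_common, 1)

  g2 <- typed_graph(
    tibble::tibble(id = c("L1", "C1"), type = c("lncRNA", "common")),
    tibble::tibble(from = "L1", to = "C1", kind = "cerna",
                   shared_mirnas = "miR-1"))
  expect_equal(regulating_proportions(g2, "L1")$p_common, 1)

  g3 <- typed_graph(
    tibble::tibble(id = c("L1", "O1"), type = c("lncRNA", "other")),
    tibble::tibble(from = "L1", to = "O1", kind = "cerna",
                   shared_mirnas = "miR-1"))
  expect_true(is.na(regulating_proportions(g3, "L1")$p_common))

  expect_error(regulating_proportions(g, "C1"),
               class = "cernet_invalid_input")
})

test_that("node metrics are invariant under node relabeling", {
  withr::local_seed(3)
  g <- random_typed_graph(7, 0.5)
  ids <- tg_nodes(g)$id
  perm <- setNames(sprintf("z%02d", sample(7)), ids)
  ed <- tg_edges(g)
  g2 <- typed_graph(tibble::tibble(id = unname(perm[ids]), type = "other"),
                    tibble::tibble(from = unname(perm[ed$from]),
                                   to = unname(perm[ed$to]), kind = "ppi"))
  m1 <- node_metrics(g)
  m2 <- node_metrics(g2)
  m2r <- m2[match(unname(perm[m1$id]), m2$id), ]
  expect_equal(unname(m2r$degree), unname(m1$degree))
  expect_equal(unname(m2r$bc), unname(m1$bc), tolerance = 1e-12)
  expect_equal(unname(m2r$tc), unname(m1$tc), tolerance = 1e-12)
})
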