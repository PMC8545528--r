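test_that("preferential-attachment backbone has the promised shape", {
  cfg <- synth_config(seed = 1, n_ppi_nodes = 3, attach_m = 1,
                      n_planted_cliques = 0, n_diabetes = 1, n_dr = 1,
                      n_common = 0)
  g <- gen_ppi_network(cfg)$graph
  expect_equal(nrow(tg_edges(g)), 2)       # m = 1 growth yields a tree
  expect_true(igraph::is_tree(igraph::simplify(g)))

  cfg2 <- synth_config(seed = 2, n_ppi_nodes = 60, n_planted_cliques = 1,
                       clique_size_range = c(5, 5))
  out <- gen_ppi_network(cfg2)
  cl <- out$truth$planted_cliques[[1]]
  expect_length(cl, 5)
  ed <- edges_sorted(out$graph)
  pairs <- utils::combn(sort(cl), 2)
  for (i in seq_len(ncol(pairs))) {
    expect_true(any(ed$from == pairs[1, i] & ed$to == pairs[2, i]))
  }

  expect_error(
    gen_ppi_network(synth_config(seed = 1, n_ppi_nodes = 10,
                                 n_planted_cliques = 3,
                                 clique_size_range = c(5, 5))),
    class = "cernet_invalid_config")
})

test_that("disease labels have exact counts and are disjoint", {
  cfg <- synth_config(seed = 3, n_ppi_nodes = 20, n_planted_cliques = 0,
                      n_diabetes = 4, n_dr = 3, n_common = 2)
  g <- gen_ppi_network(cfg)$graph
  lab <- gen_disease_sets(g, cfg)
  counts <- table(lab$assignments$type)
  expect_equal(unname(counts[["diabetes"]]), 2)
  expect_equal(unname(counts[["DR"]]), 1)
  expect_equal(unname(counts[["common"]]), 2)
  expect_equal(anyDuplicated(lab$assignments$id), 0L)

  cfg0 <- synth_config(seed = 3, n_ppi_nodes = 20, n_planted_cliques = 0,
                       n_diabetes = 4, n_dr = 3, n_common = 0)
  lab0 <- gen_disease_sets(gen_ppi_network(cfg0)$graph, cfg0)
  dia <- lab0$assignments$id[lab0$assignments$type == "diabetes"]
  dr <- lab0$assignments$id[lab0$assignments$type == "DR"]
  expect_length(intersect(dia, dr), 0)

  expect_error(
    gen_disease_sets(g, synth_config(seed = 1, n_ppi_nodes = 20,
                                     n_diabetes = 15, n_dr = 15,
                                     n_common = 2)),
    class = "cernet_invalid_config")
})

test_that("disease-set arithmetic reproduces the full-scale catalog counts", {
  # 1,349 diabetes + 371 DR genes with 269 in common, on a large backbone
  cfg <- synth_config(seed = 5, n_ppi_nodes = 2000, attach_m = 2,
                      n_planted_cliques = 0, n_diabetes = 1349, n_dr = 371,
                      n_common = 269)
  lab <- gen_disease_sets(gen_ppi_network(cfg)$graph, cfg)
  counts <- table(lab$assignments$type)
  expect_equal(unname(counts[["common"]]), 269)
  expect_equal(unname(counts[["diabetes"]]) + 269, 1349)
  expect_equal(unname(counts[["DR"]]) + 269, 371)
})

test_that("ceRNA edges are bipartite, annotated and Poisson-calibrated", {
  cfg <- synth_config(seed = 4, n_ppi_nodes = 50, n_planted_cliques = 0,
                      n_lncrna = 1, cerna_density = 3)
  g <- gen_disease_sets(gen_ppi_network(cfg)$graph, cfg)$graph
  ed <- gen_cerna_edges(g, cfg)
  expect_true(all(ed$lncrna == "L001"))
  expect_true(all(nchar(ed$shared_mirnas) > 0))
  expect_equal(anyDuplicated(ed[, c("lncrna", "gene")]), 0L)
  expect_true(all(!grepl("^L", ed$gene)))

  # mean edges per lncRNA within 10% of the Poisson mean over 50 seeds
  means <- vapply(1:50, function(s) {
    cfg_s <- synth_config(seed = s, n_ppi_nodes = 80, n_planted_cliques = 0,
                          n_lncrna = 20, cerna_density = 1.5)
    gg <- gen_disease_sets(gen_ppi_network(cfg_s)$graph, cfg_s)$graph
    nrow(gen_cerna_edges(gg, cfg_s)) / 20
  }, numeric(1))
  expect_lt(abs(mean(means) - 1.5) / 1.5, 0.1)
})

test_that("expression generator plants shifts exactly where promised", {
  cfg <- synth_config(seed = 6, de_fraction = 0.2, effect_log2fc = 5,
                      noise_sd = 0.1)
  ge <- gen_expression(sprintf("g%02d", 1:50), cfg)
  de <- differential_expression(ge$matrix)
  planted <- ge$truth$gene
  expect_true(all(de$significant[de$gene %in% planted]))

  # non-planted genes: group means agree closely on the log2 scale
  lv <- log2(ge$matrix$values + 1)
  case <- ge$matrix$groups$sample[ge$matrix$groups$group == "case"]
  ctrl <- ge$matrix$groups$sample[ge$matrix$groups$group == "control"]
  nulls <- setdiff(rownames(lv), planted)
  diffs <- rowMeans(lv[nulls, case]) - rowMeans(lv[nulls, ctrl])
  expect_lt(max(abs(diffs)), 0.5)

  expect_error(
    gen_expression("g1", synth_config(seed = 1, n_control = 1)),
    class = "cernet_invalid_config")
})

test_that("SNP fixture truth is verifiable by direct string search", {
  cfg <- synth_config(seed = 7, n_snps = 40, n_lncrna = 5)
  fix <- gen_snp_fixture(sprintf("L%03d", 1:5), cfg)
  expect_gt(nrow(fix$truth), 0)
  for (i in seq_len(nrow(fix$truth))) {
    ev <- fix$truth[i, ]
    snp <- fix$snps[fix$snps$snp_id == ev$snp_id, ]
    seqs <- fix$sequences[[snp$lncrna_id]]
    with_allele <- function(a) {
      paste0(substr(seqs, 1, snp$pos), a,
             substr(seqs, snp$pos + 2, nchar(seqs)))
    }
    present <- function(a) {
      if (ev$element_kind == "mirna_site") {
        site <- cernet:::revcomp(substr(fix$mirna_seqs[[ev$element_id]], 2, 8))
        grepl(site, substr(with_allele(a), max(1, snp$pos - 5),
                           snp$pos + 7), fixed = TRUE)
      } else {
        pat <- cernet:::iupac_regex(fix$motifs[[ev$element_id]])
        L <- nchar(fix$motifs[[ev$element_id]])
        grepl(pat, substr(with_allele(a), max(1, snp$pos + 2 - L),
                          snp$pos + L))
      }
    }
    if (ev$effect == "gain") {
      expect_true(present(snp$alt), label = paste("gain alt", ev$snp_id))
      expect_false(present(snp$ref), label = paste("gain ref", ev$snp_id))
    } else {
      expect_true(present(snp$ref), label = paste("loss ref", ev$snp_id))
      expect_false(present(snp$alt), label = paste("loss alt", ev$snp_id))
    }
  }
  # planted region classes are emitted unchanged
  classes <- fix$snps$region_class[match(fix$truth$snp_id, fix$snps$snp_id)]
  expect_true(all(ifelse(fix$truth$element_kind == "tfbs",
                         classes == "TFBS", classes == "lncRNA")))
})

test_that("region-class sampling follows the configured weights", {
  cfg <- synth_config(seed = 8, n_snps = 10000, n_lncrna = 40,
                      planted_event_fraction = 0)
  fix <- gen_snp_fixture(sprintf("L%03d", 1:40), cfg)
  props <- prop.table(table(fix$snps$region_class))
  for (cl in names(cfg$region_class_weights)) {
    expect_lt(abs(props[[cl]] - cfg$region_class_weights[[cl]]), 0.02)
  }
})

test_that("same seed reproduces byte-identical outputs, truth never dangles", {
  cfg <- synth_config(seed = 11, n_snps = 25)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  # hash a serialisable view (igraph objects carry external pointers)
  view <- function(x) list(tg_nodes(x$graph), edges_sorted(x$graph),
                           x$cerna, x$expression, x$snp_fixture, x$truth)
  expect_identical(rlang::hash(view(a)), rlang::hash(view(b)))
  c <- simulate_study(synth_config(seed = 12, n_snps = 25))
  expect_false(identical(rlang::hash(view(a)), rlang::hash(view(c))))

  # every ground-truth reference resolves to an emitted entity
  expect_true(all(unlist(a$truth$planted_cliques) %in% tg_nodes(a$graph)$id))
  expect_true(all(a$truth$planted_de$gene %in% rownames(a$expression$values)))
  expect_true(all(a$truth$planted_site_events$snp_id %in%
                    a$snp_fixture$snps$snp_id))
  expect_true(all(a$truth$disease_assignments$id %in% tg_nodes(a$graph)$id))
})
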