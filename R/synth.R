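#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study emulated by the package: a
#' scale-free PPI backbone grown by preferential attachment, overlapping
#' diabetes/DR disease-gene sets, bipartite lncRNA-gene ceRNA edges with
#' shared miRNAs, case/control expression with planted fold changes, and
#' SNPs with planted allele-dependent miRNA seed sites and TF motifs.
#' Defaults describe a desk-scale study: a 300-node backbone with seven
#' edges per attached node (the edge/node ratio of the emulated human
#' interactome), three planted cliques of 8-12 nodes, disease sets in the
#' proportions of the published gene catalogs, a 25-case / 5-control
#' expression design, planted effects of 1.5 log2 units with 0.4 log2-scale
#' noise, and a mean of 1.5 ceRNA partners per lncRNA.
#'
#' @param seed Integer master seed; every generator derives its own stream
#'   from it, so identical configs give byte-identical outputs.
#' @param n_ppi_nodes,attach_m Backbone size and edges added per node during
#'   preferential attachment.
#' @param n_diabetes,n_dr,n_common Disease-set sizes;
#'   `n_common <= min(n_diabetes, n_dr)`.
#' @param n_lncrna Number of lncRNAs.
#' @param cerna_density Mean ceRNA edges per lncRNA (Poisson).
#' @param n_mirnas Size of the shared-miRNA pool.
#' @param n_case,n_control Sample counts per expression group.
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param effect_log2fc Planted case-vs-control shift in log2 units.
#' @param noise_sd Log2-scale noise standard deviation.
#' @param n_planted_cliques,clique_size_range Module-recovery ground truth.
#' @param n_snps Number of SNPs in the variant fixture.
#' @param planted_event_fraction Fraction of eligible SNPs planted with an
#'   allele-dependent site event.
#' @param region_class_weights Named sampling weights over the region-class
#'   catalog.
#' @param seq_length Baseline transcript length (grown automatically when a
#'   transcript must host many SNPs).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_ppi_nodes = 300L, attach_m = 7L,
                         n_diabetes = 45L, n_dr = 12L, n_common = 9L,
                         n_lncrna = 60L, cerna_density = 1.5,
                         n_mirnas = 20L,
                         n_case = 25L, n_control = 5L,
                         de_fraction = 0.1, effect_log2fc = 1.5,
                         noise_sd = 0.4,
                         n_planted_cliques = 3L,
                         clique_size_range = c(8L, 12L),
                         n_snps = 60L, planted_event_fraction = 0.5,
                         region_class_weights = c(
                           enhancer = 0.10, TFBS = 0.25, lncRNA = 0.30,
                           DHS = 0.10, open_chromatin = 0.10,
                           footprint = 0.10, TAD = 0.05),
                         seq_length = 500L) {
  chk_count(seed, "seed", min = 0L)
  chk_count(n_ppi_nodes, "n_ppi_nodes")
  chk_count(attach_m, "attach_m")
  chk_count(n_diabetes, "n_diabetes")
  chk_count(n_dr, "n_dr")
  chk_count(n_common, "n_common", min = 0L)
  chk_count(n_lncrna, "n_lncrna")
  chk_count(n_mirnas, "n_mirnas")
  chk_count(n_case, "n_case")
  chk_count(n_control, "n_control")
  chk_count(n_snps, "n_snps", min = 0L)
  chk_positive(cerna_density, "cerna_density")
  chk_positive(noise_sd, "noise_sd")
  if (n_common > min(n_diabetes, n_dr)) {
    abort("n_common must not exceed min(n_diabetes, n_dr)",
          class = "cernet_invalid_config")
  }
  if (de_fraction < 0 || de_fraction > 1) {
    abort("de_fraction must be in [0, 1]", class = "cernet_invalid_config")
  }
  if (length(clique_size_range) != 2 ||
      clique_size_range[1] > clique_size_range[2] ||
      clique_size_range[1] < 2) {
    abort("clique_size_range must be c(lo, hi) with 2 <= lo <= hi",
          class = "cernet_invalid_config")
  }
  if (!setequal(names(region_class_weights), REGION_CLASSES)) {
    abort("region_class_weights must name all seven region classes",
          class = "cernet_invalid_config")
  }
  structure(list(
    seed = as.integer(seed), n_ppi_nodes = as.integer(n_ppi_nodes),
    attach_m = as.integer(attach_m), n_diabetes = as.integer(n_diabetes),
    n_dr = as.integer(n_dr), n_common = as.integer(n_common),
    n_lncrna = as.integer(n_lncrna), cerna_density = cerna_density,
    n_mirnas = as.integer(n_mirnas), n_case = as.integer(n_case),
    n_control = as.integer(n_control), de_fraction = de_fraction,
    effect_log2fc = effect_log2fc, noise_sd = noise_sd,
    n_planted_cliques = as.integer(n_planted_cliques),
    clique_size_range = as.integer(clique_size_range),
    n_snps = as.integer(n_snps),
    planted_event_fraction = planted_event_fraction,
    region_class_weights = region_class_weights,
    seq_length = as.integer(seq_length)
  ), class = "synth_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a scale-free PPI backbone with planted cliques
#'
#' Grows a simple undirected graph by preferential attachment
#' (Barabasi-Albert style, via [igraph::sample_pa()]) and embeds
#' `n_planted_cliques` complete subgraphs on randomly chosen disjoint node
#' subsets by adding all within-clique edges.
#'
#' @param cfg A [synth_config()].
#' @return A list with `graph` (a `typed_graph`, all nodes typed `other`)
#'   and `truth` (list with `planted_cliques`, a list of node-id vectors).
#' @export
gen_ppi_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, "ppi"))
  n <- cfg$n_ppi_nodes
  sizes <- if (cfg$n_planted_cliques > 0) {
    rng <- seq(cfg$clique_size_range[1], cfg$clique_size_range[2])
    rng[sample.int(length(rng), cfg$n_planted_cliques, replace = TRUE)]
  } else integer(0)
  if (sum(sizes) > n) {
    abort("planted cliques need more nodes than n_ppi_nodes provides",
          class = "cernet_invalid_config")
  }
  g0 <- igraph::sample_pa(n, m = cfg$attach_m, directed = FALSE)
  ids <- sprintf("G%04d", seq_len(n))
  el <- igraph::as_edgelist(g0)
  edges <- tibble(from = ids[as.integer(el[, 1])],
                  to = ids[as.integer(el[, 2])], kind = "ppi")
  cliques <- list()
  if (length(sizes) > 0) {
    pool <- sample(ids, sum(sizes))
    off <- 0L
    for (s in sizes) {
      members <- sort(pool[(off + 1):(off + s)])
      off <- off + s
      cliques[[length(cliques) + 1]] <- members
      pairs <- utils::combn(members, 2)
      edges <- bind_rows(edges, tibble(from = pairs[1, ], to = pairs[2, ],
                                       kind = "ppi"))
    }
  }
  g <- typed_graph(tibble(id = ids, type = "other"), edges)
  list(graph = g, truth = list(planted_cliques = cliques))
}

#' Assign overlapping disease-gene labels to network nodes
#'
#' Labels exactly `n_common` nodes `common`, `n_diabetes - n_common` nodes
#' `diabetes` and `n_dr - n_common` nodes `DR`; all labels are disjoint and
#' the rest stay `other`.
#'
#' @param graph A `typed_graph` (from [gen_ppi_network()]).
#' @param cfg A [synth_config()].
#' @return A list with `graph` (types updated) and `assignments` (tibble
#'   `id`, `type` for the labelled nodes).
#' @export
gen_disease_sets <- function(graph, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, "disease"))
  need <- cfg$n_diabetes + cfg$n_dr - cfg$n_common
  ids <- igraph::V(graph)$name
  if (need > length(ids)) {
    abort("not enough nodes for the requested disease-set sizes",
          class = "cernet_invalid_config")
  }
  chosen <- sample(ids, need)
  labels <- rep(c("common", "diabetes", "DR"),
                c(cfg$n_common, cfg$n_diabetes - cfg$n_common,
                  cfg$n_dr - cfg$n_common))
  igraph::V(graph)$type[match(chosen, ids)] <- labels
  list(graph = as_typed_graph(graph),
       assignments = tibble(id = chosen, type = labels))
}

#' Generate bipartite ceRNA edges with shared miRNAs
#'
#' Each lncRNA gets `Poisson(cerna_density)` ceRNA partners sampled among
#' the coding (non-lncRNA) nodes of the graph; every edge carries 1-3 shared
#' miRNA ids drawn from a common pool. Duplicate edges are removed.
#'
#' @param graph A `typed_graph` with disease labels assigned.
#' @param cfg A [synth_config()].
#' @return A tibble with columns `lncrna`, `gene`, `shared_mirnas`
#'   (comma-joined).
#' @export
gen_cerna_edges <- function(graph, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_lncrna < 1) {
    abort("need at least one lncRNA", class = "cernet_invalid_config")
  }
  set.seed(derive_seed(cfg$seed, "cerna"))
  lnc <- sprintf("L%03d", seq_len(cfg$n_lncrna))
  mir <- sprintf("miR-%02d", seq_len(cfg$n_mirnas))
  coding <- igraph::V(graph)$name[igraph::V(graph)$type != "lncRNA"]
  rows <- purrr::map_dfr(lnc, function(l) {
    k <- min(rpois(1, cfg$cerna_density), length(coding))
    if (k == 0) return(tibble())
    partners <- sample(coding, k)
    tibble(lncrna = l, gene = partners,
           shared_mirnas = vapply(seq_len(k), function(i) {
             paste(sort(sample(mir, sample(1:3, 1))), collapse = ",")
           }, character(1)))
  })
  distinct(rows, .data$lncrna, .data$gene, .keep_all = TRUE)
}

#' Generate case/control expression with planted fold changes
#'
#' Log-normal model: gene `g` in sample `j` takes the value
#' `2^(base_g + effect_g * case_j + noise)`, with `noise ~ N(0, noise_sd)`
#' on the log2 scale. A fraction `de_fraction` of genes gets a planted shift
#' of `effect_log2fc` log2 units (random sign per gene) in the case group;
#' all other genes have identical group means in expectation.
#'
#' @param genes Character vector of gene ids to simulate.
#' @param cfg A [synth_config()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (tibble `gene`, `direction` of the planted genes).
#' @export
gen_expression <- function(genes, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_case < 2 || cfg$n_control < 2) {
    abort("need >= 2 case and >= 2 control samples",
          class = "cernet_invalid_config")
  }
  set.seed(derive_seed(cfg$seed, "expression"))
  genes <- as.character(genes)
  n_de <- round(cfg$de_fraction * length(genes))
  de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
  direction <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
               sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  group <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  base <- runif(length(genes), 6, 10)
  shift <- setNames(rep(0, length(genes)), genes)
  shift[de_genes] <- direction * cfg$effect_log2fc
  log2_vals <- outer(base, rep(0, length(samples)), `+`) +
    outer(shift[genes], as.numeric(group == "case")) +
    matrix(rnorm(length(genes) * length(samples), 0, cfg$noise_sd),
           nrow = length(genes))
  vals <- 2^log2_vals
  dimnames(vals) <- list(genes, samples)
  list(matrix = expression_matrix(vals, setNames(group, samples)),
       truth = tibble(gene = de_genes, direction = direction))
}

# --- planted-site machinery ------------------------------------------------

iupac_allowed <- function(ch) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sets[[ch]]
}

# Independent window scanner used only to certify planted fixtures:
# plain substring / per-character IUPAC comparison, no regex, no package
# callers.
scan_window <- function(sequence, pos1, allele, mirna_seqs, motifs, mode) {
  seq2 <- paste0(substr(sequence, 1, pos1 - 1), allele,
                 substr(sequence, pos1 + 1, nchar(sequence)))
  hits <- list()
  for (id in names(mirna_seqs)) {
    seed <- switch(mode, "7mer-m8" = substr(mirna_seqs[[id]], 2, 8),
                   "6mer" = substr(mirna_seqs[[id]], 2, 7),
                   "8mer" = substr(mirna_seqs[[id]], 1, 8))
    site <- revcomp(seed)
    L <- nchar(site)
    for (s in max(1, pos1 - 7):(min(nchar(seq2), pos1 + 7) - L + 1)) {
      if (substr(seq2, s, s + L - 1) == site) {
        hits[[length(hits) + 1]] <- tibble(element_id = id,
                                           element_kind = "mirna_site")
        break
      }
    }
  }
  for (id in names(motifs)) {
    mot <- strsplit(motifs[[id]], "")[[1]]
    L <- length(mot)
    lo <- max(1, pos1 - (L - 1))
    hi <- min(nchar(seq2), pos1 + (L - 1))
    for (s in lo:(hi - L + 1)) {
      if (s < 1 || s + L - 1 > nchar(seq2)) next
      piece <- strsplit(substr(seq2, s, s + L - 1), "")[[1]]
      if (all(vapply(seq_len(L),
                     function(i) piece[i] %in% iupac_allowed(mot[i]),
                     logical(1)))) {
        hits[[length(hits) + 1]] <- tibble(element_id = id,
                                           element_kind = "tfbs")
        break
      }
    }
  }
  bind_rows(hits)
}

# Allele-dependent events in the window: the set difference of the two
# allele-wise scans.
scan_events <- function(sequence, pos1, ref, alt, mirna_seqs, motifs, mode) {
  ref_hits <- scan_window(sequence, pos1, ref, mirna_seqs, motifs, mode)
  alt_hits <- scan_window(sequence, pos1, alt, mirna_seqs, motifs, mode)
  key <- function(x) if (nrow(x) == 0) character(0) else {
    paste(x$element_id, x$element_kind)
  }
  gains <- alt_hits[!(key(alt_hits) %in% key(ref_hits)), , drop = FALSE]
  losses <- ref_hits[!(key(ref_hits) %in% key(alt_hits)), , drop = FALSE]
  bind_rows(
    if (nrow(gains) > 0) mutate(gains, effect = "gain") else tibble(),
    if (nrow(losses) > 0) mutate(losses, effect = "loss") else tibble()
  )
}

#' Generate a SNP fixture with planted allele-dependent binding sites
#'
#' Emits SNPs linked to lncRNA transcripts, a transcript FASTA-ready
#' sequence set, a miRNA-sequence pool and a TF-motif table. SNPs sample
#' their region class from `region_class_weights`; a fraction
#' `planted_event_fraction` of SNPs whose class is `lncRNA` (respectively
#' `TFBS`) is planted so that exactly one allele completes a 7mer-m8 miRNA
#' seed complement (respectively an IUPAC TF consensus). Each planted
#' fixture window is certified by an independent string scan: exactly the
#' planted event, no other allele-dependent site for any miRNA or motif in
#' the pool, and non-planted SNPs certified event-free.
#'
#' @param lncrna_ids Character vector of lncRNA ids (>= 1).
#' @param cfg A [synth_config()].
#' @param mode Seed-site convention (default `"7mer-m8"`).
#' @return A list with `snps` (SNP tibble), `sequences` (named character),
#'   `mirna_seqs`, `motifs`, and `truth` (tibble `snp_id`, `element_id`,
#'   `element_kind`, `effect`).
#' @export
gen_snp_fixture <- function(lncrna_ids, cfg, mode = "7mer-m8") {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(lncrna_ids) < 1) {
    abort("need at least one lncRNA", class = "cernet_invalid_config")
  }
  set.seed(derive_seed(cfg$seed, "snp"))
  block <- 30L
  # distinct miRNA pool; redraw until all seed sites are unique
  repeat {
    mirna_seqs <- setNames(vapply(seq_len(cfg$n_mirnas),
                                  function(i) rand_seq(22), character(1)),
                           sprintf("miR-%02d", seq_len(cfg$n_mirnas)))
    sites <- vapply(mirna_seqs, function(s) revcomp(substr(s, 2, 8)),
                    character(1))
    if (!anyDuplicated(sites)) break
  }
  motifs <- c(TF_ERGL = "AGGAWG", TF_PPARGL = "TGACCTY", TF_CREBL = "TGACGTCA")

  n <- cfg$n_snps
  if (n == 0) {
    return(list(snps = tibble(), sequences = setNames(
      vapply(lncrna_ids, function(i) rand_seq(cfg$seq_length), character(1)),
      lncrna_ids), mirna_seqs = mirna_seqs, motifs = motifs,
      truth = tibble()))
  }
  snp_lnc <- sample(lncrna_ids, n, replace = TRUE)
  classes <- sample(names(cfg$region_class_weights), n, replace = TRUE,
                    prob = cfg$region_class_weights)
  ld <- ifelse(runif(n) < 0.3, NA_real_, runif(n))
  planted <- (classes %in% c("lncRNA", "TFBS")) &
    (runif(n) < cfg$planted_event_fraction)

  # one block per SNP within its transcript
  blk <- stats::ave(seq_len(n), snp_lnc, FUN = seq_along)
  seq_len_needed <- vapply(lncrna_ids, function(l) {
    max(cfg$seq_length, block * (sum(snp_lnc == l) + 1L))
  }, numeric(1))
  sequences <- setNames(lapply(lncrna_ids, function(l) {
    strsplit(rand_seq(seq_len_needed[[l]]), "")[[1]]
  }), lncrna_ids)

  nt <- c("A", "C", "G", "T")
  truth <- list()
  snps <- vector("list", n)
  for (i in seq_len(n)) {
    l <- snp_lnc[i]
    s0 <- (blk[i] - 1L) * block           # 0-based block start
    ok <- FALSE
    for (try in 1:60) {
      seq_chars <- sequences[[l]]
      # reset block to fresh random bases
      seq_chars[(s0 + 1):(s0 + block)] <- sample(nt, block, replace = TRUE)
      if (planted[i] && classes[i] == "lncRNA") {
        mid <- sample(names(mirna_seqs), 1)
        site <- strsplit(revcomp(substr(mirna_seqs[[mid]], 2, 8)), "")[[1]]
        p0 <- s0 + 10L                     # 0-based site start
        j <- sample(0:6, 1)
        pos0 <- p0 + j
        effect <- sample(c("gain", "loss"), 1)
        seq_chars[(p0 + 1):(p0 + 7)] <- site
        if (effect == "gain") {
          ref <- sample(setdiff(nt, site[j + 1]), 1); alt <- site[j + 1]
          seq_chars[pos0 + 1] <- ref
        } else {
          ref <- site[j + 1]; alt <- sample(setdiff(nt, ref), 1)
        }
        planned <- tibble(element_id = mid, element_kind = "mirna_site",
                          effect = effect)
      } else if (planted[i] && classes[i] == "TFBS") {
        tid <- sample(names(motifs), 1)
        mot <- strsplit(motifs[[tid]], "")[[1]]
        inst <- vapply(mot, function(ch) sample(iupac_allowed(ch), 1),
                       character(1))
        degenerate <- which(vapply(mot, function(ch)
          length(iupac_allowed(ch)) < 4, logical(1)))
        j <- sample(degenerate, 1) - 1L    # 0-based offset in motif
        p0 <- s0 + 10L
        pos0 <- p0 + j
        effect <- sample(c("gain", "loss"), 1)
        seq_chars[(p0 + 1):(p0 + length(mot))] <- inst
        allowed <- iupac_allowed(mot[j + 1])
        if (effect == "gain") {
          ref <- sample(setdiff(nt, allowed), 1); alt <- inst[j + 1]
          seq_chars[pos0 + 1] <- ref
        } else {
          ref <- inst[j + 1]; alt <- sample(setdiff(nt, allowed), 1)
        }
        planned <- tibble(element_id = tid, element_kind = "tfbs",
                          effect = effect)
      } else {
        pos0 <- s0 + 10L
        ref <- seq_chars[pos0 + 1]
        alt <- sample(setdiff(nt, ref), 1)
        planned <- tibble()
      }
      seq_str <- paste(seq_chars, collapse = "")
      got <- scan_events(seq_str, pos0 + 1L, ref, alt, mirna_seqs, motifs,
                         mode)
      match_ok <- if (nrow(planned) == 0) nrow(got) == 0 else {
        nrow(got) == nrow(planned) &&
          all(paste(got$element_id, got$element_kind, got$effect) %in%
                paste(planned$element_id, planned$element_kind,
                      planned$effect))
      }
      if (match_ok) {
        sequences[[l]] <- seq_chars
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("failed to certify a planted SNP window after 60 attempts",
            class = "cernet_generator_error")
    }
    sid <- sprintf("rs%05d", i)
    snps[[i]] <- tibble(snp_id = sid, lncrna_id = l, pos = pos0,
                        ref = ref, alt = alt, region_class = classes[i],
                        ld_r2 = ld[i])
    if (nrow(planned) > 0) {
      truth[[length(truth) + 1]] <- mutate(planned, snp_id = sid,
                                           .before = 1)
    }
  }
  list(snps = bind_rows(snps),
       sequences = setNames(vapply(sequences, paste, character(1),
                                   collapse = ""), lncrna_ids),
       mirna_seqs = mirna_seqs, motifs = motifs,
       truth = if (length(truth) > 0) bind_rows(truth) else
         tibble(snp_id = character(), element_id = character(),
                element_kind = character(), effect = character()))
}

#' Simulate a complete synthetic study
#'
#' Runs every generator in order (PPI backbone with planted cliques, disease
#' labels, ceRNA edges, expression, SNP fixture) and optionally writes all
#' inputs to disk in the package's plain-text formats (edge/node TSVs,
#' expression + group TSVs, SNP TSV, transcript FASTA, miRNA/motif TSVs,
#' ground-truth JSON).
#'
#' @param cfg A [synth_config()].
#' @param outdir Optional output directory.
#' @return A list with `graph` (typed backbone with labels), `cerna`,
#'   `expression` (+ its `de_truth`), `snp_fixture` and `truth` (planted
#'   cliques, DE genes, site events).
#' @export
simulate_study <- function(cfg = synth_config(), outdir = NULL) {
  ppi <- gen_ppi_network(cfg)
  dis <- gen_disease_sets(ppi$graph, cfg)
  cerna <- gen_cerna_edges(dis$graph, cfg)
  genes <- c(igraph::V(dis$graph)$name, sprintf("L%03d", seq_len(cfg$n_lncrna)))
  expr <- gen_expression(genes, cfg)
  snp <- gen_snp_fixture(sprintf("L%03d", seq_len(cfg$n_lncrna)), cfg)
  out <- list(graph = dis$graph, cerna = cerna,
              expression = expr$matrix,
              snp_fixture = snp,
              truth = list(planted_cliques = ppi$truth$planted_cliques,
                           planted_de = expr$truth,
                           planted_site_events = snp$truth,
                           disease_assignments = dis$assignments))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_typed_graph(out$graph, file.path(outdir, "ppi_edges.tsv"),
                      file.path(outdir, "nodes.tsv"))
    write.table(cerna, file.path(outdir, "cerna_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_expression_tsv(expr$matrix, file.path(outdir, "expression.tsv"),
                         file.path(outdir, "groups.tsv"))
    write.table(snp$snps, file.path(outdir, "snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_transcripts(snp$sequences, file.path(outdir, "transcripts.fa"))
    write.table(tibble(mirna = names(snp$mirna_seqs),
                       sequence = unname(snp$mirna_seqs)),
                file.path(outdir, "mirnas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tibble(tf = names(snp$motifs),
                       consensus = unname(snp$motifs)),
                file.path(outdir, "motifs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(planted_cliques = out$truth$planted_cliques,
           planted_de = out$truth$planted_de,
           planted_site_events = out$truth$planted_site_events,
           disease_assignments = out$truth$disease_assignments),
      file.path(outdir, "ground_truth.json"))
  }
  out
}
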