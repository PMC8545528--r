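#' Pipeline configuration
#'
#' One object driving an end-to-end run: either a [synth_config()] for
#' simulate-first runs or a named list of input paths, plus every stage
#' parameter.
#'
#' @param input A [synth_config()], or a named list of paths with elements
#'   `ppi_edges`, `nodes`, `cerna`, `expression`, `groups`, `snps`,
#'   `transcripts`, `mirnas`, `motifs` (missing elements skip the dependent
#'   stage).
#' @param mcode An [mcode_params()] bundle.
#' @param hub_k Number of hubs (default 50).
#' @param r2_threshold LD filter threshold (default 0.8).
#' @param p_cutoff,fc_cutoff Differential-expression thresholds.
#' @param top_n Modules kept after ranking (default 5).
#' @param collection Optional gene-set collection tibble (see [read_gmt()]);
#'   for synthetic runs a planted collection is generated when omitted.
#' @param seed Master seed for the run (defaults to the synth config's
#'   seed when simulating).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synth_config(),
                            mcode = mcode_params(), hub_k = 50,
                            r2_threshold = 0.8, p_cutoff = 0.05,
                            fc_cutoff = 1.5, top_n = 5,
                            collection = NULL, seed = NULL) {
  if (inherits(input, "synth_config")) {
    seed <- seed %||% input$seed
  } else if (is.list(input)) {
    seed <- seed %||% 1L
    missing_files <- unlist(input)[!file.exists(unlist(input))]
    if (length(missing_files) > 0) {
      abort(sprintf("input path(s) do not exist: %s",
                    paste(missing_files, collapse = ", ")),
            class = "cernet_invalid_config")
    }
  } else {
    abort("`input` must be a synth_config or a list of paths",
          class = "cernet_invalid_config")
  }
  structure(list(input = input, mcode = mcode, hub_k = hub_k,
                 r2_threshold = r2_threshold, p_cutoff = p_cutoff,
                 fc_cutoff = fc_cutoff, top_n = top_n,
                 collection = collection, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Planted gene-set collection for synthetic runs: random background sets
# plus one set matching each planted clique (coding genes only).
synth_collection <- function(graph, cliques, seed) {
  set.seed(derive_seed(seed, "collection"))
  coding <- tg_nodes(graph)$id[tg_nodes(graph)$type != "lncRNA"]
  rand_sets <- lapply(1:8, function(i) sample(coding, min(15, length(coding))))
  sets <- c(
    setNames(rand_sets, sprintf("random_set_%02d", 1:8)),
    setNames(lapply(cliques, identity),
             sprintf("planted_clique_set_%d", seq_along(cliques)))
  )
  tibble(set = names(sets), source = "synthetic", genes = unname(sets))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Run the whole analysis end to end
#'
#' Executes build, topology, module detection, enrichment, expression and
#' variant stages in order and assembles a JSON-serialisable report with
#' every stage's headline outputs and the exact parameters used. A run with
#' a fixed seed is byte-reproducible. Stages whose inputs are absent are
#' recorded as `"skipped"`; a stage failure aborts with the stage name,
#' retaining earlier blocks in the error condition.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Optional directory for the report (`report.json`) and
#'   per-stage JSON blocks.
#' @param resume When `TRUE` and a stage block exists in `outdir`, reuse it
#'   for the report instead of the freshly computed summary.
#' @return A list of class `pipeline_report`: `parameters`, one block per
#'   stage, and `objects` (the in-memory results, not serialised).
#' @export
run_all <- function(cfg = pipeline_config(), outdir = NULL, resume = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  synthetic <- inherits(cfg$input, "synth_config")
  report <- list(parameters = list(
    seed = cfg$seed, synthetic = synthetic,
    mcode = unclass(cfg$mcode), hub_k = cfg$hub_k,
    r2_threshold = cfg$r2_threshold, p_cutoff = cfg$p_cutoff,
    fc_cutoff = cfg$fc_cutoff, top_n = cfg$top_n))
  if (synthetic) {
    report$parameters$synth <-
      cfg$input[setdiff(names(cfg$input), "region_class_weights")]
    report$parameters$synth$region_class_weights <-
      as.list(cfg$input$region_class_weights)
  }
  objects <- list()
  blocks <- list()
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  run_stage <- function(name, fun) {
    cache <- if (!is.null(outdir)) {
      file.path(outdir, paste0("stage_", name, ".json"))
    } else NULL
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "cernet_stage_error",
            report = blocks)
    })
    block <- res$block
    if (isTRUE(resume) && !is.null(cache) && file.exists(cache)) {
      block <- jsonlite::read_json(cache, simplifyVector = TRUE)
    } else if (!is.null(cache)) {
      jsonlite::write_json(block, cache, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
    }
    blocks[[name]] <<- block
    objects <<- c(objects, res$objects)
    invisible(NULL)
  }

  # -- inputs ---------------------------------------------------------------
  if (synthetic) {
    sim <- simulate_study(cfg$input)
    backbone <- sim$graph
    cerna <- sim$cerna
    gene_sets <- rename(sim$truth$disease_assignments, set = "type") |>
      mutate(set = dplyr::recode(.data$set, diabetes = "diabetes_only",
                                 DR = "dr_only", common = "common"))
    expr <- sim$expression
    snpfix <- sim$snp_fixture
    truth <- sim$truth
  } else {
    p <- cfg$input
    backbone <- read_typed_graph(p$ppi_edges, p$nodes)
    cerna <- if (!is.null(p$cerna)) {
      as_tibble(read.delim(p$cerna, colClasses = "character"))
    } else NULL
    gene_sets <- tg_nodes(backbone) |>
      filter(.data$type %in% c("diabetes", "DR", "common")) |>
      mutate(set = dplyr::recode(.data$type, diabetes = "diabetes_only",
                                 DR = "dr_only", common = "common")) |>
      select("id", "set")
    expr <- if (!is.null(p$expression) && !is.null(p$groups)) {
      read_expression_tsv(p$expression, p$groups)
    } else NULL
    snpfix <- if (!is.null(p$snps)) {
      list(snps = validate_snps(read.delim(p$snps)),
           sequences = if (!is.null(p$transcripts)) {
             read_transcripts(p$transcripts)
           } else NULL,
           mirna_seqs = if (!is.null(p$mirnas)) {
             tab <- read.delim(p$mirnas, colClasses = "character")
             setNames(tab$sequence, tab$mirna)
           } else NULL,
           motifs = if (!is.null(p$motifs)) {
             tab <- read.delim(p$motifs, colClasses = "character")
             setNames(tab$consensus, tab$tf)
           } else NULL)
    } else NULL
    truth <- NULL
  }

  # -- build ----------------------------------------------------------------
  run_stage("build", function() {
    built <- build_network(backbone, gene_sets,
                           cerna %||% tibble(lncrna = character(),
                                             gene = character(),
                                             shared_mirnas = character()))
    nd <- tg_nodes(built$graph)
    list(block = list(
      n_nodes = nrow(nd),
      n_edges = nrow(tg_edges(built$graph)),
      node_types = as.list(table(nd$type)),
      dropped_genes = nrow(built$dropped_genes),
      dropped_cerna = nrow(built$dropped_cerna)),
      objects = list(clmn = built$graph))
  })
  clmn <- objects$clmn

  run_stage("topology", function() {
    metrics <- node_metrics(clmn)
    fit_backbone <- fit_power_law(compute_degree(backbone))
    fit_clmn <- tryCatch(glance(fit_power_law(metrics$degree)),
                         error = function(e) NULL)
    comparisons <- suppressWarnings(
      bind_rows(compare_metric_by_type(metrics, "degree"),
                compare_metric_by_type(metrics, "bc"),
                compare_metric_by_type(metrics, "tc")))
    hubs <- select_hubs(metrics, k = cfg$hub_k)
    hub_lnc <- hubs$id[hubs$type == "lncRNA"]
    props <- if (length(hub_lnc) > 0) {
      regulating_proportions(clmn, hub_lnc)
    } else NULL
    list(block = list(
      backbone_powerlaw = as.list(glance(fit_backbone)),
      clmn_powerlaw = if (is.null(fit_clmn)) "undefined" else
        as.list(fit_clmn),
      n_comparisons = nrow(comparisons),
      n_hubs = nrow(hubs),
      n_hub_lncrnas = length(hub_lnc),
      mean_common_regulating_proportion = if (!is.null(props)) {
        mean(props$p_common, na.rm = TRUE)
      } else NA),
      objects = list(metrics = metrics, hubs = hubs,
                     comparisons = comparisons,
                     regulating = props,
                     backbone_fit = fit_backbone))
  })

  run_stage("modules", function() {
    mods <- rank_modules(predict_complexes(backbone, cfg$mcode),
                         top_n = cfg$top_n)
    recovery <- if (!is.null(truth) &&
                    length(truth$planted_cliques) > 0 && nrow(mods) > 0) {
      best <- vapply(truth$planted_cliques, function(cl) {
        max(vapply(mods$members, jaccard, numeric(1), b = cl))
      }, numeric(1))
      mean(best)
    } else NA
    list(block = list(
      n_modules = nrow(mods),
      top_scores = round(mods$score, 6),
      mean_clique_jaccard = recovery),
      objects = list(modules = mods))
  })

  run_stage("enrichment", function() {
    coll <- cfg$collection
    if (is.null(coll) && synthetic) {
      coll <- synth_collection(backbone, truth$planted_cliques, cfg$seed)
    }
    if (is.null(coll) || nrow(objects$modules) == 0) {
      return(list(block = "skipped", objects = list()))
    }
    nd <- tg_nodes(clmn)
    lnc <- nd$id[nd$type == "lncRNA"]
    query <- setdiff(objects$modules$members[[1]], lnc)
    res <- enrich(query, coll, exclude = lnc)
    list(block = list(
      query_size = length(query),
      n_sets = nrow(res),
      top_set = if (nrow(res) > 0) res$set[1] else NA,
      top_p_adjust = if (nrow(res) > 0) res$p_adjust[1] else NA),
      objects = list(enrichment = res))
  })

  run_stage("expression", function() {
    if (is.null(expr)) return(list(block = "skipped", objects = list()))
    de <- differential_expression(expr, p_cutoff = cfg$p_cutoff,
                                  fc_cutoff = cfg$fc_cutoff)
    pairs <- if (!is.null(cerna)) {
      filter(distinct(as_tibble(cerna), .data$lncrna, .data$gene),
             .data$lncrna %in% rownames(expr$values),
             .data$gene %in% rownames(expr$values))
    } else tibble(lncrna = character(), gene = character())
    coex <- if (nrow(pairs) > 0) {
      coexpression(pairs, log2_transform(expr), p_cutoff = cfg$p_cutoff)
    } else NULL
    list(block = list(
      n_genes = nrow(de),
      n_significant = sum(de$significant),
      n_pairs = if (is.null(coex)) 0 else nrow(coex),
      n_coexpressed = if (is.null(coex)) 0 else sum(coex$significant)),
      objects = list(de = de, coexpression = coex))
  })

  run_stage("variants", function() {
    if (is.null(snpfix) || is.null(snpfix$snps) || nrow(snpfix$snps) == 0) {
      return(list(block = "skipped", objects = list()))
    }
    kept <- ld_filter(snpfix$snps, r2_threshold = cfg$r2_threshold)
    events <- if (!is.null(snpfix$sequences)) {
      call_site_events(kept, snpfix$sequences, snpfix$mirna_seqs,
                       snpfix$motifs)
    } else tibble()
    snp_map <- build_snp_map(kept, clmn)
    disr <- if (nrow(events) > 0) {
      lnc_in_graph <- tg_nodes(clmn)$id[tg_nodes(clmn)$type == "lncRNA"]
      ev_known <- filter(
        left_join(events, select(snpfix$snps, "snp_id", "lncrna_id"),
                  by = "snp_id"),
        .data$lncrna_id %in% lnc_in_graph)
      cerna_disruption(select(ev_known, -"lncrna_id"), clmn, snpfix$snps)
    } else NULL
    list(block = list(
      n_snps_input = nrow(snpfix$snps),
      n_snps_after_ld = nrow(kept),
      n_events = nrow(events),
      n_gain = if (nrow(events) > 0) sum(events$effect == "gain") else 0L,
      n_loss = if (nrow(events) > 0) sum(events$effect == "loss") else 0L,
      fraction_lncrnas_with_snps = snp_map$fraction_with_snps,
      n_disrupted = if (is.null(disr) || nrow(disr) == 0) 0L else
        sum(disr$status == "disrupted")),
      objects = list(events = events, snp_map = snp_map,
                     disruptions = disr))
  })

  report <- c(report, blocks)
  out <- structure(list(report = report, objects = objects,
                        truth = truth), class = "pipeline_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:",
      paste(setdiff(names(x$report), "parameters"), collapse = ", "), "\n")
  invisible(x)
}
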