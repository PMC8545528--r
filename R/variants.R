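#' SNP table validation
#'
#' A SNP table has columns `snp_id`, `lncrna_id`, `pos` (0-based offset;
#' transcript coordinates for lncRNA-body SNPs), `ref`, `alt` (single
#' nucleotides), `region_class` (one of the regulatory catalog classes:
#' enhancer, TFBS, lncRNA, DHS, open_chromatin, footprint, TAD) and `ld_r2`
#' (squared LD with the lead SNP; `NA` for lead SNPs themselves).
#'
#' @param snps A data frame with the columns above.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_snps <- function(snps) {
  snps <- as_tibble(snps)
  need <- c("snp_id", "lncrna_id", "pos", "ref", "alt", "region_class",
            "ld_r2")
  miss <- setdiff(need, names(snps))
  if (length(miss) > 0) {
    abort(sprintf("SNP table missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "cernet_invalid_input")
  }
  nt <- c("A", "C", "G", "T")
  if (!all(snps$ref %in% nt) || !all(snps$alt %in% nt)) {
    abort("alleles must be single nucleotides A/C/G/T",
          class = "cernet_invalid_input")
  }
  if (any(snps$ref == snps$alt)) {
    abort("ref and alt alleles must differ", class = "cernet_invalid_input")
  }
  r2 <- snps$ld_r2[!is.na(snps$ld_r2)]
  if (any(r2 < 0 | r2 > 1)) {
    abort("ld_r2 must be in [0, 1]", class = "cernet_invalid_input")
  }
  snps
}

#' Filter SNPs by linkage disequilibrium
#'
#' Retains lead SNPs (missing `ld_r2`) and LD SNPs with `ld_r2` strictly
#' above the threshold (`r2 > 0.8` by default); `inclusive = TRUE` switches
#' to `>=`.
#'
#' @param snps A SNP tibble (see [validate_snps()]).
#' @param r2_threshold LD threshold (default 0.8).
#' @param inclusive Use `>=` instead of `>`.
#' @return The filtered tibble.
#' @export
ld_filter <- function(snps, r2_threshold = 0.8, inclusive = FALSE) {
  snps <- as_tibble(snps)
  if (nrow(snps) == 0) return(snps)
  keep <- is.na(snps$ld_r2) |
    (if (inclusive) snps$ld_r2 >= r2_threshold else snps$ld_r2 > r2_threshold)
  snps[keep, , drop = FALSE]
}

#' Classify SNPs into regulatory region classes
#'
#' Assigns every SNP each region class whose interval contains it
#' (multi-label: a SNP inside overlapping TFBS and DHS intervals gets both).
#' Intervals are 0-based half-open `[start, end)` per the BED convention and
#' are keyed by lncRNA.
#'
#' @param snps A SNP tibble (`snp_id`, `lncrna_id`, `pos`, ...).
#' @param regions A tibble with columns `lncrna_id`, `region_class`,
#'   `start`, `end`.
#' @return A list with `assignments` (one row per SNP x class:
#'   `snp_id`, `lncrna_id`, `pos`, `region_class`) and `summary`
#'   (per-class counts and proportions of assignments).
#' @export
classify_regions <- function(snps, regions) {
  snps <- as_tibble(snps)
  regions <- as_tibble(regions)
  if (any(regions$end <= regions$start)) {
    abort("malformed interval: end must exceed start",
          class = "cernet_invalid_input")
  }
  bad <- setdiff(unique(regions$region_class), REGION_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown region class(es): %s", paste(bad, collapse = ", ")),
          class = "cernet_invalid_input")
  }
  hits <- dplyr::inner_join(
    select(snps, "snp_id", "lncrna_id", "pos"),
    regions, by = "lncrna_id", relationship = "many-to-many")
  hits <- filter(hits, .data$pos >= .data$start, .data$pos < .data$end)
  assignments <- distinct(select(hits, "snp_id", "lncrna_id", "pos",
                                 "region_class"))
  summary <- count(assignments, .data$region_class, name = "n")
  summary$proportion <- if (nrow(assignments) > 0) {
    summary$n / nrow(assignments)
  } else numeric(0)
  list(assignments = assignments, summary = summary)
}

# Extract the seed-site string a miRNA would imprint on a target:
# reverse complement of the chosen seed positions of the miRNA sequence.
seed_site <- function(mirna_seq, mode = "7mer-m8") {
  if (nchar(mirna_seq) < 8) {
    abort("miRNA sequence shorter than 8 nt", class = "cernet_invalid_input")
  }
  seed <- switch(mode,
                 "7mer-m8" = substr(mirna_seq, 2, 8),
                 "6mer" = substr(mirna_seq, 2, 7),
                 "8mer" = substr(mirna_seq, 1, 8),
                 abort("mode must be one of 7mer-m8, 6mer, 8mer",
                       class = "cernet_invalid_config"))
  revcomp(seed)
}

# All 1-based start positions of fixed string `site` in `seq`.
site_positions <- function(seq, site) {
  if (nchar(seq) < nchar(site)) return(integer(0))
  m <- gregexpr(site, seq, fixed = TRUE)[[1]]
  m[m > 0]
}

apply_allele <- function(sequence, pos1, allele) {
  paste0(substr(sequence, 1, pos1 - 1), allele,
         substr(sequence, pos1 + 1, nchar(sequence)))
}

#' Call allele-dependent miRNA seed sites at a SNP
#'
#' Scans a window around the SNP for exact matches to the reverse complement
#' of each miRNA's seed (positions 2-8 of the miRNA, the 7mer-m8 convention,
#' by default) under both alleles. A `gain` is emitted when the site is
#' present under the alternate allele only, a `loss` when present under the
#' reference allele only; sites present under both alleles (i.e. not
#' overlapping the SNP) produce no event.
#'
#' @param sequence The lncRNA transcript sequence (sense strand, A/C/G/T).
#' @param snp A one-row SNP tibble; its `region_class` must include `lncRNA`.
#' @param mirna_seqs Named character vector: miRNA id to miRNA sequence
#'   (5' to 3', at least 8 nt).
#' @param mode Seed-match convention: `"7mer-m8"` (default), `"6mer"` or
#'   `"8mer"`.
#' @param window Half-width of the scanned window (default 7 nt each side).
#' @return A tibble of site events: `snp_id`, `element_id`, `element_kind`,
#'   `effect`, `allele`, `site_start` (0-based transcript offset).
#' @export
mirna_site_call <- function(sequence, snp, mirna_seqs, mode = "7mer-m8",
                            window = 7L) {
  snp <- as_tibble(snp)
  stopifnot(nrow(snp) == 1)
  if (!any(strsplit(snp$region_class, ",")[[1]] == "lncRNA")) {
    abort("SNP region_class must include 'lncRNA' for miRNA-site calling",
          class = "cernet_invalid_input")
  }
  pos1 <- snp$pos + 1L
  if (pos1 < 1 || pos1 > nchar(sequence)) {
    abort("SNP position outside the transcript sequence",
          class = "cernet_invalid_input")
  }
  lo <- max(1L, pos1 - window)
  hi <- min(nchar(sequence), pos1 + window)
  win_ref <- substr(apply_allele(sequence, pos1, snp$ref), lo, hi)
  win_alt <- substr(apply_allele(sequence, pos1, snp$alt), lo, hi)
  purrr::map_dfr(names(mirna_seqs), function(id) {
    site <- seed_site(mirna_seqs[[id]], mode)
    in_ref <- site_positions(win_ref, site)
    in_alt <- site_positions(win_alt, site)
    if (length(in_alt) > 0 && length(in_ref) == 0) {
      tibble(snp_id = snp$snp_id, element_id = id,
             element_kind = "mirna_site", effect = "gain",
             allele = snp$alt, site_start = lo - 1L + in_alt[1] - 1L)
    } else if (length(in_ref) > 0 && length(in_alt) == 0) {
      tibble(snp_id = snp$snp_id, element_id = id,
             element_kind = "mirna_site", effect = "loss",
             allele = snp$ref, site_start = lo - 1L + in_ref[1] - 1L)
    } else {
      tibble()
    }
  })
}

#' Call allele-dependent transcription-factor motifs at a SNP
#'
#' Matches each IUPAC consensus within `motif length - 1` of the SNP under
#' both alleles; gain/loss semantics as in [mirna_site_call()].
#'
#' @param sequence The sequence carrying the TFBS region (A/C/G/T).
#' @param snp A one-row SNP tibble; its `region_class` must include `TFBS`.
#' @param motifs Named character vector: TF id to IUPAC consensus.
#' @return A tibble of site events (`element_kind = "tfbs"`).
#' @export
tfbs_call <- function(sequence, snp, motifs) {
  snp <- as_tibble(snp)
  stopifnot(nrow(snp) == 1)
  if (!any(strsplit(snp$region_class, ",")[[1]] == "TFBS")) {
    abort("SNP region_class must include 'TFBS' for motif calling",
          class = "cernet_invalid_input")
  }
  pos1 <- snp$pos + 1L
  if (pos1 < 1 || pos1 > nchar(sequence)) {
    abort("SNP position outside the sequence",
          class = "cernet_invalid_input")
  }
  purrr::map_dfr(names(motifs), function(id) {
    pat <- iupac_regex(motifs[[id]])
    len <- nchar(motifs[[id]])
    lo <- max(1L, pos1 - (len - 1L))
    hi <- min(nchar(sequence), pos1 + (len - 1L))
    win_ref <- substr(apply_allele(sequence, pos1, snp$ref), lo, hi)
    win_alt <- substr(apply_allele(sequence, pos1, snp$alt), lo, hi)
    ref_hit <- regexpr(pat, win_ref)[1]
    alt_hit <- regexpr(pat, win_alt)[1]
    if (alt_hit > 0 && ref_hit < 0) {
      tibble(snp_id = snp$snp_id, element_id = id, element_kind = "tfbs",
             effect = "gain", allele = snp$alt,
             site_start = lo - 1L + alt_hit - 1L)
    } else if (ref_hit > 0 && alt_hit < 0) {
      tibble(snp_id = snp$snp_id, element_id = id, element_kind = "tfbs",
             effect = "loss", allele = snp$ref,
             site_start = lo - 1L + ref_hit - 1L)
    } else {
      tibble()
    }
  })
}

#' Call all site events over a SNP table
#'
#' Convenience driver: applies [mirna_site_call()] to SNPs whose class
#' includes `lncRNA` and [tfbs_call()] to SNPs whose class includes `TFBS`,
#' using each SNP's linked lncRNA transcript.
#'
#' @param snps A SNP tibble.
#' @param sequences Named character vector of transcript sequences by
#'   lncRNA id.
#' @param mirna_seqs,motifs As in [mirna_site_call()] and [tfbs_call()].
#' @inheritParams mirna_site_call
#' @return A tibble of site events.
#' @export
call_site_events <- function(snps, sequences, mirna_seqs = NULL,
                             motifs = NULL, mode = "7mer-m8") {
  snps <- validate_snps(snps)
  purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    seqs <- sequences[[snp$lncrna_id]]
    if (is.null(seqs)) return(tibble())
    classes <- strsplit(snp$region_class, ",")[[1]]
    out <- list()
    if ("lncRNA" %in% classes && length(mirna_seqs) > 0) {
      out$mir <- mirna_site_call(seqs, snp, mirna_seqs, mode = mode)
    }
    if ("TFBS" %in% classes && length(motifs) > 0) {
      out$tf <- tfbs_call(seqs, snp, motifs)
    }
    bind_rows(out)
  })
}

#' ceRNA-edge consequences of site gain/loss events
#'
#' An existing ceRNA edge is `disrupted` when loss events remove the sites of
#' *all* miRNAs it shares; a new lncRNA-gene relation is `created` when gain
#' events establish at least one miRNA shared with a coding gene's annotated
#' miRNA set (`rule = "any"`; `rule = "all"` requires every annotated miRNA
#' of the gene to be gained) and no edge exists yet. Everything else is
#' `unchanged`.
#'
#' @param events A site-event tibble from [call_site_events()]; each event's
#'   SNP must be linked to an lncRNA present in the graph.
#' @param g A `typed_graph` whose `cerna` edges carry shared-miRNA lists.
#' @param snps The SNP tibble (to map events to lncRNAs).
#' @param gene_mirnas A tibble with columns `gene`, `mirna`: the annotated
#'   miRNA set of each coding gene (used for `created` calls).
#' @param rule `"any"` (default) or `"all"` for `created` calls.
#' @return A tibble: `lncrna`, `gene`, `shared_mirnas`, `status`
#'   (`created` / `disrupted` / `unchanged`), `causal_snps`.
#' @export
cerna_disruption <- function(events, g, snps, gene_mirnas = NULL,
                             rule = c("any", "all")) {
  rule <- match.arg(rule)
  events <- as_tibble(events)
  snps <- as_tibble(snps)
  nd <- tg_nodes(g)
  if (nrow(events) > 0) {
    events <- left_join(events, select(snps, "snp_id", "lncrna_id"),
                        by = "snp_id")
    unknown <- setdiff(unique(events$lncrna_id),
                       nd$id[nd$type == "lncRNA"])
    if (length(unknown) > 0) {
      abort(sprintf("events reference lncRNAs absent from the graph: %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "cernet_invalid_input")
    }
  } else {
    events$lncrna_id <- character(0)
  }
  mir_events <- filter(events, .data$element_kind == "mirna_site")

  ed <- filter(tg_edges(g), .data$kind == "cerna")
  ed$lncrna <- ifelse(nd$type[match(ed$from, nd$id)] == "lncRNA",
                      ed$from, ed$to)
  ed$gene <- ifelse(ed$lncrna == ed$from, ed$to, ed$from)

  empty_out <- tibble(lncrna = character(), gene = character(),
                      shared_mirnas = character(), status = character(),
                      causal_snps = character())
  existing <- purrr::map_dfr(seq_len(nrow(ed)), function(i) {
    shared <- strsplit(ed$shared_mirnas[i], ",")[[1]]
    losses <- filter(mir_events, .data$lncrna_id == ed$lncrna[i],
                     .data$effect == "loss", .data$element_id %in% shared)
    disrupted <- length(shared) > 0 &&
      all(shared %in% losses$element_id)
    tibble(lncrna = ed$lncrna[i], gene = ed$gene[i],
           shared_mirnas = ed$shared_mirnas[i],
           status = if (disrupted) "disrupted" else "unchanged",
           causal_snps = if (disrupted) {
             paste(sort(unique(losses$snp_id)), collapse = ",")
           } else "")
  })

  created <- tibble()
  gains <- filter(mir_events, .data$effect == "gain")
  if (!is.null(gene_mirnas) && nrow(gains) > 0) {
    gene_mirnas <- as_tibble(gene_mirnas)
    created <- purrr::map_dfr(unique(gains$lncrna_id), function(l) {
      gained <- filter(gains, .data$lncrna_id == l)
      purrr::map_dfr(unique(gene_mirnas$gene), function(gn) {
        annot <- gene_mirnas$mirna[gene_mirnas$gene == gn]
        shared <- intersect(gained$element_id, annot)
        ok <- if (rule == "any") length(shared) >= 1 else {
          length(annot) > 0 && all(annot %in% gained$element_id)
        }
        has_edge <- any(ed$lncrna == l & ed$gene == gn)
        if (!ok || has_edge) return(tibble())
        causal <- gained$snp_id[gained$element_id %in% shared]
        tibble(lncrna = l, gene = gn,
               shared_mirnas = paste(sort(shared), collapse = ","),
               status = "created",
               causal_snps = paste(sort(unique(causal)), collapse = ","))
      })
    })
  }
  bind_rows(empty_out, existing, created)
}

#' Global lncRNA-SNP association map
#'
#' Summarises SNP load over the lncRNAs of a network: per-lncRNA SNP counts
#' by region class, the fraction of lncRNA nodes carrying at least one SNP,
#' and the per-class proportions of all assignments (multi-label SNPs count
#' once per class).
#'
#' @param snps A SNP tibble (or the `assignments` table of
#'   [classify_regions()]).
#' @param g A `typed_graph`.
#' @return A list with `per_lncrna` (tibble: `lncrna_id`, `region_class`,
#'   `n_snps`, `snp_ids`), `fraction_with_snps` and `class_proportions`.
#' @export
build_snp_map <- function(snps, g) {
  snps <- as_tibble(snps)
  nd <- tg_nodes(g)
  lnc <- nd$id[nd$type == "lncRNA"]
  per <- snps |>
    tidyr::separate_longer_delim("region_class", delim = ",") |>
    group_by(.data$lncrna_id, .data$region_class) |>
    summarise(n_snps = dplyr::n_distinct(.data$snp_id),
              snp_ids = paste(sort(unique(.data$snp_id)), collapse = ","),
              .groups = "drop")
  with_snps <- intersect(lnc, unique(snps$lncrna_id))
  cls <- per |>
    group_by(.data$region_class) |>
    summarise(n = sum(.data$n_snps), .groups = "drop")
  cls$proportion <- if (sum(cls$n) > 0) cls$n / sum(cls$n) else numeric(0)
  list(per_lncrna = per,
       fraction_with_snps = if (length(lnc) > 0) {
         length(with_snps) / length(lnc)
       } else NA_real_,
       class_proportions = cls)
}

#' Read / write transcript FASTA
#'
#' @param path FASTA path.
#' @return `read_transcripts()`: a named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_transcripts
#' @param sequences Named character vector of sequences.
#' @export
write_transcripts <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(sequences)
}
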