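#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join anti_join bind_rows n distinct rename count pull across desc
#' @importFrom tibble tibble as_tibble
#' @importFrom stats lm coef phyper p.adjust t.test wilcox.test cor.test
#'   rnorm runif rpois setNames
#' @importFrom utils head read.delim write.table
NULL

NODE_TYPES <- c("lncRNA", "diabetes", "DR", "common", "other")
EDGE_KINDS <- c("ppi", "cerna")
REGION_CLASSES <- c("enhancer", "TFBS", "lncRNA", "DHS",
                    "open_chromatin", "footprint", "TAD")

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate an IUPAC consensus into an anchored regular expression.
iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC code(s) in motif '%s': %s",
                  motif, paste(unique(bad), collapse = ", ")),
          class = "cernet_invalid_motif")
  }
  paste0(IUPAC_MAP[chars], collapse = "")
}

# Derive a per-stage seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(ppi = 101L, disease = 211L, cerna = 307L, expression = 401L,
               snp = 503L, pipeline = 601L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 701L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Positive scalar check used by config validators.
chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "cernet_invalid_config")
  }
  invisible(as.integer(x))
}

chk_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name),
          class = "cernet_invalid_config")
  }
  invisible(x)
}
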