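#' Expression matrices with case/control groups
#'
#' A light container pairing a non-negative genes-by-samples matrix with a
#' sample-to-group map (`case` vs `control`). Values are treated as
#' already-normalised abundances.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids). No missing values.
#' @param groups Named character vector or tibble (`sample`, `group`)
#'   mapping every sample to `"case"` or `"control"`.
#' @return A list of class `expression_matrix` with elements `values` and
#'   `groups` (tibble).
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyNA(values)) {
    abort("expression matrix contains missing values",
          class = "cernet_invalid_input")
  }
  if (any(values < 0)) {
    abort("expression values must be non-negative",
          class = "cernet_invalid_input")
  }
  if (!is.data.frame(groups)) {
    groups <- tibble(sample = names(groups), group = unname(groups))
  }
  groups <- as_tibble(groups)
  stopifnot(all(c("sample", "group") %in% names(groups)))
  if (!setequal(groups$sample, colnames(values))) {
    abort("group map must cover exactly the matrix samples",
          class = "cernet_invalid_input")
  }
  if (!all(groups$group %in% c("case", "control"))) {
    abort("groups must be 'case' or 'control'",
          class = "cernet_invalid_input")
  }
  structure(list(values = values,
                 groups = groups[match(colnames(values), groups$sample), ]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups$group == "case"),
              sum(x$groups$group == "control")))
  invisible(x)
}

#' Log2-transform an expression matrix
#'
#' Applies `x -> log2(x + pseudocount)` element-wise.
#'
#' @param m An `expression_matrix`.
#' @param pseudocount Added before the log (default 1).
#' @return An `expression_matrix` on the log2 scale.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (any(m$values < 0)) {
    abort("negative values cannot be log-transformed",
          class = "cernet_invalid_input")
  }
  out <- m
  out$values <- log2(m$values + pseudocount)
  class(out$values) <- class(m$values)
  out
}

#' Differential expression by t-test and fold change
#'
#' Per-gene two-sided t-test between case and control samples on log2-scale
#' values (the classic pooled-variance Student's test by default; Welch via
#' `var_equal = FALSE`), combined with a linear-scale fold-change gate. A gene
#' is significant iff `p < p_cutoff` and its fold change (case mean over
#' control mean, linear scale) is `>= fc_cutoff` or `<= 1/fc_cutoff`.
#' BH-adjusted p-values are reported for reference but do not drive the
#' significance flag.
#'
#' @param m An `expression_matrix` on the linear scale.
#' @param p_cutoff,fc_cutoff Significance thresholds (defaults 0.05 and 1.5).
#' @param pseudocount Pseudocount for the internal log2 transform.
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` switches to Welch.
#' @return A tibble with one row per gene: `gene`, `mean_case`,
#'   `mean_control`, `fc`, `log2_fc`, `statistic`, `p_value`, `p_adjust`,
#'   `significant`. Genes with zero variance in both groups and equal means
#'   get `p = 1` by convention; a zero control mean yields `fc = Inf`.
#' @export
differential_expression <- function(m, p_cutoff = 0.05, fc_cutoff = 1.5,
                                    pseudocount = 1, var_equal = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  case <- m$groups$sample[m$groups$group == "case"]
  ctrl <- m$groups$sample[m$groups$group == "control"]
  if (length(case) < 2 || length(ctrl) < 2) {
    abort("need >= 2 samples per group for the t-test",
          class = "cernet_invalid_input")
  }
  lv <- log2(m$values + pseudocount)
  res <- purrr::map_dfr(rownames(m$values), function(g) {
    xc <- lv[g, case]; xk <- lv[g, ctrl]
    if (stats::sd(xc) == 0 && stats::sd(xk) == 0) {
      tt <- list(statistic = if (mean(xc) == mean(xk)) 0 else Inf,
                 p.value = if (mean(xc) == mean(xk)) 1 else 0)
    } else {
      ht <- t.test(xc, xk, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    mc <- mean(m$values[g, case]); mk <- mean(m$values[g, ctrl])
    fc <- if (mk == 0) Inf else mc / mk
    tibble(gene = g, mean_case = mc, mean_control = mk,
           fc = fc, log2_fc = log2(fc),
           statistic = tt$statistic, p_value = tt$p.value)
  })
  res$p_adjust <- p.adjust(res$p_value, method = "BH")
  mutate(res, significant = .data$p_value < p_cutoff &
           (.data$fc >= fc_cutoff | .data$fc <= 1 / fc_cutoff))
}

#' ceRNA coexpression by Pearson correlation
#'
#' Pearson correlation of each lncRNA-gene pair across all samples, with the
#' usual t-distributed test (`t = r sqrt((n-2)/(1-r^2))`, `n - 2` df,
#' two-sided). Pairs involving a constant vector get `NA` with a warning.
#'
#' @param pairs A tibble with columns `lncrna` and `gene`.
#' @param m An `expression_matrix` (log2-transformed values recommended).
#' @param p_cutoff Significance threshold (default 0.05).
#' @return A tibble: `lncrna`, `gene`, `r`, `p_value`, `significant`.
#' @export
coexpression <- function(pairs, m, p_cutoff = 0.05) {
  stopifnot(inherits(m, "expression_matrix"))
  pairs <- as_tibble(pairs)
  if (ncol(m$values) < 3) {
    abort("need >= 3 samples for correlation testing",
          class = "cernet_invalid_input")
  }
  missing <- setdiff(unique(c(pairs$lncrna, pairs$gene)),
                     rownames(m$values))
  if (length(missing) > 0) {
    abort(sprintf("pair members not in the matrix: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "cernet_invalid_input")
  }
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- m$values[pairs$lncrna[i], ]; y <- m$values[pairs$gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn(sprintf("constant expression for pair %s-%s; correlation undefined",
                   pairs$lncrna[i], pairs$gene[i]))
      return(tibble(lncrna = pairs$lncrna[i], gene = pairs$gene[i],
                    r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(lncrna = pairs$lncrna[i], gene = pairs$gene[i],
           r = unname(ct$estimate), p_value = ct$p.value)
  })
  mutate(res, significant = !is.na(.data$p_value) & .data$p_value < p_cutoff)
}

#' Read / write expression matrices as TSV
#'
#' The matrix TSV has genes as rows (first column `gene`) and samples as
#' columns; the group TSV has columns `sample` and `group`.
#'
#' @param matrix_path,groups_path File paths.
#' @export
read_expression_tsv <- function(matrix_path, groups_path) {
  tab <- read.delim(matrix_path, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  groups <- as_tibble(read.delim(groups_path, colClasses = "character"))
  expression_matrix(vals, groups)
}

#' @rdname read_expression_tsv
#' @param m An `expression_matrix`.
#' @export
write_expression_tsv <- function(m, matrix_path, groups_path) {
  tab <- data.frame(gene = rownames(m$values), m$values,
                    check.names = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$groups, groups_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(m)
}
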