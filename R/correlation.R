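#' Pearson correlation between circRNAs and their parent genes
#'
#' For every (circRNA, parent gene) pair, the Pearson coefficient and its
#' two-sided t-transform p-value are computed across all shared samples.
#' Pairs with zero variance in either vector get an NA coefficient and are
#' excluded from downstream summaries. circRNAs with several parent genes
#' contribute one record per gene.
#'
#' @param circ_expr circRNA expression matrix (RPM, features x samples).
#' @param gene_expr gene expression matrix (FPKM, genes x samples) with the
#'   same sample columns.
#' @param map data.frame with circ_id, gene_id (e.g. from
#'   [assign_parent_genes()]).
#' @param p_max significance threshold (unadjusted, default 0.05).
#' @param adjust apply BH adjustment before thresholding (off by default).
#' @return data.frame with circ_id, gene_id, r, p, n, significant.
#' @export
pair_correlation <- function(circ_expr, gene_expr, map, p_max = 0.05,
                             adjust = FALSE) {
  shared <- intersect(colnames(circ_expr), colnames(gene_expr))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples for correlation", call. = FALSE)
  keep <- map$circ_id %in% rownames(circ_expr) &
    map$gene_id %in% rownames(gene_expr)
  map <- map[keep, , drop = FALSE]
  n <- length(shared)
  r <- vapply(seq_len(nrow(map)), function(i) {
    x <- circ_expr[map$circ_id[i], shared]
    y <- gene_expr[map$gene_id[i], shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1))
  p <- pearson_p(r, n)
  padj <- if (adjust) adjust_bh(p) else p
  data.frame(circ_id = map$circ_id, gene_id = map$gene_id,
             r = r, p = p, n = n,
             significant = !is.na(p) & padj <= p_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sign and significance proportions of circRNA/parent-gene correlations
#'
#' For each class of circRNAs, reports the positive and negative proportions
#' among all defined pairs and among significant pairs. Exact zeros count as
#' positive (a measure-zero tie rule). Classes with no defined records are
#' omitted with a warning.
#'
#' @param records a [pair_correlation()] table.
#' @param class_sets named list of circ_id vectors; a row for all records is
#'   always included under class `all`.
#' @return data.frame with class, n_pairs, pct_positive, pct_negative,
#'   n_significant, pct_sig_positive, pct_sig_negative (percentages).
#' @export
summarize_correlation <- function(records, class_sets = NULL) {
  records <- records[!is.na(records$r), , drop = FALSE]
  sets <- c(list(all = unique(records$circ_id)), class_sets)
  rows <- lapply(names(sets), function(nm) {
    rec <- records[records$circ_id %in% sets[[nm]], , drop = FALSE]
    if (!nrow(rec)) {
      warning(sprintf("class '%s' has no defined correlation records", nm))
      return(NULL)
    }
    pos <- rec$r >= 0
    sig <- rec$significant
    data.frame(class = nm, n_pairs = nrow(rec),
               pct_positive = 100 * mean(pos),
               pct_negative = 100 * mean(!pos),
               n_significant = sum(sig),
               pct_sig_positive = if (any(sig)) 100 * mean(pos[sig]) else NA_real_,
               pct_sig_negative = if (any(sig)) 100 * mean(!pos[sig]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
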