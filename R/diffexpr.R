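#' Exact binomial differential-expression test for two pooled libraries
#'
#' Replicates are pooled within each group; conditional on the total
#' back-spliced reads of a feature, the count in group A is binomial with
#' null proportion `n_a / (n_a + n_b)` (the library-size share). The
#' two-sided p-value doubles the smaller tail (capped at 1). The log2 fold
#' change compares the two rates with a pseudo-rate
#' `eps = 0.5 / min(n_a, n_b)` guarding zeros.
#'
#' @param count_a,count_b pooled feature counts per group (vectors).
#' @param n_a,n_b pooled library sizes (total mapped reads) per group.
#' @return data.frame with columns `log2fc` and `p`. Features with zero
#'   counts in both groups get NA in both columns.
#' @export
de_test <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("library sizes must be positive", call. = FALSE)
  # merged catalog counts are caller averages, so halves occur; the exact
  # binomial needs integers
  count_a <- round(as.numeric(count_a)); count_b <- round(as.numeric(count_b))
  tot <- count_a + count_b
  p0 <- n_a / (n_a + n_b)
  lower <- pbinom(count_a, tot, p0)
  upper <- pbinom(count_a - 1, tot, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  eps <- 0.5 / min(n_a, n_b)
  log2fc <- log2((count_a / n_a + eps) / (count_b / n_b + eps))
  none <- tot == 0
  p[none] <- NA_real_
  log2fc[none] <- NA_real_
  data.frame(log2fc = log2fc, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; NA p-values pass through as NA.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed features at fold-change and q thresholds
#'
#' Direction is `up` when `log2fc >= lfc_min` and `q <= q_max`, `down` when
#' `log2fc <= -lfc_min` and `q <= q_max`, otherwise `ns`. Both thresholds are
#' inclusive.
#'
#' @param results data.frame with `log2fc` and `p` (e.g. from [de_test()]);
#'   a `q` column is added if absent.
#' @param lfc_min minimum absolute log2 fold change.
#' @param q_max maximum BH-adjusted p-value.
#' @return the input with `q` and `direction` columns.
#' @export
call_dec <- function(results, lfc_min = 1, q_max = 0.05) {
  if (is.null(results$q)) results$q <- adjust_bh(results$p)
  dir <- rep("ns", nrow(results))
  up <- !is.na(results$q) & results$log2fc >= lfc_min & results$q <= q_max
  dn <- !is.na(results$q) & results$log2fc <= -lfc_min & results$q <= q_max
  dir[up] <- "up"; dir[dn] <- "down"
  dir[is.na(results$p)] <- NA_character_
  results$direction <- dir
  results
}

# pool counts and library sizes over the samples of one or more genotypes;
# group "MPV" pools the two parents
pool_group <- function(counts, design, group) {
  s <- design$samples
  genos <- if (identical(group, "MPV"))
    unique(s$genotype[s$role %in% c("FP", "MP")])
  else group
  cols <- s$sample_id[s$genotype %in% genos]
  if (!length(cols)) stop(sprintf("no samples for group '%s'",
                                  paste(group, collapse = "+")), call. = FALSE)
  list(counts = rowSums(counts[, cols, drop = FALSE]),
       n = sum(design$mapped_reads[cols]))
}

#' Differential expression between two genotype groups
#'
#' Pools replicates per group and applies [de_test()] feature-wise, then BH
#' adjustment and DEC calling. Either group may be `"MPV"`, the mid-parent
#' pseudo-library formed by pooling the female- and male-parent counts and
#' library sizes.
#'
#' @param counts feature x sample count matrix.
#' @param design a `sample_design`.
#' @param group_a,group_b genotype name(s) or `"MPV"`; group A is the
#'   numerator of the fold change.
#' @param lfc_min,q_max DEC thresholds, see [call_dec()].
#' @return data.frame with feature_id, group_a, group_b, count_a, count_b,
#'   n_a, n_b, log2fc, p, q, direction.
#' @export
de_compare <- function(counts, design, group_a, group_b,
                       lfc_min = 1, q_max = 0.05) {
  a <- pool_group(counts, design, group_a)
  b <- pool_group(counts, design, group_b)
  res <- de_test(a$counts, a$n, b$counts, b$n)
  res <- call_dec(res, lfc_min = lfc_min, q_max = q_max)
  data.frame(feature_id = rownames(counts),
             group_a = paste(group_a, collapse = "+"),
             group_b = paste(group_b, collapse = "+"),
             count_a = a$counts, count_b = b$counts,
             n_a = a$n, n_b = b$n,
             log2fc = res$log2fc, p = res$p, q = res$q,
             direction = res$direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test an F1 genotype against the mid-parent value
#'
#' The MPV pseudo-group pools female- and male-parent counts and library
#' sizes, so its rate estimate is `(k_FP + k_MP) / (n_FP + n_MP)`; the F1
#' pooled counts are tested against it with [de_test()].
#'
#' @param counts feature x sample count matrix.
#' @param design a `sample_design` containing both parents.
#' @param f1_genotype one F1 genotype name.
#' @param ... thresholds passed to [de_compare()].
#' @return a [de_compare()] result with group_b = "MPV".
#' @export
mpv_test <- function(counts, design, f1_genotype, ...) {
  de_compare(counts, design, f1_genotype, "MPV", ...)
}
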