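#' RPM-normalize a back-spliced read count matrix
#'
#' RPM (back-spliced reads per million mapped reads) is
#' `counts * 1e6 / mapped_reads`, per sample.
#'
#' @param counts numeric matrix, features x samples.
#' @param mapped_reads named numeric vector of total mapped reads per sample;
#'   names must cover the count matrix columns.
#' @return numeric matrix of RPM values with the same dimnames.
#' @export
rpm_normalize <- function(counts, mapped_reads) {
  if (is.null(colnames(counts)))
    stop("count matrix needs sample column names", call. = FALSE)
  totals <- mapped_reads[colnames(counts)]
  if (any(is.na(totals)))
    stop("mapped_reads missing for some samples", call. = FALSE)
  if (any(totals <= 0))
    stop("mapped-read totals must be positive", call. = FALSE)
  sweep(counts, 2, totals, "/") * 1e6
}

#' Bin RPM values into expression levels
#'
#' Low is below 100 RPM, moderate is 100-500 RPM (both boundaries
#' inclusive), high is above 500 RPM.
#'
#' @param rpm numeric vector of non-negative RPM values.
#' @return factor with levels low, moderate, high.
#' @export
bin_expression <- function(rpm) {
  if (any(rpm < 0, na.rm = TRUE))
    stop("RPM values must be non-negative", call. = FALSE)
  cut(rpm, breaks = c(-Inf, 100, 500, Inf), right = FALSE,
      labels = c("low", "moderate", "high")) -> f
  # right = FALSE puts 100 in moderate but 500 in high; fix the 500 boundary
  f[!is.na(rpm) & rpm == 500] <- "moderate"
  f
}

#' Per-genotype mean expression and mid-parent value
#'
#' Genotype means are arithmetic means of replicate values; the mid-parent
#' value (MPV) is `(mean_FP + mean_MP) / 2` per feature.
#'
#' @param expr expression matrix (features x samples), typically RPM.
#' @param design a `sample_design`.
#' @return list with `means` (features x genotypes matrix) and `mpv`
#'   (named numeric vector).
#' @export
genotype_means_and_mpv <- function(expr, design) {
  s <- design$samples
  if (!all(c("FP", "MP") %in% s$role))
    stop("design must include FP and MP roles", call. = FALSE)
  genos <- unique(s$genotype)
  means <- matrix(vapply(genos, function(g) {
    cols <- s$sample_id[s$genotype == g]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr))), nrow = nrow(expr), ncol = length(genos),
  dimnames = list(rownames(expr), genos))
  fp <- unique(s$genotype[s$role == "FP"])
  mp <- unique(s$genotype[s$role == "MP"])
  mpv <- (means[, fp] + means[, mp]) / 2
  list(means = means, mpv = mpv)
}

#' Presence/absence calls per genotype
#'
#' A feature counts as expressed in a genotype when any replicate is positive
#' (`any_replicate`, default), when the replicate mean is positive
#' (`mean_positive`, equivalent for non-negative data), or when more than
#' half the replicates are positive (`majority`).
#'
#' @param expr expression matrix (features x samples).
#' @param design a `sample_design`.
#' @param rule detection rule.
#' @return list with `presence` (logical matrix features x genotypes),
#'   `expressed_counts` (named integer vector per genotype) and
#'   `co_expressed` (features present in every genotype).
#' @export
detect_expressed <- function(expr, design,
                             rule = c("any_replicate", "mean_positive",
                                      "majority")) {
  rule <- match.arg(rule)
  s <- design$samples
  genos <- unique(s$genotype)
  presence <- vapply(genos, function(g) {
    m <- expr[, s$sample_id[s$genotype == g], drop = FALSE]
    switch(rule,
           any_replicate = apply(m > 0, 1, any),
           mean_positive = rowMeans(m) > 0,
           majority = rowMeans(m > 0) > 0.5)
  }, logical(nrow(expr)))
  dimnames(presence) <- list(rownames(expr), genos)
  list(presence = presence,
       expressed_counts = colSums(presence),
       co_expressed = rownames(expr)[rowSums(presence) == length(genos)])
}
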