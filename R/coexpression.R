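# WGCNA-style co-expression: soft threshold, TOM, modules, eigengenes, hubs.

# unsigned adjacency |cor|^beta with zero diagonal; constant rows must be
# removed beforehand
adjacency_matrix <- function(expr, beta) {
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

drop_constant_rows <- function(expr) {
  keep <- apply(expr, 1, function(x) stats::sd(x) > 0)
  if (!all(keep))
    warning(sprintf("dropping %d constant feature(s) before network construction",
                    sum(!keep)))
  expr[keep, , drop = FALSE]
}

#' Pick the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power the connectivity distribution is binned and
#' `log10 p(k)` regressed on `log10 k`; the smallest power whose fit R-squared
#' reaches `r2_target` is returned, falling back to 6 when none qualifies.
#'
#' @param expr feature x sample matrix (constant rows are dropped with a
#'   warning).
#' @param candidate_powers powers to try.
#' @param r2_target scale-free fit threshold.
#' @param n_bins connectivity histogram bins.
#' @return list with `beta`, and `fit` (data.frame: power, r2).
#' @export
pick_beta <- function(expr, candidate_powers = 1:12, r2_target = 0.8,
                      n_bins = 10L) {
  if (ncol(expr) < 4L) stop("need at least 4 samples", call. = FALSE)
  expr <- drop_constant_rows(expr)
  cc <- abs(stats::cor(t(expr)))
  diag(cc) <- 0
  r2 <- vapply(candidate_powers, function(b) {
    k <- rowSums(cc^b)
    k <- k[k > 0]
    if (length(unique(k)) < 3L) return(0)
    bins <- cut(k, breaks = n_bins)
    freq <- tapply(k, bins, length)
    kmean <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3L) return(0)
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    summary(fit)$r.squared
  }, numeric(1))
  qualifying <- candidate_powers[r2 >= r2_target]
  beta <- if (length(qualifying)) min(qualifying) else {
    warning("no candidate power reached the scale-free target; using 6")
    6
  }
  list(beta = beta, fit = data.frame(power = candidate_powers, r2 = r2))
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor(i, j)|^beta` (zero diagonal), then
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`; the diagonal is set to 1. Entries lie in `[0, 1]` and
#' the matrix is symmetric.
#'
#' @param expr feature x sample matrix.
#' @param beta soft-threshold power (>= 1).
#' @return TOM similarity matrix.
#' @export
build_tom <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  expr <- drop_constant_rows(expr)
  a <- adjacency_matrix(expr, beta)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

# WGCNA-convention module colors, assigned by decreasing module size
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue", "darkred",
                   "darkgreen", "darkturquoise", "darkgrey", "orange",
                   "darkorange", "white", "skyblue", "saddlebrown")

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than `min_module_size` fall into
#' `grey`. Module labels are color names ordered by module size.
#'
#' @param tom a [build_tom()] matrix.
#' @param min_module_size smallest retained module.
#' @param cut_height static tree-cut height on `1 - TOM`.
#' @return named character vector: feature -> module color (grey =
#'   unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 5L, cut_height = 0.99) {
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  assignments <- rep("grey", length(cl))
  names(assignments) <- rownames(tom)
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (j in seq_along(ord))
      assignments[cl == as.integer(ord[j])] <-
        MODULE_COLORS[min(j, length(MODULE_COLORS))]
  } else {
    warning("all features unassigned (grey)")
  }
  assignments
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' standardized feature x sample submatrix (unit norm), sign-oriented so the
#' mean correlation with the module's features is positive.
#'
#' @param expr feature x sample matrix.
#' @param assignments module labels from [detect_modules()]; grey is skipped.
#' @return matrix modules x samples.
#' @export
module_eigengenes <- function(expr, assignments) {
  mods <- setdiff(unique(assignments), "grey")
  eg <- t(vapply(mods, function(m) {
    sub <- expr[names(assignments)[assignments == m], , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    ori <- mean(stats::cor(v, t(sub)))
    if (!is.na(ori) && ori < 0) v <- -v
    v
  }, numeric(ncol(expr))))
  dimnames(eg) <- list(mods, colnames(expr))
  eg
}

#' Module-trait correlations
#'
#' Pearson correlation (with t-transform p-values) between each module
#' eigengene and binary sample indicators, one per genotype or one per role
#' group.
#'
#' @param eigengenes a [module_eigengenes()] matrix (samples in design
#'   order).
#' @param design a `sample_design`.
#' @param encoding `"genotype"` (one indicator per genotype) or `"role"`
#'   (FP/MP/F1_high/F1_low).
#' @return list of matrices `r` and `p`, modules x traits.
#' @export
module_trait <- function(eigengenes, design, encoding = c("genotype", "role")) {
  encoding <- match.arg(encoding)
  s <- design$samples[match(colnames(eigengenes), design$samples$sample_id), ]
  lab <- if (encoding == "genotype") s$genotype else s$role
  traits <- sort(unique(lab))
  ind <- vapply(traits, function(tr) as.numeric(lab == tr),
                numeric(length(lab)))
  n <- ncol(eigengenes)
  r <- stats::cor(t(eigengenes), ind)
  p <- matrix(pearson_p(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  single <- colSums(ind) < 2 | colSums(ind) > n - 2
  p[, single] <- NA
  list(r = r, p = p)
}

#' Select hub features by intramodular connectivity
#'
#' Features of a module ranked by `kWithin`, the sum of adjacency to the
#' other module members; the top `k` are returned (ties broken by feature
#' id). Modules smaller than `k` return all members with a warning.
#'
#' @param expr feature x sample matrix.
#' @param assignments module labels.
#' @param module module color to screen.
#' @param k number of hubs.
#' @param beta soft-threshold power used for the adjacency.
#' @return data.frame with feature_id, k_within, ordered by rank.
#' @export
select_hubs <- function(expr, assignments, module, k = 25L, beta = 6) {
  members <- names(assignments)[assignments == module]
  if (!length(members)) stop(sprintf("module '%s' not found", module), call. = FALSE)
  if (k == 0L) return(data.frame(feature_id = character(0), k_within = numeric(0)))
  a <- adjacency_matrix(expr[members, , drop = FALSE], beta)
  kw <- rowSums(a)
  ord <- order(-kw, members)
  if (length(members) < k)
    warning(sprintf("module '%s' has fewer than %d members; returning all",
                    module, k))
  top <- head(ord, k)
  data.frame(feature_id = members[top], k_within = unname(kw[top]),
             stringsAsFactors = FALSE)
}

#' Module bookkeeping summary
#'
#' Counts assigned (non-grey) features and modules and the mean number of
#' features per module.
#'
#' @param assignments module labels from [detect_modules()], or any named
#'   character vector of feature -> module with grey meaning unassigned.
#' @return data.frame with n_features, n_modules, mean_per_module.
#' @export
module_size_summary <- function(assignments) {
  assigned <- assignments[assignments != "grey"]
  n_mod <- length(unique(assigned))
  data.frame(n_features = length(assigned), n_modules = n_mod,
             mean_per_module = if (n_mod) length(assigned) / n_mod else NA_real_)
}

#' Hypergeometric enrichment of a feature set
#'
#' For every term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the feature set and the term's annotated
#' features within the universe (`phyper`). Terms with no annotated feature
#' in the universe are skipped.
#'
#' @param feature_set character vector, a subset of `universe`.
#' @param term_assignments data.frame with feature_id, term.
#' @param universe all features under consideration.
#' @param adjust also report BH-adjusted p-values.
#' @return data.frame with term, n_term, n_set, n_overlap, p (and q when
#'   `adjust`).
#' @export
enrich_hypergeometric <- function(feature_set, term_assignments, universe,
                                  adjust = FALSE) {
  if (!all(feature_set %in% universe))
    stop("feature_set must be a subset of universe", call. = FALSE)
  ta <- term_assignments[term_assignments$feature_id %in% universe, , drop = FALSE]
  terms <- unique(ta$term)
  N <- length(universe); n <- length(feature_set)
  rows <- lapply(terms, function(tm) {
    ann <- unique(ta$feature_id[ta$term == tm])
    K <- length(ann)
    x <- length(intersect(feature_set, ann))
    data.frame(term = tm, n_term = K, n_set = n, n_overlap = x,
               p = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- adjust_bh(out$p)
  out[order(out$p), , drop = FALSE]
}
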