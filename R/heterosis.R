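#' Additive vs non-additive expression from an MPV test
#'
#' A circRNA is non-additively expressed in an F1 genotype when its F1-vs-MPV
#' comparison is called up or down at the DEC thresholds; no significant
#' difference means additive inheritance. Features not expressed in the F1
#' and with zero MPV are excluded (NA).
#'
#' @param mpv_result a [mpv_test()] result (needs `direction`).
#' @return character vector: "additive", "non_additive" or NA.
#' @export
classify_additivity <- function(mpv_result) {
  ifelse(is.na(mpv_result$direction), NA_character_,
         ifelse(mpv_result$direction == "ns", "additive", "non_additive"))
}

#' Stupar subtypes of non-additive expression
#'
#' The high parent is fixed as the female parent and the low parent as the
#' male parent (they are assigned by growth potential, not by expression
#' level); `stupar_by_expression = TRUE` restores the conventional
#' higher-expressing-parent definition. For F1 expression significantly above
#' the MPV: AHP when the F1 mean exceeds the high-parent mean, otherwise HP.
#' Significantly below: BLP when the F1 mean is below the low-parent mean,
#' otherwise LP.
#'
#' @param f1_mean,fp_mean,mp_mean genotype mean expression vectors.
#' @param mpv_direction direction of the F1-vs-MPV DEC call ("up"/"down");
#'   passing "ns" is an error (additive features have no subtype).
#' @param stupar_by_expression use the higher-expressing parent as high
#'   parent instead of the female parent.
#' @return character vector in AHP/HP/LP/BLP.
#' @export
classify_stupar <- function(f1_mean, fp_mean, mp_mean, mpv_direction,
                            stupar_by_expression = FALSE) {
  if (any(!mpv_direction %in% c("up", "down")))
    stop("additive features have no Stupar subtype", call. = FALSE)
  if (stupar_by_expression) {
    hi <- pmax(fp_mean, mp_mean); lo <- pmin(fp_mean, mp_mean)
  } else {
    hi <- fp_mean; lo <- mp_mean
  }
  ifelse(mpv_direction == "up",
         ifelse(f1_mean > hi, "AHP", "HP"),
         ifelse(f1_mean < lo, "BLP", "LP"))
}

#' Parental expression patterns (SPE taxonomy)
#'
#' From per-genotype presence calls: SPE_F circRNAs are expressed in the
#' female but not the male parent, SPE_M in the male but not the female,
#' CoPE in both, and `none` in neither. The SFE flag marks circRNAs absent
#' from both parents but expressed in at least one F1 genotype.
#'
#' @param presence logical feature x genotype matrix from
#'   [detect_expressed()].
#' @param design a `sample_design`.
#' @return data.frame with circ_id, pattern (SPE_F/SPE_M/CoPE/none),
#'   sfe (logical) and f1_expressed (expressed in >= 1 F1 genotype).
#' @export
classify_parental_pattern <- function(presence, design) {
  fp <- design_genotypes(design, "FP")
  mp <- design_genotypes(design, "MP")
  f1 <- design_genotypes(design, c("F1_high", "F1_low"))
  in_fp <- presence[, fp]
  in_mp <- presence[, mp]
  in_f1 <- rowSums(presence[, f1, drop = FALSE]) > 0
  pattern <- ifelse(in_fp & in_mp, "CoPE",
                    ifelse(in_fp, "SPE_F", ifelse(in_mp, "SPE_M", "none")))
  data.frame(circ_id = rownames(presence), pattern = pattern,
             sfe = !in_fp & !in_mp & in_f1, f1_expressed = in_f1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-F1 heterosis classification of a circRNA catalog
#'
#' Runs the MPV test for every F1 genotype, classifies additivity and Stupar
#' subtype, and joins the parental pattern.
#'
#' @param counts feature x sample merged count matrix.
#' @param design a `sample_design`.
#' @param presence_rule detection rule for [detect_expressed()].
#' @param lfc_min,q_max DEC thresholds.
#' @param stupar_by_expression see [classify_stupar()].
#' @return data.frame with one row per (circ_id, F1 genotype): additivity,
#'   stupar subtype ("none" for additive), parental pattern, sfe flag, and
#'   the underlying log2fc/q/direction.
#' @export
heterosis_calls <- function(counts, design, presence_rule = "any_replicate",
                            lfc_min = 1, q_max = 0.05,
                            stupar_by_expression = FALSE) {
  rpm <- rpm_normalize(counts, design$mapped_reads)
  gm <- genotype_means_and_mpv(rpm, design)
  pres <- detect_expressed(rpm, design, presence_rule)
  pat <- classify_parental_pattern(pres$presence, design)
  fp <- design_genotypes(design, "FP")
  mp <- design_genotypes(design, "MP")
  f1 <- design_genotypes(design, c("F1_high", "F1_low"))

  out <- lapply(f1, function(g) {
    res <- mpv_test(counts, design, g, lfc_min = lfc_min, q_max = q_max)
    # tested set: expressed in this F1 or MPV > 0
    tested <- pres$presence[, g] | gm$mpv > 0
    additivity <- classify_additivity(res)
    additivity[!tested] <- NA_character_
    stupar <- rep("none", nrow(res))
    nonadd <- !is.na(additivity) & additivity == "non_additive"
    if (any(nonadd)) {
      stupar[nonadd] <- classify_stupar(
        gm$means[nonadd, g], gm$means[nonadd, fp], gm$means[nonadd, mp],
        res$direction[nonadd], stupar_by_expression)
    }
    data.frame(circ_id = res$feature_id, f1_genotype = g,
               additivity = additivity, stupar = stupar,
               log2fc = res$log2fc, q = res$q, direction = res$direction,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  idx <- match(calls$circ_id, pat$circ_id)
  calls$parental_pattern <- pat$pattern[idx]
  calls$sfe <- pat$sfe[idx]
  calls
}

#' Count single-parent-expressed circRNAs
#'
#' @param patterns data.frame with a `pattern` column
#'   (from [classify_parental_pattern()]).
#' @return data.frame with n_spe_f, n_spe_m and their total.
#' @export
count_spe <- function(patterns) {
  n_f <- sum(patterns$pattern == "SPE_F")
  n_m <- sum(patterns$pattern == "SPE_M")
  data.frame(n_spe_f = n_f, n_spe_m = n_m, n_spe_total = n_f + n_m)
}

#' Intersect DEC sets across comparisons and decompose by direction
#'
#' The co-DEC set is the intersection of the DEC (up or down) feature sets of
#' all supplied comparisons; each co-DEC is labelled `all_up`, `all_down`, or
#' `mixed` by the concordance of its directions across comparisons.
#'
#' @param dec_tables list of [de_compare()] results computed on the same
#'   catalog.
#' @return list with `co_dec` (data.frame: feature_id, concordance) and
#'   `counts` (data.frame: n_co_dec, n_all_up, n_all_down, n_mixed).
#' @export
codec_decompose <- function(dec_tables) {
  ids <- lapply(dec_tables, function(d)
    d$feature_id[!is.na(d$direction) & d$direction != "ns"])
  feats <- lapply(dec_tables, `[[`, "feature_id")
  if (length(unique(vapply(feats, function(x) paste(sort(x), collapse = ","),
                           "")) ) > 1L)
    stop("DEC tables computed on mismatched catalogs", call. = FALSE)
  common <- Reduce(intersect, ids)
  if (!length(common))
    return(list(co_dec = data.frame(feature_id = character(0),
                                    concordance = character(0)),
                counts = data.frame(n_co_dec = 0L, n_all_up = 0L,
                                    n_all_down = 0L, n_mixed = 0L)))
  dirs <- vapply(dec_tables, function(d)
    d$direction[match(common, d$feature_id)], character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  conc <- apply(dirs, 1, function(x)
    if (all(x == "up")) "all_up" else if (all(x == "down")) "all_down" else "mixed")
  co <- data.frame(feature_id = common, concordance = conc,
                   stringsAsFactors = FALSE)
  list(co_dec = co,
       counts = data.frame(n_co_dec = nrow(co),
                           n_all_up = sum(conc == "all_up"),
                           n_all_down = sum(conc == "all_down"),
                           n_mixed = sum(conc == "mixed")))
}

#' Features non-additive in at least k genotypes of a growth class
#'
#' @param calls output of [heterosis_calls()].
#' @param genotypes genotypes of one growth class.
#' @param k minimum number of genotypes (default 2, "common to at least two
#'   F1 hybrids").
#' @return character vector of circ_ids.
#' @export
common_nonadditive <- function(calls, genotypes, k = 2L) {
  sub <- calls[calls$f1_genotype %in% genotypes &
                 !is.na(calls$additivity) &
                 calls$additivity == "non_additive", ]
  tab <- table(sub$circ_id)
  names(tab)[tab >= k]
}

#' Summary tables for heterosis patterns
#'
#' Aggregates per-genotype additivity and Stupar-subtype counts, SPE totals,
#' the SPE membership of the parental DEC set, and the co-DEC decomposition
#' over the F1-high vs F1-low comparisons.
#'
#' @param calls output of [heterosis_calls()].
#' @param parent_dec [de_compare()] result for MP vs FP (or FP vs MP).
#' @param f1_dec_tables list of [de_compare()] results for the four
#'   high-vs-low F1 comparisons.
#' @return list of data.frames: `additivity` (genotype x class counts),
#'   `stupar` (genotype x subtype counts), `spe` (SPE_F/SPE_M/total),
#'   `spe_in_parent_dec` (n_parent_dec, n_spe_in_dec, n_spe_f_in_dec,
#'   n_spe_m_in_dec), `co_dec` counts.
#' @export
summarize_patterns <- function(calls, parent_dec = NULL,
                               f1_dec_tables = NULL) {
  tested <- calls[!is.na(calls$additivity), ]
  additivity <- as.data.frame.matrix(
    table(tested$f1_genotype, tested$additivity))
  additivity <- cbind(genotype = rownames(additivity), additivity,
                      stringsAsFactors = FALSE)
  rownames(additivity) <- NULL
  nonadd <- tested[tested$additivity == "non_additive", ]
  stupar <- as.data.frame.matrix(
    table(factor(nonadd$f1_genotype, unique(tested$f1_genotype)),
          factor(nonadd$stupar, c("AHP", "HP", "LP", "BLP"))))
  stupar <- cbind(genotype = rownames(stupar), stupar, stringsAsFactors = FALSE)
  rownames(stupar) <- NULL

  pat <- unique(calls[, c("circ_id", "parental_pattern")])
  spe <- count_spe(data.frame(pattern = pat$parental_pattern))

  spe_in_dec <- NULL
  if (!is.null(parent_dec)) {
    dec_ids <- parent_dec$feature_id[!is.na(parent_dec$direction) &
                                       parent_dec$direction != "ns"]
    spe_ids_f <- pat$circ_id[pat$parental_pattern == "SPE_F"]
    spe_ids_m <- pat$circ_id[pat$parental_pattern == "SPE_M"]
    spe_in_dec <- data.frame(
      n_parent_dec = length(dec_ids),
      n_spe_in_dec = length(intersect(dec_ids, c(spe_ids_f, spe_ids_m))),
      n_spe_f_in_dec = length(intersect(dec_ids, spe_ids_f)),
      n_spe_m_in_dec = length(intersect(dec_ids, spe_ids_m)))
  }
  co_dec <- if (!is.null(f1_dec_tables)) codec_decompose(f1_dec_tables)$counts

  list(additivity = additivity, stupar = stupar, spe = spe,
       spe_in_parent_dec = spe_in_dec, co_dec = co_dec)
}
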