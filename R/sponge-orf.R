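# plant miRNA target scoring (Allen-rule penalties) and circular ORF finding

BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

seq_to_int <- function(s) {
  v <- BASES[strsplit(chartr("Uu", "Tt", toupper(s)), "")[[1]]]
  if (any(is.na(v))) stop("sequence contains non-ACGT/U characters", call. = FALSE)
  unname(v)
}

# penalty lookup: rows = miRNA base, cols = target (circRNA) base.
# 0 Watson-Crick, 0.5 G:U wobble (miRNA G vs target T, or miRNA T vs target G),
# 1 mismatch.
PENALTY <- matrix(1, 4, 4, dimnames = list(names(BASES), names(BASES)))
PENALTY["A", "T"] <- 0; PENALTY["T", "A"] <- 0
PENALTY["C", "G"] <- 0; PENALTY["G", "C"] <- 0
PENALTY["G", "T"] <- 0.5; PENALTY["T", "G"] <- 0.5

#' Score one miRNA/target-site alignment
#'
#' Gap-free plant-miRNA penalty scoring: the miRNA is aligned antiparallel to
#' a circRNA window of the same length; each position contributes 0 for a
#' Watson-Crick pair, 0.5 for a G:U wobble and 1 for a mismatch, doubled at
#' miRNA positions 2-13 from the 5' end (the seed-proximal region). A perfect
#' reverse-complement site scores 0.
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (ACGU/ACGT).
#' @param circ_window circRNA window of the same length, 5' to 3'.
#' @return list with `score` (total penalty) and `alignment` (string with
#'   `|` for a pair, `o` for a wobble, `x` for a mismatch, in miRNA
#'   orientation).
#' @export
score_target <- function(mirna_seq, circ_window) {
  m <- seq_to_int(mirna_seq)
  w <- seq_to_int(circ_window)
  L <- length(m)
  if (length(w) != L)
    stop("window length must equal miRNA length in gap-free mode", call. = FALSE)
  t_opposite <- rev(w)                     # antiparallel pairing
  pen <- PENALTY[cbind(m, t_opposite)]
  weight <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  glyph <- c("|", "o", "x")[match(pen, c(0, 0.5, 1))]
  list(score = sum(pen * weight), alignment = paste(glyph, collapse = ""))
}

# penalty at every offset of a circularized sequence; returns numeric vector
# of length nchar(seq), names = 0-based offsets
scan_scores <- function(circ_seq, mirna_seq, circular = TRUE) {
  m <- seq_to_int(mirna_seq)
  L <- length(m)
  s <- seq_to_int(circ_seq)
  n <- length(s)
  if (circular) s <- c(s, s[seq_len(min(L - 1L, n))])
  n_off <- if (circular) n else n - L + 1L
  if (n_off < 1L) return(numeric(0))
  weight <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  total <- numeric(n_off)
  for (i in seq_len(L)) {
    # miRNA position i pairs the window base at index offset + (L - i)
    idx <- seq_len(n_off) + (L - i)
    total <- total + weight[i] * PENALTY[cbind(m[i], s[idx])]
  }
  names(total) <- seq_len(n_off) - 1L
  total
}

#' Find miRNA target sites on circRNAs
#'
#' Every offset of each circularized circRNA (the sequence plus its first
#' miRNA-length-minus-one nucleotides, so junction-spanning sites are
#' scanned) is scored with the plant penalty scheme of [score_target()];
#' offsets scoring at or below `cutoff` are reported.
#'
#' @param circ_seqs named character vector of circRNA sequences.
#' @param mirna_seqs named character vector of miRNA sequences (20-22 nt).
#' @param cutoff maximum penalty for a hit.
#' @param circular scan across the back-splice junction (default TRUE).
#' @return data.frame with circ_id, mirna_id, offset (0-based on the
#'   circRNA), score.
#' @export
find_targets <- function(circ_seqs, mirna_seqs, cutoff = 4.0,
                         circular = TRUE) {
  hits <- list()
  for (cid in names(circ_seqs)) {
    for (mid in names(mirna_seqs)) {
      if (nchar(circ_seqs[[cid]]) < nchar(mirna_seqs[[mid]])) next
      sc <- scan_scores(circ_seqs[[cid]], mirna_seqs[[mid]], circular)
      pass <- which(sc <= cutoff)
      if (length(pass))
        hits[[length(hits) + 1L]] <- data.frame(
          circ_id = cid, mirna_id = mid,
          offset = as.integer(names(sc)[pass]), score = unname(sc[pass]),
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(circ_id = character(0), mirna_id = character(0),
                  offset = integer(0), score = numeric(0))
}

#' Summarize target hits
#'
#' Bins targeted circRNAs by the number of distinct bound miRNAs (one site vs
#' multiple) and, for each supplied circRNA class, reports the fraction of
#' all targeted miRNAs that the class hits.
#'
#' @param hits a [find_targets()] table.
#' @param class_sets optional named list of circ_id vectors (e.g. SPE sets,
#'   common non-additive sets).
#' @return list with `totals` (n_targeted_circ, n_single_mirna,
#'   n_multi_mirna, n_targeted_mirnas) and `class_mirna_fraction`
#'   (data.frame: class, n_mirnas, fraction_of_targeted).
#' @export
summarize_targets <- function(hits, class_sets = NULL) {
  per_circ <- tapply(hits$mirna_id, hits$circ_id,
                     function(x) length(unique(x)))
  all_mirnas <- unique(hits$mirna_id)
  totals <- data.frame(
    n_targeted_circ = length(per_circ),
    n_single_mirna = sum(per_circ == 1),
    n_multi_mirna = sum(per_circ > 1),
    n_targeted_mirnas = length(all_mirnas))
  cls <- NULL
  if (!is.null(class_sets)) {
    cls <- do.call(rbind, lapply(names(class_sets), function(nm) {
      mir <- unique(hits$mirna_id[hits$circ_id %in% class_sets[[nm]]])
      data.frame(class = nm, n_mirnas = length(mir),
                 fraction_of_targeted = length(mir) /
                   max(1L, length(all_mirnas)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(totals = totals, class_mirna_fraction = cls)
}

#' Find open reading frames on a circular sequence
#'
#' The sequence is concatenated `max_wraps` times and all three frames are
#' scanned for `ATG`-to-stop ORFs whose start lies in the first copy (which
#' collapses wrap duplicates). Length is counted start codon through stop
#' codon inclusive. An ORF crossing the first copy boundary is flagged
#' `spans_junction`. A frame whose ATG never reaches a stop within the
#' allowed wraps is reported as `rolling` (rolling-circle translation) with
#' its length truncated to the frame.
#'
#' @param circ_seq circRNA sequence (character scalar).
#' @param min_orf_nt minimum reported ORF length in nt (default 63).
#' @param max_wraps number of concatenated copies scanned.
#' @return data.frame with start_offset (0-based on the circRNA), length_nt,
#'   spans_junction, rolling; zero rows when no qualifying ORF exists.
#' @export
find_circular_orfs <- function(circ_seq, min_orf_nt = 63L, max_wraps = 4L) {
  v <- seq_to_int(circ_seq)
  L <- length(v)
  ext <- rep(v, max_wraps)
  codon_at <- function(p) (v2 <- ext[p:(p + 2L)])
  is_stop <- function(cd) {
    # TAA, TAG, TGA with A=1 C=2 G=3 T=4
    (cd[1] == 4L && cd[2] == 1L && cd[3] %in% c(1L, 3L)) ||
      (cd[1] == 4L && cd[2] == 3L && cd[3] == 1L)
  }
  is_atg <- function(cd) cd[1] == 1L && cd[2] == 4L && cd[3] == 3L

  out <- list()
  consumed_starts <- character(0)
  for (p in seq_len(min(L, length(ext) - 2L))) {
    cd <- codon_at(p)
    if (!is_atg(cd)) next
    q <- p
    found_stop <- FALSE
    while (q + 2L <= length(ext)) {
      if (is_stop(ext[q:(q + 2L)])) { found_stop <- TRUE; break }
      q <- q + 3L
    }
    if (found_stop) {
      len <- q + 2L - p + 1L
      rolling <- FALSE
    } else {
      len <- ((length(ext) - p + 1L) %/% 3L) * 3L
      rolling <- TRUE
    }
    if (len < min_orf_nt) next
    keyid <- sprintf("%d:%d", (p - 1L) %% L, (p - 1L) %% 3L)
    if (keyid %in% consumed_starts) next
    consumed_starts <- c(consumed_starts, keyid)
    out[[length(out) + 1L]] <- data.frame(
      start_offset = p - 1L, length_nt = len,
      spans_junction = (p - 1L + len) > L, rolling = rolling)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start_offset = integer(0), length_nt = integer(0),
                  spans_junction = logical(0), rolling = logical(0))
}

#' Scan a set of circRNAs for circular ORFs
#'
#' @param circ_seqs named character vector.
#' @param ... passed to [find_circular_orfs()].
#' @return data.frame with a circ_id column prepended.
#' @export
find_orfs_all <- function(circ_seqs, ...) {
  res <- lapply(names(circ_seqs), function(cid) {
    h <- find_circular_orfs(circ_seqs[[cid]], ...)
    if (nrow(h)) cbind(circ_id = cid, h, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(circ_id = character(0), start_offset = integer(0),
                      length_nt = integer(0), spans_junction = logical(0),
                      rolling = logical(0))
  res
}

#' Protein-coding potential calls
#'
#' A circRNA has coding potential when it carries at least one qualifying ORF
#' and, if an IRES annotation is supplied, its IRES flag is also true
#' (ORF-only mode otherwise).
#'
#' @param orf_hits a [find_orfs_all()] table.
#' @param circ_ids all catalog circ_ids (defines the output universe).
#' @param ires_flags optional named logical vector of IRES annotations.
#' @return data.frame with circ_id, has_orf, has_ires (NA in ORF-only mode),
#'   coding_potential.
#' @export
coding_potential <- function(orf_hits, circ_ids, ires_flags = NULL) {
  has_orf <- circ_ids %in% orf_hits$circ_id
  if (is.null(ires_flags)) {
    data.frame(circ_id = circ_ids, has_orf = has_orf, has_ires = NA,
               coding_potential = has_orf, stringsAsFactors = FALSE)
  } else {
    ires <- as.logical(ires_flags[circ_ids])
    ires[is.na(ires)] <- FALSE
    data.frame(circ_id = circ_ids, has_orf = has_orf, has_ires = ires,
               coding_potential = has_orf & ires, stringsAsFactors = FALSE)
  }
}
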