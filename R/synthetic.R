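#' Generate a toy gene annotation and genome
#'
#' Lays out non-overlapping multi-exon genes along one or more chromosomes and
#' draws a random genome sequence long enough to contain them. The result is
#' the coordinate frame every other generator and the origin classifier work
#' against. Coordinates are 1-based inclusive (GFF convention).
#'
#' @param seed integer seed; the same seed reproduces the annotation and
#'   genome byte for byte.
#' @param n_chroms number of chromosomes.
#' @param n_genes total number of genes, distributed round-robin over
#'   chromosomes.
#' @param exon_length_range min/max exon length (nt).
#' @param intron_length_range min/max intron length (nt).
#' @param exons_per_gene_range min/max exon count per gene; genes with a
#'   single exon have no introns.
#' @param intergenic_gap_range min/max gap between consecutive genes (nt).
#' @return an object of class `circ_annotation`: a list with `genes`
#'   (data.frame: gene_id, chrom, start, end, strand), `exons` (data.frame:
#'   gene_id, exon_rank, chrom, start, end, strand) and `genome` (named
#'   character vector of chromosome sequences).
#' @export
generate_annotation <- function(seed, n_chroms = 2L, n_genes = 50L,
                                exon_length_range = c(150L, 400L),
                                intron_length_range = c(100L, 300L),
                                exons_per_gene_range = c(1L, 4L),
                                intergenic_gap_range = c(300L, 900L)) {
  stopifnot_scalar_count(n_chroms, "n_chroms")
  stopifnot_scalar_count(n_genes, "n_genes")
  for (rng in list(exon_length_range, intron_length_range,
                   exons_per_gene_range, intergenic_gap_range)) {
    if (length(rng) != 2L || any(rng < 1) || rng[1] > rng[2])
      stop("length/gap ranges must be positive increasing pairs", call. = FALSE)
  }
  set.seed(seed)

  chrom_names <- sprintf("chr%d", seq_len(n_chroms))
  gene_chrom <- chrom_names[((seq_len(n_genes) - 1L) %% n_chroms) + 1L]

  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  cursor <- stats::setNames(rep(1L, n_chroms), chrom_names)

  for (i in seq_len(n_genes)) {
    chrom <- gene_chrom[i]
    gap <- sample(intergenic_gap_range[1]:intergenic_gap_range[2], 1L)
    gstart <- cursor[[chrom]] + gap
    n_ex <- sample(exons_per_gene_range[1]:exons_per_gene_range[2], 1L)
    ex_len <- sample(exon_length_range[1]:exon_length_range[2], n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L)
      sample(intron_length_range[1]:intron_length_range[2], n_ex - 1L, replace = TRUE)
    else integer(0)
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("gene_%04d", i)

    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- gstart
    for (k in seq_len(n_ex)) {
      ex_start[k] <- pos
      ex_end[k] <- pos + ex_len[k] - 1L
      pos <- ex_end[k] + 1L + if (k < n_ex) in_len[k] else 0L
    }
    gend <- ex_end[n_ex]
    cursor[[chrom]] <- gend

    genes[[i]] <- data.frame(gene_id = gene_id, chrom = chrom, start = gstart,
                             end = gend, strand = strand,
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gene_id, exon_rank = seq_len(n_ex),
                             chrom = chrom, start = ex_start, end = ex_end,
                             strand = strand, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  # tail gap after the last gene on each chromosome
  genome <- vapply(chrom_names, function(ch) {
    len <- cursor[[ch]] + sample(intergenic_gap_range[1]:intergenic_gap_range[2], 1L)
    random_dna(len)
  }, character(1))

  structure(list(genes = genes, exons = exons, genome = genome),
            class = "circ_annotation")
}

# introns derived from consecutive exons of each gene
annotation_introns <- function(annotation) {
  ex <- annotation$exons
  out <- lapply(split(ex, ex$gene_id), function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2L) return(NULL)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = g$end[-nrow(g)] + 1L, end = g$start[-1L] - 1L,
               strand = g$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the sequence of a circRNA from the genome
#'
#' Exonic circRNAs are spliced (the exon pieces covered by the span are
#' concatenated in genomic order); all other classes take the contiguous
#' genomic subsequence. Minus-strand circRNAs are reverse-complemented.
#'
#' @param annotation a `circ_annotation`.
#' @param chrom,start,end,strand circRNA back-splice coordinates (1-based
#'   inclusive).
#' @param origin_class one of `"intergenic"`, `"exonic"`, `"intronic"`,
#'   `"exon_intron"`.
#' @param gene_id parent gene (required for `origin_class = "exonic"`).
#' @return the circRNA sequence as a character scalar.
#' @export
extract_circ_sequence <- function(annotation, chrom, start, end, strand,
                                  origin_class = "intergenic", gene_id = NA) {
  if (end > nchar(annotation$genome[[chrom]]) || start < 1L)
    stop("circRNA coordinates outside chromosome bounds", call. = FALSE)
  if (identical(origin_class, "exonic")) {
    if (is.na(gene_id)) stop("exonic extraction needs a parent gene", call. = FALSE)
    ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
    ex <- ex[order(ex$start), ]
    keep <- ex$end >= start & ex$start <= end
    ex <- ex[keep, , drop = FALSE]
    pieces <- vapply(seq_len(nrow(ex)), function(k) {
      substr(annotation$genome[[chrom]], max(ex$start[k], start),
             min(ex$end[k], end))
    }, character(1))
    seqc <- paste(pieces, collapse = "")
  } else {
    seqc <- substr(annotation$genome[[chrom]], start, end)
  }
  if (strand == "-") seqc <- revcomp(seqc) else seqc
}

#' Plant a labelled circRNA catalog on a synthetic annotation
#'
#' Draws `n_circ` circRNAs with origin classes in the requested proportions,
#' placing each so that re-classification against the annotation recovers its
#' planted label: intergenic spans overlap no gene, exonic spans have both
#' back-splice ends inside exons of one gene, intronic spans sit inside a
#' single intron, and exon_intron spans mix exon and intron within one gene.
#' A subset of intergenic circRNAs additionally receives a planted
#' junction-spanning open reading frame written into the genome before
#' sequence extraction: the planted window is C/G-only background around an
#' `ATG`, in-frame C/G codons, and a stop codon, so the planted ORF is the
#' only one on that circle.
#'
#' @param annotation a `circ_annotation` from [generate_annotation()].
#' @param n_circ number of circRNAs.
#' @param origin_mix proportions for (intergenic, exonic, intronic,
#'   exon_intron); must sum to 1. Defaults follow a typical leaf circRNA
#'   catalog (57.2/40.2/1.0/1.6%).
#' @param length_range circRNA length draw (nt); realized lengths sit mainly
#'   in 100-700 nt.
#' @param orf_plant_rate fraction of eligible intergenic circRNAs that get a
#'   planted junction-spanning ORF.
#' @param min_orf_nt minimum planted ORF length (start through stop,
#'   inclusive); always a multiple of 3.
#' @param seed integer seed.
#' @return an object of class `synthetic_truth`: list with `circ`
#'   (data.frame: circ_id, chrom, start, end, strand, origin_class,
#'   parent_gene_id, length), `sequences` (named character), `planted_orfs`
#'   (data.frame: circ_id, offset, length_nt, spans_junction; offsets
#'   0-based on the circRNA), `annotation` (with the ORF letters written
#'   into the genome) and `seed`.
#' @export
generate_circ_truth <- function(annotation, n_circ = 200L,
                                origin_mix = c(intergenic = 0.572,
                                               exonic = 0.402,
                                               intronic = 0.010,
                                               exon_intron = 0.016),
                                length_range = c(100L, 700L),
                                orf_plant_rate = 0.15,
                                min_orf_nt = 63L,
                                seed = 1L) {
  stopifnot_scalar_count(n_circ, "n_circ")
  if (length(origin_mix) != 4L || abs(sum(origin_mix) - 1) > 1e-9)
    stop("origin_mix must be 4 proportions summing to 1", call. = FALSE)
  classes <- c("intergenic", "exonic", "intronic", "exon_intron")
  names(origin_mix) <- classes
  introns <- annotation_introns(annotation)
  if (nrow(introns) == 0L && (origin_mix[["intronic"]] > 0 ||
                              origin_mix[["exon_intron"]] > 0))
    stop("annotation has no introns but an intron-dependent class was requested",
         call. = FALSE)
  set.seed(seed)

  class_draw <- sample(classes, n_circ, replace = TRUE, prob = origin_mix)
  genes <- annotation$genes
  multi <- unique(introns$gene_id)

  # intergenic intervals per chromosome (margin 5 nt from gene edges)
  gaps <- do.call(rbind, lapply(names(annotation$genome), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds <- c(1L, if (nrow(g)) as.vector(rbind(g$start - 5L, g$end + 5L)),
                nchar(annotation$genome[[ch]]))
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)] - 1L
    # bounds alternate gap-start, gap-end(=gene start-5), gene end+5, ...
    gs <- bounds[c(TRUE, FALSE)]
    ge <- bounds[c(FALSE, TRUE)]
    data.frame(chrom = ch, start = gs, end = ge - 0L, stringsAsFactors = FALSE)
  }))
  # 6-nt margin keeps jittered caller coordinates (<= 5 nt) inside bounds
  gaps$start <- gaps$start + 6L
  gaps$end <- gaps$end - 6L
  gaps <- gaps[gaps$end - gaps$start + 1L >= length_range[1] + 10L, , drop = FALSE]
  if (!nrow(gaps)) stop("no intergenic room for circRNAs; enlarge gaps", call. = FALSE)

  rows <- vector("list", n_circ)
  used_intergenic <- list()  # per gap: taken intervals, to keep ORF hosts clean
  propose <- function(cls, target_len) {
    if (cls == "intergenic") {
      gi <- sample(nrow(gaps), 1L)
      room <- gaps$end[gi] - gaps$start[gi] + 1L
      len <- min(target_len, room)
      s <- gaps$start[gi] + sample.int(room - len + 1L, 1L) - 1L
      e <- s + len - 1L
      prev <- used_intergenic[[as.character(gi)]]
      overlap <- !is.null(prev) && any(prev$start <= e & prev$end >= s)
      list(row = data.frame(chrom = gaps$chrom[gi], start = s, end = e,
                            strand = sample(c("+", "-"), 1L),
                            origin_class = cls,
                            parent_gene_id = NA_character_,
                            clean = !overlap, stringsAsFactors = FALSE),
           gap = gi, overlap = overlap)
    } else if (cls == "exonic") {
      gid <- sample(genes$gene_id, 1L)
      ex <- annotation$exons[annotation$exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      i1 <- sample(nrow(ex), 1L)
      i2 <- if (nrow(ex) > i1 && runif(1) < 0.3) i1 + 1L else i1
      s <- ex$start[i1] + sample.int(ex$end[i1] - ex$start[i1] + 1L, 1L) - 1L
      e <- ex$start[i2] + sample.int(ex$end[i2] - ex$start[i2] + 1L, 1L) - 1L
      if (i1 == i2 && s > e) { tmp <- s; s <- e; e <- tmp }
      if (s > e) { s <- ex$start[i1]; e <- ex$end[i2] }
      if (e - s + 1L < 50L) e <- min(ex$end[i2], s + max(50L, target_len) - 1L)
      list(row = data.frame(chrom = ex$chrom[1], start = s, end = e,
                            strand = ex$strand[1], origin_class = cls,
                            parent_gene_id = gid, clean = FALSE,
                            stringsAsFactors = FALSE))
    } else if (cls == "intronic") {
      ii <- sample(nrow(introns), 1L)
      room <- introns$end[ii] - introns$start[ii] - 1L  # strictly inside
      len <- max(20L, min(target_len, room))
      s <- introns$start[ii] + 1L +
        sample.int(max(room - len + 1L, 1L), 1L) - 1L
      e <- s + len - 1L
      list(row = data.frame(chrom = introns$chrom[ii], start = s, end = e,
                            strand = introns$strand[ii], origin_class = cls,
                            parent_gene_id = introns$gene_id[ii],
                            clean = FALSE, stringsAsFactors = FALSE))
    } else { # exon_intron: start in an exon, end in the following intron
      ii <- sample(nrow(introns), 1L)
      gid <- introns$gene_id[ii]
      ex <- annotation$exons[annotation$exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      donor <- ex[ex$end == introns$start[ii] - 1L, ][1, ]
      s <- donor$start + sample.int(donor$end - donor$start + 1L, 1L) - 1L
      e <- introns$start[ii] +
        sample.int(introns$end[ii] - introns$start[ii], 1L) - 1L
      list(row = data.frame(chrom = donor$chrom, start = s, end = e,
                            strand = donor$strand, origin_class = cls,
                            parent_gene_id = gid, clean = FALSE,
                            stringsAsFactors = FALSE))
    }
  }

  # planted circles must stay distinguishable after caller jitter (<= 5 nt per
  # end): reject placements whose both ends are within 30 nt of an earlier one
  placed <- data.frame(chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0))
  for (i in seq_len(n_circ)) {
    cls <- class_draw[i]
    target_len <- sample(length_range[1]:length_range[2], 1L)
    for (attempt in 1:100) {
      prop <- propose(cls, target_len)
      r <- prop$row
      mergeable <- any(placed$chrom == r$chrom & placed$strand == r$strand &
                         abs(placed$start - r$start) <= 30L &
                         abs(placed$end - r$end) <= 30L)
      if (!mergeable || attempt == 100L) {
        if (mergeable)
          stop("could not place distinguishable circRNAs; reduce n_circ or enlarge the annotation",
               call. = FALSE)
        rows[[i]] <- r
        placed <- rbind(placed, r[, c("chrom", "strand", "start", "end")])
        if (!is.null(prop$gap))
          used_intergenic[[as.character(prop$gap)]] <-
            rbind(used_intergenic[[as.character(prop$gap)]],
                  data.frame(start = r$start, end = r$end,
                             overlapped = prop$overlap))
        break
      }
    }
  }
  circ <- do.call(rbind, rows)
  ord <- order(circ$chrom, circ$start, circ$end)
  circ <- circ[ord, ]
  circ$circ_id <- sprintf("novel_circ_%06d", seq_len(n_circ))
  circ$length <- circ$end - circ$start + 1L
  rownames(circ) <- NULL

  # plant junction-spanning ORFs on clean plus-strand intergenic circles
  eligible <- which(circ$origin_class == "intergenic" & circ$strand == "+" &
                      circ$clean & circ$length >= min_orf_nt + 12L)
  n_plant <- round(length(eligible) * orf_plant_rate)
  planted <- if (n_plant > 0) sample(eligible, n_plant) else integer(0)
  orf_rows <- vector("list", length(planted))
  safe_codons <- apply(expand.grid(c("C", "G"), c("C", "G"), c("C", "G")), 1,
                       paste, collapse = "")
  for (j in seq_along(planted)) {
    i <- planted[j]
    L <- circ$length[i]
    max_codons <- min((L - 6L) %/% 3L, 2298L %/% 3L) - 2L
    n_inner <- sample(19L:max(19L, min(max_codons, 150L)), 1L)
    orf <- paste0("ATG", paste(sample(safe_codons, n_inner, replace = TRUE),
                               collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
    orf_len <- nchar(orf)
    offset <- L - sample.int(orf_len - 6L, 1L) - 3L  # 0-based; wraps junction
    # overwrite the whole circle: C/G background, then the ORF modulo L
    bg <- random_dna(L, alphabet = c("C", "G"))
    circle <- strsplit(bg, "")[[1]]
    pos <- ((offset + seq_len(orf_len) - 1L) %% L) + 1L
    circle[pos] <- strsplit(orf, "")[[1]]
    gseq <- annotation$genome[[circ$chrom[i]]]
    substr(gseq, circ$start[i], circ$end[i]) <- paste(circle, collapse = "")
    annotation$genome[[circ$chrom[i]]] <- gseq
    orf_rows[[j]] <- data.frame(circ_id = circ$circ_id[i], offset = offset,
                                length_nt = orf_len,
                                spans_junction = offset + orf_len > L,
                                stringsAsFactors = FALSE)
  }
  planted_orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(circ_id = character(0), offset = integer(0),
               length_nt = integer(0), spans_junction = logical(0))

  sequences <- vapply(seq_len(nrow(circ)), function(i) {
    extract_circ_sequence(annotation, circ$chrom[i], circ$start[i],
                          circ$end[i], circ$strand[i], circ$origin_class[i],
                          circ$parent_gene_id[i])
  }, character(1))
  names(sequences) <- circ$circ_id
  circ$clean <- NULL

  structure(list(circ = circ, sequences = sequences,
                 planted_orfs = planted_orfs, annotation = annotation,
                 seed = seed),
            class = "synthetic_truth")
}

#' Build the sample design of a two-parent / F1 cross
#'
#' Seven genotypes by default: a female parent (FP), a male parent (MP),
#' three F1 hybrids with high growth potential and two with low growth
#' potential, each with three biological replicates. Per-sample mapped-read
#' totals are drawn uniformly (default 1-10 million) to exercise RPM
#' normalization.
#'
#' @param n_high,n_low number of high/low growth-potential F1 genotypes.
#' @param n_reps biological replicates per genotype.
#' @param mapped_reads_range min/max total mapped reads per sample.
#' @param seed integer seed.
#' @return an object of class `sample_design`: list with `samples`
#'   (data.frame: sample_id, genotype, role, replicate) and `mapped_reads`
#'   (named numeric vector).
#' @export
make_design <- function(n_high = 3L, n_low = 2L, n_reps = 3L,
                        mapped_reads_range = c(1e6, 1e7), seed = 1L) {
  stopifnot_scalar_count(n_reps, "n_reps")
  set.seed(seed)
  genotypes <- c("FP", "MP",
                 if (n_high > 0) sprintf("H%d", seq_len(n_high)),
                 if (n_low > 0) sprintf("L%d", seq_len(n_low)))
  roles <- c("FP", "MP", rep("F1_high", n_high), rep("F1_low", n_low))
  samples <- do.call(rbind, lapply(seq_along(genotypes), function(g) {
    data.frame(sample_id = sprintf("%s_r%d", genotypes[g], seq_len(n_reps)),
               genotype = genotypes[g], role = roles[g],
               replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  }))
  mapped <- round(runif(nrow(samples), mapped_reads_range[1],
                        mapped_reads_range[2]))
  names(mapped) <- samples$sample_id
  structure(list(samples = samples, mapped_reads = mapped),
            class = "sample_design")
}

# genotype labels by role
design_genotypes <- function(design, role = NULL) {
  s <- design$samples
  if (is.null(role)) unique(s$genotype)
  else unique(s$genotype[s$role %in% role])
}

#' Plant heterosis classes and parental patterns into a count matrix
#'
#' Assigns each circRNA a parental expression pattern (CoPE, SPE-F, SPE-M or
#' SFE) and one heterosis class per F1 growth group (additive, AHP, HP, LP
#' or BLP; all genotypes of a growth group share the class, so
#' high-vs-low-growth contrasts carry planted differential expression),
#' constructs expected RPM means that satisfy the class definitions, and
#' draws negative-binomial counts around them. Single-parent
#' and F1-specific patterns are enforced as structural zeros: a planted SPE-F
#' circRNA has exactly zero counts in every male-parent sample. Parent genes
#' of genic circRNAs get an FPKM profile coupled to the circRNA (positively
#' for SPE-F hosts, negatively for SPE-M hosts, random sign otherwise) so the
#' correlation stage has planted signs to recover.
#'
#' @param truth a `synthetic_truth`.
#' @param design a `sample_design`.
#' @param class_mix proportions over heterosis classes (additive, AHP, HP,
#'   LP, BLP). HP defaults to 0: with both parents expressed, an F1 at or
#'   below the high parent cannot be twofold above the MPV, so detectable HP
#'   is a boundary case (observed rates in leaf tissue are near zero).
#' @param pattern_mix proportions over parental patterns (CoPE, SPE_F,
#'   SPE_M, SFE).
#' @param effect_fold planted fold change of non-additive F1 means relative
#'   to the MPV (> 1).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param base_rpm_meanlog,base_rpm_sdlog log-normal draw for baseline
#'   expression on the RPM scale; floored at `base_rpm_min`.
#' @param base_rpm_min floor for planted nonzero means (RPM), keeping planted
#'   presence detectable across replicates.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix circRNA x sample), `gene_fpkm`
#'   (matrix gene x sample), `class_labels` (data.frame: circ_id, genotype,
#'   class), `parental_pattern` (data.frame: circ_id, pattern),
#'   `expected_rpm` (matrix circRNA x genotype of planted means), and
#'   `gene_coupling` (data.frame: gene_id, circ_id, sign).
#' @export
generate_expression <- function(truth, design,
                                class_mix = c(additive = 0.90, AHP = 0.05,
                                              HP = 0, LP = 0.02, BLP = 0.03),
                                pattern_mix = c(CoPE = 0.72, SPE_F = 0.12,
                                                SPE_M = 0.10, SFE = 0.06),
                                effect_fold = 4, dispersion = 0.05,
                                base_rpm_meanlog = log(40),
                                base_rpm_sdlog = 0.8,
                                base_rpm_min = 10,
                                seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1", call. = FALSE)
  if (abs(sum(pattern_mix) - 1) > 1e-9)
    stop("pattern_mix must sum to 1", call. = FALSE)
  if (effect_fold <= 1) stop("effect_fold must be > 1", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  set.seed(seed)

  circ_ids <- truth$circ$circ_id
  n <- length(circ_ids)
  classes <- names(class_mix)
  patterns <- names(pattern_mix)
  pattern <- sample(patterns, n, replace = TRUE, prob = pattern_mix)
  class_hi_raw <- sample(classes, n, replace = TRUE, prob = class_mix)
  class_lo_raw <- sample(classes, n, replace = TRUE, prob = class_mix)

  geno_hi <- design_genotypes(design, "F1_high")
  geno_lo <- design_genotypes(design, "F1_low")
  all_geno <- design_genotypes(design)

  base <- pmax(base_rpm_min, exp(rnorm(n, base_rpm_meanlog, base_rpm_sdlog)))
  mu_fp <- numeric(n); mu_mp <- numeric(n)
  mu_hi <- numeric(n); mu_lo <- numeric(n)
  class_hi <- character(n); class_lo <- character(n)

  # reconcile a raw class with the parental pattern
  fix_class <- function(cls, pat) {
    if (pat == "SFE") return("AHP")                 # MPV = 0 forces up
    if (pat == "SPE_M" && cls == "LP") return("BLP") # FP = 0: no room for LP
    if (pat == "SPE_F" && cls == "BLP") return("LP") # MP = 0: F1 cannot go lower
    cls
  }
  f1_mean_for <- function(cls, pat, i) {
    mpv <- (mu_fp[i] + mu_mp[i]) / 2
    mu <- switch(cls,
      additive = mpv,
      AHP = if (pat == "SFE") base[i] else effect_fold * max(mpv, mu_fp[i]),
      HP  = max(mu_fp[i], 2 * mpv),   # boundary construction, see docs
      LP  = max(mu_mp[i] * 1.2, mpv / effect_fold),
      BLP = mu_mp[i] / effect_fold)
    if (cls == "BLP") mu <- max(mu, 1)  # nonzero so the F1 stays expressed
    mu
  }

  for (i in seq_len(n)) {
    pat <- pattern[i]
    ch <- fix_class(class_hi_raw[i], pat)
    cl <- fix_class(class_lo_raw[i], pat)
    if (pat == "CoPE" && (ch == "LP" || cl == "LP")) {
      # LP needs headroom between the parents
      mu_mp[i] <- base[i]
      mu_fp[i] <- base[i] * runif(1, 6, 8)
    } else {
      delta <- 2^rnorm(1, 0, 0.3)
      mu_fp[i] <- if (pat %in% c("SPE_M", "SFE")) 0 else base[i] * delta
      mu_mp[i] <- if (pat %in% c("SPE_F", "SFE")) 0 else base[i] / delta
    }
    mu_hi[i] <- f1_mean_for(ch, pat, i)
    mu_lo[i] <- f1_mean_for(cl, pat, i)
    class_hi[i] <- ch; class_lo[i] <- cl
  }

  expected_rpm <- matrix(0, n, length(all_geno),
                         dimnames = list(circ_ids, all_geno))
  expected_rpm[, "FP"] <- mu_fp
  expected_rpm[, "MP"] <- mu_mp
  for (g in geno_hi) expected_rpm[, g] <- mu_hi
  for (g in geno_lo) expected_rpm[, g] <- mu_lo

  samples <- design$samples
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(circ_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu_count <- expected_rpm[, samples$genotype[s]] *
      design$mapped_reads[[samples$sample_id[s]]] / 1e6
    nz <- mu_count > 0
    draw <- integer(n)
    if (any(nz)) {
      draw[nz] <- if (dispersion == 0) rpois(sum(nz), mu_count[nz])
      else rnbinom(sum(nz), mu = mu_count[nz], size = 1 / dispersion)
    }
    counts[, s] <- draw
  }

  class_labels <- do.call(rbind, lapply(c(geno_hi, geno_lo), function(g) {
    data.frame(circ_id = circ_ids, genotype = g,
               class = if (g %in% geno_hi) class_hi else class_lo,
               stringsAsFactors = FALSE)
  }))
  parental_pattern <- data.frame(circ_id = circ_ids, pattern = pattern,
                                 stringsAsFactors = FALSE)

  # parent-gene FPKM with planted coupling sign
  genes <- truth$annotation$genes$gene_id
  gene_fpkm <- matrix(0, length(genes), nrow(samples),
                      dimnames = list(genes, samples$sample_id))
  rpm <- sweep(counts, 2, design$mapped_reads[colnames(counts)], "/") * 1e6
  coupling <- NULL
  parented <- !is.na(truth$circ$parent_gene_id)
  for (i in which(parented)) {
    gid <- truth$circ$parent_gene_id[i]
    if (!is.null(coupling) && gid %in% coupling$gene_id) next  # one profile per gene
    sgn <- switch(pattern[i], SPE_F = 1, SPE_M = -1, sample(c(-1, 1), 1))
    amp <- rpm[i, ] - mean(rpm[i, ])
    # offset keeps the planted profile positive, so no clipping distorts it
    prof <- (max(abs(amp)) + 5) + sgn * amp +
      rnorm(length(amp), 0, 0.05 * sd(rpm[i, ]) + 0.1)
    gene_fpkm[gid, ] <- pmax(prof, 0.01)
    coupling <- rbind(coupling, data.frame(gene_id = gid,
                                           circ_id = circ_ids[i], sign = sgn,
                                           stringsAsFactors = FALSE))
  }
  orphan <- setdiff(genes, if (is.null(coupling)) character(0) else coupling$gene_id)
  for (gid in orphan)
    gene_fpkm[gid, ] <- exp(rnorm(nrow(samples), log(15), 0.5))

  list(counts = counts, gene_fpkm = gene_fpkm, class_labels = class_labels,
       parental_pattern = parental_pattern, expected_rpm = expected_rpm,
       gene_coupling = coupling %||%
         data.frame(gene_id = character(0), circ_id = character(0),
                    sign = numeric(0)))
}

#' Emulate two back-splice callers over the planted catalog
#'
#' Each caller reports every planted circRNA unless dropped (false-negative
#' rate per caller), with independent integer jitter on each junction end.
#' Jitter is clamped to 5 nt per end so any pair of surviving calls for the
#' same circle stays within the 10-nt merge window by construction.
#' Per-sample read counts are noisy versions of the planted count matrix;
#' with `jitter_sd = 0`, `fn_rate = 0`, `count_noise = 0` the merged catalog
#' reproduces the planted one exactly.
#'
#' @param truth a `synthetic_truth`.
#' @param counts planted count matrix from [generate_expression()].
#' @param jitter_sd standard deviation of the per-end coordinate jitter (nt).
#' @param fn_rate per-caller probability of missing a circRNA entirely.
#' @param count_noise relative (log-normal) sd of per-caller read counts.
#' @param seed integer seed.
#' @return list of two data.frames (`calls_A`, `calls_B`) with columns
#'   chrom, start, end, strand, n_reads, sample_id, caller.
#' @export
generate_caller_calls <- function(truth, counts, jitter_sd = 1,
                                  fn_rate = 0.05, count_noise = 0.1,
                                  seed = 1L) {
  if (fn_rate < 0 || fn_rate >= 1) stop("fn_rate must be in [0,1)", call. = FALSE)
  if (jitter_sd < 0 || count_noise < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  set.seed(seed)
  circ <- truth$circ
  out <- list()
  for (caller in c("A", "B")) {
    keep <- runif(nrow(circ)) >= fn_rate
    jit_s <- pmax(-5L, pmin(5L, as.integer(round(rnorm(nrow(circ), 0, jitter_sd)))))
    jit_e <- pmax(-5L, pmin(5L, as.integer(round(rnorm(nrow(circ), 0, jitter_sd)))))
    rows <- list()
    for (i in which(keep)) {
      cts <- counts[circ$circ_id[i], ]
      nz <- which(cts > 0)
      if (!length(nz)) next
      noisy <- if (count_noise == 0) cts[nz]
      else pmax(1L, round(cts[nz] * exp(rnorm(length(nz), 0, count_noise))))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = circ$chrom[i], start = circ$start[i] + jit_s[i],
        end = circ$end[i] + jit_e[i], strand = circ$strand[i],
        n_reads = as.integer(noisy), sample_id = names(cts)[nz],
        caller = caller, stringsAsFactors = FALSE)
    }
    out[[paste0("calls_", caller)]] <- if (length(rows)) do.call(rbind, rows)
    else data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    strand = character(0), n_reads = integer(0),
                    sample_id = character(0), caller = character(0))
  }
  out
}

#' Generate miRNAs with planted perfect target sites
#'
#' Planted miRNAs are the reverse complement of a randomly chosen window of a
#' circRNA's (circularized) sequence, so each planted site scores 0 under the
#' plant complementarity scorer at its recorded offset; remaining miRNAs are
#' random background. Sites may span the back-splice junction.
#'
#' @param truth a `synthetic_truth`.
#' @param n_mirnas number of miRNAs (20-22 nt each).
#' @param planted_site_rate fraction of circRNAs that donate a planted site
#'   (capped at one site per miRNA).
#' @param seed integer seed.
#' @return list with `mirnas` (named character vector) and `planted_targets`
#'   (data.frame: circ_id, mirna_id, offset; offset 0-based on the circRNA).
#' @export
generate_mirnas <- function(truth, n_mirnas = 20L, planted_site_rate = 0.1,
                            seed = 1L) {
  if (n_mirnas == 0L)
    return(list(mirnas = character(0),
                planted_targets = data.frame(circ_id = character(0),
                                             mirna_id = character(0),
                                             offset = integer(0))))
  stopifnot_scalar_count(n_mirnas, "n_mirnas")
  set.seed(seed)
  seqs <- truth$sequences
  mir_len <- sample(20:22, n_mirnas, replace = TRUE)
  mirna_ids <- sprintf("mir_%03d", seq_len(n_mirnas))

  hosts <- names(seqs)[nchar(seqs) >= 30L]
  n_sites <- min(n_mirnas, round(length(hosts) * planted_site_rate))
  donors <- if (n_sites > 0) sample(hosts, n_sites) else character(0)

  mirnas <- character(n_mirnas)
  targets <- list()
  for (j in seq_len(n_mirnas)) {
    L <- mir_len[j]
    if (j <= length(donors)) {
      s <- seqs[[donors[j]]]
      Lc <- nchar(s)
      ext <- paste0(s, substr(s, 1L, L - 1L))
      offset <- sample.int(Lc, 1L) - 1L   # 0-based; may wrap the junction
      window <- substr(ext, offset + 1L, offset + L)
      mirnas[j] <- revcomp(window)
      targets[[length(targets) + 1L]] <-
        data.frame(circ_id = donors[j], mirna_id = mirna_ids[j],
                   offset = offset, stringsAsFactors = FALSE)
    } else {
      mirnas[j] <- random_dna(L)
    }
  }
  names(mirnas) <- mirna_ids
  list(mirnas = mirnas,
       planted_targets = if (length(targets)) do.call(rbind, targets)
       else data.frame(circ_id = character(0), mirna_id = character(0),
                       offset = integer(0)))
}

#' Simulate a complete labelled study
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [generate_circ_truth()], [make_design()], [generate_expression()],
#' [generate_caller_calls()] and [generate_mirnas()] with one master seed.
#'
#' @param seed master seed; stage seeds are derived deterministically from it.
#' @param n_genes,n_circ,n_mirnas scale of the study.
#' @param ... forwarded to [generate_expression()].
#' @param jitter_sd,fn_rate,count_noise caller noise, see
#'   [generate_caller_calls()].
#' @return list with `annotation`, `truth`, `design`, `expression` (the
#'   [generate_expression()] bundle), `calls` (two caller tables) and
#'   `mirnas`.
#' @export
simulate_study <- function(seed = 1L, n_genes = 40L, n_circ = 150L,
                           n_mirnas = 20L, jitter_sd = 1, fn_rate = 0.05,
                           count_noise = 0.1, ...) {
  seeds <- seed + 0:5
  ann <- generate_annotation(seeds[1], n_genes = n_genes)
  truth <- generate_circ_truth(ann, n_circ = n_circ, seed = seeds[2])
  design <- make_design(seed = seeds[3])
  expr <- generate_expression(truth, design, seed = seeds[4], ...)
  calls <- generate_caller_calls(truth, expr$counts, jitter_sd = jitter_sd,
                                 fn_rate = fn_rate, count_noise = count_noise,
                                 seed = seeds[5])
  mir <- generate_mirnas(truth, n_mirnas = n_mirnas, seed = seeds[6])
  list(annotation = truth$annotation, truth = truth, design = design,
       expression = expr, calls = calls, mirnas = mir)
}

#' Write a synthetic annotation as GFF3 and FASTA
#'
#' @param annotation a `circ_annotation`.
#' @param gff_path,fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path) {
  g <- annotation$genes
  e <- annotation$exons
  lines <- c("##gff-version 3",
             sprintf("%s\tcircheterosis\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id),
             sprintf("%s\tcircheterosis\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                     e$chrom, e$start, e$end, e$strand, e$gene_id,
                     e$exon_rank, e$gene_id))
  writeLines(lines, gff_path)
  dna <- Biostrings::DNAStringSet(annotation$genome)
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(c(gff_path, fasta_path))
}

#' Read a GFF3 gene/exon annotation and genome FASTA
#'
#' Counterpart of [write_annotation()]; accepts any GFF3 whose gene rows
#' carry `ID=` and whose exon rows carry `Parent=`.
#'
#' @param gff_path,fasta_path input paths.
#' @return a `circ_annotation`.
#' @export
read_annotation <- function(gff_path, fasta_path) {
  raw <- readLines(gff_path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- do.call(rbind, strsplit(raw, "\t", fixed = TRUE))
  df <- data.frame(chrom = f[, 1], type = f[, 3],
                   start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                   strand = f[, 7], attr = f[, 9], stringsAsFactors = FALSE)
  get_attr <- function(a, key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", a)
  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = get_attr(genes$attr, "ID"), chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", ]
  ex <- ex[order(get_attr(ex$attr, "Parent"), ex$start), ]
  gene_of <- get_attr(ex$attr, "Parent")
  ranks <- stats::ave(seq_along(gene_of), gene_of, FUN = seq_along)
  exons <- data.frame(gene_id = gene_of, exon_rank = as.integer(ranks),
                      chrom = ex$chrom, start = ex$start, end = ex$end,
                      strand = ex$strand, stringsAsFactors = FALSE)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  genome <- stats::setNames(as.character(dna),
                            sub("\\s.*", "", names(dna)))
  structure(list(genes = genes, exons = exons, genome = genome),
            class = "circ_annotation")
}
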