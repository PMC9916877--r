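#' Merge back-splice calls from two callers into a circRNA catalog
#'
#' Calls from the two callers are grouped when they lie on the same
#' chromosome and strand and both their start and end coordinates agree
#' within `tolerance` nucleotides (single-link over the pairwise relation, so
#' chains collapse to one entry). The group representative takes the
#' coordinates of the member call with the highest total read support (ties:
#' caller A, then smaller start). Per-sample merged counts are the mean of
#' the two callers' counts where both report a sample and the single caller's
#' count otherwise.
#'
#' @param calls_a,calls_b data.frames with columns chrom, start, end, strand,
#'   n_reads, sample_id (coordinates 1-based inclusive). `calls_b` may be
#'   empty.
#' @param tolerance maximum per-end coordinate difference for grouping (nt).
#' @return an object of class `circ_catalog`: list with `table` (data.frame:
#'   circ_id, chrom, start, end, strand, length, support, n_callers) and
#'   `counts` (numeric matrix circ_id x sample_id of merged per-sample
#'   back-spliced read counts).
#' @export
merge_calls <- function(calls_a, calls_b = NULL, tolerance = 10L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_reads = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(calls_b)) calls_b <- empty
  calls_a$caller <- "A"
  if (nrow(calls_b)) calls_b$caller <- "B" else calls_b <- cbind(empty, caller = character(0))
  calls <- rbind(calls_a[, c("chrom", "start", "end", "strand", "n_reads",
                             "sample_id", "caller")],
                 calls_b[, c("chrom", "start", "end", "strand", "n_reads",
                             "sample_id", "caller")])
  if (!nrow(calls)) stop("no calls to merge", call. = FALSE)
  if (any(calls$end < calls$start))
    stop("negative circRNA length: mixed coordinate conventions?", call. = FALSE)
  if (any(calls$n_reads < 0)) stop("negative read counts", call. = FALSE)

  # unique junctions per caller, with total support over samples
  key <- paste(calls$caller, calls$chrom, calls$start, calls$end, calls$strand,
               sep = "\r")
  junc <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  parts <- strsplit(junc$key, "\r", fixed = TRUE)
  junc$caller <- vapply(parts, `[`, "", 1L)
  junc$chrom <- vapply(parts, `[`, "", 2L)
  junc$start <- as.integer(vapply(parts, `[`, "", 3L))
  junc$end <- as.integer(vapply(parts, `[`, "", 4L))
  junc$strand <- vapply(parts, `[`, "", 5L)
  junc$support <- as.vector(tapply(calls$n_reads, key, sum)[junc$key])

  # single-link grouping within (chrom, strand)
  junc$group <- NA_integer_
  next_group <- 0L
  for (blk in split(seq_len(nrow(junc)),
                    paste(junc$chrom, junc$strand, sep = "\r"))) {
    n <- length(blk)
    if (n == 1L) {
      junc$group[blk] <- next_group + 1L
      next_group <- next_group + 1L
      next
    }
    s <- junc$start[blk]; e <- junc$end[blk]
    pairs <- which(outer(s, s, function(x, y) abs(x - y) <= tolerance) &
                     outer(e, e, function(x, y) abs(x - y) <= tolerance),
                   arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(pairs[, 1], pairs[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    junc$group[blk] <- next_group + comp
    next_group <- next_group + max(comp)
  }

  # representative per group: highest support, tie -> caller A, then smaller start
  reps <- do.call(rbind, lapply(split(junc, junc$group), function(jg) {
    ord <- order(-jg$support, jg$caller, jg$start)
    top <- jg[ord[1L], ]
    data.frame(group = top$group, chrom = top$chrom, start = top$start,
               end = top$end, strand = top$strand,
               support = sum(jg$support),
               n_callers = length(unique(jg$caller)),
               stringsAsFactors = FALSE)
  }))
  ord <- order(reps$chrom, reps$start, reps$end)
  reps <- reps[ord, ]
  reps$circ_id <- sprintf("novel_circ_%06d", seq_len(nrow(reps)))

  # per-sample merged counts: sum within caller, then mean over callers present
  calls$group <- junc$group[match(key, junc$key)]
  samples <- sort(unique(calls$sample_id))
  counts <- matrix(0, nrow(reps), length(samples),
                   dimnames = list(reps$circ_id, samples))
  agg <- stats::aggregate(n_reads ~ group + caller + sample_id, calls, sum)
  for (grp in split(agg, agg$group)) {
    cid <- reps$circ_id[match(grp$group[1], reps$group)]
    per_sample <- tapply(grp$n_reads, grp$sample_id, mean)
    counts[cid, names(per_sample)] <- as.vector(per_sample)
  }
  reps$group <- NULL
  reps$length <- reps$end - reps$start + 1L
  reps <- reps[, c("circ_id", "chrom", "start", "end", "strand", "length",
                   "support", "n_callers")]
  rownames(reps) <- NULL
  structure(list(table = reps, counts = counts), class = "circ_catalog")
}

#' Classify the genomic origin of circRNAs
#'
#' Against the annotation, each circRNA is: `exonic` when both back-splice
#' ends fall in exons of a single overlapping gene and the span stays within
#' that gene; `intronic` when the span lies entirely inside one intron;
#' `exon_intron` when it overlaps a gene but is neither purely exonic nor
#' purely intronic; `intergenic` when it overlaps no gene. Overlap is tested
#' on the matching strand first, falling back to either strand when no
#' same-strand gene overlaps (rescued calls are flagged).
#'
#' @param circs data.frame with chrom, start, end, strand (e.g. the `table`
#'   of a `circ_catalog`).
#' @param annotation a `circ_annotation`.
#' @return the input data.frame with columns `origin_class`,
#'   `parent_gene_ids` (comma-separated, empty for intergenic) and
#'   `strand_rescued` added.
#' @export
classify_origin <- function(circs, annotation) {
  for (ch in unique(circs$chrom)) {
    if (!ch %in% names(annotation$genome))
      stop(sprintf("chromosome '%s' absent from annotation", ch), call. = FALSE)
    bad <- circs$chrom == ch & (circs$start < 1L |
                                  circs$end > nchar(annotation$genome[[ch]]))
    if (any(bad)) stop("circRNA outside chromosome bounds", call. = FALSE)
  }
  genes <- annotation$genes
  exons <- annotation$exons
  introns <- annotation_introns(annotation)

  gr_circ <- GenomicRanges::GRanges(circs$chrom,
                                    IRanges::IRanges(circs$start, circs$end),
                                    strand = circs$strand)
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    strand = genes$strand)
  hit_s <- GenomicRanges::findOverlaps(gr_circ, gr_gene)
  hit_any <- GenomicRanges::findOverlaps(gr_circ, gr_gene, ignore.strand = TRUE)

  by_circ_s <- split(S4Vectors::subjectHits(hit_s), S4Vectors::queryHits(hit_s))
  by_circ_a <- split(S4Vectors::subjectHits(hit_any), S4Vectors::queryHits(hit_any))

  n <- nrow(circs)
  origin <- character(n); parents <- character(n); rescued <- logical(n)
  exons_by_gene <- split(exons, exons$gene_id)
  introns_by_gene <- split(introns, introns$gene_id)

  for (i in seq_len(n)) {
    gi <- by_circ_s[[as.character(i)]]
    if (is.null(gi)) {
      gi <- by_circ_a[[as.character(i)]]
      rescued[i] <- !is.null(gi)
    }
    if (is.null(gi)) {
      origin[i] <- "intergenic"; parents[i] <- ""
      next
    }
    s <- circs$start[i]; e <- circs$end[i]
    cls <- "exon_intron"
    for (g in gi) {
      gid <- genes$gene_id[g]
      within_gene <- s >= genes$start[g] && e <= genes$end[g]
      if (!within_gene) next
      ex <- exons_by_gene[[gid]]
      s_in_ex <- any(ex$start <= s & ex$end >= s)
      e_in_ex <- any(ex$start <= e & ex$end >= e)
      if (s_in_ex && e_in_ex) { cls <- "exonic"; break }
      intr <- introns_by_gene[[gid]]
      if (!is.null(intr) && any(intr$start <= s & intr$end >= e)) {
        cls <- "intronic"; break
      }
    }
    origin[i] <- cls
    parents[i] <- paste(genes$gene_id[gi], collapse = ",")
  }
  circs$origin_class <- origin
  circs$parent_gene_ids <- parents
  circs$strand_rescued <- rescued
  circs
}

#' Map circRNAs to parent genes and summarize multiplicities
#'
#' @param classified output of [classify_origin()] (needs `circ_id` and
#'   `parent_gene_ids`).
#' @return list with `map` (data.frame: circ_id, gene_id; one row per pair),
#'   `per_gene` (data.frame: gene_id, n_circ) and `summary` (data.frame:
#'   bin in 1/2/3+, n_genes, fraction).
#' @export
assign_parent_genes <- function(classified) {
  has <- nzchar(classified$parent_gene_ids) & !is.na(classified$parent_gene_ids)
  map <- if (any(has)) {
    genes <- strsplit(classified$parent_gene_ids[has], ",", fixed = TRUE)
    data.frame(circ_id = rep(classified$circ_id[has], lengths(genes)),
               gene_id = unlist(genes), stringsAsFactors = FALSE)
  } else data.frame(circ_id = character(0), gene_id = character(0))
  per_gene <- as.data.frame(table(gene_id = map$gene_id),
                            stringsAsFactors = FALSE)
  names(per_gene)[2] <- "n_circ"
  bin <- cut(per_gene$n_circ, c(0, 1, 2, Inf), labels = c("1", "2", "3+"))
  tab <- table(bin)
  summary <- data.frame(bin = names(tab), n_genes = as.integer(tab),
                        fraction = as.numeric(tab) / max(1L, nrow(per_gene)),
                        stringsAsFactors = FALSE)
  list(map = map, per_gene = per_gene, summary = summary)
}
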