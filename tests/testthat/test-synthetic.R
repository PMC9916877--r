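test_that("annotation generation is deterministic and structurally sound", {
  a1 <- generate_annotation(seed = 1, n_chroms = 2, n_genes = 50)
  a2 <- generate_annotation(seed = 1, n_chroms = 2, n_genes = 50)
  expect_identical(a1, a2)

  expect_equal(nrow(a1$genes), 50)
  # every exon within its gene span
  idx <- match(a1$exons$gene_id, a1$genes$gene_id)
  expect_true(all(a1$exons$start >= a1$genes$start[idx]))
  expect_true(all(a1$exons$end <= a1$genes$end[idx]))
  # genes do not overlap within a chromosome
  for (ch in unique(a1$genes$chrom)) {
    g <- a1$genes[a1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    expect_gte(nchar(a1$genome[[ch]]), max(g$end))
  }
  expect_error(generate_annotation(seed = 1, n_genes = 0), "n_genes")
  expect_error(generate_annotation(seed = 1, exon_length_range = c(5, 2)),
               "increasing")
})

test_that("written GFF and FASTA are byte-identical across runs", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, c("a1.gff3", "a1.fa"))
  p2 <- file.path(d, c("a2.gff3", "a2.fa"))
  write_annotation(generate_annotation(seed = 3, n_genes = 12), p1[1], p1[2])
  write_annotation(generate_annotation(seed = 3, n_genes = 12), p2[1], p2[2])
  expect_identical(readBin(p1[1], "raw", file.size(p1[1])),
                   readBin(p2[1], "raw", file.size(p2[1])))
  expect_identical(readBin(p1[2], "raw", file.size(p1[2])),
                   readBin(p2[2], "raw", file.size(p2[2])))
  # round trip preserves the annotation tables and sequences
  back <- read_annotation(p1[1], p1[2])
  fwd <- generate_annotation(seed = 3, n_genes = 12)
  expect_equal(back$genes, fwd$genes)
  expect_equal(back$exons, fwd$exons)
  expect_identical(back$genome, fwd$genome)
})

test_that("planted circRNA truth re-classifies to its own labels", {
  sim <- noise_free_sim()
  truth <- sim$truth
  reclass <- classify_origin(truth$circ, sim$annotation)
  expect_identical(reclass$origin_class, truth$circ$origin_class)
  # sequences equal fresh extraction (ORF planting happened before extraction)
  fresh <- vapply(seq_len(nrow(truth$circ)), function(i)
    extract_circ_sequence(sim$annotation, truth$circ$chrom[i],
                          truth$circ$start[i], truth$circ$end[i],
                          truth$circ$strand[i], truth$circ$origin_class[i],
                          truth$circ$parent_gene_id[i]), character(1))
  expect_identical(unname(truth$sequences), fresh)
})

test_that("degenerate origin mixes behave as stated", {
  ann <- generate_annotation(seed = 2, n_genes = 20)
  allinter <- generate_circ_truth(ann, n_circ = 40,
                                  origin_mix = c(1, 0, 0, 0), seed = 4)
  expect_true(all(allinter$circ$origin_class == "intergenic"))
  cl <- classify_origin(allinter$circ, allinter$annotation)
  expect_true(all(cl$origin_class == "intergenic"))
  expect_true(all(!nzchar(cl$parent_gene_ids)))
  expect_error(generate_circ_truth(ann, origin_mix = c(0.5, 0.5, 0.1, 0)),
               "sum")
  # single-exon-only annotation cannot host intron-dependent classes
  flat <- generate_annotation(seed = 2, n_genes = 10,
                              exons_per_gene_range = c(1, 1))
  expect_error(generate_circ_truth(flat, origin_mix = c(0.5, 0.3, 0.2, 0)),
               "intron")
})

test_that("minus-strand sequences are reverse complements of plus extraction", {
  sim <- noise_free_sim()
  circ <- sim$truth$circ
  minus <- which(circ$strand == "-")[1:5]
  for (i in minus) {
    plus_seq <- extract_circ_sequence(sim$annotation, circ$chrom[i],
                                      circ$start[i], circ$end[i], "+",
                                      circ$origin_class[i],
                                      circ$parent_gene_id[i])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus_seq)))
    expect_identical(unname(sim$truth$sequences[circ$circ_id[i]]), rc)
  }
})

test_that("realized origin proportions converge to the requested mix", {
  ann <- generate_annotation(seed = 8, n_chroms = 4, n_genes = 300)
  mix <- c(intergenic = 0.572, exonic = 0.402, intronic = 0.010,
           exon_intron = 0.016)
  truth <- generate_circ_truth(ann, n_circ = 2000, origin_mix = mix, seed = 8)
  counts <- table(factor(truth$circ$origin_class, names(mix)))
  for (k in names(mix)) {
    sdk <- sqrt(2000 * mix[[k]] * (1 - mix[[k]]))
    expect_lte(abs(counts[[k]] - 2000 * mix[[k]]), 3 * sdk + 1)
  }
})

test_that("structural zeros are exact for SPE and SFE patterns", {
  sim <- noisy_sim()
  counts <- sim$expression$counts
  pat <- sim$expression$parental_pattern
  s <- sim$design$samples
  mp_cols <- s$sample_id[s$genotype == "MP"]
  fp_cols <- s$sample_id[s$genotype == "FP"]
  spe_f <- pat$circ_id[pat$pattern == "SPE_F"]
  spe_m <- pat$circ_id[pat$pattern == "SPE_M"]
  sfe <- pat$circ_id[pat$pattern == "SFE"]
  expect_true(all(counts[spe_f, mp_cols] == 0))
  expect_true(all(counts[spe_m, fp_cols] == 0))
  expect_true(all(counts[sfe, c(fp_cols, mp_cols)] == 0))
  # planted expected means satisfy the class definitions
  er <- sim$expression$expected_rpm
  lab <- sim$expression$class_labels
  mpv <- (er[, "FP"] + er[, "MP"]) / 2
  for (g in unique(lab$genotype)) {
    lg <- lab[lab$genotype == g, ]
    add <- lg$circ_id[lg$class == "additive"]
    expect_equal(er[add, g], mpv[add])
    ahp <- lg$circ_id[lg$class == "AHP"]
    expect_true(all(er[ahp, g] > er[ahp, "FP"]))
    expect_true(all(er[ahp, g] > mpv[ahp]))
    blp <- lg$circ_id[lg$class == "BLP"]
    expect_true(all(er[blp, g] < pmax(er[blp, "MP"], 1 + 1e-12)))
    lp <- lg$circ_id[lg$class == "LP"]
    expect_true(all(er[lp, g] < mpv[lp]))
    expect_true(all(er[lp, g] >= er[lp, "MP"]))
  }
})

test_that("expression generation validates inputs and respects the noise model", {
  sim <- noise_free_sim()
  expect_error(generate_expression(sim$truth, sim$design,
                                   class_mix = c(additive = 0.5, AHP = 0.4,
                                                 HP = 0, LP = 0, BLP = 0)),
               "sum")
  expect_error(generate_expression(sim$truth, sim$design, effect_fold = 1),
               "effect_fold")
  expect_error(generate_expression(sim$truth, sim$design, dispersion = -1),
               "dispersion")
  e1 <- generate_expression(sim$truth, sim$design, dispersion = 0, seed = 2)
  e2 <- generate_expression(sim$truth, sim$design, dispersion = 0, seed = 2)
  expect_identical(e1$counts, e2$counts)
  # Poisson limit has tighter replicate scatter than a strongly overdispersed draw
  e3 <- generate_expression(sim$truth, sim$design, dispersion = 2, seed = 2)
  cv <- function(m) {
    s <- sim$design$samples
    reps <- m[, s$sample_id[s$genotype == "H1"], drop = FALSE]
    mu <- rowMeans(reps)
    stats::median((apply(reps, 1, sd) / pmax(mu, 1))[mu > 10])
  }
  expect_lt(cv(e1$counts), cv(e3$counts))
})

test_that("planted ORFs and miRNA sites obey their contracts", {
  sim <- noise_free_sim()
  orfs <- sim$truth$planted_orfs
  expect_gt(nrow(orfs), 0)
  expect_true(all(orfs$length_nt %% 3 == 0))
  expect_true(all(orfs$length_nt >= 63))
  expect_true(all(orfs$spans_junction))

  mir <- sim$mirnas
  expect_true(all(nchar(mir$mirnas) %in% 20:22))
  expect_gt(nrow(mir$planted_targets), 0)
  for (i in seq_len(nrow(mir$planted_targets))) {
    tg <- mir$planted_targets[i, ]
    s <- sim$truth$sequences[[tg$circ_id]]
    L <- nchar(mir$mirnas[[tg$mirna_id]])
    ext <- paste0(s, substr(s, 1, L - 1))
    window <- substr(ext, tg$offset + 1, tg$offset + L)
    expect_identical(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(window))),
      unname(mir$mirnas[[tg$mirna_id]]))
  }
  empty <- generate_mirnas(sim$truth, n_mirnas = 0)
  expect_identical(nrow(empty$planted_targets), 0L)
})

test_that("caller emulation is bounded and degenerates cleanly", {
  sim <- noise_free_sim()
  calls <- sim$calls
  # noise-free: both callers report identical coordinates
  key <- function(df) paste(df$chrom, df$start, df$end, df$strand)
  expect_setequal(unique(key(calls$calls_A)), unique(key(calls$calls_B)))
  expect_error(generate_caller_calls(sim$truth, sim$expression$counts,
                                     fn_rate = 1), "fn_rate")
  # jitter never exceeds 5 nt per end
  jit <- generate_caller_calls(sim$truth, sim$expression$counts,
                               jitter_sd = 50, fn_rate = 0, count_noise = 0,
                               seed = 2)
  for (df in jit) {
    idx <- circheterosis:::match_catalog_to_truth(
      df[!duplicated(paste(df$chrom, df$start, df$end, df$strand)), ],
      sim$truth)
    expect_true(all(!is.na(idx)))
  }
})
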