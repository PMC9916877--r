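test_that("Stupar subtypes follow the growth-potential parent rule", {
  # F1 significantly above MPV: AHP above the female (high) parent, else HP
  expect_identical(classify_stupar(100, 80, 20, "up"), "AHP")
  expect_identical(classify_stupar(60, 80, 20, "up"), "HP")
  # significantly below: BLP below the male (low) parent, else LP
  expect_identical(classify_stupar(10, 80, 20, "down"), "BLP")
  expect_identical(classify_stupar(30, 80, 20, "down"), "LP")
  # vectorized
  expect_identical(classify_stupar(c(100, 60), c(80, 80), c(20, 20),
                                   c("up", "up")), c("AHP", "HP"))
  # the flag restores the higher-expressing-parent convention: an F1 between
  # the parents is above the fixed (female) high parent but below the
  # higher-expressing one
  expect_identical(classify_stupar(60, 20, 80, "up"), "AHP")
  expect_identical(classify_stupar(60, 20, 80, "up",
                                   stupar_by_expression = TRUE), "HP")
  expect_error(classify_stupar(10, 20, 30, "ns"), "additive")
})

test_that("parental patterns partition expressed circRNAs", {
  des <- tiny_design(c("H1", "L1"))
  pres <- matrix(FALSE, 4, 4,
                 dimnames = list(sprintf("c%d", 1:4), c("FP", "MP", "H1", "L1")))
  pres["c1", c("FP", "H1")] <- TRUE          # SPE_F
  pres["c2", c("MP")] <- TRUE                # SPE_M, silent in F1
  pres["c3", c("FP", "MP", "L1")] <- TRUE    # CoPE
  pres["c4", c("H1", "L1")] <- TRUE          # SFE
  pat <- classify_parental_pattern(pres, des)
  expect_identical(pat$pattern, c("SPE_F", "SPE_M", "CoPE", "none"))
  expect_identical(pat$sfe, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(pat$f1_expressed, c(TRUE, FALSE, TRUE, TRUE))

  # planted patterns recovered exactly on the simulated study
  sim <- noisy_sim()
  rpm <- rpm_normalize(sim$expression$counts, sim$design$mapped_reads)
  pres2 <- detect_expressed(rpm, sim$design)$presence
  pat2 <- classify_parental_pattern(pres2, sim$design)
  planted <- sim$expression$parental_pattern
  pred <- ifelse(pat2$sfe, "SFE", pat2$pattern)
  expect_identical(pred, planted$pattern[match(pat2$circ_id, planted$circ_id)])
  # SPE_F and SPE_M are disjoint by construction
  expect_equal(sum(pat2$pattern == "SPE_F" & pat2$pattern == "SPE_M"), 0)
})

test_that("additivity calls partition tested features and recover planted labels", {
  sim <- noisy_sim()
  het <- heterosis_calls(sim$expression$counts, sim$design)
  tested <- het[!is.na(het$additivity), ]
  # every tested call is additive xor non-additive; subtype iff non-additive
  expect_true(all(tested$additivity %in% c("additive", "non_additive")))
  expect_true(all((tested$stupar != "none") ==
                    (tested$additivity == "non_additive")))
  # per-genotype: additive + non_additive = tested features
  for (g in unique(tested$f1_genotype)) {
    sub <- tested[tested$f1_genotype == g, ]
    expect_equal(sum(sub$additivity == "additive") +
                   sum(sub$additivity == "non_additive"), nrow(sub))
  }
  # planted recovery at 4-fold effects, 3 replicates
  lab <- sim$expression$class_labels
  key <- paste(het$circ_id, het$f1_genotype)
  truth_cls <- lab$class[match(key, paste(lab$circ_id, lab$genotype))]
  ok <- !is.na(het$additivity)
  pred <- het$additivity[ok]
  tru <- ifelse(truth_cls[ok] == "additive", "additive", "non_additive")
  expect_gte(mean(pred == tru), 0.95)
})

test_that("SPE counting and DEC intersection bookkeeping are exact", {
  pats <- data.frame(pattern = c(rep("SPE_F", 3), rep("SPE_M", 2),
                                 "CoPE", "none"))
  sp <- count_spe(pats)
  expect_equal(sp$n_spe_f, 3)
  expect_equal(sp$n_spe_m, 2)
  expect_equal(sp$n_spe_total, 5)

  # four DEC tables with a planted decomposition
  feats <- sprintf("c%03d", 1:100)
  mk_dec <- function(up, down) {
    dir <- rep("ns", 100)
    dir[up] <- "up"; dir[down] <- "down"
    data.frame(feature_id = feats, direction = dir, stringsAsFactors = FALSE)
  }
  # 1:10 up everywhere, 11:17 down everywhere, 18 mixed, 19:30 DEC in some only
  tabs <- list(mk_dec(c(1:10, 18, 19:24), c(11:17)),
               mk_dec(c(1:10, 18), c(11:17, 25:30)),
               mk_dec(c(1:10), c(11:17, 18)),
               mk_dec(c(1:10, 18), c(11:17)))
  dec <- codec_decompose(tabs)
  expect_equal(dec$counts$n_co_dec, 18)
  expect_equal(dec$counts$n_all_up, 10)
  expect_equal(dec$counts$n_all_down, 7)
  expect_equal(dec$counts$n_mixed, 1)
  expect_identical(dec$co_dec$concordance[dec$co_dec$feature_id == "c018"],
                   "mixed")
  # empty intersection
  empty <- codec_decompose(list(mk_dec(1, 2), mk_dec(3, 4)))
  expect_equal(empty$counts$n_co_dec, 0)
  # mismatched catalogs are rejected
  bad <- mk_dec(1, 2)[1:50, ]
  expect_error(codec_decompose(list(mk_dec(1, 2), bad)), "mismatched")
})

test_that("recovered co-DEC directions agree with planted group means", {
  sim <- noisy_sim()
  high <- c("H1", "H2"); low <- c("L1", "L2")
  decs <- lapply(expand.grid(l = low, h = high, stringsAsFactors = FALSE) |>
                   asplit(1), function(pr)
    de_compare(sim$expression$counts, sim$design, pr[["l"]], pr[["h"]]))
  dec <- codec_decompose(decs)
  expect_gt(dec$counts$n_co_dec, 0)
  er <- sim$expression$expected_rpm
  planted_lfc <- log2((er[dec$co_dec$feature_id, "L1"] + 0.1) /
                        (er[dec$co_dec$feature_id, "H1"] + 0.1))
  expect_true(all(dec$co_dec$concordance[planted_lfc > 0.5] == "all_up"))
  expect_true(all(dec$co_dec$concordance[planted_lfc < -0.5] == "all_down"))
  # strongly planted differences (>= 4-fold, well expressed) are all recovered
  strong <- rownames(er)[abs(log2((er[, "L1"] + 0.1) / (er[, "H1"] + 0.1))) >= 2 &
                           pmax(er[, "L1"], er[, "H1"]) >= 10]
  expect_gte(mean(strong %in% dec$co_dec$feature_id), 0.95)
})

test_that("summary tables stay internally consistent on a full run", {
  sim <- noisy_sim()
  het <- heterosis_calls(sim$expression$counts, sim$design)
  parent_dec <- de_compare(sim$expression$counts, sim$design, "MP", "FP")
  f1_dec <- list(de_compare(sim$expression$counts, sim$design, "L1", "H1"),
                 de_compare(sim$expression$counts, sim$design, "L2", "H1"))
  s <- summarize_patterns(het, parent_dec, f1_dec)
  # Stupar subtype counts sum to the non-additive count per genotype
  stopifnot(identical(s$additivity$genotype, s$stupar$genotype))
  expect_equal(rowSums(s$stupar[, c("AHP", "HP", "LP", "BLP")]),
               s$additivity$non_additive)
  # SPE total is the sum of its two components
  expect_equal(s$spe$n_spe_total, s$spe$n_spe_f + s$spe$n_spe_m)
  # SPE circRNAs inside the parental DEC set can never exceed either set
  expect_lte(s$spe_in_parent_dec$n_spe_in_dec, s$spe_in_parent_dec$n_parent_dec)
  expect_lte(s$spe_in_parent_dec$n_spe_in_dec, s$spe$n_spe_total)
  expect_equal(s$spe_in_parent_dec$n_spe_in_dec,
               s$spe_in_parent_dec$n_spe_f_in_dec +
                 s$spe_in_parent_dec$n_spe_m_in_dec)
  # common non-additive membership uses the at-least-two rule
  common <- common_nonadditive(het, c("H1", "H2", "H3"), k = 2)
  tab <- table(het$circ_id[het$f1_genotype %in% c("H1", "H2", "H3") &
                             !is.na(het$additivity) &
                             het$additivity == "non_additive"])
  expect_setequal(common, names(tab)[tab >= 2])
})
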