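test_that("TOM matches brute-force evaluation and its limit cases", {
  mat <- orthogonal_blocks()[c(1:10, 31:40), ]
  beta <- 6
  tom <- build_tom(mat, beta)
  # brute force, element by element
  a <- abs(cor(t(mat)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    brute[i, j] <- (sum(a[i, ] * a[, j]) + a[i, j]) /
      (min(k[i], k[j]) + 1 - a[i, j])
  }
  diag(brute) <- 1
  expect_lt(max(abs(tom - brute)), 1e-10)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  # two identical profiles in isolation: a = 1, TOM = 1
  two <- rbind(f1 = c(1, 2, 3, 4, 2), f2 = c(1, 2, 3, 4, 2) * 2)
  t2 <- build_tom(two, 6)
  expect_equal(unname(t2[1, 2]), 1)
  # orthogonal profiles with no shared neighbours: TOM ~ 0
  orth <- rbind(f1 = rep(c(1, -1), 4), f2 = rep(c(1, 1, -1, -1), 2))
  expect_lt(build_tom(orth, 6)[1, 2], 1e-6)
  expect_error(build_tom(two, 0.5), "beta")
})

test_that("soft-threshold selection respects its contract", {
  mat <- orthogonal_blocks()
  expect_error(pick_beta(mat[, 1:3]), "4 samples")
  # r2_target = 0 returns the smallest candidate power
  expect_equal(pick_beta(mat, candidate_powers = 2:8, r2_target = 0)$beta, 2)
  # constant rows dropped with a warning
  matc <- rbind(mat, constant = rep(1, ncol(mat)))
  expect_warning(pick_beta(matc, r2_target = 0), "constant")
  # fallback warning when nothing qualifies
  expect_warning(b <- pick_beta(mat[1:10, ], r2_target = 0.999999)$beta,
                 "using 6")
})

test_that("planted orthogonal blocks are recovered as modules", {
  mat <- orthogonal_blocks(noise_sd = 0.1)
  truth <- attr(mat, "truth")
  tom <- build_tom(mat, 6)
  mods <- detect_modules(tom, min_module_size = 5)
  expect_gte(rand_index(mods, truth), 0.95)
  expect_equal(length(setdiff(unique(mods), "grey")), 3)
  # labels are size-ordered WGCNA colors
  expect_true(all(mods %in% c("turquoise", "blue", "brown")))
  # min_module_size larger than n -> everything grey
  expect_warning(g <- detect_modules(tom, min_module_size = 1000), "grey")
  expect_true(all(g == "grey"))
  # permutation invariance up to label names (co-membership identical)
  perm <- sample(nrow(mat))
  mods_p <- detect_modules(build_tom(mat[perm, ], 6), min_module_size = 5)
  mods_p <- mods_p[rownames(mat)]
  expect_equal(rand_index(mods, mods_p), 1)
})

test_that("eigengenes summarize modules with a deterministic orientation", {
  mat <- orthogonal_blocks(noise_sd = 0.1)
  tom <- build_tom(mat, 6)
  mods <- detect_modules(tom, min_module_size = 5)
  eg <- module_eigengenes(mat, mods)
  expect_equal(sort(rownames(eg)), sort(setdiff(unique(mods), "grey")))
  for (m in rownames(eg)) {
    v <- eg[m, ]
    expect_equal(sum(v^2), 1, tolerance = 1e-8)          # unit norm
    members <- mat[names(mods)[mods == m], , drop = FALSE]
    expect_gt(mean(cor(v, t(members))), 0)               # orientation rule
    # PC1 explains at least as much variance as any member profile direction
    z <- t(scale(t(members)))
    var_along <- function(d) sum((z %*% d / sqrt(sum(d^2)))^2)
    for (i in 1:5) expect_gte(var_along(v) + 1e-8, var_along(z[i, ]))
  }
})

test_that("module-trait correlation flags the planted driver genotype group", {
  sim <- noisy_sim()
  rpm <- rpm_normalize(sim$expression$counts, sim$design$mapped_reads)
  # features planted high in the high-growth F1s and low elsewhere
  er <- sim$expression$expected_rpm
  lfc <- log2((er[, "H1"] + 0.1) / (pmax(er[, "FP"], er[, "MP"], er[, "L1"]) + 0.1))
  drivers <- names(sort(lfc, decreasing = TRUE))[1:12]
  assignments <- setNames(rep("blue", length(drivers)), drivers)
  eg <- module_eigengenes(rpm[drivers, ], assignments)
  mt <- module_trait(eg, sim$design, encoding = "role")
  expect_gt(mt$r["blue", "F1_high"], 0)
  expect_equal(colnames(mt$r), sort(unique(sim$design$samples$role)))
  expect_true(mt$r["blue", "F1_high"] == max(mt$r["blue", ]))
  # p-values match the t-transform of r
  n <- ncol(eg)
  expect_equal(unname(mt$p["blue", "F1_high"]),
               2 * pt(abs(mt$r["blue", "F1_high"]) *
                        sqrt((n - 2) / (1 - mt$r["blue", "F1_high"]^2)),
                      n - 2, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("hub selection ranks by intramodular connectivity", {
  set.seed(4)
  hub_profile <- rnorm(10)
  mat <- rbind(hub = hub_profile,
               t(sapply(1:29, function(i) hub_profile + rnorm(10, 0, 0.6))))
  rownames(mat) <- c("hub", sprintf("m%02d", 1:29))
  assignments <- setNames(rep("blue", 30), rownames(mat))
  hubs <- select_hubs(mat, assignments, "blue", k = 5, beta = 6)
  expect_equal(hubs$feature_id[1], "hub")
  expect_equal(nrow(hubs), 5)
  expect_true(all(diff(hubs$k_within) <= 0))
  expect_equal(nrow(select_hubs(mat, assignments, "blue", k = 0)), 0)
  expect_warning(all30 <- select_hubs(mat, assignments, "blue", k = 50),
                 "fewer")
  expect_equal(nrow(all30), 30)
  # stable under adding pure-noise features outside the module
  noise <- matrix(rnorm(300), 30, 10,
                  dimnames = list(sprintf("n%02d", 1:30), NULL))
  colnames(noise) <- colnames(mat)
  big <- rbind(mat, noise)
  a2 <- c(assignments, setNames(rep("grey", 30), rownames(noise)))
  hubs2 <- select_hubs(big, a2, "blue", k = 5, beta = 6)
  expect_identical(hubs2$feature_id, hubs$feature_id)
  expect_error(select_hubs(mat, assignments, "red"), "not found")
})

test_that("hypergeometric enrichment equals the closed-form tail sum", {
  universe <- sprintf("f%02d", 1:40)
  terms <- data.frame(
    feature_id = c(universe[1:8], universe[5:20]),
    term = c(rep("T1", 8), rep("T2", 16)), stringsAsFactors = FALSE)
  fset <- universe[1:10]
  res <- enrich_hypergeometric(fset, terms, universe)
  # closed form: P(X >= x) for hypergeometric(N, K, n)
  closed <- function(x, K, N, n)
    sum(choose(K, x:min(K, n)) * choose(N - K, n - (x:min(K, n)))) / choose(N, n)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$p, closed(r1$n_overlap, 8, 40, 10), tolerance = 1e-12)
  r2 <- res[res$term == "T2", ]
  expect_equal(r2$p, closed(r2$n_overlap, 16, 40, 10), tolerance = 1e-12)
  # disjoint set: x = 0 so the upper tail is everything
  disj <- enrich_hypergeometric(universe[30:35], terms[1:8, ], universe)
  expect_equal(disj$p, 1)
  # saturated set: every term's p = 1
  sat <- enrich_hypergeometric(universe, terms, universe)
  expect_true(all(sat$p == 1))
  expect_error(enrich_hypergeometric(c("zzz"), terms, universe), "subset")
})

test_that("module bookkeeping averages features over modules", {
  a <- setNames(c(rep("blue", 10), rep("brown", 5), rep("grey", 3)),
                sprintf("f%02d", 1:18))
  s <- module_size_summary(a)
  expect_equal(s$n_features, 15)
  expect_equal(s$n_modules, 2)
  expect_equal(s$mean_per_module, 7.5)
})
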