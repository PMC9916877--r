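# shared fixtures and small independent oracles

# memoize expensive simulations across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

noise_free_sim <- function() {
  cached("noise_free", suppressWarnings(
    simulate_study(seed = 11, jitter_sd = 0, fn_rate = 0, count_noise = 0)))
}

noisy_sim <- function() {
  cached("noisy", suppressWarnings(simulate_study(seed = 5, n_circ = 200)))
}

# Rand index between two partitions (pair-counting)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# three orthogonal feature blocks over 12 samples
orthogonal_blocks <- function(noise_sd = 0.1, per_block = 30, seed = 9) {
  set.seed(seed)
  bases <- list(rep(c(1, -1), 6), rep(c(1, 1, -1, -1), 3),
                rep(c(1, 1, 1, -1, -1, -1), 2))
  mat <- do.call(rbind, lapply(bases, function(b)
    t(sapply(seq_len(per_block), function(i) b + rnorm(12, 0, noise_sd)))))
  rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", 1:12)
  attr(mat, "truth") <- rep(1:3, each = per_block)
  mat
}

# independent ORF oracle: codon-walk over an explicitly doubled/wrapped
# sequence using substring arithmetic only
oracle_orfs <- function(s, min_orf_nt = 63, max_wraps = 4) {
  L <- nchar(s)
  big <- paste(rep(s, max_wraps), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  out <- NULL
  for (p in seq_len(L)) {
    if (substr(big, p, p + 2) != "ATG") next
    q <- p; len <- NA; rolling <- FALSE
    repeat {
      if (q + 2 > nchar(big)) {
        len <- ((nchar(big) - p + 1) %/% 3) * 3
        rolling <- TRUE
        break
      }
      if (substr(big, q, q + 2) %in% stops) { len <- q + 2 - p + 1; break }
      q <- q + 3
    }
    if (len >= min_orf_nt)
      out <- rbind(out, data.frame(start_offset = p - 1, length_nt = len,
                                   spans_junction = (p - 1 + len) > L,
                                   rolling = rolling))
  }
  if (is.null(out))
    data.frame(start_offset = integer(0), length_nt = integer(0),
               spans_junction = logical(0), rolling = logical(0))
  else out
}

# a circular sequence whose only ORF is ATG + n_inner C/G codons + stop,
# crossing the back-splice junction
planted_orf_circle <- function(len = 300, n_inner = 19, tail_nt = 10,
                               seed = 1) {
  set.seed(seed)
  orf <- paste0("ATG", paste(sample(c("CCG", "CGC", "GGC", "GCG", "CCC", "GGG"),
                                    n_inner, replace = TRUE), collapse = ""),
                "TAA")
  orf_len <- nchar(orf)
  offset <- len - tail_nt  # 0-based start; ORF wraps after tail_nt bases
  circle <- strsplit(paste(sample(c("C", "G"), len, replace = TRUE),
                           collapse = ""), "")[[1]]
  pos <- ((offset + seq_len(orf_len) - 1) %% len) + 1
  circle[pos] <- strsplit(orf, "")[[1]]
  list(seq = paste(circle, collapse = ""), offset = offset,
       length_nt = orf_len)
}

# minimal design: FP, MP and one or more F1 genotypes, equal library sizes
tiny_design <- function(f1 = c("H1"), n_reps = 3, lib = 1e6) {
  genos <- c("FP", "MP", f1)
  roles <- c("FP", "MP", ifelse(grepl("^H", f1), "F1_high", "F1_low"))
  samples <- do.call(rbind, lapply(seq_along(genos), function(g)
    data.frame(sample_id = sprintf("%s_r%d", genos[g], seq_len(n_reps)),
               genotype = genos[g], role = roles[g], replicate = seq_len(n_reps),
               stringsAsFactors = FALSE)))
  mapped <- setNames(rep(lib, nrow(samples)), samples$sample_id)
  structure(list(samples = samples, mapped_reads = mapped),
            class = "sample_design")
}
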