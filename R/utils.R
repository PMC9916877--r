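# Internal helpers shared across modules.

# reverse complement of a DNA string given as plain character
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# random DNA of length n from the current RNG stream
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# write a data.frame as TSV without quoting or row names
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# two-sided p-value for a Pearson r via the exact t transform
pearson_p <- function(r, n) {
  ifelse(is.na(r) | n < 3, NA_real_, {
    tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  })
}
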