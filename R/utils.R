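# internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# random DNA string(s)
random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

# substitute single positions (1-based) in a sequence string
substitute_bases <- function(seq, positions, bases) {
  stopifnot(length(positions) == length(bases))
  for (i in seq_along(positions)) {
    substr(seq, positions[i], positions[i]) <- bases[i]
  }
  seq
}

# Hamming mismatches over the common prefix of two strings
prefix_mismatch_positions <- function(a, b) {
  l <- min(nchar(a), nchar(b))
  if (l == 0L) return(integer(0))
  av <- strsplit(substr(a, 1L, l), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, l), "", fixed = TRUE)[[1]]
  which(av != bv)
}

assert_frequency_vector <- function(x, what, tol = 1e-9) {
  if (any(x < 0)) stop(what, ": frequencies must be non-negative", call. = FALSE)
  if (abs(sum(x) - 1) > tol) {
    stop(what, ": frequencies must sum to 1 (got ", format(sum(x)), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic child seeds below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
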