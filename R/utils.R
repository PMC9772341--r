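# Internal helpers shared across modules.

# Split residue string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Integer codes 1..20 for canonical residues, NA for ambiguity codes.
aa_codes <- function(residues) {
  match(chars(residues), amino_acids())
}

# Validate a residue string: canonical + tolerated ambiguity codes only.
check_alphabet <- function(residues, id = "<sequence>") {
  ok <- c(amino_acids(), AMBIGUOUS_CODES)
  bad <- setdiff(unique(chars(residues)), ok)
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' contains invalid residue code(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# log2(2^a + 2^b) elementwise, safe for -Inf.
log2sum <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log2(2^(a - m) + 2^(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# Deterministic sub-seed derivation: one stream per generator operation.
# Keeps derived seeds inside the 32-bit integer range.
split_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}
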