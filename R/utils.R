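# Internal helpers shared across modules.

# The 20 proteinogenic residues, and the extended set tolerated in databases
# (X unknown, U selenocysteine, B Asx, Z Glx).
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_EXTENDED <- c(AA_STANDARD, "X", "U", "B", "Z")
PAD_CHAR <- "-"

abort_validation <- function(msg, ...) {
  abort(msg, class = "ligandr_validation_error", ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = c("ligandr_parse_error", "ligandr_validation_error"), ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = "ligandr_io_error", ...)
}

# TRUE where a string is made only of the given residue alphabet.
is_valid_sequence <- function(x, alphabet = AA_EXTENDED) {
  pattern <- sprintf("^[%s]+$", paste(alphabet, collapse = ""))
  nzchar(x) & grepl(pattern, x)
}

# First offending character of each invalid string (NA where valid).
offending_residue <- function(x, alphabet = AA_EXTENDED) {
  pattern <- sprintf("[^%s]", paste(alphabet, collapse = ""))
  m <- regmatches(x, regexpr(pattern, x))
  out <- rep(NA_character_, length(x))
  hit <- regexpr(pattern, x) > 0
  out[hit] <- m
  out
}

# Integer allocation of n slots to fractions summing to 1 (largest remainder;
# ties broken by position so the result is deterministic).
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort_validation("organism fractions must sum to 1")
  }
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# sample() treats a length-1 numeric as 1:x; this keeps a degenerate
# range (min == max) meaning "that one value".
sample_from <- function(values, n) {
  if (length(values) == 1) {
    rep(values, n)
  } else {
    sample(values, n, replace = TRUE)
  }
}

# One seeded RNG scope per generator call; never touches global state
# beyond the scope of `code`.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_validation("`seed` must be a single integer")
  }
  withr::with_seed(as.integer(seed), code)
}
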