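#' Extract flanking n-mers around identified peptides
#'
#' For every (peptide, mapping interval) pair — repeated occurrences
#' contribute their own local context, since cleavage context is positional —
#' takes the `n` residues immediately before the mapping start (upstream) and
#' after its end (downstream) in the parent protein, padding with `-` at
#' protein termini so both flanks always have length `n`.
#'
#' @param exp A `pepexp`.
#' @param n Flank length (default 5).
#' @return A tibble of class `flank_set` with columns `peptide`, `protein`,
#'   `start`, `upstream`, `downstream`, and the flank length in attribute `n`.
#' @export
extract_flanks <- function(exp, n = 5) {
  stopifnot(inherits(exp, "pepexp"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_validation("`n` must be a positive integer")
  }
  n <- as.integer(n)
  m <- exp$mappings
  seqs <- exp$proteins[m$protein]
  len <- nchar(seqs)

  up_raw <- substr(seqs, pmax(m$start - n + 1L, 1L), m$start)
  up <- paste0(strrep(PAD_CHAR, n - nchar(up_raw)), up_raw)
  down_raw <- substr(seqs, m$end + 1L, pmin(m$end + n, len))
  down <- paste0(down_raw, strrep(PAD_CHAR, n - nchar(down_raw)))

  structure(
    tibble(
      peptide = m$peptide, protein = m$protein, start = m$start,
      upstream = up, downstream = down
    ),
    n = n, pad_char = PAD_CHAR,
    class = c("flank_set", class(tibble()))
  )
}

#' Write a flank set to TSV
#'
#' Columns `peptide`, `protein`, `start`, `upstream`, `downstream` — directly
#' usable as input to external motif tools.
#'
#' @param flanks A `flank_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flank_table <- function(flanks, path) {
  readr::write_tsv(as_tibble(flanks), path)
  invisible(path)
}

#' Position frequency matrix of equal-length sequences
#'
#' Column-wise residue frequencies over the 20-letter amino-acid alphabet plus
#' the `-` padding character; each row (position) sums to 1.
#'
#' @param seqs Character vector of equal-length sequences (e.g. the upstream
#'   flanks of a [extract_flanks()] result).
#' @return A numeric matrix of class `pfm` (positions x alphabet) with the
#'   number of sequences in attribute `n_sequences`.
#' @export
position_frequency_matrix <- function(seqs) {
  if (length(seqs) == 0) {
    abort_validation("at least one sequence is required")
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) {
    abort_validation(sprintf(
      "sequences must have equal length (found lengths %s)",
      paste(sort(lens), collapse = ", ")
    ))
  }
  alphabet <- c(AA_STANDARD, PAD_CHAR)
  chars <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  bad <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "residue(s) outside the 20-letter alphabet: %s",
      paste(bad, collapse = ", ")
    ))
  }
  counts <- t(apply(chars, 2, function(col) {
    tabulate(factor(col, levels = alphabet), nbins = length(alphabet))
  }))
  freqs <- counts / length(seqs)
  dimnames(freqs) <- list(seq_len(lens) - 1L, alphabet)
  structure(freqs,
    n_sequences = length(seqs),
    class = c("pfm", "matrix", "array")
  )
}

#' @method print pfm
#' @export
print.pfm <- function(x, ...) {
  cat(sprintf(
    "<pfm> %d position(s) over %d sequence(s)\n",
    nrow(x), attr(x, "n_sequences")
  ))
  m <- x
  class(m) <- c("matrix", "array")
  attr(m, "n_sequences") <- NULL
  print(round(m, 3))
  invisible(x)
}

#' @method tidy pfm
#' @export
tidy.pfm <- function(x, ...) {
  m <- x
  class(m) <- c("matrix", "array")
  attr(m, "n_sequences") <- NULL
  out <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(out) <- c("position", "residue", "frequency")
  out$position <- as.integer(out$position)
  out
}

#' Write a position frequency matrix to TSV
#' @param pfm A `pfm` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  m <- pfm
  class(m) <- c("matrix", "array")
  attr(m, "n_sequences") <- NULL
  out <- tibble(position = as.integer(rownames(m)), !!!as_tibble(m))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Per-position information content of a position frequency matrix
#'
#' `IC_p = log2(20) - H_p`, where the Shannon entropy `H_p` is taken over the
#' 20 amino-acid frequencies after renormalizing out the padding mass; an
#' all-padding position carries no sequence information and gets IC 0.
#'
#' @param pfm A `pfm` matrix.
#' @return Numeric vector of bits per position, in `[0, log2(20)]`.
#' @export
information_content <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  aa <- pfm[, AA_STANDARD, drop = FALSE]
  apply(aa, 1, function(f) {
    s <- sum(f)
    if (s <= 0) {
      return(0)
    }
    fn <- f[f > 0] / s
    log2(20) + sum(fn * log2(fn))
  })
}
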