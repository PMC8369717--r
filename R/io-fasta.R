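#' Read a protein FASTA file into a sequence database
#'
#' Parses a FASTA file (UniProt header dialect or plain headers) into a
#' `seq_db` tibble with one row per record. For UniProt-style headers
#' (`>db|ACC|ENTRY description OS=... OX=...`) the accession is the second
#' pipe-delimited field and the organism is the `OS=` value, which runs until
#' the next `XX=` token or the end of the line. For plain headers the accession
#' is the first whitespace-delimited token and the organism is unknown (`NA`).
#'
#' Sequences are uppercased and must use the 20-letter amino-acid alphabet plus
#' `X`/`U`/`B`/`Z`; any other character, a duplicate accession, or sequence
#' data before the first header is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of class `seq_db` with columns `accession`, `entry_name`,
#'   `organism` (`NA` when unknown), `description`, `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(
#'   ">sp|P02774|VTDB_HUMAN Vitamin D-binding protein OS=Homo sapiens OX=9606",
#'   "MKRVLVLLLAVAFGHA"
#' ), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("FASTA file does not exist: '%s'", path))
  }
  if (file.size(path) == 0) {
    abort_parse(sprintf("FASTA file is empty: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort_parse(sprintf("FASTA file contains no records: '%s'", path))
  }
  first <- nonblank[[1]]
  if (!startsWith(trimws(lines[[first]]), ">")) {
    abort_parse(sprintf(
      "malformed FASTA: sequence data before the first header (line %d)", first
    ))
  }

  # read without alphabet restriction so residue validation (and its error
  # message) stays in one place below
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    abort_parse(sprintf("FASTA file contains no records: '%s'", path))
  }
  header <- names(seqs)
  sequence <- toupper(as.character(seqs))
  names(sequence) <- NULL

  parsed <- parse_fasta_headers(header)

  dup <- unique(parsed$accession[duplicated(parsed$accession)])
  if (length(dup) > 0) {
    abort_parse(sprintf(
      "duplicate accession(s) in FASTA: %s", paste(dup, collapse = ", ")
    ))
  }
  empty <- !nzchar(sequence)
  if (any(empty)) {
    abort_parse(sprintf(
      "empty sequence for record(s): %s",
      paste(parsed$accession[empty], collapse = ", ")
    ))
  }
  bad <- !is_valid_sequence(sequence)
  if (any(bad)) {
    i <- which(bad)[[1]]
    abort_parse(sprintf(
      "illegal residue '%s' in record '%s'",
      offending_residue(sequence[[i]]), parsed$accession[[i]]
    ))
  }

  new_seq_db(tibble(
    accession = parsed$accession,
    entry_name = parsed$entry_name,
    organism = parsed$organism,
    description = parsed$description,
    sequence = sequence
  ))
}

# Header fields for both dialects. Organism (OS=) terminates at the next
# two-capital-letter `XX=` token, the UniProt convention.
parse_fasta_headers <- function(header) {
  header <- trimws(header)
  uniprot <- grepl("^[A-Za-z0-9]+\\|[^|[:space:]]+\\|\\S+", header)

  accession <- entry_name <- organism <- description <-
    rep(NA_character_, length(header))

  if (any(uniprot)) {
    h <- header[uniprot]
    accession[uniprot] <- sub("^[^|]+\\|([^|[:space:]]+)\\|.*$", "\\1", h)
    entry_name[uniprot] <- sub("^[^|]+\\|[^|]+\\|(\\S+).*$", "\\1", h)
    rest <- trimws(sub("^[^|]+\\|[^|]+\\|\\S+\\s*", "", h))
    os <- stringr::str_match(rest, "\\bOS=(.*?)(?=\\s+[A-Z]{2}=|$)")[, 2]
    organism[uniprot] <- trimws(os)
    desc <- ifelse(
      is.na(os), rest,
      trimws(sub("\\s*\\bOS=.*$", "", rest))
    )
    description[uniprot] <- desc
  }
  if (any(!uniprot)) {
    h <- header[!uniprot]
    accession[!uniprot] <- sub("\\s.*$", "", h)
    description[!uniprot] <- trimws(sub("^\\S+\\s*", "", h))
  }
  list(
    accession = accession,
    entry_name = entry_name,
    organism = organism,
    description = description
  )
}

new_seq_db <- function(x) {
  structure(x, class = c("seq_db", class(tibble())))
}

#' Write a sequence database to FASTA
#'
#' Entries with an `entry_name` are written in the UniProt dialect
#' (`>sp|ACC|ENTRY description OS=organism`); entries without one get a plain
#' `>ACC description` header. An organism on a plain-header entry cannot be
#' represented and triggers a warning (it would be lost on re-reading).
#'
#' @param db A `seq_db` tibble as returned by [read_fasta()] or
#'   [simulate_proteome()].
#' @param path Output path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60) {
  stopifnot(inherits(db, "seq_db") || is.data.frame(db))
  uniprot <- !is.na(db$entry_name)
  if (any(!uniprot & !is.na(db$organism))) {
    warn("organism on plain-header entries is not written to FASTA")
  }
  desc <- ifelse(is.na(db$description) | !nzchar(db$description),
    "", paste0(" ", db$description)
  )
  os <- ifelse(uniprot & !is.na(db$organism),
    paste0(" OS=", db$organism), ""
  )
  header <- ifelse(
    uniprot,
    paste0("sp|", db$accession, "|", db$entry_name, desc, os),
    paste0(db$accession, desc)
  )
  out <- Biostrings::AAStringSet(setNames(db$sequence, header))
  tryCatch(
    Biostrings::writeXStringSet(out, path, width = width),
    error = function(e) abort_io(sprintf("cannot write FASTA to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Look up sequences by accession
#'
#' Total over loaded entries: asking for an accession absent from the database
#' is an error, not a silent empty result.
#'
#' @param db A `seq_db` tibble.
#' @param accessions Character vector of accessions.
#' @return Named character vector of sequences.
#' @export
db_sequences <- function(db, accessions) {
  idx <- match(accessions, db$accession)
  missing <- accessions[is.na(idx)]
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "accession(s) not in sequence database: %s",
      paste(unique(missing), collapse = ", ")
    ))
  }
  setNames(db$sequence[idx], accessions)
}
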