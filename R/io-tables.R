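#' Read a peptide identification table
#'
#' Loads a delimited identification export into the canonical internal form:
#' one row per (peptide, protein accession, optional coordinates). Peptide
#' strings are normalized before anything else touches them:
#'
#' * a flanking-residue dialect `X.PEPTIDE.X` is stripped to `PEPTIDE`;
#' * modification annotations in parentheses or square brackets, e.g.
#'   `PEPT(+79.97)IDE` or `PEPTM[Oxidation]IDE`, are removed;
#' * the remainder is uppercased.
#'
#' Rows whose normalized peptide is empty or contains characters outside the
#' amino-acid alphabet are dropped with a warning (identification exports are
#' messy); exact duplicate rows are collapsed. Both counts are recorded in the
#' load report (`attr(x, "report")`), which always satisfies
#' `n_input == n_emitted + n_dropped + n_collapsed`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the roles `peptide`,
#'   `protein` and optionally `start`, `end` to column names in the file.
#' @param delim Field delimiter; TAB by default, use `","` for CSV.
#' @param one_based If `TRUE`, start coordinates in the file are 1-based and
#'   are converted to the internal 0-based half-open convention on load.
#' @param source_name Label stored with the table; defaults to the file name.
#' @return A tibble of class `ident_tbl` with columns `peptide`, `protein`,
#'   `start`, `end` (integer, `NA` when absent), plus attributes
#'   `source_name` and `report`.
#' @export
read_identification_table <- function(path,
                                      column_map = c(
                                        peptide = "peptide",
                                        protein = "protein",
                                        start = "start",
                                        end = "end"
                                      ),
                                      delim = "\t",
                                      one_based = FALSE,
                                      source_name = basename(path)) {
  if (!file.exists(path)) {
    abort_io(sprintf("identification table does not exist: '%s'", path))
  }
  for (role in c("peptide", "protein")) {
    if (!role %in% names(column_map)) {
      abort_validation(sprintf("column_map must name a '%s' column", role))
    }
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    skip_empty_rows = TRUE, trim_ws = TRUE
  )
  missing_cols <- setdiff(
    unname(column_map[intersect(names(column_map), c("peptide", "protein"))]),
    names(raw)
  )
  if (length(missing_cols) > 0) {
    abort_validation(sprintf(
      "mapped column(s) %s not found; available columns: %s",
      paste(missing_cols, collapse = ", "),
      paste(names(raw), collapse = ", ")
    ))
  }
  n_input <- nrow(raw)
  if (n_input == 0) {
    abort_validation(sprintf("identification table '%s' has no rows", path))
  }

  peptide <- normalize_peptides(raw[[column_map[["peptide"]]]])
  protein <- trimws(raw[[column_map[["protein"]]]])

  get_int <- function(role) {
    col <- column_map[role]
    if (!is.na(col) && role %in% names(column_map) && col %in% names(raw)) {
      suppressWarnings(as.integer(raw[[col]]))
    } else {
      rep(NA_integer_, n_input)
    }
  }
  start <- get_int("start")
  end <- get_int("end")
  if (one_based) start <- start - 1L
  # a lone coordinate is unusable; treat the pair as absent
  lone <- xor(is.na(start), is.na(end))
  start[lone] <- NA_integer_
  end[lone] <- NA_integer_

  bad_pep <- !is_valid_sequence(peptide, AA_EXTENDED)
  has_coord <- !is.na(start)
  bad_coord <- has_coord & !bad_pep &
    (start < 0L | end <= start | (end - start) != nchar(peptide))
  drop <- bad_pep | bad_coord
  if (any(drop)) {
    warn(sprintf(
      "dropped %d row(s): %d with unusable peptide strings, %d with inconsistent coordinates",
      sum(drop), sum(bad_pep), sum(bad_coord)
    ))
  }

  rows <- tibble(
    peptide = peptide[!drop],
    protein = protein[!drop],
    start = start[!drop],
    end = end[!drop]
  )
  out <- distinct(rows)
  n_collapsed <- nrow(rows) - nrow(out)
  if (n_collapsed > 0) {
    inform(sprintf("collapsed %d exact duplicate row(s)", n_collapsed))
  }
  if (nrow(out) == 0) {
    abort_validation(sprintf(
      "identification table '%s' is empty after normalization", path
    ))
  }
  out <- arrange(out, .data$peptide, .data$protein, .data$start)
  new_ident_tbl(
    out,
    source_name = source_name,
    report = list(
      n_input = n_input,
      n_emitted = nrow(out),
      n_dropped = sum(drop),
      n_collapsed = n_collapsed
    )
  )
}

# Strip the flanking-residue dialect and bracketed modification annotations,
# then uppercase.
normalize_peptides <- function(x) {
  x <- trimws(x)
  x <- sub("^[A-Za-z*_-]\\.", "", x)
  x <- sub("\\.[A-Za-z*_-]$", "", x)
  x <- gsub("\\([^()]*\\)", "", x)
  x <- gsub("\\[[^][]*\\]", "", x)
  toupper(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble ident_tbl
#' @export
as_tibble.ident_tbl <- function(x, ...) {
  # data only: the provenance label and load report are not part of the rows
  attr(x, "source_name") <- NULL
  attr(x, "report") <- NULL
  class(x) <- class(tibble())
  x
}

#' @method as_tibble flank_set
#' @export
as_tibble.flank_set <- function(x, ...) {
  attr(x, "n") <- NULL
  attr(x, "pad_char") <- NULL
  class(x) <- class(tibble())
  x
}

#' @method as_tibble presentation_split
#' @export
as_tibble.presentation_split <- function(x, ...) {
  attr(x, "report") <- NULL
  class(x) <- class(tibble())
  x
}

new_ident_tbl <- function(x, source_name = "unknown", report = NULL) {
  structure(
    as_tibble(x),
    source_name = source_name,
    report = report %||% list(
      n_input = nrow(x), n_emitted = nrow(x), n_dropped = 0L, n_collapsed = 0L
    ),
    class = c("ident_tbl", class(tibble()))
  )
}

#' Construct an identification table from vectors
#'
#' Programmatic counterpart of [read_identification_table()], applying the same
#' validation (0-based half-open coordinates consistent with peptide length,
#' duplicate collapse).
#'
#' @param peptide,protein Character vectors of equal length.
#' @param start,end Optional integer coordinate vectors (0-based half-open).
#' @param source_name Label stored with the table.
#' @return An `ident_tbl` tibble.
#' @export
identification_table <- function(peptide, protein, start = NULL, end = NULL,
                                 source_name = "constructed") {
  n <- length(peptide)
  start <- as.integer(start %||% rep(NA_integer_, n))
  end <- as.integer(end %||% rep(NA_integer_, n))
  peptide <- toupper(peptide)
  if (!all(is_valid_sequence(peptide))) {
    abort_validation("peptide strings must be non-empty amino-acid sequences")
  }
  has <- !is.na(start)
  if (any(has & (start < 0L | end <= start | (end - start) != nchar(peptide)))) {
    abort_validation("coordinates must satisfy 0 <= start < end and end - start == nchar(peptide)")
  }
  out <- distinct(tibble(
    peptide = peptide, protein = protein, start = start, end = end
  ))
  out <- arrange(out, .data$peptide, .data$protein, .data$start)
  new_ident_tbl(out, source_name = source_name)
}

#' Write an identification table to TSV
#'
#' Canonical columns `peptide`, `protein`, `start`, `end`; absent coordinates
#' serialize as empty fields. [read_identification_table()] on the result
#' reproduces the table.
#'
#' @param table An `ident_tbl` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identification_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as_tibble(table)[, c("peptide", "protein", "start", "end")]
  tryCatch(
    readr::write_tsv(out, path, na = ""),
    error = function(e) abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read a gene-expression table
#'
#' Expects columns `accession`, `value` and optionally `aux` (values `core` or
#' `auxiliary`; missing means `core`). Expression values must be finite and
#' non-negative. Duplicate accessions with identical values collapse;
#' conflicting duplicates are an error.
#'
#' @param path Path to a TSV file with a header.
#' @param delim Field delimiter.
#' @return A tibble of class `expression_profile` with columns `accession`,
#'   `value`, `aux`.
#' @export
read_expression_table <- function(path, delim = "\t") {
  raw <- read_layer_table(path, delim, required = c("accession", "value"))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- is.na(value) | !is.finite(value) | value < 0
  if (any(bad)) {
    abort_validation(sprintf(
      "non-numeric or negative expression value(s) for: %s",
      paste(unique(raw$accession[bad]), collapse = ", ")
    ))
  }
  out <- distinct(tibble(
    accession = trimws(raw$accession),
    value = value,
    aux = parse_aux(raw)
  ))
  check_conflicting(out, "expression")
  structure(out, class = c("expression_profile", class(tibble())))
}

#' Read a subcellular-location table
#'
#' Expects columns `accession`, `compartments` (semicolon-separated compartment
#' names) and optionally `aux`. An empty compartment field means the location
#' is unknown and yields an empty list.
#'
#' @inheritParams read_expression_table
#' @return A tibble of class `location_map` with columns `accession`,
#'   `compartments` (list column of character vectors), `aux`.
#' @export
read_location_table <- function(path, delim = "\t") {
  raw <- read_layer_table(path, delim, required = c("accession", "compartments"))
  comp <- lapply(raw$compartments, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) {
      return(character(0))
    }
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  })
  out <- tibble(
    accession = trimws(raw$accession),
    compartments = comp,
    aux = parse_aux(raw)
  )
  key <- paste(out$accession, vapply(out$compartments, paste, "", collapse = ";"), out$aux)
  out <- out[!duplicated(key), ]
  check_conflicting(out, "location")
  structure(out, class = c("location_map", class(tibble())))
}

#' Write an expression profile to TSV
#' @param profile An `expression_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(profile, path) {
  readr::write_tsv(as_tibble(profile)[, c("accession", "value", "aux")], path)
  invisible(path)
}

#' Write a subcellular-location map to TSV
#' @param locmap A `location_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_location_table <- function(locmap, path) {
  out <- tibble(
    accession = locmap$accession,
    compartments = vapply(locmap$compartments, paste, "", collapse = ";"),
    aux = locmap$aux
  )
  readr::write_tsv(out, path)
  invisible(path)
}

read_layer_table <- function(path, delim, required) {
  if (!file.exists(path)) {
    abort_io(sprintf("table does not exist: '%s'", path))
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    skip_empty_rows = TRUE, trim_ws = TRUE
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf(
      "missing column(s) %s in '%s'; available: %s",
      paste(missing_cols, collapse = ", "), path,
      paste(names(raw), collapse = ", ")
    ))
  }
  raw
}

parse_aux <- function(raw) {
  if ("aux" %in% names(raw)) {
    aux <- tolower(trimws(raw$aux))
    aux[is.na(aux) | !nzchar(aux)] <- "core"
    bad <- !aux %in% c("core", "auxiliary")
    if (any(bad)) {
      abort_validation(sprintf(
        "aux flag must be 'core' or 'auxiliary', got: %s",
        paste(unique(aux[bad]), collapse = ", ")
      ))
    }
    aux
  } else {
    rep("core", nrow(raw))
  }
}

check_conflicting <- function(out, what) {
  dup <- unique(out$accession[duplicated(out$accession)])
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "conflicting duplicate %s rows for accession(s): %s",
      what, paste(dup, collapse = ", ")
    ))
  }
  invisible(out)
}
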