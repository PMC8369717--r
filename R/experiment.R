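#' Find all occurrences of a peptide in a protein sequence
#'
#' Exact substring search reporting every (possibly overlapping) occurrence as
#' a 0-based half-open interval, ascending by start. No match is a valid,
#' empty result.
#'
#' @param peptide Uppercase peptide string.
#' @param protein_sequence Uppercase protein sequence.
#' @return A tibble with integer columns `start`, `end`.
#' @export
#' @examples
#' map_peptide_to_protein("AA", "AAAA") # three overlapping occurrences
map_peptide_to_protein <- function(peptide, protein_sequence) {
  stopifnot(is.character(peptide), length(peptide) == 1, nzchar(peptide))
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1)
  # lookahead makes the scan report overlapping occurrences
  hits <- gregexpr(
    sprintf("(?=%s)", peptide), protein_sequence,
    perl = TRUE
  )[[1]]
  if (hits[[1]] == -1) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  start <- as.integer(hits) - 1L
  tibble(start = start, end = start + nchar(peptide))
}

#' Build an experiment from an identification table and a sequence database
#'
#' The anchor object of all downstream analyses: it binds identified peptides
#' to their inferred parent proteins as a bipartite peptide-to-protein mapping
#' graph, together with optional tissue, HLA and free-form metadata.
#'
#' Rows carrying coordinates are trusted but validated against the named
#' protein sequence; rows without coordinates are located by exact substring
#' search, one mapping per occurrence. Rows whose accession is absent from the
#' database, or whose peptide does not occur in the named protein, are dropped
#' with a warning and counted in the build report. The proteins slot holds
#' exactly the accessions with at least one surviving peptide (the inferred
#' proteins).
#'
#' @param table An `ident_tbl` tibble.
#' @param db A `seq_db` tibble.
#' @param name Experiment name.
#' @param tissue Optional [tissue()] object.
#' @param hla Optional [hla_set()] object.
#' @param metadata Named list of free-form sample metadata.
#' @return An object of class `pepexp`.
#' @export
build_experiment <- function(table, db, name,
                             tissue = NULL, hla = NULL, metadata = list()) {
  stopifnot(is.data.frame(table), is.data.frame(db))
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort_validation("experiment `name` must be a non-empty string")
  }
  rows <- tibble(
    peptide = table$peptide, protein = table$protein,
    start = table$start, end = table$end
  )
  n_in <- nrow(rows)

  known <- rows$protein %in% db$accession
  n_missing <- sum(!known)
  rows <- rows[known, ]
  seqs <- setNames(db$sequence, db$accession)

  has_coord <- !is.na(rows$start)

  # coordinate rows: trust but verify against the sequence
  withc <- rows[has_coord, ]
  if (nrow(withc) > 0) {
    s <- seqs[withc$protein]
    ok <- withc$end <= nchar(s) & withc$start >= 0 &
      substr(s, withc$start + 1L, withc$end) == withc$peptide
    n_bad_coord <- sum(!ok)
    withc <- withc[ok, ]
  } else {
    n_bad_coord <- 0L
  }

  # coordinate-free rows: substring search, one mapping per occurrence
  noc <- distinct(rows[!has_coord, ], .data$peptide, .data$protein)
  n_no_match <- 0L
  if (nrow(noc) > 0) {
    found <- purrr::pmap(noc, function(peptide, protein) {
      occ <- map_peptide_to_protein(peptide, seqs[[protein]])
      if (nrow(occ) == 0) {
        return(NULL)
      }
      tibble(peptide = peptide, protein = protein, start = occ$start, end = occ$end)
    })
    n_no_match <- sum(vapply(found, is.null, logical(1)))
    noc <- bind_rows(found)
  } else {
    noc <- withc[0, ]
  }

  mappings <- distinct(bind_rows(withc, noc))
  if (n_missing + n_bad_coord + n_no_match > 0) {
    warn(sprintf(
      "experiment '%s': dropped %d row(s) (%d unknown accession, %d failed coordinate check, %d peptide not found in protein)",
      name, n_missing + n_bad_coord + n_no_match,
      n_missing, n_bad_coord, n_no_match
    ))
  }
  if (nrow(mappings) == 0) {
    abort_validation(sprintf(
      "experiment '%s': no peptide survived mapping against the database", name
    ))
  }
  mappings <- arrange(mappings, .data$peptide, .data$protein, .data$start)
  inferred <- sort(unique(mappings$protein))

  new_experiment(
    name = name,
    mappings = mappings,
    proteins = seqs[inferred],
    tissue = tissue, hla = hla, metadata = metadata,
    report = list(
      n_rows_in = n_in,
      n_dropped_unknown_accession = n_missing,
      n_dropped_bad_coordinates = n_bad_coord,
      n_dropped_no_match = n_no_match
    )
  )
}

new_experiment <- function(name, mappings, proteins, tissue = NULL,
                           hla = NULL, metadata = list(), report = list()) {
  structure(
    list(
      name = name,
      mappings = mappings,
      proteins = proteins,
      tissue = tissue,
      hla = hla,
      metadata = metadata,
      report = report
    ),
    class = "pepexp"
  )
}

#' @method print pepexp
#' @export
print.pepexp <- function(x, ...) {
  cat(sprintf(
    "<pepexp> '%s': %d unique peptides, %d inferred proteins, %d mappings\n",
    x$name, length(peptides(x)), length(x$proteins), nrow(x$mappings)
  ))
  if (!is.null(x$tissue)) cat(sprintf("  tissue: %s\n", x$tissue$name))
  if (!is.null(x$hla)) {
    cat(sprintf(
      "  HLA (%s): %s\n", x$hla$hla_class,
      paste(x$hla$alleles, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Tissue descriptor
#'
#' Binds a tissue name to its optional gene-expression profile and
#' subcellular-location map; either layer may be absent.
#'
#' @param name Non-empty tissue name.
#' @param expression Optional `expression_profile` tibble.
#' @param location Optional `location_map` tibble.
#' @return An object of class `pep_tissue`.
#' @export
tissue <- function(name, expression = NULL, location = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort_validation("tissue `name` must be a non-empty string")
  }
  structure(
    list(name = name, expression = expression, location = location),
    class = "pep_tissue"
  )
}

#' HLA allele set
#'
#' Allele names are stored verbatim. The class is inferred from the names when
#' not given: alleles at the DR/DP/DQ loci are class II, A/B/C are class I.
#'
#' @param alleles Non-empty character vector of allele names.
#' @param hla_class One of `"I"`, `"II"`, `"mixed"`; inferred by default.
#' @return An object of class `hla_set`.
#' @export
hla_set <- function(alleles, hla_class = NULL) {
  if (length(alleles) == 0) {
    abort_validation("`alleles` must be non-empty")
  }
  if (is.null(hla_class)) {
    ii <- grepl("^(HLA-)?D[RPQO]", alleles)
    hla_class <- if (all(ii)) "II" else if (!any(ii)) "I" else "mixed"
  }
  hla_class <- match.arg(hla_class, c("I", "II", "mixed"))
  structure(
    list(alleles = as.character(alleles), hla_class = hla_class),
    class = "hla_set"
  )
}

#' Collect experiments into an ordered, uniquely named set
#'
#' @param ... `pepexp` objects, or a single list of them. Names default to each
#'   experiment's own name.
#' @return An object of class `pepexp_set` (a named list of experiments).
#' @export
experiment_set <- function(...) {
  exps <- list(...)
  if (length(exps) == 1 && is.list(exps[[1]]) && !inherits(exps[[1]], "pepexp")) {
    exps <- exps[[1]]
  }
  if (length(exps) == 0) {
    abort_validation("an experiment set needs at least one experiment")
  }
  ok <- vapply(exps, inherits, logical(1), "pepexp")
  if (!all(ok)) {
    abort_validation("all elements must be pepexp objects")
  }
  nm <- names(exps)
  own <- vapply(exps, function(e) e$name, character(1))
  if (is.null(nm)) nm <- own
  nm[is.na(nm) | !nzchar(nm)] <- own[is.na(nm) | !nzchar(nm)]
  if (anyDuplicated(nm)) {
    abort_validation(sprintf(
      "experiment names must be unique; duplicated: %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  structure(setNames(exps, nm), class = "pepexp_set")
}

#' @method print pepexp_set
#' @export
print.pepexp_set <- function(x, ...) {
  cat(sprintf("<pepexp_set> %d experiment(s): %s\n", length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Distinct peptide sequences of an experiment
#' @param x A `pepexp` or `pepexp_set`.
#' @param ... Unused.
#' @return Sorted character vector of distinct peptide sequences (for a set,
#'   the union over experiments).
#' @export
peptides <- function(x, ...) UseMethod("peptides")

#' @export
peptides.pepexp <- function(x, ...) sort(unique(x$mappings$peptide))

#' @export
peptides.pepexp_set <- function(x, ...) {
  sort(unique(unlist(lapply(x, peptides), use.names = FALSE)))
}

#' Inferred protein accessions of an experiment
#' @inheritParams peptides
#' @return Sorted character vector of accessions (for a set, the union).
#' @export
inferred_proteins <- function(x, ...) UseMethod("inferred_proteins")

#' @export
inferred_proteins.pepexp <- function(x, ...) names(x$proteins)

#' @export
inferred_proteins.pepexp_set <- function(x, ...) {
  sort(unique(unlist(lapply(x, inferred_proteins), use.names = FALSE)))
}

#' Peptides (or proteins) identified in every experiment of a set
#'
#' Exact set intersection over per-experiment distinct peptide sequences or
#' inferred protein accessions.
#'
#' @param expset A `pepexp_set`.
#' @return Sorted character vector.
#' @export
peptides_in_all <- function(expset) {
  stopifnot(inherits(expset, "pepexp_set"))
  sort(Reduce(intersect, lapply(expset, peptides)))
}

#' @rdname peptides_in_all
#' @export
peptides_union <- function(expset) {
  stopifnot(inherits(expset, "pepexp_set"))
  peptides(expset)
}

#' @rdname peptides_in_all
#' @export
proteins_in_all <- function(expset) {
  stopifnot(inherits(expset, "pepexp_set"))
  sort(Reduce(intersect, lapply(expset, inferred_proteins)))
}

#' @rdname peptides_in_all
#' @export
proteins_union <- function(expset) {
  stopifnot(inherits(expset, "pepexp_set"))
  inferred_proteins(expset)
}

#' Partition an experiment set by a metadata key
#'
#' `"tissue"` is a built-in key resolving to the tissue name; any other key is
#' looked up in each experiment's metadata. Every experiment lands in exactly
#' one group.
#'
#' @param expset A `pepexp_set`.
#' @param key Metadata key, or `"tissue"`.
#' @return Named list of `pepexp_set` objects, one per distinct value.
#' @export
group_by_metadata <- function(expset, key) {
  stopifnot(inherits(expset, "pepexp_set"))
  values <- vapply(names(expset), function(nm) {
    e <- expset[[nm]]
    v <- if (identical(key, "tissue")) {
      if (is.null(e$tissue)) NULL else e$tissue$name
    } else {
      e$metadata[[key]]
    }
    if (is.null(v) || is.na(v)) {
      abort_validation(sprintf(
        "experiment '%s' has no value for key '%s'", nm, key
      ))
    }
    as.character(v)
  }, character(1))
  lapply(split(names(expset), values), function(nms) {
    experiment_set(setNames(unclass(expset)[nms], nms))
  })
}

#' Count distinct peptides per inferred protein
#'
#' A peptide shared between proteins counts once for every protein it maps to
#' (no parsimony is applied); repeated occurrences within one protein count
#' once at this level.
#'
#' @param exp A `pepexp`.
#' @return A tibble with columns `protein`, `n_peptides`, sorted by count
#'   descending then accession ascending.
#' @export
peptides_per_protein <- function(exp) {
  stopifnot(inherits(exp, "pepexp"))
  out <- count(
    distinct(exp$mappings, .data$peptide, .data$protein),
    .data$protein,
    name = "n_peptides"
  )
  arrange(out, desc(.data$n_peptides), .data$protein)
}

#' Most-presented proteins of an experiment
#'
#' @param exp A `pepexp`.
#' @param n Number of proteins to return; all of them when `n` exceeds the
#'   inferred-protein count.
#' @return The first `n` rows of [peptides_per_protein()].
#' @export
top_n_proteins <- function(exp, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_validation("`n` must be a positive integer")
  }
  head(peptides_per_protein(exp), n)
}

#' @method tidy pepexp
#' @export
tidy.pepexp <- function(x, ...) as_tibble(x$mappings)

#' @method glance pepexp
#' @export
glance.pepexp <- function(x, ...) {
  tibble(
    name = x$name,
    n_peptides = length(peptides(x)),
    n_proteins = length(x$proteins),
    n_mappings = nrow(x$mappings)
  )
}

#' @method glance pepexp_set
#' @export
glance.pepexp_set <- function(x, ...) {
  bind_rows(lapply(x, glance.pepexp))
}

#' Serialize an experiment to the canonical TSV plus a JSON sidecar
#'
#' Writes the mapping table with [write_identification_table()] and a small
#' JSON sidecar holding the experiment name, tissue, HLA alleles and metadata.
#'
#' @param exp A `pepexp`.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(exp, path) {
  stopifnot(inherits(exp, "pepexp"))
  write_identification_table(new_ident_tbl(exp$mappings, exp$name), path)
  sidecar <- list(
    name = exp$name,
    tissue = if (!is.null(exp$tissue)) exp$tissue$name else NULL,
    hla_alleles = if (!is.null(exp$hla)) exp$hla$alleles else NULL,
    hla_class = if (!is.null(exp$hla)) exp$hla$hla_class else NULL,
    metadata = exp$metadata
  )
  jsonlite::write_json(
    sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}
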