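#' Build an accession-to-organism map
#'
#' From a sequence database the organism is the parsed `OS=` header field
#' (`"unknown"` where absent, e.g. plain headers); from a two-column table
#' (`accession`, `organism`) the mapping is taken verbatim, trimmed.
#' Conflicting duplicate rows are an error. Lookups through [organism_of()]
#' are total: any accession not in the map resolves to `"unknown"`.
#'
#' @param source A `seq_db` tibble or a data frame with columns `accession`
#'   and `organism`.
#' @return A tibble of class `organism_db` with columns `accession`,
#'   `organism`.
#' @export
build_organism_db <- function(source) {
  if (inherits(source, "seq_db")) {
    out <- tibble(
      accession = source$accession,
      organism = coalesce(trimws(source$organism), "unknown")
    )
  } else if (is.data.frame(source)) {
    missing_cols <- setdiff(c("accession", "organism"), names(source))
    if (length(missing_cols) > 0) {
      abort_validation(sprintf(
        "organism table must have columns accession and organism (missing: %s)",
        paste(missing_cols, collapse = ", ")
      ))
    }
    out <- distinct(tibble(
      accession = trimws(source$accession),
      organism = coalesce(trimws(source$organism), "unknown")
    ))
  } else {
    abort_validation("`source` must be a seq_db or a data frame")
  }
  if (nrow(out) == 0) {
    abort_validation("organism source is empty")
  }
  out$organism[!nzchar(out$organism)] <- "unknown"
  dup <- unique(out$accession[duplicated(out$accession)])
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "conflicting organism rows for accession(s): %s",
      paste(dup, collapse = ", ")
    ))
  }
  structure(out, class = c("organism_db", class(tibble())))
}

#' Organism of origin for accessions
#'
#' @param odb An `organism_db` tibble.
#' @param accessions Character vector.
#' @return Character vector of organism names, `"unknown"` for accessions not
#'   in the map.
#' @export
organism_of <- function(odb, accessions) {
  stopifnot(inherits(odb, "organism_db"))
  out <- odb$organism[match(accessions, odb$accession)]
  out[is.na(out)] <- "unknown"
  setNames(out, accessions)
}

#' Count inferred proteins and peptides per organism
#'
#' Each inferred protein is counted under its organism of origin; each peptide
#' is counted under every organism of its mapped proteins, so a peptide shared
#' across organisms contributes to each (their number is reported in the
#' `n_shared_peptides` attribute).
#'
#' @param exp A `pepexp`.
#' @param odb An `organism_db`.
#' @return A tibble with columns `organism`, `n_proteins`, `n_peptides`.
#' @export
count_per_organism <- function(exp, odb) {
  stopifnot(inherits(exp, "pepexp"))
  prot <- inferred_proteins(exp)
  org <- organism_of(odb, prot)
  prot_counts <- count(
    tibble(organism = unname(org)), .data$organism,
    name = "n_proteins"
  )
  pep_org <- distinct(tibble(
    peptide = exp$mappings$peptide,
    organism = unname(org[exp$mappings$protein])
  ))
  pep_counts <- count(pep_org, .data$organism, name = "n_peptides")
  out <- left_join(prot_counts, pep_counts, by = "organism")
  out$n_peptides <- coalesce(out$n_peptides, 0L)
  out <- arrange(out, desc(.data$n_proteins), .data$organism)
  shared <- sum(table(pep_org$peptide) > 1)
  structure(out, n_shared_peptides = as.integer(shared))
}

#' Filter an experiment by organism of origin
#'
#' Retains peptides with at least one mapping to a protein of a kept organism
#' (the inclusive rule: a peptide shared between a kept and a non-kept
#' organism survives, and the number of such ambiguous peptides is reported).
#' Mappings to non-kept proteins are removed, as are proteins left without
#' peptides. The input experiment is not modified.
#'
#' @param exp A `pepexp`.
#' @param odb An `organism_db`.
#' @param keep Non-empty character vector of organism names to keep.
#' @return A new `pepexp`.
#' @export
filter_by_organism <- function(exp, odb, keep) {
  stopifnot(inherits(exp, "pepexp"))
  if (length(keep) == 0) {
    abort_validation("`keep` must name at least one organism")
  }
  org <- organism_of(odb, names(exp$proteins))
  kept_prot <- names(org)[org %in% keep]
  m <- exp$mappings
  kept_m <- m[m$protein %in% kept_prot, ]
  if (nrow(kept_m) == 0) {
    abort_validation(sprintf(
      "no peptide maps to a kept organism (keep = %s)",
      paste(keep, collapse = ", ")
    ))
  }
  ambiguous <- intersect(
    unique(kept_m$peptide),
    unique(m$peptide[!m$protein %in% kept_prot])
  )
  if (length(ambiguous) > 0) {
    inform(sprintf(
      "%d peptide(s) also map to non-kept organisms and were retained (inclusive filter)",
      length(ambiguous)
    ))
  }
  inferred <- sort(unique(kept_m$protein))
  new_experiment(
    name = exp$name,
    mappings = kept_m,
    proteins = exp$proteins[inferred],
    tissue = exp$tissue, hla = exp$hla, metadata = exp$metadata,
    report = c(exp$report, list(
      organism_filter = keep,
      n_ambiguous_peptides = length(ambiguous)
    ))
  )
}

#' Write an organism map to TSV
#' @param odb An `organism_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_organism_table <- function(odb, path) {
  readr::write_tsv(as_tibble(odb)[, c("accession", "organism")], path)
  invisible(path)
}
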