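#' Per-residue peptide coverage of a protein
#'
#' The coverage array of a protein has one cell per residue, counting the
#' unique identified peptides that cover that position. Each distinct peptide
#' contributes once per mapping interval: a peptide occurring twice in the
#' protein increments both sites (coverage is positional), while duplicate
#' identification rows never double-count.
#'
#' @param exp A `pepexp`.
#' @param accession Accession of one of the experiment's inferred proteins.
#' @return An integer vector of class `coverage_array`, length equal to the
#'   protein length, with the accession attached as an attribute.
#' @export
compute_coverage <- function(exp, accession) {
  stopifnot(inherits(exp, "pepexp"))
  if (!accession %in% names(exp$proteins)) {
    abort_validation(sprintf(
      "accession '%s' is not an inferred protein of experiment '%s'",
      accession, exp$name
    ))
  }
  len <- nchar(exp$proteins[[accession]])
  m <- distinct(
    exp$mappings[exp$mappings$protein == accession, ],
    .data$peptide, .data$start, .data$end
  )
  new_coverage_array(interval_coverage(m$start, m$end, len), accession)
}

# Difference-array accumulation of half-open intervals over [0, len).
interval_coverage <- function(start, end, len) {
  delta <- integer(len + 1L)
  if (length(start) > 0) {
    up <- tabulate(start + 1L, nbins = len + 1L)
    down <- tabulate(end + 1L, nbins = len + 1L)
    delta <- up - down
  }
  as.integer(cumsum(delta))[seq_len(len)]
}

new_coverage_array <- function(values, accession) {
  structure(as.integer(values), accession = accession, class = "coverage_array")
}

#' @method print coverage_array
#' @export
print.coverage_array <- function(x, ...) {
  cat(sprintf(
    "<coverage_array> %s: %d residues, max coverage %d\n",
    attr(x, "accession"), length(x), if (length(x)) max(x) else 0L
  ))
  print(as.integer(x))
  invisible(x)
}

#' @method tidy coverage_array
#' @export
tidy.coverage_array <- function(x, ...) {
  tibble(
    accession = attr(x, "accession"),
    position = seq_along(x) - 1L,
    coverage = as.integer(x)
  )
}

#' L1 distance between two coverage arrays of the same protein
#'
#' The per-protein coverage difference between two conditions: the sum of
#' absolute differences between corresponding cells. Zero exactly when the
#' arrays are identical. A length mismatch signals inconsistent sequence
#' databases and is an error.
#'
#' @param c1,c2 `coverage_array` objects (or plain integer vectors) of equal
#'   length.
#' @return A single non-negative number.
#' @export
protein_coverage_distance <- function(c1, c2) {
  if (length(c1) != length(c2)) {
    abort_validation(sprintf(
      "coverage arrays differ in length (%d vs %d): inconsistent sequence databases?",
      length(c1), length(c2)
    ))
  }
  a1 <- attr(c1, "accession")
  a2 <- attr(c2, "accession")
  if (!is.null(a1) && !is.null(a2) && !identical(a1, a2)) {
    abort_validation(sprintf(
      "coverage arrays belong to different proteins ('%s' vs '%s')", a1, a2
    ))
  }
  sum(abs(as.numeric(c1) - as.numeric(c2)))
}

# Coverage of `accession` in `exp`, or an all-zero array when the protein was
# not inferred there. `len` fixes the array length from the shared database.
coverage_or_zero <- function(exp, accession, len) {
  if (accession %in% names(exp$proteins)) {
    have <- nchar(exp$proteins[[accession]])
    if (have != len) {
      abort_validation(sprintf(
        "protein '%s' has length %d in experiment '%s' but %d elsewhere: inconsistent sequence databases",
        accession, have, exp$name, len
      ))
    }
    compute_coverage(exp, accession)
  } else {
    new_coverage_array(integer(len), accession)
  }
}

# Protein lengths over a set of experiments, erroring on conflicts.
universe_lengths <- function(exps, universe) {
  lens <- setNames(rep(NA_integer_, length(universe)), universe)
  for (e in exps) {
    acc <- intersect(universe, names(e$proteins))
    l <- nchar(e$proteins[acc])
    conflict <- !is.na(lens[acc]) & lens[acc] != l
    if (any(conflict)) {
      abort_validation(sprintf(
        "protein(s) %s have different lengths across experiments: inconsistent sequence databases",
        paste(acc[conflict], collapse = ", ")
      ))
    }
    lens[acc] <- l
  }
  unresolved <- names(lens)[is.na(lens)]
  if (length(unresolved) > 0) {
    abort_validation(sprintf(
      "accession(s) not inferred in any experiment: %s",
      paste(unresolved, collapse = ", ")
    ))
  }
  lens
}

#' Coverage distance between two experiments
#'
#' The mean over a protein universe of the per-protein L1 coverage distance.
#' A protein absent from one experiment contributes an all-zero array there.
#' By default the universe is the union of the two experiments' inferred
#' proteins; pass `protein_universe` to fix it externally (as
#' [coverage_distance_matrix()] does, set-wide).
#'
#' @param e1,e2 `pepexp` objects sharing a sequence database.
#' @param protein_universe Optional character vector of accessions; defaults to
#'   the union of inferred proteins of `e1` and `e2`.
#' @param length_normalized If `TRUE`, each protein's score is divided by its
#'   length before averaging.
#' @return A single non-negative number.
#' @export
experiment_distance <- function(e1, e2, protein_universe = NULL,
                                length_normalized = FALSE) {
  stopifnot(inherits(e1, "pepexp"), inherits(e2, "pepexp"))
  universe <- protein_universe %||%
    sort(union(names(e1$proteins), names(e2$proteins)))
  if (length(universe) == 0) {
    abort_validation("the protein universe is empty")
  }
  lens <- universe_lengths(list(e1, e2), universe)
  scores <- vapply(universe, function(acc) {
    d <- protein_coverage_distance(
      coverage_or_zero(e1, acc, lens[[acc]]),
      coverage_or_zero(e2, acc, lens[[acc]])
    )
    if (length_normalized) d / lens[[acc]] else d
  }, numeric(1))
  mean(scores)
}

#' Coverage distance matrix over an experiment set
#'
#' Pairwise [experiment_distance()] with the protein universe fixed to the
#' union of inferred proteins over the whole set, identical for every pair.
#' With a fixed universe the result is a scaled L1 metric, so the triangle
#' inequality is guaranteed; it is asserted after computation as a sanity
#' check on the shared database.
#'
#' @param expset A `pepexp_set` over a shared sequence database.
#' @inheritParams experiment_distance
#' @return A symmetric matrix of class `exp_matrix` (type
#'   `"coverage_distance"`), with the universe attached as an attribute.
#' @export
coverage_distance_matrix <- function(expset, length_normalized = FALSE) {
  stopifnot(inherits(expset, "pepexp_set"))
  nm <- names(expset)
  n <- length(nm)
  universe <- proteins_union(expset)
  lens <- universe_lengths(expset, universe)

  # flatten each experiment's coverage over the universe once; pairwise
  # distance is then the mean per-protein L1 over the concatenated arrays
  weight <- if (length_normalized) {
    rep(1 / lens, times = lens)
  } else {
    rep(1, sum(lens))
  }
  flat <- vapply(expset, function(e) {
    unlist(lapply(universe, function(acc) {
      as.numeric(coverage_or_zero(e, acc, lens[[acc]]))
    }), use.names = FALSE)
  }, numeric(sum(lens)))

  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <-
          sum(abs(flat[, i] - flat[, j]) * weight) / length(universe)
      }
    }
  }
  assert_metric(d)
  new_exp_matrix(d, type = "coverage_distance", universe = universe)
}

# Symmetry, zero diagonal, non-negativity and the triangle inequality,
# up to floating-point tolerance.
assert_metric <- function(d, tol = 1e-9) {
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = tol)))
  stopifnot(all(abs(diag(d)) <= tol), all(d >= -tol))
  n <- nrow(d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (any(d[i, j] > d[i, ] + d[, j] + tol)) {
        abort_validation("triangle inequality violated in distance matrix")
      }
    }
  }
  invisible(d)
}

new_exp_matrix <- function(m, type, level = NULL, universe = NULL) {
  structure(
    m,
    type = type, level = level, universe = universe,
    class = c("exp_matrix", "matrix", "array")
  )
}

#' @method print exp_matrix
#' @export
print.exp_matrix <- function(x, ...) {
  cat(sprintf(
    "<exp_matrix> %s%s, %d experiment(s)\n",
    attr(x, "type"),
    if (!is.null(attr(x, "level"))) paste0(" (", attr(x, "level"), " level)") else "",
    nrow(x)
  ))
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "type") <- NULL
  attr(x, "level") <- NULL
  attr(x, "universe") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' @method tidy exp_matrix
#' @export
tidy.exp_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  out <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(out) <- c("experiment_1", "experiment_2", "value")
  out
}

#' @method as.matrix exp_matrix
#' @export
as.matrix.exp_matrix <- function(x, ...) unclass_matrix(x)

#' Write a square named matrix to TSV
#'
#' Row names become the first column (`name`); suitable for distance, overlap
#' and Jaccard matrices.
#'
#' @param m A matrix with identical row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  out <- as_tibble(m)
  out <- tibble(name = rownames(m), !!!out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Coverage of one protein across an experiment set
#'
#' The n-coverage representation: one row per experiment, one column per
#' residue of the protein. Experiments in which the protein was not inferred
#' contribute an all-zero row.
#'
#' @param expset A `pepexp_set`.
#' @param accession Protein accession, inferred in at least one experiment.
#' @return An integer matrix of class `ncoverage` (experiments x positions)
#'   with the accession attached as an attribute.
#' @export
n_coverage_table <- function(expset, accession) {
  stopifnot(inherits(expset, "pepexp_set"))
  holders <- names(expset)[vapply(
    expset, function(e) accession %in% names(e$proteins), logical(1)
  )]
  if (length(holders) == 0) {
    abort_validation(sprintf(
      "accession '%s' is not inferred in any experiment of the set", accession
    ))
  }
  len <- universe_lengths(expset, accession)[[accession]]
  m <- t(vapply(expset, function(e) {
    as.integer(coverage_or_zero(e, accession, len))
  }, integer(len)))
  dimnames(m) <- list(names(expset), NULL)
  structure(m,
    accession = accession,
    class = c("ncoverage", "matrix", "array")
  )
}

#' @method tidy ncoverage
#' @export
tidy.ncoverage <- function(x, ...) {
  m <- x
  class(m) <- c("matrix", "array")
  attr(m, "accession") <- NULL
  colnames(m) <- as.character(seq_len(ncol(m)) - 1L)
  out <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(out) <- c("experiment", "position", "coverage")
  out$position <- as.integer(out$position)
  out$coverage <- as.integer(out$coverage)
  out$accession <- attr(x, "accession")
  out[, c("accession", "experiment", "position", "coverage")]
}

#' Export an n-coverage table as TSV
#'
#' Rows are experiments, columns 0-based residue indices.
#'
#' @param nc An `ncoverage` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ncoverage_tsv <- function(nc, path) {
  m <- nc
  class(m) <- c("matrix", "array")
  attr(m, "accession") <- NULL
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- as.character(seq_len(ncol(m)) - 1L)
  out <- tibble(experiment = rownames(m), !!!out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Map a coverage array onto a \[0, 1\] color gradient
#'
#' Max-normalization of a coverage array for coloring residues, e.g. on a
#' protein structure: the most covered position maps to 1, uncovered positions
#' to 0, and an all-zero array stays all-zero. Monotone in coverage and
#' invariant under positive scaling.
#'
#' @param c A `coverage_array` (or non-negative numeric vector).
#' @return A numeric vector in \[0, 1\] of the same length.
#' @export
coverage_color_scale <- function(c) {
  v <- as.numeric(c)
  m <- max(v)
  if (m > 0) v / m else rep(0, length(v))
}
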