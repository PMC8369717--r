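#' Simulate a protein sequence database
#'
#' Generates `n_proteins` random proteins with i.i.d. uniform residues over
#' the 20-letter alphabet, lengths uniform over `length_range`, and an
#' organism of origin planted per the `organisms` fractions (allocated exactly
#' by largest remainder, so `c(human = 0.8, virus = 0.2)` over 100 proteins
#' yields precisely 80/20). Entries carry UniProt-dialect fields (`SYNnnnnn`
#' accessions, entry names, `OS=` organisms), so [write_fasta()] round-trips
#' them exactly; the organism column is the planted ground truth. The same
#' seed reproduces the database byte-for-byte.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector `c(min, max)` of protein lengths.
#' @param organisms Named numeric vector of organism fractions summing to 1.
#' @param seed Integer seed.
#' @return A `seq_db` tibble.
#' @export
simulate_proteome <- function(n_proteins,
                              length_range = c(150, 400),
                              organisms = c("Homo sapiens" = 1),
                              seed = 1) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    abort_validation("`n_proteins` must be >= 1")
  }
  n_proteins <- as.integer(n_proteins)
  if (is.null(names(organisms)) || any(!nzchar(names(organisms)))) {
    abort_validation("`organisms` must be a named vector of fractions")
  }
  if (any(organisms < 0)) {
    abort_validation("organism fractions must be non-negative")
  }
  counts <- largest_remainder(n_proteins, organisms)
  org <- rep(names(organisms), counts)

  with_seed(seed, {
    lens <- sample_from(
      seq(length_range[[1]], length_range[[2]]), n_proteins
    )
    seqs <- vapply(lens, function(l) {
      paste(sample(AA_STANDARD, l, replace = TRUE), collapse = "")
    }, character(1))
    acc <- sprintf("SYN%05d", seq_len(n_proteins))
    new_seq_db(tibble(
      accession = acc,
      entry_name = paste0(acc, "_SYNTH"),
      organism = org,
      description = sprintf("Synthetic protein %d", seq_len(n_proteins)),
      sequence = seqs
    ))
  })
}

#' Simulate a peptide identification experiment with known ground truth
#'
#' Emulates an HLA class II-like peptidome over a protein database: a
#' `hotspot_fraction` of the peptides form nested, overlapping ladders around
#' shared 9-residue binding cores with ragged 0-4 residue extensions on each
#' side (clipped at the protein termini), and the rest are drawn uniformly
#' (random protein, length uniform over `length_range`, random start). Rows
#' are shuffled; every emitted row's true interval is recorded.
#'
#' @param db A `seq_db` tibble (e.g. from [simulate_proteome()]).
#' @param n_peptides Number of identification rows to draw (>= 1).
#' @param length_range Integer `c(min, max)` peptide lengths for the uniform
#'   draws; must be feasible for the shortest protein.
#' @param hotspot_fraction Fraction of peptides drawn from hotspot ladders.
#' @param peptides_per_hotspot Ladder size used to decide how many hotspots to
#'   plant.
#' @param seed Integer seed.
#' @param include_coordinates Emit the true start/end in the table? When
#'   `FALSE` the coordinates must be rediscovered by substring search.
#' @return A list with elements `table` (an `ident_tbl`) and `ground_truth`
#'   (list: `mappings` tibble of distinct planted intervals, `coverage` named
#'   list of per-protein integer arrays, `hotspots` tibble, `seed`).
#' @export
simulate_experiment <- function(db, n_peptides,
                                length_range = c(9, 17),
                                hotspot_fraction = 0.5,
                                peptides_per_hotspot = 10,
                                seed = 1,
                                include_coordinates = TRUE) {
  stopifnot(is.data.frame(db))
  if (!is.numeric(n_peptides) || n_peptides < 1) {
    abort_validation("`n_peptides` must be >= 1")
  }
  n_peptides <- as.integer(n_peptides)
  if (hotspot_fraction < 0 || hotspot_fraction > 1) {
    abort_validation("`hotspot_fraction` must be in [0, 1]")
  }
  lens <- nchar(db$sequence)
  core_len <- 9L
  max_ext <- 4L
  if (length_range[[1]] < 1 || length_range[[2]] < length_range[[1]]) {
    abort_validation("`length_range` must satisfy 1 <= min <= max")
  }
  if (length_range[[2]] > min(lens) || core_len > min(lens)) {
    abort_validation(sprintf(
      "peptide lengths up to %d are infeasible for the shortest protein (length %d)",
      max(length_range[[2]], core_len), min(lens)
    ))
  }

  n_hot <- as.integer(round(hotspot_fraction * n_peptides))
  n_unif <- n_peptides - n_hot

  with_seed(seed, {
    rows <- list()
    hotspots <- tibble(
      protein = character(0), core_start = integer(0)
    )
    if (n_hot > 0) {
      n_spots <- max(1L, ceiling(n_hot / peptides_per_hotspot))
      spot_protein <- sample(db$accession, n_spots, replace = TRUE)
      spot_len <- lens[match(spot_protein, db$accession)]
      spot_core <- vapply(spot_len, function(l) {
        sample.int(l - core_len + 1L, 1L) - 1L
      }, integer(1))
      hotspots <- tibble(protein = spot_protein, core_start = spot_core)
      spot_of <- rep(seq_len(n_spots), length.out = n_hot)
      ext_l <- sample(0:max_ext, n_hot, replace = TRUE)
      ext_r <- sample(0:max_ext, n_hot, replace = TRUE)
      start <- pmax(spot_core[spot_of] - ext_l, 0L)
      end <- pmin(spot_core[spot_of] + core_len + ext_r, spot_len[spot_of])
      rows$hot <- tibble(
        protein = spot_protein[spot_of],
        start = as.integer(start), end = as.integer(end)
      )
    }
    if (n_unif > 0) {
      prot_i <- sample.int(nrow(db), n_unif, replace = TRUE)
      plen <- sample_from(
        seq(length_range[[1]], length_range[[2]]), n_unif
      )
      start <- vapply(seq_len(n_unif), function(i) {
        sample.int(lens[prot_i[[i]]] - plen[[i]] + 1L, 1L) - 1L
      }, integer(1))
      rows$unif <- tibble(
        protein = db$accession[prot_i],
        start = as.integer(start), end = as.integer(start + plen)
      )
    }
    planted <- bind_rows(rows)
    planted$peptide <- substr(
      db$sequence[match(planted$protein, db$accession)],
      planted$start + 1L, planted$end
    )
    planted <- planted[sample.int(nrow(planted)), c("peptide", "protein", "start", "end")]

    truth_map <- arrange(
      distinct(planted),
      .data$peptide, .data$protein, .data$start
    )
    truth_cov <- lapply(
      split(truth_map, truth_map$protein),
      function(m) {
        # a distinct peptide covers each of its occurrence sites once
        occ <- distinct(m, .data$peptide, .data$start, .data$end)
        interval_coverage(
          occ$start, occ$end,
          nchar(db$sequence[[match(m$protein[[1]], db$accession)]])
        )
      }
    )

    table <- new_ident_tbl(
      if (include_coordinates) {
        truth_map
      } else {
        distinct(truth_map[, c("peptide", "protein")]) |>
          mutate(start = NA_integer_, end = NA_integer_)
      },
      source_name = sprintf("simulated_seed_%d", as.integer(seed))
    )

    list(
      table = table,
      ground_truth = list(
        mappings = truth_map,
        coverage = truth_cov,
        hotspots = hotspots,
        seed = as.integer(seed)
      )
    )
  })
}

#' Simulate a gene-expression profile with a planted presentation effect
#'
#' Draws a log-normal expression baseline (`2^N(baseline_log2_mean,
#' noise_sd)`) for every protein in the database and multiplies the presented
#' accessions by `2^log2_shift`. With the defaults (a 2-fold shift, log2-scale
#' noise SD 0.5) the presented-vs-background rank-sum comparison is reliably
#' significant at group sizes of 50 and above.
#'
#' @param db A `seq_db` tibble.
#' @param presented_accessions Accessions carrying the shift.
#' @param log2_shift Planted log2 fold change (>= 0; default 1, i.e. 2-fold).
#' @param noise_sd Log2-scale standard deviation of the baseline.
#' @param baseline_log2_mean Log2-scale mean of the baseline.
#' @param seed Integer seed.
#' @return An `expression_profile` tibble (all entries flagged `core`).
#' @export
simulate_expression <- function(db, presented_accessions,
                                log2_shift = 1,
                                noise_sd = 0.5,
                                baseline_log2_mean = 5,
                                seed = 1) {
  stopifnot(is.data.frame(db))
  if (log2_shift < 0) {
    abort_validation("`log2_shift` must be >= 0")
  }
  with_seed(seed, {
    log2_val <- rnorm(nrow(db), mean = baseline_log2_mean, sd = noise_sd) +
      log2_shift * (db$accession %in% presented_accessions)
    structure(
      tibble(
        accession = db$accession,
        value = 2^log2_val,
        aux = "core"
      ),
      class = c("expression_profile", class(tibble()))
    )
  })
}

#' Simulate a subcellular-location map
#'
#' Assigns each protein 1-2 compartments drawn from `compartments`, leaving a
#' `p_unknown` fraction unannotated (empty compartment list), the way real
#' annotation tables carry proteins of unknown location.
#'
#' @param db A `seq_db` tibble.
#' @param compartments Compartment name pool.
#' @param p_unknown Probability of an empty annotation.
#' @param seed Integer seed.
#' @return A `location_map` tibble (all entries flagged `core`).
#' @export
simulate_locations <- function(db,
                               compartments = c(
                                 "Cytosol", "Nucleus", "Plasma membrane",
                                 "Secreted", "Lysosome", "Endoplasmic reticulum"
                               ),
                               p_unknown = 0.3,
                               seed = 1) {
  stopifnot(is.data.frame(db))
  with_seed(seed, {
    comp <- lapply(seq_len(nrow(db)), function(i) {
      if (stats::runif(1) < p_unknown) {
        return(character(0))
      }
      sample(compartments, sample(1:2, 1))
    })
    structure(
      tibble(accession = db$accession, compartments = comp, aux = "core"),
      class = c("location_map", class(tibble()))
    )
  })
}

#' Serialize simulation ground truth to JSON
#'
#' @param ground_truth The `ground_truth` element of a [simulate_experiment()]
#'   result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(
      mappings = ground_truth$mappings,
      coverage = ground_truth$coverage,
      hotspots = ground_truth$hotspots,
      seed = ground_truth$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
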