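# Small in-code fixtures shared across test files.

# Hand-written 3-protein database with known sequences.
tiny_db <- function() {
  ligandr:::new_seq_db(tibble::tibble(
    accession = c("P1", "P2", "P3"),
    entry_name = c("P1_TEST", "P2_TEST", NA),
    organism = c("Homo sapiens", "Homo sapiens", NA),
    description = c("protein one", "protein two", ""),
    sequence = c(
      "MKLVAQWERTY", # length 11
      "ABCDEF",      # uses B (Asx) legally; length 6
      "AAAAGGGG"     # repeats for overlap tests; length 8
    )
  ))
}

# Experiment over tiny_db with known mappings.
tiny_experiment <- function(name = "tiny") {
  tbl <- identification_table(
    peptide = c("KLV", "VAQ", "ABC", "CDE", "AAA"),
    protein = c("P1", "P1", "P2", "P2", "P3")
  )
  suppressWarnings(build_experiment(tbl, tiny_db(), name = name))
}

# Random synthetic experiment (coordinates included so the planted graph is
# authoritative).
random_experiment <- function(seed, n_proteins = 8, n_peptides = 40,
                              name = paste0("exp", seed), ...) {
  db <- simulate_proteome(n_proteins, length_range = c(60, 120), seed = seed)
  sim <- simulate_experiment(db, n_peptides, seed = seed + 500000L, ...)
  exp <- build_experiment(sim$table, db, name = name)
  list(db = db, sim = sim, exp = exp)
}

# Several experiments over one shared database, as a real comparison needs.
random_experiment_set <- function(seed, n_exps, n_proteins = 8,
                                  n_peptides = 30, prefix = "r") {
  db <- simulate_proteome(n_proteins, length_range = c(60, 120), seed = seed)
  exps <- lapply(seq_len(n_exps), function(i) {
    sim <- simulate_experiment(db, n_peptides, seed = seed + i)
    build_experiment(sim$table, db, paste0(prefix, i))
  })
  list(db = db, exps = exps, expset = experiment_set(exps))
}

# Brute-force per-cell coverage recount: cell i (0-based) is covered by every
# distinct (peptide, interval) with start <= i < end.
brute_force_coverage <- function(exp, accession) {
  m <- unique(exp$mappings[exp$mappings$protein == accession,
    c("peptide", "start", "end")
  ])
  len <- nchar(exp$proteins[[accession]])
  vapply(seq_len(len) - 1L, function(i) {
    sum(m$start <= i & i < m$end)
  }, numeric(1))
}

expect_setequal_sorted <- function(x, y) {
  expect_identical(sort(unique(x)), sort(unique(y)))
}
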