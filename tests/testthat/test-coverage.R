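make_db <- function(...) {
  seqs <- c(...)
  ligandr:::new_seq_db(tibble::tibble(
    accession = names(seqs),
    entry_name = NA_character_, organism = NA_character_, description = "",
    sequence = unname(seqs)
  ))
}

test_that("coverage arrays count per-position peptide occurrences", {
  db <- make_db(P = "ABCDEF")
  exp <- build_experiment(
    identification_table(c("ABC", "CDE"), c("P", "P")), db, "cov"
  )
  expect_identical(
    as.integer(compute_coverage(exp, "P")),
    c(1L, 1L, 2L, 1L, 1L, 0L)
  )
  expect_error(compute_coverage(exp, "NOPE"), class = "ligandr_validation_error")
})

test_that("a repeated occurrence of one distinct peptide covers both sites", {
  db <- make_db(P3 = "AAAAGGGG")
  exp <- build_experiment(identification_table("AAAA", "P3"), db, "rep")
  # only one occurrence of AAAA at 0..4
  expect_identical(as.integer(compute_coverage(exp, "P3")), c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  exp2 <- build_experiment(identification_table("AA", "P3"), db, "rep2")
  # AA occurs at 0,1,2 -> positions 0..3 covered 1,2,2,1
  expect_identical(as.integer(compute_coverage(exp2, "P3")), c(1L, 2L, 2L, 1L, 0L, 0L, 0L, 0L))
})

test_that("coverage matches a brute-force per-cell recount on random experiments", {
  for (seed in c(2, 13, 77)) {
    got <- random_experiment(seed, n_peptides = 100)
    for (acc in inferred_proteins(got$exp)) {
      cov <- compute_coverage(got$exp, acc)
      expect_identical(as.numeric(cov), brute_force_coverage(got$exp, acc))
      # conservation: total coverage mass equals the summed interval lengths
      occ <- unique(got$exp$mappings[
        got$exp$mappings$protein == acc, c("peptide", "start", "end")
      ])
      expect_equal(sum(as.numeric(cov)), sum(as.numeric(occ$end - occ$start)))
    }
  }
})

test_that("protein coverage distance is an elementwise L1 sum", {
  expect_identical(protein_coverage_distance(c(1, 1, 0, 0), c(0, 1, 1, 0)), 2)
  v <- c(3, 1, 4, 1, 5)
  expect_identical(protein_coverage_distance(v, v), 0)
  expect_error(
    protein_coverage_distance(c(1, 2), c(1, 2, 3)),
    class = "ligandr_validation_error"
  )
  withr::with_seed(8, {
    for (i in 1:10) {
      a <- sample(0:5, 30, replace = TRUE)
      b <- sample(0:5, 30, replace = TRUE)
      expect_identical(protein_coverage_distance(a, b), as.numeric(sum(abs(a - b))))
    }
  })
})

test_that("experiment distance averages per-protein L1 over the universe", {
  db <- make_db(P = "ABCD", Q = "MKLVAQWE")
  e1 <- build_experiment(identification_table("AB", "P"), db, "e1")
  e2 <- build_experiment(identification_table("KLV", "Q"), db, "e2")
  # identical experiments have distance zero
  expect_identical(experiment_distance(e1, e1), 0)
  # universe {P}: e1 covers [1,1,0,0], e2 nothing -> distance 2
  expect_identical(experiment_distance(e1, e2, protein_universe = "P"), 2)
  # default pair-union universe {P, Q}: (2 + 3) / 2
  expect_identical(experiment_distance(e1, e2), 2.5)
  # length-normalized variant divides per-protein scores by protein length
  expect_identical(
    experiment_distance(e1, e2, length_normalized = TRUE),
    (2 / 4 + 3 / 8) / 2
  )
})

test_that("set-wide distances equal a flat concatenated-vector oracle", {
  got <- random_experiment_set(9000, 5, prefix = "d")
  exps <- got$exps
  expset <- got$expset
  dm <- coverage_distance_matrix(expset)
  universe <- attr(dm, "universe")
  expect_setequal_sorted(universe, proteins_union(expset))

  flat <- sapply(exps, function(e) {
    unlist(lapply(universe, function(acc) {
      len <- nchar(exps[[which(sapply(exps, function(x) acc %in% names(x$proteins)))[1]]]$proteins[[acc]])
      if (acc %in% names(e$proteins)) {
        as.numeric(compute_coverage(e, acc))
      } else {
        numeric(len)
      }
    }))
  })
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(
        dm[i, j],
        sum(abs(flat[, i] - flat[, j])) / length(universe)
      )
    }
  }
})

test_that("the coverage distance matrix satisfies the metric axioms", {
  exps <- random_experiment_set(9100, 4, n_peptides = 25, prefix = "m")$exps
  dm <- coverage_distance_matrix(experiment_set(exps))
  m <- as.matrix(dm)
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0))
  for (i in 1:4) {
    for (j in 1:4) {
      for (k in 1:4) {
        expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
      }
    }
  }
  # identical experiments are indiscernible
  twin <- experiment_set(setNames(exps[c(1, 1)], c("a", "b")))
  expect_identical(unname(as.matrix(coverage_distance_matrix(twin))), matrix(0, 2, 2))
})

test_that("permuting experiment order permutes the matrix consistently", {
  exps <- random_experiment_set(9200, 3, n_peptides = 20, prefix = "p")$exps
  d1 <- as.matrix(coverage_distance_matrix(experiment_set(exps)))
  d2 <- as.matrix(coverage_distance_matrix(experiment_set(exps[c(3, 1, 2)])))
  expect_identical(d1[rownames(d2), colnames(d2)], d2)
})

test_that("n-coverage tables stack per-experiment arrays with zero rows", {
  db <- make_db(P = "ABCDEF", Q = "MKLVAQWE")
  e1 <- build_experiment(identification_table(c("ABC", "KLV"), c("P", "Q")), db, "e1")
  e2 <- build_experiment(identification_table("CDE", "P"), db, "e2")
  e3 <- build_experiment(identification_table("KLV", "Q"), db, "e3")
  expset <- experiment_set(e1, e2, e3)

  nc <- n_coverage_table(expset, "P")
  expect_identical(dim(nc), c(3L, 6L))
  expect_identical(rownames(nc), c("e1", "e2", "e3"))
  expect_identical(unname(nc["e1", ]), as.integer(compute_coverage(e1, "P")))
  expect_identical(unname(nc["e3", ]), rep(0L, 6)) # absent -> zero row

  # single-experiment reduction
  nc1 <- n_coverage_table(experiment_set(e1), "P")
  expect_identical(unname(nc1[1, ]), as.integer(compute_coverage(e1, "P")))

  # row sums equal per-experiment occurrence-length sums
  expect_identical(unname(rowSums(nc)), c(3, 3, 0))

  expect_error(n_coverage_table(expset, "ZZ"), class = "ligandr_validation_error")
})

test_that("the color scale max-normalizes and is scale invariant", {
  expect_identical(coverage_color_scale(c(0, 27)), c(0, 1))
  expect_identical(coverage_color_scale(c(0, 0, 0)), c(0, 0, 0))
  withr::with_seed(5, {
    v <- sample(0:30, 50, replace = TRUE)
    s <- coverage_color_scale(v)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(coverage_color_scale(3 * v), s) # scale invariance
    expect_true(all(diff(s[order(v)]) >= -1e-12)) # monotone in coverage
  })
})

test_that("matrices and coverage tables export as TSV", {
  db <- make_db(P = "ABCDEF")
  e1 <- build_experiment(identification_table("ABC", "P"), db, "e1")
  e2 <- build_experiment(identification_table("CDE", "P"), db, "e2")
  expset <- experiment_set(e1, e2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(coverage_distance_matrix(expset), f1)
  back <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_identical(names(back), c("name", "e1", "e2"))
  expect_identical(back$e2[1], 4) # |[1,1,2,1,1,0]-[0,0,1,1,1,0]| = 4... on one protein

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ncoverage_tsv(n_coverage_table(expset, "P"), f2)
  nc <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_identical(dim(nc), c(2L, 7L))
  expect_identical(names(nc)[1:3], c("experiment", "0", "1"))
})
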