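test_that("map_peptide_to_protein reports all occurrences, overlapping included", {
  expect_identical(
    map_peptide_to_protein("KLV", "MKLVA"),
    tibble::tibble(start = 1L, end = 4L)
  )
  expect_identical(
    map_peptide_to_protein("AA", "AAAA"),
    tibble::tibble(start = 0:2, end = 2:4)
  )
  expect_identical(nrow(map_peptide_to_protein("WWW", "MKLVA")), 0L)
})

test_that("substring mapping agrees with a naive scan oracle on planted peptides", {
  naive_scan <- function(pep, prot) {
    k <- nchar(pep)
    hits <- integer(0)
    for (i in seq_len(nchar(prot) - k + 1)) {
      if (substr(prot, i, i + k - 1) == pep) hits <- c(hits, i - 1L)
    }
    hits
  }
  withr::with_seed(17, {
    for (rep in 1:20) {
      prot <- paste(sample(c("A", "C", "D", "G"), 80, replace = TRUE), collapse = "")
      pep <- substr(prot, 11, 13) # guaranteed at least one hit
      got <- map_peptide_to_protein(pep, prot)
      expect_identical(got$start, naive_scan(pep, prot))
      expect_identical(got$end, got$start + nchar(pep))
    }
  })
})

test_that("build_experiment maps, validates and drops as specified", {
  db <- tiny_db()
  tbl <- identification_table(c("KLV", "ABC"), c("P1", "P2"))
  exp <- build_experiment(tbl, db, name = "two")
  expect_identical(length(peptides(exp)), 2L)
  expect_identical(inferred_proteins(exp), c("P1", "P2"))

  # unknown accession is dropped and counted
  tbl2 <- identification_table(c("KLV", "QQQ"), c("P1", "NOPE"))
  expect_warning(exp2 <- build_experiment(tbl2, db, name = "drop"), "dropped 1")
  expect_identical(exp2$report$n_dropped_unknown_accession, 1L)
  expect_identical(inferred_proteins(exp2), "P1")

  # peptide not found in the named protein is dropped too
  tbl3 <- identification_table(c("KLV", "WWWW"), c("P1", "P1"))
  expect_warning(exp3 <- build_experiment(tbl3, db, name = "nomatch"), "not found")
  expect_identical(exp3$report$n_dropped_no_match, 1L)

  # zero survivors is an error
  tbl4 <- identification_table("WWWW", "P1")
  expect_error(
    suppressWarnings(build_experiment(tbl4, db, name = "none")),
    class = "ligandr_validation_error"
  )
})

test_that("provided coordinates are trusted, validated, and localize repeats", {
  db <- tiny_db() # P3 = AAAAGGGG: "AAA" occurs at 0 and 1
  with_coord <- identification_table("AAA", "P3", start = 1L, end = 4L)
  exp <- build_experiment(with_coord, db, name = "coord")
  expect_identical(exp$mappings$start, 1L) # no substring fallback

  no_coord <- identification_table("AAA", "P3")
  exp2 <- build_experiment(no_coord, db, name = "nocoord")
  expect_identical(exp2$mappings$start, c(0L, 1L)) # all occurrences

  bad <- identification_table("AAA", "P3", start = 4L, end = 7L) # GGG there
  expect_warning(
    expect_error(build_experiment(bad, db, name = "bad")),
    "coordinate"
  )
})

test_that("build_experiment is deterministic and row-order invariant", {
  db <- tiny_db()
  tbl <- identification_table(
    c("KLV", "ABC", "AAA", "CDE"), c("P1", "P2", "P3", "P2")
  )
  perm <- tibble::as_tibble(tbl)[c(3, 1, 4, 2), ]
  e1 <- build_experiment(tbl, db, name = "x")
  e2 <- build_experiment(ligandr:::new_ident_tbl(perm), db, name = "x")
  expect_identical(e1$mappings, e2$mappings)
  expect_identical(e1$proteins, e2$proteins)
})

test_that("the mapping graph is bipartite: edges link peptides to proteins only", {
  got <- random_experiment(21)
  m <- got$exp$mappings
  expect_true(all(m$peptide %in% got$sim$table$peptide))
  expect_true(all(m$protein %in% got$db$accession))
  # no peptide ever appears as a protein node or vice versa
  expect_length(intersect(unique(m$peptide), unique(m$protein)), 0)
  # every mapped accession is in the proteins slot and vice versa
  expect_setequal_sorted(m$protein, names(got$exp$proteins))
})

test_that("set algebra over experiment sets matches brute force", {
  exps <- lapply(1:5, function(s) random_experiment(s, name = paste0("e", s))$exp)
  expset <- experiment_set(exps)
  pep_sets <- lapply(exps, peptides)
  prot_sets <- lapply(exps, inferred_proteins)
  expect_setequal_sorted(peptides_in_all(expset), Reduce(intersect, pep_sets))
  expect_setequal_sorted(peptides_union(expset), Reduce(union, pep_sets))
  expect_setequal_sorted(proteins_in_all(expset), Reduce(intersect, prot_sets))
  expect_setequal_sorted(proteins_union(expset), Reduce(union, prot_sets))

  # single-experiment identity
  single <- experiment_set(exps[[1]])
  expect_identical(peptides_in_all(single), peptides_union(single))
})

test_that("small worked example: {A,B} vs {B,C}", {
  db <- ligandr:::new_seq_db(tibble::tibble(
    accession = c("X1", "X2", "X3"),
    entry_name = NA_character_, organism = NA_character_, description = "",
    sequence = c("MAAAM", "MCCCM", "MGGGM")
  ))
  e1 <- build_experiment(identification_table(c("AAA", "CCC"), c("X1", "X2")), db, "e1")
  e2 <- build_experiment(identification_table(c("CCC", "GGG"), c("X2", "X3")), db, "e2")
  expset <- experiment_set(e1, e2)
  expect_identical(peptides_in_all(expset), "CCC")
  expect_identical(peptides_union(expset), c("AAA", "CCC", "GGG"))
})

test_that("group_by_metadata partitions the set", {
  db <- tiny_db()
  mk <- function(nm, tis) {
    build_experiment(
      identification_table("KLV", "P1"), db, nm,
      tissue = tissue(tis), metadata = list(donor = substr(nm, 1, 1))
    )
  }
  expset <- experiment_set(mk("a1", "lung"), mk("a2", "lung"), mk("b1", "colon"))
  groups <- group_by_metadata(expset, "tissue")
  expect_setequal_sorted(names(groups), c("lung", "colon"))
  expect_identical(length(groups$lung), 2L)
  expect_identical(length(groups$colon), 1L)

  # each experiment lands in exactly one group; sizes sum to the set size
  withr::with_seed(4, {
    for (i in 1:10) {
      labels <- sample(c("u", "v", "w"), 3, replace = TRUE)
      es <- experiment_set(lapply(1:3, function(j) {
        build_experiment(
          identification_table("KLV", "P1"), db, paste0("g", j),
          metadata = list(lab = labels[j])
        )
      }))
      gs <- group_by_metadata(es, "lab")
      expect_identical(sum(lengths(gs)), 3L)
      expect_setequal_sorted(unlist(lapply(gs, names)), names(es))
    }
  })

  expect_error(
    group_by_metadata(expset, "missing_key"), "a1",
    class = "ligandr_validation_error"
  )
})

test_that("peptides_per_protein counts distinct peptides, shared ones per protein", {
  db <- ligandr:::new_seq_db(tibble::tibble(
    accession = c("PA", "PB"),
    entry_name = NA_character_, organism = NA_character_, description = "",
    sequence = c("MKLVACDE", "MACDEKLV") # both contain ACDE and KLV
  ))
  tbl <- identification_table(
    c("KLV", "ACDE", "ACDE"), c("PA", "PA", "PB")
  )
  exp <- build_experiment(tbl, db, "shared")
  counts <- peptides_per_protein(exp)
  expect_identical(
    counts,
    tibble::tibble(protein = c("PA", "PB"), n_peptides = c(2L, 1L))
  )
  expect_identical(
    top_n_proteins(exp, 1),
    tibble::tibble(protein = "PA", n_peptides = 2L)
  )
  # n beyond the protein count returns everything
  expect_identical(nrow(top_n_proteins(exp, 100)), 2L)

  # ties break lexicographically by accession
  tbl2 <- identification_table(c("KLV", "KLV"), c("PB", "PA"))
  exp2 <- build_experiment(tbl2, db, "tie")
  expect_identical(top_n_proteins(exp2, 2)$protein, c("PA", "PB"))
})

test_that("per-protein counts match a brute-force recount on synthetic data", {
  got <- random_experiment(33, n_peptides = 60)
  counts <- peptides_per_protein(got$exp)
  m <- unique(got$exp$mappings[, c("peptide", "protein")])
  for (i in seq_len(nrow(counts))) {
    expect_identical(
      counts$n_peptides[i],
      length(unique(m$peptide[m$protein == counts$protein[i]]))
    )
  }
  # sum over proteins >= unique peptides, equality iff nothing is shared
  expect_gte(sum(counts$n_peptides), length(peptides(got$exp)))
})

test_that("experiment metadata layers attach and serialize", {
  db <- tiny_db()
  exp <- build_experiment(
    identification_table(c("KLV", "ABC"), c("P1", "P2")), db, "meta",
    tissue = tissue("lung"),
    hla = hla_set(c("DRB1*15:01", "DRB1*07:01")),
    metadata = list(donor = "D1")
  )
  expect_identical(exp$hla$hla_class, "II") # inferred from DR locus
  expect_identical(hla_set(c("A*02:01"))$hla_class, "I")
  expect_identical(hla_set(c("A*02:01", "DRB1*15:01"))$hla_class, "mixed")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_experiment(exp, tsv)
  sidecar <- jsonlite::read_json(paste0(tsv, ".json"))
  expect_identical(sidecar$name, "meta")
  expect_identical(sidecar$tissue, "lung")
  expect_identical(sidecar$metadata$donor, "D1")
  back <- read_identification_table(tsv)
  expect_identical(tibble::as_tibble(back), exp$mappings)
})
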