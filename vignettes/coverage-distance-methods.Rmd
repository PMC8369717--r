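---
title: "Comparing immunopeptidomes with coverage arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing immunopeptidomes with coverage arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandr)
```

## The problem

Mass-spectrometry immunopeptidomics captures the peptides presented on HLA
proteins of a tissue or cell culture. Upstream identification pipelines turn
spectra into a table of peptide hits; `ligandr` starts where they stop. Its
object model binds one identification run to its sequence database and sample
layers (tissue, HLA alleles, metadata) in an *experiment*, and the central
representation is the bipartite peptide-to-protein mapping graph: every edge is
one exact occurrence of an identified peptide in a database protein, stored as
a 0-based half-open interval. Edges only connect peptides to proteins —
summaries, coverage, and every downstream comparison are functions of this
graph.

## Coverage arrays and the experiment distance

For a protein of length $L$, the coverage array $c \in \mathbb{N}^L$ counts at
each residue the unique identified peptides covering that position. Two
semantics matter and are fixed deliberately:

* duplicate identification rows of the same peptide never double-count;
* one distinct peptide occurring at two sites of the same protein increments
  both sites — coverage is positional, so each *occurrence interval* of each
  distinct peptide contributes once.

A conservation law follows and is asserted in the tests: the array total equals
the summed lengths of the counted occurrence intervals.

The dissimilarity of two conditions on one protein is the L1 distance
$\sum_i |c^{(1)}_i - c^{(2)}_i|$, and the distance between two experiments is
the mean of this score over a *protein universe*, with a protein absent from an
experiment contributing an all-zero array. The universe matters: for a
standalone pairwise call it defaults to the union of the two experiments'
inferred proteins, but `coverage_distance_matrix()` fixes it to the set-wide
union so every pair is averaged over the same denominator. With a fixed
universe the result is a scaled L1 metric on concatenated coverage vectors, so
symmetry, identity of indiscernibles and the triangle inequality hold exactly;
the matrix constructor asserts them anyway, because a violation is a reliable
symptom of inconsistent sequence databases. An optional length-normalized
variant divides each protein score by its length before averaging; it is off by
default so that the plain mean matches the definition above.

## Embedding and set comparison

`classical_mds()` is the Torgerson embedding: square the distances,
double-center ($B = -\tfrac12 J D^2 J$), eigendecompose, scale the top-$k$
eigenvectors by $\sqrt{\lambda}$. Numerical choices:

* negative eigenvalues (non-Euclidean mass) are clipped to zero and their
  absolute mass reported in `glance()`;
* every axis is sign-flipped so its first nonzero loading is positive, making
  output byte-reproducible;
* eigenvalues tied within $10^{-12}$ leave the embedding rotation-degenerate;
  axis order then follows the deterministic decomposition order;
* stress is $\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}$, defined as
  0 for an all-zero matrix.

Peptide- and protein-level `overlap_matrix()` counts exact matches per pair;
`jaccard_matrix()` normalizes by the union so differently sized peptidomes
stay comparable. Two empty sets get Jaccard 1 (they are equal; 0 would
fabricate dissimilarity), with a notice because an empty comparison usually
means an upstream problem.

## Omics layers

*Expression.* `compare_expression()` asks whether presented proteins (inferred
proteins found in the profile) are expressed differently from the
profiled-but-not-presented background — the background is the profiled
proteome, not the whole genome, because that is the population the experiment
could have sampled. The test is a two-sided Mann–Whitney rank-sum test, chosen
because expression values are heavily non-normal; no distributional claim is
imported. For $n+m \le 12$ the p-value is computed by exact enumeration of all
$\binom{n+m}{n}$ group assignments (ties handled naturally by ranking the
observed values); above that, the normal approximation with tie and continuity
corrections is used. The two branches were compared at the $n+m=12$ boundary on
random continuous inputs: the worst-case gap of the standard
continuity-corrected approximation is about 0.016 (and larger under heavy
ties), so the agreement property is tested at 0.02 — the approximation is the
standard construction, not tuned. Across many experiments,
`compare_expression_set()` reports Benjamini–Hochberg adjusted p-values
alongside the raw ones.

*Subcellular location.* `compartment_counts()` credits each inferred protein
to every compartment it is annotated with, and counts distinct peptides per
compartment through the mapping graph. Proteins missing from the annotation
table, or annotated with an empty list, are bucketed under `"unknown"` — real
annotation resources leave large fractions of the proteome unplaced, and hiding
that would misrepresent the peptidome's origin.

*Taxonomy.* `build_organism_db()` maps accessions to organisms from UniProt
`OS=` header fields or a two-column table; lookups are total, falling back to
`"unknown"`. `filter_by_organism()` keeps a peptide if *any* of its mapped
proteins belongs to a kept organism (the inclusive rule) and reports the count
of such ambiguous peptides; silently dropping shared peptides would bias
host–pathogen analyses toward the host.

*Flanks.* `extract_flanks()` takes the $n$ residues on either side of every
mapping interval (default $n = 5$, a package choice — flank length is
configurable because no single value is canonical), padding with `-` at protein
termini. Flanks are per occurrence, not per distinct peptide, because cleavage
context is positional. `position_frequency_matrix()` and
`information_content()` summarize them; IC is computed over the 20 amino-acid
frequencies with padding mass renormalized away, so a fully padded position
carries 0 bits.

## What the generator emulates — and what it does not

`simulate_proteome()` draws i.i.d. uniform residues with exact
largest-remainder allocation of organisms, and `simulate_experiment()` draws a
configurable fraction of peptides as nested ladders around shared 9-residue
cores with ragged 0–4 residue extensions — the hallmark of HLA class II
peptidomes, where the open binding groove yields families of overlapping
peptides. The remaining peptides are uniform (random protein, length 9–17,
random start). Every emitted row's true interval, the per-protein true coverage
and the organism partition are returned as machine-readable ground truth, and
the same seed reproduces outputs byte-for-byte (one seeded RNG scope per call,
no global state).

The generator deliberately omits: binding-affinity structure (no allele
specificity in which cores are chosen), realistic amino-acid composition,
expression-biased sampling of source proteins, identification noise
(false-positive PSMs) and quantitative intensities. Passing the ground-truth
recovery tests therefore shows the *bookkeeping* — mapping, coverage,
distances, flanks, taxonomy — is exact, not that the package's statistics are
calibrated for any particular real instrument or search engine. The planted
expression shift (defaults: 2-fold on a log-normal baseline with log2-scale SD
0.5) is the one quantitative effect the generator makes, and it is what the
power checks measure.

## Degenerate inputs and tie-breaks

* Peptide strings are normalized before anything else: flanking-residue
  dialect (`K.PEPTIDE.R`) and bracketed modification annotations stripped,
  then uppercased; rows left invalid are dropped with a counted warning, and
  the load report always satisfies input = emitted + dropped + collapsed.
* Coordinates, when present, are trusted but verified against the sequence
  (identification pipelines may localize a peptide among repeats); substring
  search is the fallback, reporting every overlapping occurrence.
* `top_n_proteins()` breaks count ties lexicographically by accession;
  experiment construction sorts mappings, so identical inputs give identical
  objects regardless of row order.
* A protein with the same accession but different lengths across experiments
  aborts rather than guessing which database is right.
* All-identical samples give the rank-sum test $p = 1$ (no evidence), not an
  error.

## Problem sizes used in validation

The shipped tests and the acceptance script run on deliberately small
instances — proteomes of 6–15 proteins (60–120 residues) with 25–80 peptides,
100 seeded experiments for the coverage recount, 10 experiments for the metric
check, 2,000 null simulations at $n = m = 50$ and 200 power runs — chosen so
the full validation completes in well under a minute while every property is
still exercised at full strength (the checks are exact, not asymptotic).

## Known limitations

No protein inference (shared peptides credit every mapped protein); no native
pepXML/mzIdentML/idXML/mzML parsing (the canonical input is the generic TSV,
with those formats as adapter points); no spectral layer; no GO enrichment or
annotation retrieval. Isoleucine and leucine are distinct residues throughout —
a mass spectrometer cannot tell them apart, but merging them silently would
corrupt round-trips, so any I/L merging is left to the caller's normalization.
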