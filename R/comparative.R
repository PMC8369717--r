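#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|` over the distinct elements of the two
#' inputs. Two empty sets are identical, so the index is 1 (a notice is
#' emitted, since an empty comparison usually means an upstream problem).
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) {
    inform("both sets are empty; returning Jaccard index 1 (identical sets)")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

exp_level_sets <- function(expset, level) {
  level <- match.arg(level, c("peptide", "protein"))
  getter <- if (level == "peptide") peptides else inferred_proteins
  lapply(expset, getter)
}

#' Pairwise overlap counts between experiments
#'
#' The number of peptides (or inferred proteins) with an exact match between
#' each pair of experiments; the diagonal holds each experiment's own set
#' size. Computed on distinct sequences (accessions).
#'
#' @param expset A `pepexp_set`.
#' @param level `"peptide"` or `"protein"`.
#' @return A symmetric integer matrix of class `exp_matrix` (type
#'   `"overlap"`).
#' @export
overlap_matrix <- function(expset, level = c("peptide", "protein")) {
  stopifnot(inherits(expset, "pepexp_set"))
  level <- match.arg(level)
  sets <- exp_level_sets(expset, level)
  m <- pairwise_matrix(sets, function(a, b) length(intersect(a, b)))
  storage.mode(m) <- "integer"
  new_exp_matrix(m, type = "overlap", level = level)
}

#' Pairwise Jaccard indices between experiments
#'
#' Size-normalized counterpart of [overlap_matrix()]: intersection over union
#' of the two experiments' sets, so diagonals are 1 and values are comparable
#' across experiments with differently sized peptidomes.
#'
#' @inheritParams overlap_matrix
#' @return A symmetric numeric matrix of class `exp_matrix` (type
#'   `"jaccard"`), diagonal all 1.
#' @export
jaccard_matrix <- function(expset, level = c("peptide", "protein")) {
  stopifnot(inherits(expset, "pepexp_set"))
  level <- match.arg(level)
  sets <- exp_level_sets(expset, level)
  m <- pairwise_matrix(sets, function(a, b) suppressMessages(jaccard(a, b)))
  new_exp_matrix(m, type = "jaccard", level = level)
}

pairwise_matrix <- function(sets, f) {
  n <- length(sets)
  nm <- names(sets)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- f(sets[[i]], sets[[j]])
    }
  }
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `k` dimensions by double-centering the squared
#' distances (`B = -J D^2 J / 2`), eigendecomposing, and scaling the top-`k`
#' eigenvectors by the square root of their eigenvalues. Negative eigenvalues
#' (non-Euclidean distance mass) are clipped to zero and their absolute mass
#' reported. For reproducibility each coordinate axis is flipped so that its
#' first nonzero loading is positive; when eigenvalues tie within 1e-12 the
#' axis order follows the deterministic decomposition order (the embedding is
#' rotation-degenerate there).
#'
#' Stress is `sqrt(sum((d - dhat)^2) / sum(d^2))` over all pairs, with the
#' all-zero matrix defined to have stress 0.
#'
#' @param dm A symmetric distance matrix (e.g. from
#'   [coverage_distance_matrix()]), zero diagonal.
#' @param k Number of dimensions, `1 <= k <= n - 1`.
#' @return An object of class `mds_embedding` with fields `names`, `coords`
#'   (n x k), `eigenvalues` (descending, unclipped), `stress`,
#'   `negative_eigenvalue_mass`, `k`.
#' @export
classical_mds <- function(dm, k = 2) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2 || nrow(d) != ncol(d)) {
    abort_validation("`dm` must be a square matrix over at least 2 experiments")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n - 1) {
    abort_validation(sprintf("`k` must satisfy 1 <= k <= %d", n - 1))
  }
  k <- as.integer(k)
  assert_metric(d, tol = 1e-8)
  nm <- rownames(d) %||% paste0("exp", seq_len(n))

  j_mat <- diag(n) - matrix(1 / n, n, n)
  b_mat <- -0.5 * j_mat %*% (d^2) %*% j_mat
  ee <- eigen((b_mat + t(b_mat)) / 2, symmetric = TRUE)
  ev <- ee$values
  neg_mass <- sum(abs(ev[ev < 0]))
  lam <- pmax(ev[seq_len(k)], 0)
  coords <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam), nrow = k)

  # deterministic sign convention: first nonzero loading of each axis positive
  for (col in seq_len(k)) {
    nz <- which(abs(coords[, col]) > 1e-12)
    if (length(nz) > 0 && coords[nz[[1]], col] < 0) {
      coords[, col] <- -coords[, col]
    }
  }
  dimnames(coords) <- list(nm, paste0("dim", seq_len(k)))

  dhat <- as.matrix(dist(coords))
  denom <- sum(d^2)
  stress <- if (denom == 0) 0 else sqrt(sum((d - dhat)^2) / denom)

  structure(
    list(
      names = nm, coords = coords, eigenvalues = ev,
      stress = stress, negative_eigenvalue_mass = neg_mass, k = k
    ),
    class = "mds_embedding"
  )
}

#' @method print mds_embedding
#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf(
    "<mds_embedding> %d experiment(s) in %d dimension(s); stress %.3g, clipped eigenvalue mass %.3g\n",
    length(x$names), x$k, x$stress, x$negative_eigenvalue_mass
  ))
  print(x$coords)
  invisible(x)
}

#' @method tidy mds_embedding
#' @export
tidy.mds_embedding <- function(x, ...) {
  out <- as_tibble(x$coords)
  tibble(name = x$names, !!!out)
}

#' @method glance mds_embedding
#' @export
glance.mds_embedding <- function(x, ...) {
  tibble(
    n = length(x$names),
    k = x$k,
    stress = x$stress,
    negative_eigenvalue_mass = x$negative_eigenvalue_mass
  )
}
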