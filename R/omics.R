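#' Split an expression profile into presented and background proteins
#'
#' Presented proteins are the profiled accessions that are inferred proteins
#' of the experiment; the background is every other profiled accession (the
#' profiled-but-not-presented proteins, not the whole genome).
#' Auxiliary-flagged entries are excluded by default; inferred proteins absent
#' from the profile cannot be compared and are only counted in the report.
#' Either group coming out empty leaves nothing to compare and is an error.
#'
#' @param exp A `pepexp`.
#' @param profile An `expression_profile` tibble.
#' @param include_auxiliary Keep auxiliary-flagged entries?
#' @return A tibble of class `presentation_split` with columns `accession`,
#'   `value`, `group` (`"presented"`/`"background"`), and a `report`
#'   attribute (`n_presented`, `n_background`, `n_not_profiled`,
#'   `n_auxiliary_excluded`).
#' @export
split_presented_background <- function(exp, profile, include_auxiliary = FALSE) {
  stopifnot(inherits(exp, "pepexp"), is.data.frame(profile))
  if (nrow(profile) == 0) {
    abort_validation("the expression profile is empty")
  }
  prof <- as_tibble(profile)
  n_aux <- 0L
  if (!include_auxiliary && "aux" %in% names(prof)) {
    n_aux <- sum(prof$aux == "auxiliary")
    prof <- prof[prof$aux != "auxiliary", ]
  }
  inferred <- inferred_proteins(exp)
  group <- ifelse(prof$accession %in% inferred, "presented", "background")
  n_not_profiled <- length(setdiff(inferred, prof$accession))
  out <- tibble(
    accession = prof$accession,
    value = prof$value,
    group = group
  )
  if (!any(group == "presented")) {
    abort_validation("no inferred protein is present in the expression profile (empty presented group)")
  }
  if (!any(group == "background")) {
    abort_validation("every profiled protein is presented (empty background group); nothing to compare")
  }
  structure(
    out,
    report = list(
      n_presented = sum(group == "presented"),
      n_background = sum(group == "background"),
      n_not_profiled = n_not_profiled,
      n_auxiliary_excluded = n_aux
    ),
    class = c("presentation_split", class(tibble()))
  )
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Tests whether two samples come from the same distribution using the
#' Mann-Whitney U statistic (number of pairs where `x` exceeds `y`, ties
#' counted 1/2). For `n + m <= 12` the p-value is computed by exact
#' enumeration of all group assignments of the observed values (ties handled
#' naturally); larger samples use the normal approximation with tie and
#' continuity corrections. Two identical value sets carry no evidence and give
#' p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A one-row tibble with `statistic` (U), `p_value`, `n_x`, `n_y`,
#'   `method`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort_validation("both groups must be non-empty")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_validation("values must be finite")
  }
  n <- length(x)
  m <- length(y)
  big_n <- n + m
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2

  if (big_n <= 12) {
    # exact permutation distribution of U over all C(n+m, n) assignments
    idx <- combn(big_n, n)
    u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    tibble(statistic = u, p_value = p, n_x = n, n_y = m, method = "exact")
  } else {
    rank_sum_normal_approx(x, y)
  }
}

# Normal approximation with tie and continuity corrections; also used to
# check exact/approximate agreement at the branch boundary.
rank_sum_normal_approx <- function(x, y) {
  n <- length(x)
  m <- length(y)
  big_n <- n + m
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (big_n * (big_n - 1))
  sigma2 <- n * m / 12 * ((big_n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all values identical: no evidence against the null
    p <- 1
  } else {
    z <- max((abs(u - mu) - 0.5) / sqrt(sigma2), 0)
    p <- min(1, 2 * pnorm(-z))
  }
  tibble(statistic = u, p_value = p, n_x = n, n_y = m, method = "normal_approx")
}

#' Compare expression of presented vs non-presented proteins
#'
#' Combines [split_presented_background()] with [rank_sum_test()] to ask
#' whether the proteins sampled into the immunopeptidome are expressed
#' differently from the profiled proteins that were not presented.
#'
#' @inheritParams split_presented_background
#' @return An object of class `expression_comparison`: the split data plus the
#'   test result, accessible via [tidy()] (per-accession rows) and [glance()]
#'   (statistic, p-value, group sizes).
#' @export
compare_expression <- function(exp, profile, include_auxiliary = FALSE) {
  split <- split_presented_background(exp, profile, include_auxiliary)
  test <- rank_sum_test(
    split$value[split$group == "presented"],
    split$value[split$group == "background"]
  )
  structure(
    list(
      experiment = exp$name,
      data = as_tibble(split),
      statistic = test$statistic,
      p_value = test$p_value,
      method = test$method,
      report = attr(split, "report")
    ),
    class = "expression_comparison"
  )
}

#' @method print expression_comparison
#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf(
    "<expression_comparison> '%s': U = %g, p = %.3g (%d presented vs %d background)\n",
    x$experiment, x$statistic, x$p_value,
    x$report$n_presented, x$report$n_background
  ))
  invisible(x)
}

#' @method tidy expression_comparison
#' @export
tidy.expression_comparison <- function(x, ...) x$data

#' @method glance expression_comparison
#' @export
glance.expression_comparison <- function(x, ...) {
  tibble(
    experiment = x$experiment,
    statistic = x$statistic,
    p_value = x$p_value,
    n_presented = x$report$n_presented,
    n_background = x$report$n_background,
    n_not_profiled = x$report$n_not_profiled,
    method = x$method
  )
}

#' Expression comparison across an experiment set
#'
#' Runs [compare_expression()] per experiment and applies Benjamini-Hochberg
#' FDR correction across the resulting p-values.
#'
#' @param expset A `pepexp_set`.
#' @param profile An `expression_profile` shared by the experiments.
#' @param include_auxiliary Keep auxiliary-flagged entries?
#' @return A tibble, one row per experiment, with `p_value` and `p_adjusted`.
#' @export
compare_expression_set <- function(expset, profile, include_auxiliary = FALSE) {
  stopifnot(inherits(expset, "pepexp_set"))
  out <- bind_rows(lapply(
    expset, function(e) glance(compare_expression(e, profile, include_auxiliary))
  ))
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Count inferred proteins and peptides per subcellular compartment
#'
#' Each inferred protein contributes to every compartment it is annotated
#' with; proteins absent from the location map, or annotated with an empty
#' compartment list, are counted under `"unknown"`. Per compartment,
#' `n_peptides` is the number of distinct peptides mapping to at least one
#' protein of that compartment.
#'
#' @param exp A `pepexp`.
#' @param locmap A `location_map` tibble.
#' @return A tibble of class `compartment_counts` with columns `compartment`,
#'   `n_proteins`, `n_peptides` (an `"unknown"` row is always present), sorted
#'   by `n_proteins` descending.
#' @export
compartment_counts <- function(exp, locmap) {
  stopifnot(inherits(exp, "pepexp"), is.data.frame(locmap))
  prot <- inferred_proteins(exp)
  idx <- match(prot, locmap$accession)
  comp_of <- lapply(seq_along(prot), function(i) {
    if (is.na(idx[[i]])) {
      return("unknown")
    }
    comp <- locmap$compartments[[idx[[i]]]]
    if (length(comp) == 0) "unknown" else comp
  })
  long <- tibble(
    protein = rep(prot, lengths(comp_of)),
    compartment = unlist(comp_of, use.names = FALSE)
  )
  pep_map <- distinct(exp$mappings, .data$peptide, .data$protein)
  joined <- left_join(long, pep_map, by = "protein", relationship = "many-to-many")
  out <- summarise(
    group_by(joined, .data$compartment),
    n_proteins = n_distinct(.data$protein),
    n_peptides = n_distinct(.data$peptide),
    .groups = "drop"
  )
  if (!"unknown" %in% out$compartment) {
    out <- bind_rows(out, tibble(
      compartment = "unknown", n_proteins = 0L, n_peptides = 0L
    ))
  }
  out <- arrange(out, desc(.data$n_proteins), .data$compartment)
  structure(out, class = c("compartment_counts", class(tibble())))
}
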