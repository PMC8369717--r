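# ggplot2 front-ends; every figure has a TSV twin via the write_* helpers so
# numbers can be asserted without rendering.

#' @method autoplot coverage_array
#' @export
autoplot.coverage_array <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::labs(
      x = "residue position (0-based)", y = "peptide coverage",
      title = attr(object, "accession")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ncoverage
#' @export
autoplot.ncoverage <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$experiment, fill = .data$coverage
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "residue position (0-based)", y = NULL,
      fill = "coverage", title = attr(object, "accession")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot exp_matrix
#' @export
autoplot.exp_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$experiment_1, y = .data$experiment_2, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = attr(object, "type"),
      title = paste(
        attr(object, "type"),
        if (!is.null(attr(object, "level"))) paste0("(", attr(object, "level"), ")") else ""
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, ...) {
  df <- tidy(object)
  if (object$k == 1) {
    df$dim2 <- 0
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(size = 3, color = "steelblue4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1, size = 3) +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2",
      title = sprintf("classical MDS (stress %.3g)", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot expression_comparison
#' @export
autoplot.expression_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$value, fill = .data$group
  )) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "expression value (log scale)",
      title = sprintf(
        "%s: presented vs background (p = %.3g)",
        object$experiment, object$p_value
      )
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @method autoplot pfm
#' @export
autoplot.pfm <- function(object, ...) {
  ic <- information_content(object)
  df <- tibble(position = as.integer(rownames(object)), bits = ic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "position", y = "information content (bits)",
      title = sprintf("flank motif over %d sequences", attr(object, "n_sequences"))
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of compartment counts
#'
#' @param counts A `compartment_counts` tibble.
#' @param what `"proteins"` or `"peptides"`.
#' @return A ggplot object.
#' @export
plot_compartment_counts <- function(counts, what = c("proteins", "peptides")) {
  what <- match.arg(what)
  col <- paste0("n_", what)
  df <- as_tibble(counts)
  df$compartment <- factor(df$compartment, levels = rev(df$compartment))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[col]], y = .data$compartment
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = paste("inferred", what), y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of peptides per inferred protein
#'
#' @param exp A `pepexp`.
#' @return A ggplot object.
#' @export
plot_peptides_per_protein <- function(exp) {
  df <- peptides_per_protein(exp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_peptides)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", color = "white") +
    ggplot2::labs(
      x = "peptides per protein", y = "proteins",
      title = exp$name
    ) +
    ggplot2::theme_minimal()
}
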