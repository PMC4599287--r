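# ggplot2 views of the result tables

#' Volcano plot of a differential-expression table
#'
#' @param de Table from [differential_expression()].
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(.data$fold_change,
                                   -log10(.data$p_adjusted),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Fold change (mean log2, P3 - P1&2)",
                  y = "-log10 adjusted p", color = "Significant") +
    ggplot2::theme_minimal()
}

#' Expression heatmap of the differential signature
#'
#' Genes are split up/down in P3 and ordered by fold change; samples are
#' ordered by prognosis group, then by average-linkage hierarchical
#' clustering on correlation distance within each group.
#'
#' @param expr Expression tibble/matrix.
#' @param de Table from [differential_expression()] (significant genes are
#'   drawn).
#' @param assignments Prognosis assignments.
#' @return A ggplot.
#' @export
plot_signature_heatmap <- function(expr, de, assignments) {
  m <- expr_to_matrix(expr)
  sig <- de |>
    filter(.data$significant) |>
    arrange(desc(.data$direction), desc(.data$fold_change))
  if (nrow(sig) == 0) abort("no significant genes to draw")
  sub <- m[sig$gene_id, , drop = FALSE]
  a <- assignments[match(colnames(sub), assignments$sample_id), ]
  order_within <- function(ids) {
    if (length(ids) < 3) return(ids)
    cm <- suppressWarnings(cor(sub[, ids, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    ids[hc$order]
  }
  ord <- c(order_within(colnames(sub)[a$group == "P1&2"]),
           order_within(colnames(sub)[a$group == "P3"]))
  z <- t(scale(t(sub[, ord, drop = FALSE])))
  z[!is.finite(z)] <- 0
  long <- matrix_to_tbl(z) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "z") |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(sig$gene_id)),
           sample_id = factor(.data$sample_id, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "black",
                                  high = "red") +
    ggplot2::labs(x = "Patients (P1&2 then P3)", y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
}

#' Histogram of prognosis-group proportions per molecular subtype
#'
#' @param tab Table from [tabulate_subtypes()].
#' @return A ggplot.
#' @export
plot_subtype_proportions <- function(tab) {
  long <- tab |>
    tidyr::pivot_longer(c("frac_p12", "frac_p3"), names_to = "group",
                        values_to = "fraction") |>
    mutate(group = ifelse(.data$group == "frac_p3", "P3", "P1&2"))
  ggplot2::ggplot(long, ggplot2::aes(.data$subtype, .data$fraction,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("P1&2" = "grey40",
                                          "P3" = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Proportion of patients", fill = NULL) +
    ggplot2::theme_minimal()
}
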