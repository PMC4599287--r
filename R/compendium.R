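#' Classify genes by tissue-group predominance
#'
#' A gene is predominantly expressed in a tissue group when its maximum
#' expression across the germline/ES/placenta/somatic compendium exceeds the
#' mean of the normal somatic tissues plus `k` standard deviations, and that
#' maximum falls outside the somatic group. Genes failing the rule are
#' returned with `predominant = FALSE` (no particular specificity of
#' expression). Non-leukemic bone-marrow samples never participate in the
#' predominance call; they feed the silence filter
#' ([filter_marrow_silent()]) instead.
#'
#' Ties for the maximum group are broken in the fixed order germline > ES >
#' placenta > somatic. The SD is the sample standard deviation (n - 1
#' denominator); zero somatic variance is legal, in which case the threshold
#' equals the somatic mean.
#'
#' @param expr Expression tibble (first column `gene_id`, one numeric column
#'   per sample, log2 scale) or an equivalent matrix.
#' @param annotation Tibble with columns `sample_id` and `group` (levels
#'   `germline`, `es`, `placenta`, `somatic`, `bm_nonleukemic`).
#' @param k SD multiplier of the predominance threshold (3 for arrays).
#' @param baseline `"somatic"` (default) computes the reference mean/SD over
#'   the somatic tissues only; `"all"` uses all four predominance groups.
#' @return A tibble with one row per gene: `gene_id`, `somatic_mean`,
#'   `somatic_sd`, `threshold`, `max_value`, `max_group`, `predominant`.
#' @export
call_predominance <- function(expr, annotation, k = 3,
                              baseline = c("somatic", "all")) {
  baseline <- match.arg(baseline)
  m <- expr_to_matrix(expr)
  ann <- validate_annotation(annotation, colnames(m))
  groups <- predominance_group_levels()
  missing <- setdiff(groups, unique(ann$group))
  if (length(missing)) {
    abort(paste0("tissue annotation lacks required group(s): ",
                 paste(missing, collapse = ", ")))
  }
  som_ids <- ann$sample_id[ann$group == "somatic"]
  if (length(som_ids) < 2) {
    abort("at least two somatic samples are required (SD undefined)")
  }
  base_ids <- if (baseline == "somatic") {
    som_ids
  } else {
    ann$sample_id[ann$group %in% groups]
  }
  ref_mean <- rowMeans(m[, base_ids, drop = FALSE])
  ref_sd <- row_sds(m[, base_ids, drop = FALSE])
  threshold <- ref_mean + k * ref_sd

  group_max <- vapply(groups, function(g) {
    row_maxs(m[, ann$sample_id[ann$group == g], drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(group_max))) {
    group_max <- matrix(group_max, nrow = nrow(m), dimnames = list(NULL, groups))
  }
  max_value <- row_maxs(group_max)
  # column order encodes the tie-break priority germline > es > placenta > somatic
  max_group <- groups[max.col(group_max, ties.method = "first")]

  tibble(gene_id = rownames(m),
         somatic_mean = unname(ref_mean), somatic_sd = unname(ref_sd),
         threshold = unname(threshold),
         max_value = unname(max_value), max_group = max_group,
         predominant = max_value > threshold & max_group != "somatic")
}

#' Filter predominant genes to those silent in non-leukemic bone marrow
#'
#' Retains predominant genes whose expression stays at or below their
#' activation threshold in every non-leukemic bone-marrow sample; a single
#' above-threshold marrow sample excludes the gene (sporadic marrow
#' expression disqualifies it as "normally silent"). A value exactly at the
#' threshold is not "above" it, so the gene is retained.
#'
#' @param calls Predominance calls from [call_predominance()].
#' @param expr Compendium expression tibble/matrix (must contain the
#'   bone-marrow samples).
#' @param annotation Tissue annotation; must include `bm_nonleukemic`
#'   samples, otherwise the filter is undefined and an error is raised.
#' @param thresholds Per-gene activation thresholds from
#'   [compute_thresholds()] covering every predominant gene.
#' @return A tibble of the retained (marrow-silent, predominant) genes:
#'   `gene_id`, `threshold`, `marrow_max`, `n_marrow_above` (always 0 among
#'   the retained).
#' @export
filter_marrow_silent <- function(calls, expr, annotation, thresholds) {
  m <- expr_to_matrix(expr)
  ann <- validate_annotation(annotation, colnames(m))
  bm_ids <- ann$sample_id[ann$group == "bm_nonleukemic"]
  if (length(bm_ids) == 0) {
    abort("no non-leukemic bone-marrow samples in the annotation: silence filter undefined")
  }
  pred <- calls$gene_id[calls$predominant]
  if (length(pred) == 0) {
    return(tibble(gene_id = character(0), threshold = numeric(0),
                  marrow_max = numeric(0), n_marrow_above = integer(0)))
  }
  no_thr <- setdiff(pred, thresholds$gene_id)
  if (length(no_thr)) {
    abort(paste0("predominant gene(s) without a threshold: ",
                 paste(head(no_thr, 5), collapse = ", ")))
  }
  thr <- thresholds$threshold[match(pred, thresholds$gene_id)]
  bm <- m[pred, bm_ids, drop = FALSE]
  marrow_max <- row_maxs(bm)
  n_above <- rowSums(bm > thr)
  tibble(gene_id = pred, threshold = thr, marrow_max = marrow_max,
         n_marrow_above = as.integer(n_above)) |>
    filter(.data$n_marrow_above == 0L)
}
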