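#' Compute per-gene activation thresholds from a reference panel
#'
#' The activation threshold of a gene is the mean of its signal in the
#' reference samples plus `k` standard deviations (sample SD, n - 1
#' denominator): mean + 3 SD of the 112 normal somatic tissues for array
#' data, mean + 2 SD of the 10 normal samples for qPCR ratios. For a cohort
#' profiled on a different platform, pass that study's own non-leukemic
#' control samples as `ref_expr` and the same formula applies.
#'
#' @param ref_expr Reference expression tibble/matrix (genes x reference
#'   samples, log scale). At least two reference samples are required.
#' @param k Positive SD multiplier (3 for arrays, 2 for qPCR).
#' @return A tibble `gene_id`, `ref_mean`, `ref_sd`, `k`, `threshold`,
#'   `n_ref`.
#' @export
compute_thresholds <- function(ref_expr, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("'k' must be a single positive multiplier")
  }
  m <- expr_to_matrix(ref_expr, what = "reference expression")
  if (ncol(m) < 2) {
    abort("at least two reference samples are required (SD undefined)")
  }
  mu <- rowMeans(m)
  sdv <- row_sds(m)
  tibble(gene_id = rownames(m), ref_mean = unname(mu), ref_sd = unname(sdv),
         k = k, threshold = unname(mu + k * sdv), n_ref = ncol(m))
}

#' Binarize tumor expression at per-gene thresholds
#'
#' A call is `TRUE` exactly when the expression value is strictly above the
#' gene's threshold; values equal to the threshold are "not expressed". The
#' operation is deterministic, idempotent with respect to re-application of
#' the thresholds, and invariant to sample order.
#'
#' @param expr Expression tibble/matrix (genes x tumors).
#' @param thresholds Thresholds from [compute_thresholds()]; every gene in
#'   `expr` must have one.
#' @return A boolean call tibble (first column `gene_id`, one logical column
#'   per sample).
#' @export
binarize_expression <- function(expr, thresholds) {
  m <- expr_to_matrix(expr)
  no_thr <- setdiff(rownames(m), thresholds$gene_id)
  if (length(no_thr)) {
    abort(paste0("gene(s) without a threshold: ",
                 paste(head(no_thr, 10), collapse = ", ")))
  }
  thr <- thresholds$threshold[match(rownames(m), thresholds$gene_id)]
  calls <- m > thr
  matrix_to_tbl(calls)
}

#' Per-gene aberrant-activation frequency of a call matrix
#'
#' @param calls Boolean call tibble from [binarize_expression()].
#' @return A tibble `gene_id`, `n_expressers`, `n`, `frequency`.
#' @export
call_frequency <- function(calls) {
  m <- expr_to_matrix(calls, what = "call")
  tibble(gene_id = rownames(m),
         n_expressers = as.integer(rowSums(m)),
         n = ncol(m),
         frequency = rowMeans(m))
}

#' Retain genes aberrantly expressed in at least a minimum fraction of every
#' cohort
#'
#' Genes aberrantly expressed in less than `min_freq` of the tumors of any
#' cohort are filtered out; a gene must reach the frequency bar in every
#' series to be retained, and exactly `min_freq` counts as retained.
#'
#' @param calls A boolean call tibble or a (optionally named) list of them,
#'   one per cohort. Cohorts must share the same gene universe.
#' @param min_freq Retention bar as a fraction in (0, 1); default 0.10.
#' @return A tibble with `gene_id`, one `freq_<cohort>` column per cohort,
#'   and `retained`.
#' @export
frequency_filter <- function(calls, min_freq = 0.10) {
  if (!is.numeric(min_freq) || length(min_freq) != 1 ||
      min_freq <= 0 || min_freq >= 1) {
    abort("'min_freq' must be a fraction strictly between 0 and 1")
  }
  if (is.data.frame(calls) || is.matrix(calls)) calls <- list(calls)
  if (length(calls) == 0) abort("at least one cohort of calls is required")
  if (is.null(names(calls)) || any(names(calls) == "")) {
    names(calls) <- paste0("cohort", seq_along(calls))
  }
  mats <- map(calls, expr_to_matrix, what = "call")
  empty <- names(mats)[vapply(mats, ncol, 0L) == 0]
  if (length(empty)) {
    abort(paste0("cohort(s) with no samples: ", paste(empty, collapse = ", ")))
  }
  genes <- rownames(mats[[1]])
  same <- vapply(mats, function(m) identical(sort(rownames(m)), sort(genes)), TRUE)
  if (!all(same)) {
    abort("all cohorts must share the same gene universe")
  }
  freqs <- map(mats, function(m) rowMeans(m[genes, , drop = FALSE]))
  out <- tibble(gene_id = genes)
  for (nm in names(freqs)) out[[paste0("freq_", nm)]] <- unname(freqs[[nm]])
  out$retained <- reduce(map(freqs, function(f) f >= min_freq), `&`)
  out
}
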