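#' Parameters of the discovery pipeline
#'
#' Houses the fixed constants of the procedure: the 3 SD array threshold,
#' the 2 SD qPCR threshold, the 10% aberrant-frequency bar, the per-cohort
#' significance level of the survival screen, the differential-expression
#' level, the univariate bar of the multivariate Cox screen, and the top-3
#' selection per direction.
#'
#' @param k_array SD multiplier for array activation thresholds (3).
#' @param k_qpcr SD multiplier for qPCR aberrancy thresholds (2).
#' @param min_freq Aberrant-frequency retention bar (0.10).
#' @param alpha_screen Per-cohort logrank significance level (0.05).
#' @param alpha_de Differential-expression level on adjusted p (0.01).
#' @param screen_p_multivariate Univariate bar of the multivariate Cox
#'   screen (0.20).
#' @param n_top Genes retained per direction (3).
#' @param rank_by Cross-cohort p-value ranking key (see
#'   [cross_cohort_select()]).
#' @param baseline Predominance baseline (see [call_predominance()]).
#' @param n_perm Permutations for enrichment p-values.
#' @param survival_horizon Optional administrative censoring horizon.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(k_array = 3, k_qpcr = 2, min_freq = 0.10,
                            alpha_screen = 0.05, alpha_de = 0.01,
                            screen_p_multivariate = 0.20, n_top = 3,
                            rank_by = "max", baseline = "somatic",
                            n_perm = 1000, survival_horizon = NULL) {
  for (nm in c("min_freq", "alpha_screen", "alpha_de", "screen_p_multivariate")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) abort(paste0("'", nm, "' must lie strictly in (0, 1)"))
  }
  if (k_array <= 0 || k_qpcr <= 0) abort("SD multipliers must be positive")
  structure(list(k_array = k_array, k_qpcr = k_qpcr, min_freq = min_freq,
                 alpha_screen = alpha_screen, alpha_de = alpha_de,
                 screen_p_multivariate = screen_p_multivariate,
                 n_top = n_top, rank_by = rank_by, baseline = baseline,
                 n_perm = n_perm, survival_horizon = survival_horizon),
            class = "pipeline_params")
}

#' Run the full discovery pipeline on a study bundle
#'
#' Chains the discovery steps end to end: (1) tissue-predominance calls on
#' the compendium; (2) per-gene activation thresholds from the somatic
#' reference panel; (3) the non-leukemic bone-marrow silence filter;
#' (4) binarization of every tumor cohort and the >= `min_freq`
#' every-cohort frequency filter; (5) the per-gene survival screen in each
#' cohort and the cross-cohort selection of the top genes per direction;
#' (6) P1/P2/P3 assignment in the learning cohort, the P3-versus-P1&2
#' Kaplan-Meier comparison, and the cohort report. Optionally (7) the
#' P3-versus-P1&2 differential expression in the learning cohort.
#'
#' @param bundle A [simulate_bundle()] result, or any list shaped like one:
#'   `compendium$expression`, `compendium$annotation`, and `cohorts`, each
#'   cohort a list with `expression` and `survival`.
#' @param params A [pipeline_params()].
#' @param learning_cohort Index or name of the cohort used for
#'   classification and reporting (default the first).
#' @param run_de Also run the differential-expression step (default FALSE).
#' @return An object of class `prognosix_pipeline` carrying every
#'   intermediate artifact: `predominance`, `thresholds`, `silent`,
#'   `calls`, `frequency`, `screens`, `selection`, `signature`,
#'   `assignments`, `km`, `report`, and optionally `de`.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(),
                         learning_cohort = 1, run_de = FALSE) {
  comp <- bundle$compendium
  ann <- comp$annotation
  predominance <- call_predominance(comp$expression, ann, k = params$k_array,
                                    baseline = params$baseline)
  m <- expr_to_matrix(comp$expression)
  som_ids <- ann$sample_id[ann$group == "somatic"]
  thresholds <- compute_thresholds(m[, som_ids, drop = FALSE],
                                   k = params$k_array)
  silent <- filter_marrow_silent(predominance, comp$expression, ann, thresholds)
  silent_genes <- silent$gene_id

  calls <- map(bundle$cohorts, function(co) {
    cm <- expr_to_matrix(co$expression)
    binarize_expression(cm[silent_genes, , drop = FALSE], thresholds)
  })
  frequency <- frequency_filter(calls, min_freq = params$min_freq)
  kept_genes <- frequency$gene_id[frequency$retained]

  screens <- map2(calls, bundle$cohorts, function(cl, co) {
    screen_genes(cl, co$survival, genes = kept_genes)
  })
  selection <- cross_cohort_select(screens, n_top = params$n_top,
                                   alpha = params$alpha_screen,
                                   rank_by = params$rank_by)

  signature <- NULL
  assignments <- NULL
  km <- NULL
  report <- NULL
  de <- NULL
  if (length(selection$positive) > 0 && length(selection$negative) > 0) {
    signature <- signature_genes(selection$positive, selection$negative)
    lc <- bundle$cohorts[[learning_cohort]]
    lc_calls <- calls[[learning_cohort]]
    assignments <- assign_prognosis(lc_calls, signature)
    km <- compare_groups_km(assignments, lc$survival,
                            horizon = params$survival_horizon)
    report <- cohort_report(assignments)
    if (run_de) {
      de <- differential_expression(lc$expression, assignments,
                                    alpha = params$alpha_de)
    }
  }

  structure(list(predominance = predominance, thresholds = thresholds,
                 silent = silent, calls = calls, frequency = frequency,
                 screens = screens, selection = selection,
                 signature = signature, assignments = assignments,
                 km = km, report = report, de = de, params = params),
            class = "prognosix_pipeline")
}

#' @export
print.prognosix_pipeline <- function(x, ...) {
  cat("<prognosix_pipeline>\n")
  cat("  predominant genes:", sum(x$predominance$predominant), "of",
      nrow(x$predominance), "\n")
  cat("  marrow-silent genes:", nrow(x$silent), "\n")
  cat("  frequency-filtered genes:", sum(x$frequency$retained), "\n")
  if (!is.null(x$signature)) {
    cat("  selected positive:", paste(x$signature$positive, collapse = ", "), "\n")
    cat("  selected negative:", paste(x$signature$negative, collapse = ", "), "\n")
    if (!is.null(x$km) && x$km$testable) {
      cat("  learning-cohort P3 vs P1&2 logrank p =",
          format.pval(x$km$p, digits = 3), "\n")
    }
    if (!is.null(x$report)) print(x$report)
  } else {
    cat("  no full signature selected (one direction empty)\n")
  }
  invisible(x)
}
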