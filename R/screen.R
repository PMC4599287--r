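# per-gene survival screen: Mantel-Cox logrank p + univariate Cox HR

surv_test_one <- function(x, surv_obj) {
  n1 <- sum(x)
  n <- length(x)
  out <- list(n = n, n_expressers = as.integer(n1), hr = NA_real_,
              logrank_p = NA_real_, testable = FALSE)
  if (n1 == 0L || n1 == n) return(out)
  sd_fit <- tryCatch(survival::survdiff(surv_obj ~ x), error = function(e) NULL)
  if (is.null(sd_fit)) return(out)
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  coef <- tryCatch(
    suppressWarnings(survival::coxph(surv_obj ~ x)$coefficients[[1]]),
    error = function(e) NA_real_
  )
  out$hr <- exp(coef)
  out$logrank_p <- p
  out$testable <- TRUE
  out
}

#' Survival association of a single gene's aberrant-activation call
#'
#' Compares overall survival between patients whose blasts express the gene
#' (call `TRUE`) and those whose blasts do not, with a Mantel-Cox logrank
#' test; the hazard ratio is estimated by a univariate Cox
#' proportional-hazards fit of the binary call. `hr > 1` means expressers
#' die faster. A gene with an empty expresser or non-expresser group is
#' returned flagged `testable = FALSE` (excluded from ranking), not as an
#' error.
#'
#' @param calls Boolean call tibble ([binarize_expression()]); columns must
#'   match the survival table's sample ids.
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @param gene_id Gene to test.
#' @param min_n Minimum total number of patients (default 10; the screen is
#'   undefined below that).
#' @param horizon Optional administrative censoring horizon (e.g. 60 months
#'   for 5-year overall survival); default off.
#' @return A one-row tibble `gene_id`, `n`, `n_expressers`, `hr`,
#'   `logrank_p`, `testable`.
#' @export
gene_survival_test <- function(calls, surv, gene_id, min_n = 10,
                               horizon = NULL) {
  screen_genes(calls, surv, genes = gene_id, min_n = min_n, horizon = horizon)
}

#' Screen every gene's activation call for survival association
#'
#' Vectorized driver of [gene_survival_test()] over a call matrix: for each
#' gene, a Mantel-Cox logrank p-value and a univariate Cox hazard ratio of
#' expressers versus non-expressers.
#'
#' @inheritParams gene_survival_test
#' @param genes Optional subset of gene ids to screen (default all).
#' @return A tibble with one row per gene: `gene_id`, `n`, `n_expressers`,
#'   `hr`, `logrank_p`, `testable`.
#' @export
screen_genes <- function(calls, surv, genes = NULL, min_n = 10,
                         horizon = NULL) {
  m <- expr_to_matrix(calls, what = "call")
  m <- align_samples(m, surv)
  if (ncol(m) < min_n) {
    abort(paste0("the survival screen needs at least ", min_n, " patients"))
  }
  if (!is.null(horizon)) {
    over <- surv$time > horizon
    surv$event[over] <- FALSE
    surv$time[over] <- horizon
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(paste0("gene(s) absent from calls: ",
                   paste(head(missing, 10), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  surv_obj <- survival::Surv(surv$time, as.integer(surv$event))
  rows <- lapply(rownames(m), function(g) {
    r <- surv_test_one(m[g, ], surv_obj)
    tibble(gene_id = g, n = r$n, n_expressers = r$n_expressers,
           hr = r$hr, logrank_p = r$logrank_p, testable = r$testable)
  })
  bind_rows(rows)
}

#' Select the most consistently prognostic genes across cohorts
#'
#' Keeps genes that are testable in every cohort, direction-consistent (all
#' cohort hazard ratios above 1, or all below 1) and significant in every
#' cohort (logrank p below `alpha`); splits them into a negative list
#' (HR > 1, shorter survival) and a positive list (HR < 1, longer survival);
#' ranks each list by increasing p-value and returns the first `n_top` of
#' each. Ties are broken deterministically by gene id.
#'
#' @param results Named list of per-cohort screen tibbles from
#'   [screen_genes()], all over a common gene list (at least two cohorts).
#' @param n_top Number of genes to retain per direction (default 3).
#' @param alpha Per-cohort significance bar (default 0.05).
#' @param rank_by How to combine the cohort p-values into the ranking key:
#'   `"max"` (default; respects the every-cohort significance criterion),
#'   `"mean"`, or `"first"` (learning cohort only).
#' @return An object of class `signature_selection` with elements
#'   `positive`, `negative` (character vectors), `table` (per-gene wide
#'   tibble with consistency flags and ranks) and the selection parameters.
#' @export
cross_cohort_select <- function(results, n_top = 3,
                                alpha = 0.05,
                                rank_by = c("max", "mean", "first")) {
  rank_by <- match.arg(rank_by)
  if (!is.list(results) || is.data.frame(results) || length(results) < 2) {
    abort("'results' must be a list of screen tibbles from at least two cohorts")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("cohort", seq_along(results))
  }
  tabs <- imap(results, function(res, nm) {
    res |>
      select("gene_id", "hr", "logrank_p", "testable") |>
      rename_with(function(x) paste0(x, "_", nm), -"gene_id")
  })
  wide <- reduce(tabs, inner_join, by = "gene_id")
  hr_m <- as.matrix(wide[grep("^hr_", names(wide))])
  p_m <- as.matrix(wide[grep("^logrank_p_", names(wide))])
  testable <- rowSums(as.matrix(wide[grep("^testable_", names(wide))])) == ncol(hr_m)
  all_up <- rowSums(hr_m > 1, na.rm = TRUE) == ncol(hr_m)
  all_down <- rowSums(hr_m < 1, na.rm = TRUE) == ncol(hr_m)
  wide$direction_consistent <- testable & (all_up | all_down)
  wide$direction <- ifelse(all_up, "negative", ifelse(all_down, "positive", NA))
  wide$direction[!testable] <- NA
  wide$significant_both <- testable & rowSums(p_m < alpha, na.rm = TRUE) == ncol(p_m)
  wide$p_rank_key <- switch(rank_by,
    max = apply(p_m, 1, max),
    mean = rowMeans(p_m),
    first = p_m[, 1]
  )
  wide$eligible <- wide$direction_consistent & wide$significant_both

  pick <- function(dir) {
    elig <- wide |>
      filter(.data$eligible, .data$direction == dir) |>
      arrange(.data$p_rank_key, .data$gene_id)
    if (nrow(elig) < n_top) {
      warn(paste0("only ", nrow(elig), " eligible ", dir,
                  " gene(s); fewer than n_top = ", n_top))
    }
    head(elig$gene_id, n_top)
  }
  negative <- pick("negative")
  positive <- pick("positive")
  wide <- wide |>
    group_by(.data$direction) |>
    arrange(.data$p_rank_key, .data$gene_id, .by_group = TRUE) |>
    mutate(rank = ifelse(.data$eligible, cumsum(.data$eligible), NA_integer_)) |>
    ungroup() |>
    arrange(.data$gene_id)

  structure(list(positive = positive, negative = negative, table = wide,
                 n_top = n_top, alpha = alpha, rank_by = rank_by,
                 cohorts = names(results)),
            class = "signature_selection")
}

#' @export
print.signature_selection <- function(x, ...) {
  cat("<signature_selection> over cohorts:",
      paste(x$cohorts, collapse = ", "), "\n")
  cat("  positive (HR < 1):", paste(x$positive, collapse = ", "), "\n")
  cat("  negative (HR > 1):", paste(x$negative, collapse = ", "), "\n")
  cat("  eligible genes:", sum(x$table$eligible, na.rm = TRUE),
      "of", nrow(x$table), "screened\n")
  invisible(x)
}

#' @export
tidy.signature_selection <- function(x, ...) {
  x$table
}

#' @export
glance.signature_selection <- function(x, ...) {
  tibble(n_genes = nrow(x$table),
         n_consistent_negative = sum(x$table$direction_consistent &
                                       x$table$direction == "negative", na.rm = TRUE),
         n_consistent_positive = sum(x$table$direction_consistent &
                                       x$table$direction == "positive", na.rm = TRUE),
         n_eligible = sum(x$table$eligible, na.rm = TRUE),
         alpha = x$alpha, n_top = x$n_top)
}
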