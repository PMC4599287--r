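# readers/writers for the interchange formats: expression / annotation /
# survival / calls TSV, Ct CSV, GMT gene sets, YAML simulation configs

#' Read and write genes-x-samples expression TSV
#'
#' Tab-separated, header row, first column `gene_id`, one numeric column
#' per sample, '.' decimal separator.
#'
#' @param path File path.
#' @return A tibble (first column `gene_id`).
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene_id"
  expr_to_matrix(out)  # validates uniqueness / completeness
  out
}

#' @rdname read_expression_tsv
#' @param x Expression tibble or matrix.
#' @export
write_expression_tsv <- function(x, path) {
  if (is.matrix(x)) x <- matrix_to_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV (`sample_id`, `group`)
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a survival TSV (`sample_id`, `time`, `event`, covariate columns)
#' @param path File path.
#' @return A tibble; `event` is coerced to logical.
#' @export
read_survival_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort(paste0("survival table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out$event <- as.logical(out$event)
  if (any(out$time < 0, na.rm = TRUE)) abort("survival times must be non-negative")
  out
}

#' Read and write boolean call matrices as 0/1 TSV
#' @param path File path.
#' @return A tibble of logicals (first column `gene_id`).
#' @export
read_calls_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene_id"
  out |> mutate(across(-"gene_id", function(v) as.logical(as.integer(v))))
}

#' @rdname read_calls_tsv
#' @param calls Call tibble from [binarize_expression()].
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls |> mutate(across(-"gene_id", as.integer))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a Ct table CSV
#'
#' Comma-separated with columns `sample_id`, `gene_id`, `ct_dup1`,
#' `ct_dup2`, `ct_noRT`, `role` (target/control/frequent).
#'
#' @param path File path.
#' @return A Ct record tibble (with derived `is_control_gene`,
#'   `is_frequent_gene`).
#' @export
read_ct_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "gene_id", "ct_dup1", "ct_dup2", "ct_noRT", "role")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out |>
    mutate(is_control_gene = .data$role == "control",
           is_frequent_gene = .data$role == "frequent")
}

#' @rdname read_ct_csv
#' @param records Ct record tibble.
#' @export
write_ct_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return A named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param gene_sets Named list of gene-id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a simulation config as structured key/value text (YAML)
#' @param path File path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("tissue_groups", "cohort_sizes", "covariate_freqs")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(v) {
    if (!is.null(names(v)) && length(v) > 1) as.list(v) else v
  }), path)
  invisible(path)
}

#' Write a synthetic bundle to disk in the pipeline's interchange formats
#'
#' Expression and annotation TSVs for the compendium, expression + survival
#' TSVs per cohort, and a JSON sidecar with the planted truth (predominant
#' genes, activated genes and roles, per-gene thresholds, signature, and
#' the per-cohort activation masks).
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(bundle$compendium$expression,
                       file.path(dir, "compendium_expression.tsv"))
  readr::write_tsv(bundle$compendium$annotation,
                   file.path(dir, "compendium_annotation.tsv"), progress = FALSE)
  for (nm in names(bundle$cohorts)) {
    co <- bundle$cohorts[[nm]]
    write_expression_tsv(co$expression,
                         file.path(dir, paste0(nm, "_expression.tsv")))
    readr::write_tsv(co$survival, file.path(dir, paste0(nm, "_survival.tsv")),
                     progress = FALSE)
  }
  truth <- bundle$truth
  truth_json <- list(
    predominant = truth$predominant,
    activated = truth$activated,
    thresholds = truth$thresholds,
    signature = if (!is.null(truth$signature)) {
      list(positive = truth$signature$positive,
           negative = truth$signature$negative)
    },
    activation_masks = lapply(bundle$cohorts, function(co) co$activation)
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Cohort prognosis report with the printed-count arithmetic
#'
#' Aggregates a cohort's prognosis assignments into counts and
#' nearest-integer percentages, the way results are reported in print
#' (e.g. `P3: 61/207 (29%)`).
#'
#' @param assignments Prognosis assignments from [assign_prognosis()] (or
#'   [classify_qpcr()]; unclassified samples are dropped with a message in
#'   the report).
#' @return An object of class `cohort_report` with a `table` of counts and
#'   percentages and the formatted `lines`.
#' @export
cohort_report <- function(assignments) {
  a <- assignments |> filter(!is.na(.data$klass))
  n_dropped <- nrow(assignments) - nrow(a)
  total <- nrow(a)
  counts <- tibble(
    label = c("P1", "P2", "P3", "P1&2"),
    n = c(sum(a$klass == "P1"), sum(a$klass == "P2"),
          sum(a$klass == "P3"), sum(a$group == "P1&2"))
  ) |>
    mutate(total = total, pct = pct_round(.data$n, total))
  lines <- c(
    sprintf("Prognosis report (n = %d)", total),
    sprintf("  %s: %d/%d (%d%%)", counts$label, counts$n, counts$total,
            counts$pct),
    if (n_dropped > 0) sprintf("  [%d unclassified sample(s) excluded]", n_dropped)
  )
  structure(list(table = counts, lines = lines, n = total,
                 n_dropped = n_dropped),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' @export
tidy.cohort_report <- function(x, ...) {
  x$table
}
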