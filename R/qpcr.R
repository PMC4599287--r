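# RT-qPCR arm: Ct QC, testis-relative ratios, mean + 2 SD thresholds,
# six-gene classification of new patients

QC_NO_RT <- "NO_RT_CONTAMINATION"
QC_DUP <- "DUPLICATE_SPREAD"
QC_CTRL <- "CONTROL_UNSTABLE"
QC_MISSING <- "MISSING_DUPLICATE"

#' Quality-control flags for RT-qPCR Ct records
#'
#' Advisory QC (records are flagged, never dropped; downstream operations
#' require `qc_pass`):
#' * `NO_RT_CONTAMINATION` when the no-reverse-transcriptase control has
#'   Ct < 36 (Ct >= 36 is satisfactory);
#' * `DUPLICATE_SPREAD` when the two duplicate Cts are 0.5 cycles or more
#'   apart (acceptable duplicates are < 0.5 apart);
#' * `CONTROL_UNSTABLE` when a control gene's coefficient of variation of
#'   the mean Ct across samples exceeds `max_control_cv` (stable
#'   housekeeping genes range around 5-10%);
#' * `MISSING_DUPLICATE` when either duplicate is absent.
#'
#' @param records Ct tibble with columns `sample_id`, `gene_id`, `ct_dup1`,
#'   `ct_dup2`, `ct_noRT` and either a `role` column
#'   (target/control/frequent) or logical `is_control_gene` /
#'   `is_frequent_gene` columns.
#' @param no_rt_min Minimum satisfactory no-RT Ct (default 36).
#' @param max_dup_spread Duplicate spread at or above which the record is
#'   flagged (default 0.5 cycles).
#' @param max_control_cv Maximum coefficient of variation of a control
#'   gene's Ct across samples (default 0.10).
#' @return `records` with `ct_mean` (arithmetic mean of the duplicates),
#'   `qc_flags` (semicolon-joined, empty when clean) and `qc_pass`.
#' @export
qc_ct <- function(records, no_rt_min = 36, max_dup_spread = 0.5,
                  max_control_cv = 0.10) {
  need <- c("sample_id", "gene_id", "ct_dup1", "ct_dup2", "ct_noRT")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("Ct records lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rec <- as_tibble(records)
  if (!"is_control_gene" %in% names(rec)) {
    if (!"role" %in% names(rec)) {
      abort("Ct records need a 'role' column or 'is_control_gene'/'is_frequent_gene'")
    }
    rec$is_control_gene <- rec$role == "control"
    rec$is_frequent_gene <- rec$role == "frequent"
  }
  rec$ct_mean <- (rec$ct_dup1 + rec$ct_dup2) / 2

  missing_dup <- is.na(rec$ct_dup1) | is.na(rec$ct_dup2)
  no_rt <- !is.na(rec$ct_noRT) & rec$ct_noRT < no_rt_min
  dup_spread <- !missing_dup & abs(rec$ct_dup1 - rec$ct_dup2) >= max_dup_spread

  ctrl_cv <- rec |>
    filter(.data$is_control_gene, !is.na(.data$ct_mean)) |>
    group_by(.data$gene_id) |>
    summarise(cv = sd(.data$ct_mean) / mean(.data$ct_mean), .groups = "drop")
  unstable <- ctrl_cv$gene_id[!is.na(ctrl_cv$cv) & ctrl_cv$cv > max_control_cv]
  ctrl_bad <- rec$is_control_gene & rec$gene_id %in% unstable

  flags <- mapply(function(a, b, c, d) {
    paste(c(QC_MISSING[a], QC_NO_RT[b], QC_DUP[c], QC_CTRL[d]), collapse = ";")
  }, missing_dup, no_rt, dup_spread, ctrl_bad)
  rec$qc_flags <- unname(flags)
  rec$qc_pass <- rec$qc_flags == ""
  rec
}

#' Testis-relative expression ratios from Ct records
#'
#' Implements the relative quantification formula verbatim:
#' `ratio = 2^(Ct_gene,testis - Ct_gene,sample) /
#' 2^(mean Ct_controls,testis - mean Ct_controls,sample)`, using the
#' arithmetic mean Ct of the duplicates. A sample Ct one cycle below the
#' testis Ct (more template) yields ratio 2. Base 2 is the default; pass
#' per-gene `efficiency` bases to use primer-specific amplification bases
#' (all equal to 2 reduces exactly to the printed formula).
#'
#' Records failing QC keep their flags and `qc_pass = FALSE`; a failed
#' control-gene record invalidates the whole sample's normalization, so all
#' of that sample's ratios are additionally flagged. Downstream operations
#' ([qpcr_thresholds()], [classify_qpcr()]) only consume `qc_pass` rows.
#'
#' @param records Ct records; [qc_ct()] is applied automatically when the
#'   QC columns are absent.
#' @param testis_sample Sample id of the testis reference (default
#'   "testis").
#' @param control_genes The four housekeeping normalizer genes; all must be
#'   measured in every sample and in testis, otherwise an error names the
#'   missing gene.
#' @param efficiency Optional named vector of per-gene amplification bases
#'   (default: base 2 for every gene).
#' @return A tibble over non-control genes of non-testis samples:
#'   `sample_id`, `gene_id`, `ratio`, `is_frequent_gene`, `qc_pass`,
#'   `qc_flags`.
#' @export
relative_expression <- function(records, testis_sample = "testis",
                                control_genes = c("ACTB", "U6", "RELA", "AUP1"),
                                efficiency = NULL) {
  rec <- if (!"qc_pass" %in% names(records)) qc_ct(records) else as_tibble(records)
  if (!"ct_mean" %in% names(rec)) rec$ct_mean <- (rec$ct_dup1 + rec$ct_dup2) / 2
  if (!testis_sample %in% rec$sample_id) {
    abort(paste0("testis reference sample '", testis_sample, "' not found"))
  }
  base_of <- function(g) {
    if (is.null(efficiency)) return(rep(2, length(g)))
    b <- efficiency[g]
    ifelse(is.na(b), 2, b)
  }

  ctrl <- rec |> filter(.data$gene_id %in% control_genes)
  ctrl_mean <- ctrl |>
    group_by(.data$sample_id) |>
    summarise(ctrl_ct = mean(.data$ct_mean),
              n_ctrl = n(),
              ctrl_fail = any(!.data$qc_pass),
              .groups = "drop")
  short <- ctrl_mean |> filter(.data$n_ctrl < length(control_genes))
  if (nrow(short)) {
    bad <- rec |>
      filter(.data$sample_id %in% short$sample_id) |>
      group_by(.data$sample_id) |>
      summarise(miss = paste(setdiff(control_genes, .data$gene_id), collapse = ", "),
                .groups = "drop")
    abort(paste0("missing control gene(s): ",
                 paste(paste0(bad$sample_id, ": ", bad$miss), collapse = "; ")))
  }
  testis_ctrl <- ctrl_mean$ctrl_ct[ctrl_mean$sample_id == testis_sample]
  testis_ct <- rec |>
    filter(.data$sample_id == testis_sample, !.data$gene_id %in% control_genes) |>
    select("gene_id", testis_ct = "ct_mean")

  out <- rec |>
    filter(.data$sample_id != testis_sample,
           !.data$gene_id %in% control_genes) |>
    inner_join(testis_ct, by = "gene_id") |>
    inner_join(ctrl_mean[c("sample_id", "ctrl_ct", "ctrl_fail")],
               by = "sample_id")
  g_base <- base_of(out$gene_id)
  out |>
    mutate(ratio = as.numeric(g_base^(.data$testis_ct - .data$ct_mean) /
             2^(testis_ctrl - .data$ctrl_ct)),
           qc_flags = ifelse(.data$ctrl_fail & .data$qc_flags == "",
                             "CONTROL_QC_FAIL",
                             ifelse(.data$ctrl_fail,
                                    paste0(.data$qc_flags, ";CONTROL_QC_FAIL"),
                                    .data$qc_flags)),
           qc_pass = .data$qc_pass & !.data$ctrl_fail) |>
    select("sample_id", "gene_id", "ratio", "is_frequent_gene",
           "qc_pass", "qc_flags")
}

#' Per-gene aberrancy thresholds from normal qPCR samples
#'
#' The aberrant-expression threshold of a gene is the mean plus two
#' standard deviations of its testis-relative ratio across the normal
#' reference samples (seven normal bone marrows and three cord bloods in
#' the assay's design). A gene is considered positively expressed when its
#' ratio lies strictly above this threshold.
#'
#' @param rel Relative-expression tibble from [relative_expression()].
#' @param normal_samples Sample ids of the normal reference samples; each
#'   gene needs at least two QC-passing normal measurements.
#' @param k SD multiplier (default 2 for qPCR).
#' @return A threshold tibble compatible with [binarize_expression()]:
#'   `gene_id`, `ref_mean`, `ref_sd`, `k`, `threshold`, `n_ref`.
#' @export
qpcr_thresholds <- function(rel, normal_samples, k = 2) {
  norm <- rel |>
    filter(.data$sample_id %in% normal_samples, .data$qc_pass)
  if (nrow(norm) == 0) abort("no QC-passing normal samples found")
  out <- norm |>
    group_by(.data$gene_id) |>
    summarise(ref_mean = mean(.data$ratio), ref_sd = sd(.data$ratio),
              n_ref = n(), .groups = "drop")
  low <- out |> filter(.data$n_ref < 2)
  if (nrow(low)) {
    abort(paste0("gene(s) with fewer than two normal measurements: ",
                 paste(low$gene_id, collapse = ", ")))
  }
  out |>
    mutate(k = k, threshold = .data$ref_mean + k * .data$ref_sd) |>
    select("gene_id", "ref_mean", "ref_sd", "k", "threshold", "n_ref")
}

#' Classify new patients from qPCR ratios with the six-gene algorithm
#'
#' Binarizes the testis-relative ratios at the qPCR aberrancy thresholds
#' and applies the P1/P2/P3 classifier unchanged. Samples with a failed QC
#' measurement on any signature gene are not classified (`klass = NA`,
#' quality note `QC_FAIL`). When no prognostic gene is expressed, the
#' quality note reports whether any of the frequently-activated control
#' genes is expressed, to help judge sample quality: `LOW_CONFIDENCE` when
#' none is, `NO_PROGNOSTIC_FREQUENT_DETECTED` when at least one is.
#'
#' @param rel Relative-expression tibble from [relative_expression()].
#' @param thresholds Thresholds from [qpcr_thresholds()].
#' @param signature A [signature_genes()] object; all six genes must be
#'   measured.
#' @param frequent_genes Frequently-activated quality-control genes
#'   (default COX8C, DKFZp761D1918, RPL10L).
#' @return Prognosis assignments (`sample_id`, `npos`, `nneg`, `klass`,
#'   `group`) plus `n_frequent_expressed` and `quality_note`.
#' @export
classify_qpcr <- function(rel, thresholds, signature = reference_signature(),
                          frequent_genes = c("COX8C", "DKFZp761D1918", "RPL10L")) {
  sig <- as_signature(signature)
  sig_genes <- c(sig$positive, sig$negative)
  missing <- setdiff(sig_genes, unique(rel$gene_id))
  if (length(missing)) {
    abort(paste0("prognostic gene(s) not measured: ",
                 paste(missing, collapse = ", ")))
  }
  no_thr <- setdiff(intersect(c(sig_genes, frequent_genes), unique(rel$gene_id)),
                    thresholds$gene_id)
  if (length(no_thr)) {
    abort(paste0("gene(s) without a qPCR threshold: ",
                 paste(no_thr, collapse = ", ")))
  }
  d <- rel |>
    inner_join(thresholds[c("gene_id", "threshold")], by = "gene_id") |>
    mutate(expressed = .data$ratio > .data$threshold)

  per_sample <- d |>
    group_by(.data$sample_id) |>
    summarise(
      qc_ok = all(.data$qc_pass[.data$gene_id %in% sig_genes]) &&
        sum(.data$gene_id %in% sig_genes) == length(sig_genes),
      npos = sum(.data$expressed & .data$gene_id %in% sig$positive &
                   .data$qc_pass),
      nneg = sum(.data$expressed & .data$gene_id %in% sig$negative &
                   .data$qc_pass),
      n_frequent_expressed = sum(.data$expressed &
                                   .data$gene_id %in% frequent_genes &
                                   .data$qc_pass),
      .groups = "drop")

  per_sample |>
    mutate(
      klass = ifelse(!.data$qc_ok, NA_character_,
                     ifelse(.data$nneg >= 1 & .data$npos <= 1, "P3",
                            ifelse(.data$nneg == 0 & .data$npos >= 2, "P1", "P2"))),
      klass = factor(.data$klass, levels = c("P1", "P2", "P3")),
      group = factor(ifelse(is.na(.data$klass), NA_character_,
                            ifelse(.data$klass == "P3", "P3", "P1&2")),
                     levels = c("P1&2", "P3")),
      quality_note = ifelse(!.data$qc_ok, "QC_FAIL",
                            ifelse(.data$npos + .data$nneg > 0, "OK",
                                   ifelse(.data$n_frequent_expressed > 0,
                                          "NO_PROGNOSTIC_FREQUENT_DETECTED",
                                          "LOW_CONFIDENCE"))),
      npos = as.integer(.data$npos), nneg = as.integer(.data$nneg),
      n_frequent_expressed = as.integer(.data$n_frequent_expressed)) |>
    select("sample_id", "npos", "nneg", "klass", "group",
           "n_frequent_expressed", "quality_note")
}
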