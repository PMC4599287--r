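# small in-code fixtures shared across test files

# a tiny hand-built compendium: 4 genes x (2 germline, 2 es, 2 placenta,
# 4 somatic, 3 marrow) with known structure
tiny_compendium <- function() {
  samples <- c("g1", "g2", "e1", "e2", "p1", "p2",
               "s1", "s2", "s3", "s4", "b1", "b2", "b3")
  group <- c("germline", "germline", "es", "es", "placenta", "placenta",
             rep("somatic", 4), rep("bm_nonleukemic", 3))
  m <- rbind(
    flat    = rep(5, 13),                                   # constant everywhere
    germ    = c(9, 9, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),     # germline-predominant, marrow silent
    germ_bm = c(9, 9, 5, 5, 5, 5, 5, 5, 5, 5, 9, 5, 5),     # germline-predominant, marrow expressed
    plac    = c(5, 5, 5, 5, 8, 7, 5, 5, 5, 5, 5, 5, 5)      # placenta-predominant
  )
  colnames(m) <- samples
  list(expression = prognosix:::matrix_to_tbl(m),
       annotation = tibble::tibble(sample_id = samples, group = group))
}

# calls tibble from a named logical matrix
calls_tbl <- function(m) prognosix:::matrix_to_tbl(m)

# a deterministic two-group survival table: expressers of "gx" die fast
toy_survival <- function(n = 20, fast = 1, slow = 10) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    time = rep(c(fast, slow), each = n / 2),
    event = TRUE
  )
}

# exact Ct table for planted testis-relative ratios (no noise, shared
# per-sample offset cancelled by the controls)
exact_ct_table <- function(ratios, offsets = NULL,
                           control_genes = c("ACTB", "U6", "RELA", "AUP1")) {
  genes <- rownames(ratios)
  samples <- colnames(ratios)
  offsets <- offsets %||% stats::setNames(seq_along(samples) * 0.5, samples)
  testis_ct <- stats::setNames(25 + seq_along(genes), genes)
  ctrl_ct <- stats::setNames(c(20, 21, 22, 23), control_genes)
  rows <- list(
    tibble::tibble(sample_id = "testis",
                   gene_id = c(genes, control_genes),
                   ct = c(testis_ct, ctrl_ct))
  )
  for (s in samples) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample_id = s,
      gene_id = c(genes, control_genes),
      ct = c(testis_ct - log2(ratios[, s]) + offsets[[s]],
             ctrl_ct + offsets[[s]])
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(ct_dup1 = ct + 0.1, ct_dup2 = ct - 0.1,
                  ct_noRT = 38,
                  role = ifelse(gene_id %in% control_genes, "control", "target")) |>
    dplyr::select(-ct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
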