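test_that("QC gates fire exactly at their boundaries", {
  rec <- tibble::tibble(
    sample_id = "s1",
    gene_id = c("A", "B", "C", "D"),
    ct_dup1 = c(30.0, 30.0, 30.0, 30.0),
    ct_dup2 = c(30.0, 30.6, 30.49, 29.5),
    ct_noRT = c(36.0, 38, 35.99, 38),
    role = "target"
  )
  out <- qc_ct(rec)
  # no-RT exactly 36 is satisfactory; 35.99 is contamination
  expect_false(grepl("NO_RT", out$qc_flags[1]))
  expect_true(grepl("NO_RT_CONTAMINATION", out$qc_flags[3]))
  # duplicates 0.6 and exactly 0.5 apart flag; 0.49 does not
  expect_true(grepl("DUPLICATE_SPREAD", out$qc_flags[2]))
  expect_true(grepl("DUPLICATE_SPREAD", out$qc_flags[4]))
  expect_false(grepl("DUPLICATE_SPREAD", out$qc_flags[3]))
  expect_identical(out$qc_pass, !nzchar(out$qc_flags))
})

test_that("unstable control genes are flagged by their cross-sample CV", {
  rec <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("s%d", 1:6), gene_id = "ACTB",
                   ct_dup1 = c(20, 30, 20, 31, 19, 30),
                   ct_dup2 = c(20, 30, 20, 31, 19, 30),
                   ct_noRT = 38, role = "control"),
    tibble::tibble(sample_id = sprintf("s%d", 1:6), gene_id = "U6",
                   ct_dup1 = c(20, 20.2, 20.1, 19.9, 20, 20.1),
                   ct_dup2 = c(20, 20.2, 20.1, 19.9, 20, 20.1),
                   ct_noRT = 38, role = "control")
  )
  out <- qc_ct(rec)
  expect_true(all(grepl("CONTROL_UNSTABLE",
                        out$qc_flags[out$gene_id == "ACTB"])))
  expect_false(any(grepl("CONTROL_UNSTABLE",
                         out$qc_flags[out$gene_id == "U6"])))
})

test_that("the ratio formula is the printed identity, sign convention included", {
  # sample Cts equal testis Cts everywhere -> ratio 1
  r1 <- matrix(1, 2, 1, dimnames = list(c("CAMSAP1", "STARD4"), "s1"))
  rec <- exact_ct_table(r1, offsets = c(s1 = 0))
  rel <- relative_expression(qc_ct(rec))
  expect_equal(rel$ratio, c(1, 1), tolerance = 1e-12)

  # gene Ct one cycle LOWER in testis than in the sample, controls equal:
  # exponent (testis - sample) = -1 -> ratio 0.5
  rec2 <- rec
  rec2 <- dplyr::mutate(rec2,
    ct_dup1 = ifelse(sample_id == "s1" & gene_id == "CAMSAP1", ct_dup1 + 1, ct_dup1),
    ct_dup2 = ifelse(sample_id == "s1" & gene_id == "CAMSAP1", ct_dup2 + 1, ct_dup2))
  rel2 <- relative_expression(qc_ct(rec2))
  expect_equal(rel2$ratio[rel2$gene_id == "CAMSAP1"], 0.5, tolerance = 1e-12)
  # and a cycle lower in the sample (more template) doubles the ratio
  rec3 <- dplyr::mutate(rec,
    ct_dup1 = ifelse(sample_id == "s1" & gene_id == "STARD4", ct_dup1 - 1, ct_dup1),
    ct_dup2 = ifelse(sample_id == "s1" & gene_id == "STARD4", ct_dup2 - 1, ct_dup2))
  rel3 <- relative_expression(qc_ct(rec3))
  expect_equal(rel3$ratio[rel3$gene_id == "STARD4"], 2, tolerance = 1e-12)
})

test_that("planted ratios round-trip exactly through Ct space", {
  ratios <- matrix(c(0.5, 1, 2, 8,
                     8, 2, 1, 0.5), 4,
                   dimnames = list(c("CAMSAP1", "PCGF6", "SH3RF3", "STARD4"),
                                   c("s1", "s2")))
  rec <- exact_ct_table(ratios)
  rel <- relative_expression(qc_ct(rec))
  got <- rel |> dplyr::mutate(planted = ratios[cbind(gene_id, sample_id)])
  expect_equal(got$ratio, got$planted, tolerance = 1e-12)

  # normalization contract: a constant added to every Ct of a sample cancels
  rec_shift <- dplyr::mutate(rec,
    ct_dup1 = ifelse(sample_id == "s1", ct_dup1 + 3.3, ct_dup1),
    ct_dup2 = ifelse(sample_id == "s1", ct_dup2 + 3.3, ct_dup2))
  rel_shift <- relative_expression(qc_ct(rec_shift))
  expect_equal(rel_shift$ratio, rel$ratio, tolerance = 1e-12)
})

test_that("missing control genes are named in the error", {
  ratios <- matrix(1, 1, 1, dimnames = list("CAMSAP1", "s1"))
  rec <- exact_ct_table(ratios) |> dplyr::filter(gene_id != "RELA")
  expect_error(relative_expression(qc_ct(rec)), "RELA")
})

test_that("qPCR thresholds are mean + 2 SD with degenerate cases handled", {
  rel <- tibble::tibble(
    sample_id = rep(sprintf("n%d", 1:4), 2),
    gene_id = rep(c("g_zero", "g_one"), each = 4),
    ratio = c(0, 0, 0, 0, 1, 1, 1, 1),
    is_frequent_gene = FALSE, qc_pass = TRUE, qc_flags = ""
  )
  thr <- qpcr_thresholds(rel, sprintf("n%d", 1:4))
  expect_equal(thr$threshold[thr$gene_id == "g_zero"], 0)  # any positive ratio is aberrant
  expect_equal(thr$threshold[thr$gene_id == "g_one"], 1)   # SD 0
  expect_error(qpcr_thresholds(rel[1, ], "n1"), "fewer than two")
})

test_that("qPCR classification equals the array classifier on all 64 patterns", {
  sig <- reference_signature()
  genes <- c(sig$positive, sig$negative)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(grid) <- genes
  thr <- tibble::tibble(gene_id = c(genes, "COX8C"),
                        threshold = 0.05)
  rel <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    tibble::tibble(sample_id = sprintf("pat%02d", i),
                   gene_id = c(genes, "COX8C"),
                   ratio = c(ifelse(unlist(grid[i, ]), 1, 0.001), 0.001),
                   is_frequent_gene = c(rep(FALSE, 6), TRUE),
                   qc_pass = TRUE, qc_flags = "")
  })
  got <- classify_qpcr(rel, thr, sig)
  m <- t(as.matrix(grid))
  colnames(m) <- sprintf("pat%02d", seq_len(ncol(m)))
  want <- assign_prognosis(calls_tbl(m), sig)
  got <- got[match(want$sample_id, got$sample_id), ]
  expect_identical(as.character(got$klass), as.character(want$klass))
  expect_identical(as.character(got$group), as.character(want$group))
})

test_that("classification quality notes track the frequent control genes", {
  sig <- reference_signature()
  genes <- c(sig$positive, sig$negative)
  thr <- tibble::tibble(gene_id = c(genes, "COX8C", "RPL10L"), threshold = 0.05)
  base <- tibble::tibble(gene_id = c(genes, "COX8C", "RPL10L"),
                         ratio = 0.001,
                         is_frequent_gene = c(rep(FALSE, 6), TRUE, TRUE),
                         qc_pass = TRUE, qc_flags = "")
  # nothing expressed anywhere -> P2 with LOW_CONFIDENCE
  r1 <- dplyr::mutate(base, sample_id = "s1", .before = 1)
  g1 <- classify_qpcr(r1, thr, sig)
  expect_equal(as.character(g1$klass), "P2")
  expect_equal(g1$quality_note, "LOW_CONFIDENCE")
  # no prognostic gene but a frequent gene detected -> quality reassured
  r2 <- dplyr::mutate(r1, ratio = ifelse(gene_id == "COX8C", 1, ratio))
  g2 <- classify_qpcr(r2, thr, sig)
  expect_equal(as.character(g2$klass), "P2")
  expect_equal(g2$quality_note, "NO_PROGNOSTIC_FREQUENT_DETECTED")
  # two positive genes -> P1; one of each -> P3
  r3 <- dplyr::mutate(r1, ratio = ifelse(gene_id %in% c("CAMSAP1", "PCGF6"), 1, ratio))
  expect_equal(as.character(classify_qpcr(r3, thr, sig)$klass), "P1")
  r4 <- dplyr::mutate(r1, ratio = ifelse(gene_id %in% c("CAMSAP1", "STARD4"), 1, ratio))
  expect_equal(as.character(classify_qpcr(r4, thr, sig)$klass), "P3")
  # QC failure on a prognostic gene blocks classification
  r5 <- dplyr::mutate(r1, qc_pass = ifelse(gene_id == "CAMSAP1", FALSE, qc_pass))
  g5 <- classify_qpcr(r5, thr, sig)
  expect_true(is.na(g5$klass))
  expect_equal(g5$quality_note, "QC_FAIL")
})

test_that("per-primer efficiency bases of exactly 2 reduce to the printed formula", {
  ratios <- matrix(c(0.5, 2), 2, 1,
                   dimnames = list(c("CAMSAP1", "STARD4"), "s1"))
  rec <- qc_ct(exact_ct_table(ratios))
  plain <- relative_expression(rec)
  eff2 <- relative_expression(rec, efficiency = c(CAMSAP1 = 2, STARD4 = 2))
  expect_equal(eff2$ratio, plain$ratio, tolerance = 1e-12)
  # a higher efficiency base changes the ratio monotonically
  eff_hi <- relative_expression(rec, efficiency = c(CAMSAP1 = 2.1, STARD4 = 2.1))
  expect_false(isTRUE(all.equal(eff_hi$ratio, plain$ratio)))
})
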