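mk_assign <- function(ids_p3, ids_p12) {
  tibble::tibble(
    sample_id = c(ids_p3, ids_p12),
    npos = 0L, nneg = 0L,
    klass = factor(rep(c("P3", "P2"), c(length(ids_p3), length(ids_p12))),
                   levels = c("P1", "P2", "P3")),
    group = factor(rep(c("P3", "P1&2"), c(length(ids_p3), length(ids_p12))),
                   levels = c("P1&2", "P3"))
  )
}

test_that("completely separated groups of 4 reproduce the exact enumeration p-value", {
  m <- matrix(c(10, 11, 12, 13, 1, 2, 3, 4), 1,
              dimnames = list("g1", sprintf("s%d", 1:8)))
  a <- mk_assign(sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  de <- differential_expression(m, a, adjust = "none")
  # 2 of the choose(8,4) = 70 rank configurations are as extreme
  expect_equal(de$p_raw, 2 / 70)
  expect_equal(de$direction, "up_in_P3")
  expect_true(de$fold_change > 0)
})

test_that("label swap mirrors directions with identical p-values; adjustment is monotone", {
  set.seed(71)
  m <- matrix(rnorm(30 * 12, 5, 1), 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  m[1:5, 1:6] <- m[1:5, 1:6] + 2
  a <- mk_assign(sprintf("s%02d", 1:6), sprintf("s%02d", 7:12))
  a_swap <- mk_assign(sprintf("s%02d", 7:12), sprintf("s%02d", 1:6))
  d1 <- differential_expression(m, a)
  d2 <- differential_expression(m, a_swap)
  expect_equal(d1$p_raw, d2$p_raw, tolerance = 1e-12)
  up1 <- d1$gene_id[d1$direction == "up_in_P3"]
  expect_setequal(up1, d2$gene_id[d2$direction == "down_in_P3"])
  expect_true(all(d1$p_adjusted >= d1$p_raw))
  ord <- order(d1$p_raw)
  expect_true(all(diff(d1$p_adjusted[ord]) >= -1e-12))
})

test_that("constant genes are never significant", {
  m <- matrix(5, 2, 10,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:10)))
  m["g2", ] <- rnorm(10)
  a <- mk_assign(sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))
  de <- differential_expression(m, a)
  expect_equal(de$p_raw[de$gene_id == "g1"], 1)
  expect_false(de$significant[de$gene_id == "g1"])
})

test_that("a planted expression shift is recovered with high sensitivity", {
  set.seed(72)
  n_per <- 60
  n_genes <- 300
  m <- matrix(rnorm(n_genes * 2 * n_per, 5, 0.3), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(2 * n_per))))
  planted <- sprintf("g%03d", 1:100)
  m[planted, seq_len(n_per)] <- m[planted, seq_len(n_per)] + 0.6  # 2 * noise SD
  a <- mk_assign(sprintf("s%03d", seq_len(n_per)),
                 sprintf("s%03d", n_per + seq_len(n_per)))
  de <- differential_expression(m, a)
  sens <- mean(de$significant[de$gene_id %in% planted])
  expect_gte(sens, 0.9)
  fp <- mean(de$significant[!de$gene_id %in% planted])
  expect_lt(fp, 0.05)
})

test_that("P3-like detection flags centroid copies and respects the strict tie rule", {
  set.seed(73)
  genes <- sprintf("g%02d", 1:20)
  p3 <- matrix(rnorm(20 * 5, 8, 0.2), 20)
  p12 <- matrix(rnorm(20 * 5, 5, 0.2), 20)
  p3[1:10, ] <- p3[1:10, ] - 6   # give the signature a shape, not just a level
  m <- cbind(p3, p12)
  dimnames(m) <- list(genes, sprintf("s%02d", 1:10))
  a <- mk_assign(sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))

  # plant a P1&2 sample that copies the P3 centroid exactly
  m[, "s06"] <- rowMeans(m[, sprintf("s%02d", 1:5)])
  res <- detect_p3_like(m, a, genes)
  expect_true(res$p3_like[res$sample_id == "s06"])
  expect_false(any(res$p3_like[res$sample_id != "s06"]))

  # equidistant profile (identical centroids) is not flagged
  m2 <- m
  m2[, sprintf("s%02d", 1:5)] <- m2[, sprintf("s%02d", 6:10)]
  res2 <- detect_p3_like(m2, a, genes)
  expect_false(any(res2$p3_like &
                     abs(res2$cor_p3 - res2$cor_p12) < 1e-12))
})

test_that("P1&2 samples generated from the P3 model are flagged P3-like", {
  # the two prognosis groups have distinct signature shapes (that is what the
  # differential-expression genes encode); a handful of P1&2-labelled samples
  # are drawn from the P3 expression model and must be recovered
  set.seed(74)
  genes <- sprintf("g%02d", 1:40)
  shape_p3 <- rnorm(40, 0, 2)
  shape_p12 <- rnorm(40, 0, 2)
  draw <- function(n, shape) matrix(rnorm(40 * n, 5, 0.3), 40) + shape
  m <- cbind(draw(10, shape_p3), draw(30, shape_p12), draw(6, shape_p3))
  dimnames(m) <- list(genes, sprintf("s%02d", 1:46))
  a <- mk_assign(sprintf("s%02d", 1:10), sprintf("s%02d", 11:46))
  res <- detect_p3_like(m, a, genes)
  planted <- sprintf("s%02d", 41:46)  # P1&2 labels, P3 expression model
  expect_gte(mean(res$p3_like[res$sample_id %in% planted]), 0.9)
  expect_lte(mean(res$p3_like[!res$sample_id %in% planted]), 0.1)
})

test_that("the whole-universe gene set has score 0 and p 1", {
  set.seed(75)
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                           weight = sort(rnorm(200), decreasing = TRUE))
  res <- wks_enrichment(ranked, list(all = ranked$gene_id), n_perm = 50)
  expect_equal(res$es, 0)
  expect_equal(res$p_value, 1)
})

test_that("WKS p-values are invariant to positive weight rescaling", {
  set.seed(76)
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                           weight = sort(rnorm(300, 0, 2), decreasing = TRUE))
  sets <- list(s1 = sample(ranked$gene_id, 30),
               s2 = sample(ranked$gene_id, 50))
  r1 <- wks_enrichment(ranked, sets, n_perm = 200, seed = 9)
  ranked2 <- dplyr::mutate(ranked, weight = weight * 13.7)
  r2 <- wks_enrichment(ranked2, sets, n_perm = 200, seed = 9)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$es, r2$es, tolerance = 1e-12)
})

test_that("a set occupying the top ranks attains the permutation minimum p", {
  ranked <- tibble::tibble(gene_id = sprintf("g%04d", 1:5000),
                           weight = sort(abs(rnorm(5000)) + 0.1,
                                         decreasing = TRUE))
  res <- wks_enrichment(ranked, list(top = ranked$gene_id[1:50]),
                        n_perm = 200, seed = 10)
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$direction, "top")
})

test_that("undersized gene sets are skipped with a warning", {
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                           weight = 50:1)
  expect_warning(
    res <- wks_enrichment(ranked, list(tiny = c("g001", "zzz")), n_perm = 20),
    "skipped"
  )
  expect_equal(nrow(res), 0)
})

test_that("the pre-ranked list orders the universe by decreasing fold change", {
  de <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       u_statistic = 0, p_raw = 1, p_adjusted = 1,
                       fold_change = c(0.5, -1, 2, 0.5),
                       direction = "up_in_P3", significant = FALSE)
  r <- rank_by_fold_change(de)
  expect_equal(r$gene_id, c("c", "a", "d", "b"))  # tie a/d broken by id
  expect_equal(r$weight, c(2, 0.5, 0.5, -1))
})
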