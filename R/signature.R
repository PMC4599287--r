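#' Mann-Whitney differential expression between P3 and P1&2
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per gene between the P3
#' and the P1&2 patients, with configurable multiple-testing adjustment
#' (Benjamini-Hochberg by default; `adjust = "none"` reproduces raw-p
#' thresholding). The fold change is the mean log-expression difference
#' (P3 minus P1&2) and fixes the direction label. A gene constant across
#' all patients gets p = 1 and is never significant.
#'
#' @param expr Expression tibble/matrix (genes x patients, log scale).
#' @param assignments Prognosis assignments from [assign_prognosis()]; both
#'   groups need at least 3 patients.
#' @param alpha Significance bar on the adjusted p-value (default 0.01).
#' @param adjust Adjustment method passed to [stats::p.adjust()]; `"BH"`
#'   default, `"none"` disables adjustment.
#' @return A tibble per gene: `gene_id`, `u_statistic`, `p_raw`,
#'   `p_adjusted`, `fold_change`, `direction` (`up_in_P3` / `down_in_P3`),
#'   `significant`.
#' @export
differential_expression <- function(expr, assignments, alpha = 0.01,
                                    adjust = "BH") {
  m <- expr_to_matrix(expr)
  a <- assignments[match(colnames(m), assignments$sample_id), ]
  if (anyNA(a$sample_id)) {
    abort("every expression sample must have a prognosis assignment")
  }
  in_p3 <- a$group == "P3"
  if (sum(in_p3) < 3 || sum(!in_p3) < 3) {
    abort("both prognosis groups need at least 3 patients")
  }
  res <- apply(m, 1, function(x) {
    if (all(x == x[1])) {
      return(c(u = length(x[in_p3]) * length(x[!in_p3]) / 2, p = 1))
    }
    wt <- suppressWarnings(wilcox.test(x[in_p3], x[!in_p3]))
    c(u = unname(wt$statistic), p = wt$p.value)
  })
  fc <- unname(rowMeans(m[, in_p3, drop = FALSE]) -
                 rowMeans(m[, !in_p3, drop = FALSE]))
  p_raw <- res["p", ]
  p_adj <- p.adjust(p_raw, method = adjust)
  tibble(gene_id = rownames(m),
         u_statistic = unname(res["u", ]),
         p_raw = unname(p_raw), p_adjusted = unname(p_adj),
         fold_change = unname(fc),
         direction = ifelse(fc > 0, "up_in_P3",
                            ifelse(fc < 0, "down_in_P3", NA_character_)),
         significant = p_adj < alpha)
}

#' Rank the gene universe by fold change for pre-ranked enrichment
#'
#' @param de Differential-expression table from
#'   [differential_expression()] covering the whole gene universe.
#' @return A tibble `gene_id`, `weight` ordered by decreasing fold change
#'   (ties broken by gene id).
#' @export
rank_by_fold_change <- function(de) {
  de |>
    arrange(desc(.data$fold_change), .data$gene_id) |>
    transmute(gene_id = .data$gene_id, weight = .data$fold_change)
}

#' Flag P1&2 patients whose expression profile resembles the P3 centroid
#'
#' Algorithmic surrogate for the heatmap-based call of a "P3-like"
#' subgroup: over the differential-expression signature genes, a P1&2
#' patient is flagged P3-like when the Pearson correlation of its profile
#' with the P3 centroid strictly exceeds the correlation with the P1&2
#' centroid. A patient equidistant from both centroids is not flagged.
#'
#' @param expr Expression tibble/matrix (genes x patients).
#' @param assignments Prognosis assignments (both groups need >= 2
#'   patients).
#' @param de_genes Signature gene ids, or a [differential_expression()]
#'   table (its significant genes are used). Must be non-empty.
#' @return A tibble over the P1&2 patients: `sample_id`, `cor_p3`,
#'   `cor_p12`, `p3_like`.
#' @export
detect_p3_like <- function(expr, assignments, de_genes) {
  if (is.data.frame(de_genes) && "significant" %in% names(de_genes)) {
    de_genes <- de_genes$gene_id[de_genes$significant]
  }
  de_genes <- as.character(de_genes)
  if (length(de_genes) == 0) abort("the differential-expression signature is empty")
  m <- expr_to_matrix(expr)
  missing <- setdiff(de_genes, rownames(m))
  if (length(missing)) {
    abort(paste0("signature gene(s) absent from expression: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  a <- assignments[match(colnames(m), assignments$sample_id), ]
  in_p3 <- a$group == "P3"
  if (sum(in_p3) < 2 || sum(!in_p3) < 2) {
    abort("both prognosis groups need at least 2 patients")
  }
  sub <- m[de_genes, , drop = FALSE]
  c_p3 <- rowMeans(sub[, in_p3, drop = FALSE])
  c_p12 <- rowMeans(sub[, !in_p3, drop = FALSE])
  p12_ids <- colnames(m)[!in_p3]
  cor_safe <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  cor_p3 <- vapply(p12_ids, function(s) cor_safe(sub[, s], c_p3), numeric(1))
  cor_p12 <- vapply(p12_ids, function(s) cor_safe(sub[, s], c_p12), numeric(1))
  tibble(sample_id = p12_ids, cor_p3 = unname(cor_p3),
         cor_p12 = unname(cor_p12),
         p3_like = !is.na(cor_p3) & !is.na(cor_p12) & cor_p3 > cor_p12)
}

# centered cumulated-weight enrichment statistic: running sum of
# weight * (membership - m/N), rescaled by its Brownian-bridge-like scale
# so the statistic is invariant to positive rescaling of the weights
wks_stat_core <- function(w, member_idx) {
  N <- length(w)
  m <- length(member_idx)
  s <- numeric(N)
  s[member_idx] <- w[member_idx]
  drift <- (m / N) * cumsum(w)
  C <- cumsum(s) - drift
  scale <- sqrt(sum(w^2) * (m / N) * (1 - m / N))
  if (scale == 0) {
    return(list(es = 0, direction = "none"))
  }
  i <- which.max(abs(C))
  list(es = abs(C[i]) / scale,
       direction = if (C[i] >= 0) "top" else "bottom")
}

#' Weighted Kolmogorov-Smirnov gene-set enrichment on a pre-ranked list
#'
#' For each gene set, the enrichment score is the supremum of the centered,
#' rescaled cumulated-weight function over the ranked list: the running sum
#' of `weight * (membership indicator - set_size/universe_size)`, divided
#' by a scale factor that makes the score invariant to positive rescaling
#' of the weights. Significance comes from a gene-label permutation null
#' (`n_perm` uniform redraws of the set members over the ranked universe):
#' `p = (1 + #{permutation score >= observed}) / (n_perm + 1)`, so the same
#' seed yields identical p-values and the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' @param ranked Ranked tibble `gene_id`, `weight` from
#'   [rank_by_fold_change()] (re-sorted defensively by decreasing weight).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size Minimum overlap of a set with the ranked universe; sets
#'   below it are skipped with a warning (default 5).
#' @param seed Optional seed fixed at entry for reproducible p-values.
#' @return A tibble per retained set: `gene_set_id`, `size`, `es`,
#'   `direction` (`top` = enriched among high weights), `p_value`.
#' @export
wks_enrichment <- function(ranked, gene_sets, n_perm = 1000, min_size = 5,
                           seed = NULL) {
  if (!all(c("gene_id", "weight") %in% names(ranked))) {
    abort("'ranked' must have columns 'gene_id' and 'weight'")
  }
  if (!is.null(seed)) set.seed(seed)
  ranked <- arrange(ranked, desc(.data$weight), .data$gene_id)
  ids <- ranked$gene_id
  w <- ranked$weight
  N <- length(ids)
  drift_base <- cumsum(w)
  sum_w2 <- sum(w^2)

  rows <- imap(gene_sets, function(genes, set_id) {
    member_idx <- which(ids %in% genes)
    m <- length(member_idx)
    if (m < min_size) {
      warn(paste0("gene set '", set_id, "' overlaps the universe in ", m,
                  " gene(s) (< ", min_size, "); skipped"))
      return(NULL)
    }
    obs <- wks_stat_core(w, member_idx)
    if (obs$direction == "none") {
      return(tibble(gene_set_id = set_id, size = m, es = 0,
                    direction = "none", p_value = 1))
    }
    frac <- m / N
    drift <- frac * drift_base
    scale <- sqrt(sum_w2 * frac * (1 - frac))
    x <- numeric(N)
    perm <- vapply(seq_len(n_perm), function(b) {
      sel <- sample.int(N, m)
      x[sel] <<- w[sel]
      stat <- max(abs(cumsum(x) - drift)) / scale
      x[sel] <<- 0
      stat
    }, numeric(1))
    tibble(gene_set_id = set_id, size = m, es = obs$es,
           direction = obs$direction,
           p_value = (1 + sum(perm >= obs$es)) / (n_perm + 1))
  })
  bind_rows(rows)
}
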