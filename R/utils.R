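# shared internal helpers

# expression / call tables travel as tibbles whose first column is the gene id
# and whose remaining columns are samples; these convert to and from matrices.

expr_to_matrix <- function(x, id_col = "gene_id", what = "expression") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(paste0(what, " matrix must have gene ids as rownames"))
    }
    m <- x
  } else {
    if (!is.data.frame(x)) abort(paste0(what, " table must be a data frame or matrix"))
    if (!id_col %in% names(x)) {
      abort(paste0(what, " table must carry a '", id_col, "' column"))
    }
    ids <- as.character(x[[id_col]])
    m <- as.matrix(x[setdiff(names(x), id_col)])
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) abort(paste0(what, " gene ids must be unique"))
  if (anyNA(m)) abort(paste0(what, " values must not contain missing entries"))
  m
}

matrix_to_tbl <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, rownames = id_col)
  out
}

# sample standard deviation per row (n - 1 denominator)
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2) abort("at least two columns are required to compute a standard deviation")
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

row_maxs <- function(m) {
  if (ncol(m) == 1L) return(as.numeric(m[, 1L]))
  do.call(pmax, as.data.frame(m))
}

# deterministic sub-stream seeds derived from one user-facing integer seed;
# kept below 2^31 - 1 so set.seed() accepts them
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 2654435) %% 2147483629)
}

# nearest-integer percentage, conventional rounding (round-half-up)
pct_round <- function(n, total) {
  as.integer(floor(100 * n / total + 0.5))
}

tissue_group_levels <- function() {
  c("germline", "es", "placenta", "somatic", "bm_nonleukemic")
}

predominance_group_levels <- function() {
  c("germline", "es", "placenta", "somatic")
}

validate_annotation <- function(annotation, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(annotation))) {
    abort("annotation must have columns 'sample_id' and 'group'")
  }
  ann <- as_tibble(annotation)
  if (anyDuplicated(ann$sample_id)) {
    abort("each sample must be annotated exactly once")
  }
  bad_group <- setdiff(unique(ann$group), tissue_group_levels())
  if (length(bad_group)) {
    abort(paste0("unknown tissue group(s): ", paste(bad_group, collapse = ", ")))
  }
  missing <- setdiff(sample_ids, ann$sample_id)
  if (length(missing)) {
    abort(paste0("samples without annotation: ", paste(head(missing, 5), collapse = ", ")))
  }
  ann[match(sample_ids, ann$sample_id), ]
}

# align a calls/expression table with a survival table; errors on mismatches
align_samples <- function(m, surv) {
  if (!all(c("sample_id", "time", "event") %in% names(surv))) {
    abort("survival table must have columns 'sample_id', 'time', 'event'")
  }
  extra <- setdiff(colnames(m), surv$sample_id)
  missing <- setdiff(surv$sample_id, colnames(m))
  if (length(extra) || length(missing)) {
    abort(paste0(
      "sample ids do not match between calls and survival table; ",
      "unmatched: ", paste(head(c(extra, missing), 5), collapse = ", ")
    ))
  }
  m[, surv$sample_id, drop = FALSE]
}
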