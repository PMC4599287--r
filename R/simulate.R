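#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter of the simulated study: a multi-tissue expression
#' compendium with a planted fraction of germline/ES/placenta-predominant
#' genes, tumor cohorts in which a subset of the normally silent genes is
#' aberrantly activated in a fraction of patients, proportional-hazards
#' survival times in which activation of designated genes multiplies the
#' hazard, and RT-qPCR Ct tables consistent with the testis-relative ratio
#' formula.
#'
#' Defaults mirror the study conditions the pipeline was designed around:
#' 112 normal somatic tissues and 74 non-leukemic bone marrows as reference
#' panels, two pediatric cohorts of 207 and 59 patients, hazard multipliers
#' of 2.5 (poor-prognosis genes) and 0.4 (favorable genes), an activation
#' frequency of 30%, and RMA-like log2 expression with SD 0.3 around a
#' baseline of 5.
#'
#' @param seed Integer seed; every sub-stream (compendium, cohorts, Ct
#'   tables) is derived deterministically from it, so identical
#'   configurations reproduce identical outputs.
#' @param n_genes Number of genes in the simulated universe.
#' @param frac_predominant Fraction of genes planted as predominantly
#'   expressed in germline/ES/placenta.
#' @param frac_bm_expressed Fraction of the planted predominant genes that
#'   also express in non-leukemic bone marrow (and are therefore removed by
#'   the marrow-silence filter).
#' @param tissue_groups Named counts of compendium samples per tissue group
#'   (`germline`, `es`, `placenta`, `somatic`, `bm_nonleukemic`).
#' @param cohort_sizes Named integer vector of tumor cohort sizes.
#' @param frac_activated Fraction of the marrow-silent predominant genes that
#'   are aberrantly activated in the tumor cohorts.
#' @param activation_freq Per-gene Bernoulli probability that a patient's
#'   blasts activate an activated gene.
#' @param n_positive,n_negative Numbers of planted prognostic genes whose
#'   activation multiplies the hazard by `hr_positive` (< 1, favorable) and
#'   `hr_negative` (> 1, adverse).
#' @param hr_positive,hr_negative Hazard multipliers for the planted
#'   prognostic genes.
#' @param baseline_hazard Baseline event rate per time unit (months).
#' @param censor_rate Rate of the independent exponential censoring process;
#'   0 disables censoring.
#' @param noise_sd Log2-expression standard deviation.
#' @param activation_shift Log2-expression increment of an active call; must
#'   exceed `3 * noise_sd` or planting would be undetectable by construction.
#' @param baseline_expr Baseline log2 expression level.
#' @param threshold_k SD multiplier of the activation threshold the
#'   generator guarantees its planted truth against (3, as for arrays).
#' @param covariate_freqs Named Bernoulli frequencies for the simulated
#'   clinical covariates, drawn independently of the planted genes.
#' @param n_qpcr_patients,n_qpcr_normals Sample counts for the simulated Ct
#'   tables (normals = 7 bone marrows + 3 cord bloods by default).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_bundle()], [simulate_compendium()],
#'   [simulate_cohort()], [simulate_ct_table()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 600L,
                       frac_predominant = 0.2,
                       frac_bm_expressed = 0.1,
                       tissue_groups = c(germline = 12L, es = 6L, placenta = 10L,
                                         somatic = 112L, bm_nonleukemic = 74L),
                       cohort_sizes = c(learning = 207L, validation = 59L),
                       frac_activated = 0.3,
                       activation_freq = 0.3,
                       n_positive = 3L,
                       n_negative = 3L,
                       hr_positive = 0.4,
                       hr_negative = 2.5,
                       baseline_hazard = 0.01,
                       censor_rate = 0.002,
                       noise_sd = 0.3,
                       activation_shift = 4,
                       baseline_expr = 5,
                       threshold_k = 3,
                       covariate_freqs = c(MLL = 0.05, BCR_ABL = 0.03,
                                           CRLF2_high = 0.23, MRD_d29 = 0.30,
                                           IKZF1_mutdel = 0.29, age_ge10 = 0.50,
                                           WBC_ge50 = 0.40, CNS = 0.10,
                                           male = 0.55),
                       n_qpcr_patients = 20L,
                       n_qpcr_normals = 10L) {
  frac_in_01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("'", nm, "' must be a fraction in [0, 1]"))
    }
  }
  frac_in_01(frac_predominant, "frac_predominant")
  frac_in_01(frac_bm_expressed, "frac_bm_expressed")
  frac_in_01(frac_activated, "frac_activated")
  frac_in_01(activation_freq, "activation_freq")
  if (n_genes < 1) abort("'n_genes' must be positive")
  if (any(tissue_groups < 0) ||
      !all(tissue_group_levels() %in% names(tissue_groups))) {
    abort("'tissue_groups' must name non-negative counts for germline, es, placenta, somatic, bm_nonleukemic")
  }
  if (any(cohort_sizes < 1)) abort("cohort sizes must be positive")
  if (n_positive > 0 && !(hr_positive > 0 && hr_positive < 1)) {
    abort("'hr_positive' must lie in (0, 1) when positive genes are planted")
  }
  if (n_negative > 0 && !(hr_negative > 1)) {
    abort("'hr_negative' must exceed 1 when negative genes are planted")
  }
  if (baseline_hazard <= 0) abort("'baseline_hazard' must be positive")
  if (censor_rate < 0) abort("'censor_rate' must be non-negative")
  if (noise_sd <= 0) abort("'noise_sd' must be positive")
  if (is.null(names(cohort_sizes))) {
    names(cohort_sizes) <- paste0("cohort", seq_along(cohort_sizes))
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         frac_predominant = frac_predominant,
         frac_bm_expressed = frac_bm_expressed,
         tissue_groups = tissue_groups,
         cohort_sizes = cohort_sizes,
         frac_activated = frac_activated,
         activation_freq = activation_freq,
         n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         hr_positive = hr_positive, hr_negative = hr_negative,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         noise_sd = noise_sd, activation_shift = activation_shift,
         baseline_expr = baseline_expr, threshold_k = threshold_k,
         covariate_freqs = covariate_freqs,
         n_qpcr_patients = as.integer(n_qpcr_patients),
         n_qpcr_normals = as.integer(n_qpcr_normals)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genes:", x$n_genes, "\n")
  cat("  tissue groups:",
      paste(names(x$tissue_groups), x$tissue_groups, sep = "=", collapse = " "), "\n")
  cat("  cohorts:",
      paste(names(x$cohort_sizes), x$cohort_sizes, sep = "=", collapse = " "), "\n")
  cat("  planted:", round(x$frac_predominant * x$n_genes), "predominant,",
      x$n_positive, "favorable +", x$n_negative, "adverse prognostic genes\n")
  invisible(x)
}

# truncated-normal draws below (or above) a per-row bound, via the quantile
# transform so every draw stays deterministic under the stream seed
rtrunc_below <- function(u, bound, mean, sd) {
  p <- pnorm(bound, mean, sd)
  qnorm(u * p, mean, sd)
}

rtrunc_above <- function(u, bound, mean, sd) {
  p <- pnorm(bound, mean, sd)
  qnorm(p + u * (1 - p), mean, sd)
}

#' Simulate a multi-tissue expression compendium with planted truth
#'
#' Draws an RMA-like log2 expression matrix over five tissue groups. A
#' planted subset of genes is predominantly expressed in a germline, ES or
#' placenta home group (baseline + `activation_shift`); all other values sit
#' at the common baseline. Per gene, the somatic panel defines the
#' activation threshold (somatic mean + `threshold_k` * SD) and every
#' non-somatic background value is truncated below that realized threshold,
#' so the planted truth is exact: predominance calls recover exactly the
#' planted set, and planted marrow-silent genes never exceed their threshold
#' in a non-leukemic marrow sample.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expression` (tibble, genes x samples), `annotation`
#'   (sample_id, group) and `truth` (planted predominant genes with home
#'   group and marrow status, the activated-gene roles, per-gene thresholds,
#'   and the planted six-gene signature when prognostic genes are planted).
#' @export
simulate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$activation_shift <= 3 * cfg$noise_sd) {
    abort(paste0(
      "activation_shift (", cfg$activation_shift, ") must exceed 3 * noise_sd (",
      3 * cfg$noise_sd, "): planted activation would be undetectable against ",
      "the mean + 3 SD threshold by construction"
    ))
  }
  if (cfg$tissue_groups[["somatic"]] < 2) {
    abort("at least two somatic samples are required (threshold SD undefined)")
  }
  set.seed(derive_seed(cfg$seed, 1L))

  sizes <- cfg$tissue_groups[tissue_group_levels()]
  group <- rep(names(sizes), times = sizes)
  sample_ids <- unlist(lapply(names(sizes), function(g) {
    sprintf("%s_%03d", g, seq_len(sizes[[g]]))
  }), use.names = FALSE)
  n_s <- length(sample_ids)
  n_g <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_g))
  mu0 <- cfg$baseline_expr
  sd0 <- cfg$noise_sd
  mu1 <- mu0 + cfg$activation_shift

  som <- which(group == "somatic")
  vals <- matrix(NA_real_, n_g, n_s, dimnames = list(gene_ids, sample_ids))
  vals[, som] <- rnorm(n_g * length(som), mu0, sd0)
  som_mean <- rowMeans(vals[, som, drop = FALSE])
  som_sd <- row_sds(vals[, som, drop = FALSE])
  thr <- som_mean + cfg$threshold_k * som_sd

  nons <- which(group != "somatic")
  u <- matrix(runif(n_g * length(nons)), n_g)
  vals[, nons] <- rtrunc_below(u, thr, mu0, sd0)

  n_pred <- round(cfg$frac_predominant * n_g)
  pred_genes <- character(0)
  home <- character(0)
  bm_expr <- logical(0)
  if (n_pred > 0) {
    pred_genes <- sort(sample(gene_ids, n_pred))
    home <- sample(c("germline", "es", "placenta"), n_pred, replace = TRUE)
    bm_expr <- rep(FALSE, n_pred)
    n_bm <- round(cfg$frac_bm_expressed * n_pred)
    if (n_bm > 0) bm_expr[sample.int(n_pred, n_bm)] <- TRUE
    for (i in seq_len(n_pred)) {
      gi <- match(pred_genes[i], gene_ids)
      cols <- which(group == home[i])
      vals[gi, cols] <- rtrunc_above(runif(length(cols)), thr[gi], mu1, sd0)
      if (bm_expr[i]) {
        bmc <- which(group == "bm_nonleukemic")
        vals[gi, bmc] <- rtrunc_above(runif(length(bmc)), thr[gi], mu1, sd0)
      }
    }
  }

  silent <- pred_genes[!bm_expr]
  n_act <- round(cfg$frac_activated * length(silent))
  activated <- if (n_act > 0) sort(sample(silent, n_act)) else character(0)
  role <- rep("null", length(activated))
  signature <- NULL
  n_prog <- cfg$n_positive + cfg$n_negative
  if (n_prog > 0 && length(activated) >= n_prog) {
    prog <- sample(activated, n_prog)
    pos <- sort(prog[seq_len(cfg$n_positive)])
    neg <- sort(prog[cfg$n_positive + seq_len(cfg$n_negative)])
    role[activated %in% pos] <- "positive"
    role[activated %in% neg] <- "negative"
    if (length(pos) && length(neg)) signature <- signature_genes(pos, neg)
  } else if (n_prog > 0 && length(activated) > 0) {
    warn("fewer activated genes than requested prognostic genes; none planted")
  }

  truth <- list(
    predominant = tibble(gene_id = pred_genes, home_group = home,
                         bm_expressed = bm_expr),
    activated = tibble(gene_id = activated, role = role),
    thresholds = tibble(gene_id = gene_ids, ref_mean = som_mean,
                        ref_sd = som_sd, k = cfg$threshold_k,
                        threshold = thr, n_ref = length(som)),
    signature = signature
  )
  list(expression = matrix_to_tbl(vals),
       annotation = tibble(sample_id = sample_ids, group = group),
       truth = truth)
}

#' Simulate a tumor cohort with survival times tied to planted genes
#'
#' Every activated gene switches on (baseline + `activation_shift`, above the
#' gene's threshold) in a Bernoulli(`activation_freq`) subset of patients and
#' stays at truncated background elsewhere, so binarization at the
#' compendium thresholds reproduces the planted activation mask exactly.
#' Survival times are exponential with hazard
#' `baseline_hazard * prod(hazard multipliers of the patient's active
#' planted prognostic genes)`, independently right-censored at
#' `censor_rate`. Clinical covariates are independent Bernoulli draws.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` component returned by [simulate_compendium()].
#' @param size Number of patients; defaults to `cfg$cohort_sizes[index]`.
#' @param cohort_id Label used to build sample ids.
#' @param index Cohort index (selects the seed sub-stream and default size).
#' @return A list with `expression`, `survival` (sample_id, time, event,
#'   covariates), `activation` (planted activation mask for the activated
#'   genes) and `cohort_id`.
#' @export
simulate_cohort <- function(cfg, truth, size = NULL, cohort_id = NULL,
                            index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  size <- size %||% unname(cfg$cohort_sizes[min(index, length(cfg$cohort_sizes))])
  cohort_id <- cohort_id %||%
    names(cfg$cohort_sizes)[min(index, length(cfg$cohort_sizes))]
  if (size < 10) {
    abort("cohort size must be at least 10: the survival screen is undefined below that")
  }
  sig <- truth$signature
  if (!is.null(sig) &&
      !all(c(sig$positive, sig$negative) %in% truth$activated$gene_id)) {
    abort("planted prognostic genes must be a subset of the planted activated genes")
  }
  set.seed(derive_seed(cfg$seed, 100L + index))

  thr_tbl <- truth$thresholds
  gene_ids <- thr_tbl$gene_id
  thr <- thr_tbl$threshold
  n_g <- length(gene_ids)
  mu0 <- cfg$baseline_expr
  sd0 <- cfg$noise_sd
  mu1 <- mu0 + cfg$activation_shift
  sample_ids <- sprintf("%s_p%03d", cohort_id, seq_len(size))

  u <- matrix(runif(n_g * size), n_g)
  vals <- rtrunc_below(u, thr, mu0, sd0)
  dimnames(vals) <- list(gene_ids, sample_ids)

  act <- truth$activated$gene_id
  mask <- matrix(FALSE, length(act), size, dimnames = list(act, sample_ids))
  if (length(act)) {
    mask[] <- runif(length(act) * size) < cfg$activation_freq
    on <- which(mask, arr.ind = TRUE)
    if (nrow(on)) {
      gi <- match(act[on[, 1]], gene_ids)
      vals[cbind(gi, on[, 2])] <-
        rtrunc_above(runif(nrow(on)), thr[gi], mu1, sd0)
    }
  }

  log_h <- rep(log(cfg$baseline_hazard), size)
  pos_genes <- truth$activated$gene_id[truth$activated$role == "positive"]
  neg_genes <- truth$activated$gene_id[truth$activated$role == "negative"]
  if (length(pos_genes)) {
    log_h <- log_h + colSums(mask[pos_genes, , drop = FALSE]) * log(cfg$hr_positive)
  }
  if (length(neg_genes)) {
    log_h <- log_h + colSums(mask[neg_genes, , drop = FALSE]) * log(cfg$hr_negative)
  }
  t_event <- rexp(size, exp(log_h))
  t_cens <- if (cfg$censor_rate > 0) rexp(size, cfg$censor_rate) else rep(Inf, size)
  surv <- tibble(sample_id = sample_ids,
                 time = pmin(t_event, t_cens),
                 event = t_event <= t_cens)
  for (nm in names(cfg$covariate_freqs)) {
    surv[[nm]] <- rbinom(size, 1L, cfg$covariate_freqs[[nm]])
  }

  list(expression = matrix_to_tbl(vals), survival = surv,
       activation = matrix_to_tbl(mask), cohort_id = cohort_id)
}

#' Simulate the full synthetic study bundle
#'
#' Runs [simulate_compendium()] once and [simulate_cohort()] for every entry
#' of `cfg$cohort_sizes`, under seed sub-streams derived from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `synthetic_bundle`: a list with `config`,
#'   `compendium`, `cohorts` (named list) and `truth`.
#' @export
simulate_bundle <- function(cfg) {
  comp <- simulate_compendium(cfg)
  cohorts <- imap(as.list(cfg$cohort_sizes), function(size, nm) {
    simulate_cohort(cfg, comp$truth, size = size, cohort_id = nm,
                    index = match(nm, names(cfg$cohort_sizes)))
  })
  structure(list(config = cfg, compendium = comp[c("expression", "annotation")],
                 cohorts = cohorts, truth = comp$truth),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat("  genes:", nrow(x$compendium$expression),
      " compendium samples:", ncol(x$compendium$expression) - 1L, "\n")
  cat("  cohorts:", paste(names(x$cohorts),
                          vapply(x$cohorts, function(co) nrow(co$survival), 0L),
                          sep = "=", collapse = " "), "\n")
  cat("  planted: ", nrow(x$truth$predominant), " predominant, ",
      nrow(x$truth$activated), " activated",
      if (!is.null(x$truth$signature)) ", six-gene signature planted" else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate an RT-qPCR Ct table consistent with the ratio formula
#'
#' Plants testis-relative expression ratios and converts them into duplicate
#' Ct values by exact algebraic inversion of the quantification formula
#' `2^(Ct_testis - Ct_sample) / 2^(mean ctrl Ct_testis - mean ctrl
#' Ct_sample)`: each sample receives a global Ct offset (normalization) that
#' cancels through the four control genes, duplicates are split
#' symmetrically around the true Ct (spread < 0.5 cycles) so their mean
#' inverts exactly, and no-RT controls sit at Ct >= 36 unless a sample is
#' planted as contaminated.
#'
#' @param cfg A [sim_config()]; `n_qpcr_patients`, `n_qpcr_normals`,
#'   `activation_freq` and `seed` are used.
#' @param ratios Optional genes x samples matrix (or gene_id tibble) of
#'   planted ratios; when `NULL`, patient and normal ratios are drawn from
#'   the generator's background/aberrant model.
#' @param contaminated Character vector of sample ids planted with genomic
#'   contamination (no-RT Ct < 36).
#' @param signature,frequent_genes,control_genes Gene panels measured on the
#'   plate; defaults are the classifier's six genes, the three
#'   frequently-activated quality-control genes, and the four housekeeping
#'   normalizers.
#' @return A list with `records` (one row per sample x gene Ct measurement)
#'   and `truth` (planted ratio matrix, activation mask relative to the
#'   normals' mean + 2 SD thresholds, the thresholds themselves, and the
#'   normal/testis sample ids).
#' @export
simulate_ct_table <- function(cfg, ratios = NULL, contaminated = character(0),
                              signature = reference_signature(),
                              frequent_genes = c("COX8C", "DKFZp761D1918", "RPL10L"),
                              control_genes = c("ACTB", "U6", "RELA", "AUP1")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 500L))
  target_genes <- c(signature$positive, signature$negative, frequent_genes)

  if (is.null(ratios)) {
    n_pat <- cfg$n_qpcr_patients
    n_norm <- cfg$n_qpcr_normals
    n_bm <- min(7L, n_norm)
    sample_ids <- c(sprintf("patient_%02d", seq_len(n_pat)),
                    c(sprintf("normal_bm_%d", seq_len(n_bm)),
                      sprintf("normal_cb_%d", seq_len(n_norm - n_bm))))
    normal_ids <- grep("^normal_", sample_ids, value = TRUE)
    # background ratios are tiny (around 2^-8 relative to testis); normals
    # define the mean + 2 SD aberrancy threshold, and patient background is
    # truncated below it so the planted mask is exact
    rmat <- matrix(NA_real_, length(target_genes), length(sample_ids),
                   dimnames = list(target_genes, sample_ids))
    rmat[, normal_ids] <- 2^rnorm(length(target_genes) * length(normal_ids), -8, 0.8)
    thr <- rowMeans(rmat[, normal_ids, drop = FALSE]) +
      2 * row_sds(rmat[, normal_ids, drop = FALSE])
    pat_ids <- setdiff(sample_ids, normal_ids)
    mask <- matrix(runif(length(target_genes) * length(pat_ids)) < cfg$activation_freq,
                   length(target_genes), length(pat_ids),
                   dimnames = list(target_genes, pat_ids))
    lthr <- log2(thr)
    for (j in seq_along(pat_ids)) {
      u <- runif(length(target_genes))
      bg <- 2^rtrunc_below(u, lthr, -8, 0.8)
      ab <- 2^runif(length(target_genes), -1, 3)  # 0.5x to 8x testis
      rmat[, pat_ids[j]] <- ifelse(mask[, j], pmax(ab, thr * 1.01), bg)
    }
  } else {
    rmat <- expr_to_matrix(ratios, what = "ratio")
    target_genes <- rownames(rmat)
    sample_ids <- colnames(rmat)
    normal_ids <- character(0)
    mask <- NULL
    thr <- NULL
  }

  testis_ct <- setNames(round(runif(length(target_genes), 23, 27), 2), target_genes)
  ctrl_ct <- setNames(round(runif(length(control_genes), 18, 22), 2), control_genes)
  offsets <- setNames(rnorm(length(sample_ids), 0, 1), sample_ids)

  build_records <- function(sid, delta) {
    ct_target <- testis_ct[target_genes] - log2(rmat[target_genes, sid]) + delta
    ct_ctrl <- ctrl_ct + delta
    gene <- c(target_genes, control_genes)
    ct <- c(ct_target, ct_ctrl)
    spread <- runif(length(gene), 0, 0.4)
    no_rt <- if (sid %in% contaminated) runif(length(gene), 30, 34) else 38 + runif(length(gene), 0, 2)
    tibble(sample_id = sid, gene_id = gene,
           ct_dup1 = ct + spread / 2, ct_dup2 = ct - spread / 2,
           ct_noRT = no_rt,
           role = c(ifelse(target_genes %in% frequent_genes, "frequent", "target"),
                    rep("control", length(control_genes))))
  }
  testis_records <- {
    gene <- c(target_genes, control_genes)
    ct <- c(testis_ct, ctrl_ct)
    spread <- runif(length(gene), 0, 0.4)
    tibble(sample_id = "testis", gene_id = gene,
           ct_dup1 = ct + spread / 2, ct_dup2 = ct - spread / 2,
           ct_noRT = 38 + runif(length(gene), 0, 2),
           role = c(ifelse(target_genes %in% frequent_genes, "frequent", "target"),
                    rep("control", length(control_genes))))
  }
  records <- bind_rows(
    testis_records,
    map_dfr(sample_ids, function(sid) build_records(sid, offsets[[sid]]))
  ) |>
    mutate(is_control_gene = .data$role == "control",
           is_frequent_gene = .data$role == "frequent")

  list(records = records,
       truth = list(ratio = matrix_to_tbl(rmat),
                    mask = if (!is.null(mask)) matrix_to_tbl(mask) else NULL,
                    thresholds = if (!is.null(thr)) {
                      tibble(gene_id = target_genes, threshold = unname(thr))
                    } else NULL,
                    normal_samples = normal_ids,
                    testis_sample = "testis"))
}
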