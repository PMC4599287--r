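#' Construct a six-gene (or n-gene) prognostic signature
#'
#' @param positive Gene ids whose aberrant expression associates with longer
#'   survival (HR < 1).
#' @param negative Gene ids whose aberrant expression associates with
#'   shorter survival (HR > 1). The two lists must be disjoint and
#'   non-empty.
#' @return An object of class `signature_genes`.
#' @export
signature_genes <- function(positive, negative) {
  positive <- as.character(positive)
  negative <- as.character(negative)
  if (length(positive) == 0 || length(negative) == 0) {
    abort("both the positive and the negative gene list must be non-empty")
  }
  overlap <- intersect(positive, negative)
  if (length(overlap)) {
    abort(paste0("positive and negative lists must be disjoint; shared: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(positive = positive, negative = negative),
            class = "signature_genes")
}

#' @export
print.signature_genes <- function(x, ...) {
  cat("<signature_genes>\n")
  cat("  positive:", paste(x$positive, collapse = ", "), "\n")
  cat("  negative:", paste(x$negative, collapse = ", "), "\n")
  invisible(x)
}

#' The published six-gene ALL signature
#'
#' The three genes whose aberrant expression associates with a favorable
#' outcome (CAMSAP1, PCGF6, SH3RF3) and the three associated with poor
#' prognosis (AK022211, FASTKD1, STARD4).
#'
#' @return A [signature_genes()] object.
#' @export
reference_signature <- function() {
  signature_genes(positive = c("CAMSAP1", "PCGF6", "SH3RF3"),
                  negative = c("AK022211", "FASTKD1", "STARD4"))
}

as_signature <- function(sig) {
  if (inherits(sig, "signature_genes")) return(sig)
  if (inherits(sig, "signature_selection")) {
    return(signature_genes(sig$positive, sig$negative))
  }
  if (is.list(sig) && all(c("positive", "negative") %in% names(sig))) {
    return(signature_genes(sig$positive, sig$negative))
  }
  abort("'signature' must be a signature_genes, signature_selection, or list(positive=, negative=)")
}

#' Assign P1/P2/P3 prognosis classes from activation calls
#'
#' Counts, per patient, the expressed positive and negative signature genes
#' and applies the classifier: P3 (poorest survival) when at least one
#' negative gene is expressed together with none or only one positive gene;
#' P1 (most favorable) when no negative gene and at least two positive
#' genes are expressed; P2 otherwise. P1 and P2 merge into the `P1&2`
#' group, opposed to `P3`. Every patient receives exactly one class.
#'
#' @param calls Boolean call tibble containing all signature genes.
#' @param signature A [signature_genes()] object (or a
#'   [cross_cohort_select()] result).
#' @return A tibble `sample_id`, `npos`, `nneg`, `klass` (factor P1/P2/P3),
#'   `group` (factor `P1&2`/`P3`).
#' @export
assign_prognosis <- function(calls, signature) {
  sig <- as_signature(signature)
  m <- expr_to_matrix(calls, what = "call")
  missing <- setdiff(c(sig$positive, sig$negative), rownames(m))
  if (length(missing)) {
    abort(paste0("signature gene(s) absent from calls: ",
                 paste(missing, collapse = ", ")))
  }
  npos <- colSums(m[sig$positive, , drop = FALSE])
  nneg <- colSums(m[sig$negative, , drop = FALSE])
  klass <- ifelse(nneg >= 1 & npos <= 1, "P3",
                  ifelse(nneg == 0 & npos >= 2, "P1", "P2"))
  tibble(sample_id = colnames(m),
         npos = as.integer(npos), nneg = as.integer(nneg),
         klass = factor(klass, levels = c("P1", "P2", "P3")),
         group = factor(ifelse(klass == "P3", "P3", "P1&2"),
                        levels = c("P1&2", "P3")))
}

#' Kaplan-Meier comparison of the P3 and P1&2 prognosis groups
#'
#' Estimates Kaplan-Meier curves and a Mantel-Cox logrank p-value for P3
#' versus P1&2, optionally within a covariate-defined stratum of the
#' survival table (e.g. `MLL == 0`). If either group is empty after
#' stratification the comparison is returned flagged untestable rather than
#' as an error.
#'
#' @param assignments Prognosis assignments from [assign_prognosis()].
#' @param surv Survival tibble (`sample_id`, `time`, `event`, covariates).
#' @param stratum Optional unquoted filtering expression evaluated on the
#'   joined table, e.g. `MLL == 0`.
#' @param horizon Optional administrative censoring horizon (same time unit
#'   as `time`); events after the horizon count as censored at the horizon.
#' @return An object of class `km_comparison`: Kaplan-Meier fit, logrank p,
#'   Cox hazard ratio of P3 versus P1&2, group sizes, and the stratum label.
#' @export
compare_groups_km <- function(assignments, surv, stratum = NULL, horizon = NULL) {
  d <- inner_join(assignments, surv, by = "sample_id")
  squo <- enquo(stratum)
  stratum_label <- if (quo_is_null(squo)) NA_character_ else as_label(squo)
  if (!quo_is_null(squo)) d <- filter(d, !!squo)
  if (!is.null(horizon)) {
    over <- d$time > horizon
    d$event[over] <- FALSE
    d$time[over] <- horizon
  }
  counts <- table(factor(d$group, levels = c("P1&2", "P3")))
  if (nrow(d) == 0 || any(counts == 0)) {
    return(structure(list(fit = NULL, p = NA_real_, hr = NA_real_,
                          n = as.integer(counts), data = d,
                          stratum = stratum_label, testable = FALSE),
                     class = "km_comparison"))
  }
  s <- survival::Surv(d$time, as.integer(d$event))
  sd_fit <- tryCatch(survival::survdiff(s ~ group, data = d),
                     error = function(e) NULL)
  p <- if (is.null(sd_fit)) NA_real_ else {
    pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  }
  hr <- tryCatch(
    exp(suppressWarnings(
      survival::coxph(s ~ I(group == "P3"), data = d)$coefficients[[1]]
    )),
    error = function(e) NA_real_
  )
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ group,
                           data = d)
  structure(list(fit = fit, p = p, hr = hr, n = as.integer(counts),
                 data = d, stratum = stratum_label,
                 testable = !is.na(p)),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("<km_comparison> P3 vs P1&2")
  if (!is.na(x$stratum)) cat(" within", x$stratum)
  cat("\n")
  if (!x$testable) {
    cat("  untestable: one prognosis group is empty in this stratum\n")
    return(invisible(x))
  }
  cat("  n =", x$n[1], "(P1&2) vs", x$n[2], "(P3)\n")
  cat("  logrank p =", format.pval(x$p, digits = 3),
      "; HR(P3 vs P1&2) =", signif(x$hr, 3), "\n")
  invisible(x)
}

#' @export
tidy.km_comparison <- function(x, ...) {
  if (is.null(x$fit)) return(tibble())
  s <- summary(x$fit)
  tibble(group = sub("^group=", "", as.character(s$strata)),
         time = s$time, n_risk = s$n.risk, n_event = s$n.event,
         estimate = s$surv, std_error = s$std.err,
         conf_low = s$lower, conf_high = s$upper)
}

#' @export
glance.km_comparison <- function(x, ...) {
  tibble(n_p12 = x$n[1], n_p3 = x$n[2], logrank_p = x$p, hr_p3 = x$hr,
         stratum = x$stratum, testable = x$testable)
}

#' @export
autoplot.km_comparison <- function(object, ...) {
  curves <- tidy(object)
  if (nrow(curves) == 0) abort("untestable comparison: nothing to plot")
  curves <- curves |>
    group_by(.data$group) |>
    group_modify(function(df, key) {
      bind_rows(tibble(time = 0, estimate = 1), df[c("time", "estimate")])
    }) |>
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$estimate,
                                       color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c("P1&2" = "grey40", "P3" = "firebrick")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Overall survival probability",
                  color = "Prognosis group",
                  subtitle = sprintf("logrank p = %s",
                                     format.pval(object$p, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Tabulate prognosis-group proportions by molecular subtype
#'
#' @param assignments Prognosis assignments from [assign_prognosis()].
#' @param subtypes Tibble `sample_id`, `subtype`; every assigned sample must
#'   be labelled.
#' @return A tibble per subtype: `subtype`, `n`, `n_p12`, `n_p3`,
#'   `frac_p12`, `frac_p3` (fractions sum to 1 within each subtype).
#' @export
tabulate_subtypes <- function(assignments, subtypes) {
  if (!all(c("sample_id", "subtype") %in% names(subtypes))) {
    abort("'subtypes' must have columns 'sample_id' and 'subtype'")
  }
  missing <- setdiff(assignments$sample_id, subtypes$sample_id)
  if (length(missing)) {
    abort(paste0("unlabelled sample(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  inner_join(assignments, subtypes, by = "sample_id") |>
    group_by(.data$subtype) |>
    summarise(n = n(),
              n_p12 = sum(.data$group == "P1&2"),
              n_p3 = sum(.data$group == "P3"),
              .groups = "drop") |>
    mutate(frac_p12 = .data$n_p12 / .data$n, frac_p3 = .data$n_p3 / .data$n)
}

# greedy drop-1 backward elimination on a Cox fit by information criterion;
# k = 2 is AIC, k = log(#events) is the BIC variant used here
backward_eliminate <- function(d, vars, k) {
  fit_vars <- function(v) {
    if (length(v) == 0) return(NULL)
    f <- reformulate(v, response = "survival::Surv(time, as.integer(event))")
    survival::coxph(f, data = d)
  }
  ic <- function(fit, nv) {
    if (is.null(fit)) {
      # null model: no parameters, loglik of the empty Cox model
      return(-2 * fit_null_loglik(d))
    }
    -2 * as.numeric(logLik(fit)) + k * nv
  }
  current <- vars
  fit <- fit_vars(current)
  best_ic <- ic(fit, length(current))
  repeat {
    if (length(current) == 0) break
    cand <- lapply(seq_along(current), function(i) current[-i])
    fits <- lapply(cand, fit_vars)
    ics <- vapply(seq_along(cand), function(i) ic(fits[[i]], length(cand[[i]])),
                  numeric(1))
    if (min(ics) < best_ic - 1e-8) {
      j <- which.min(ics)
      current <- cand[[j]]
      fit <- fits[[j]]
      best_ic <- ics[j]
    } else {
      break
    }
  }
  list(variables = current, fit = fit, ic = best_ic)
}

fit_null_loglik <- function(d) {
  f0 <- survival::coxph(survival::Surv(time, as.integer(event)) ~ 1, data = d)
  as.numeric(f0$loglik[1])
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param fit_small,fit_big Nested `coxph` fits (the smaller model's
#'   variables are a subset of the bigger's). Identical likelihoods give
#'   p = 1.
#' @return A one-row tibble `statistic`, `df`, `p_value`.
#' @export
cox_lrt <- function(fit_small, fit_big) {
  # a NULL small model stands for the empty (null) Cox model on the same data
  ll_small <- if (is.null(fit_small)) fit_big$loglik[1] else as.numeric(logLik(fit_small))
  ll_big <- as.numeric(logLik(fit_big))
  df <- length(stats::coef(fit_big)) -
    if (is.null(fit_small)) 0L else length(stats::coef(fit_small))
  stat <- max(0, 2 * (ll_big - ll_small))
  p <- if (df <= 0 || stat <= 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble(statistic = stat, df = as.integer(df), p_value = p)
}

#' Multivariate Cox analysis with univariate screening and backward
#' elimination
#'
#' Reproduces the standard multivariate workflow around the classifier:
#' (i) a univariate logrank screen of each candidate variable at
#' `p < screen_p`; (ii) a Cox proportional-hazards fit on the retained
#' variables; (iii) backward elimination by AIC and by BIC (BIC penalty
#' `log(#events)`); (iv) likelihood-ratio tests comparing the full model to
#' each drop-one submodel and each single variable to the null model; and
#' (v) a Schoenfeld-residual proportional-hazards diagnostic per
#' regression. The prognosis indicator `P3vsP12` (P3 = 1) is always added
#' to the candidate list.
#'
#' @param surv Survival tibble (`sample_id`, `time`, `event`, covariate
#'   columns).
#' @param assignments Prognosis assignments from [assign_prognosis()].
#' @param covariates Candidate covariate column names; default: every
#'   column of `surv` other than `sample_id`, `time`, `event`.
#' @param screen_p Univariate retention bar (default 0.20).
#' @param horizon Optional administrative censoring horizon (e.g. 60 months
#'   for 5-year overall survival).
#' @return An object of class `cox_screen`: univariate table, full fit,
#'   AIC- and BIC-selected variable sets and fits, LRT table, Schoenfeld
#'   test table, sample and event counts.
#' @export
multivariate_cox <- function(surv, assignments, covariates = NULL,
                             screen_p = 0.20, horizon = NULL) {
  d <- inner_join(surv, assignments[c("sample_id", "group")], by = "sample_id")
  d$P3vsP12 <- as.integer(d$group == "P3")
  d$group <- NULL
  if (!is.null(horizon)) {
    over <- d$time > horizon
    d$event[over] <- FALSE
    d$time[over] <- horizon
  }
  covariates <- covariates %||%
    setdiff(names(surv), c("sample_id", "time", "event"))
  cands <- unique(c(covariates, "P3vsP12"))
  if (length(cands) < 2) abort("at least two candidate variables are required")
  n_events <- sum(d$event)
  if (n_events < 10) abort("at least 10 events are required for the multivariate analysis")

  s <- survival::Surv(d$time, as.integer(d$event))
  uni_p <- vapply(cands, function(v) {
    x <- d[[v]]
    if (length(unique(x)) < 2) return(NA_real_)
    if (length(unique(x)) <= 5) {
      fit <- tryCatch(survival::survdiff(s ~ x), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pchisq(fit$chisq, df = length(unique(x)) - 1, lower.tail = FALSE)
    } else {
      fit <- tryCatch(suppressWarnings(survival::coxph(s ~ x)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      summary(fit)$sctest[["pvalue"]]
    }
  }, numeric(1))
  univariate <- tibble(variable = cands, logrank_p = unname(uni_p),
                       retained = !is.na(uni_p) & uni_p < screen_p)
  retained <- univariate$variable[univariate$retained]

  if (length(retained) == 0) {
    return(structure(list(univariate = univariate, fit = NULL,
                          aic = NULL, bic = NULL, lrt = tibble(),
                          schoenfeld = tibble(), n = nrow(d),
                          n_events = n_events, screen_p = screen_p,
                          note = "no variable passed the univariate screen"),
                     class = "cox_screen"))
  }

  f_full <- reformulate(retained,
                        response = "survival::Surv(time, as.integer(event))")
  full <- tryCatch(suppressWarnings(survival::coxph(f_full, data = d)),
                   error = function(e) NULL)
  if (is.null(full)) {
    return(structure(list(univariate = univariate, fit = NULL, aic = NULL,
                          bic = NULL, lrt = tibble(), schoenfeld = tibble(),
                          n = nrow(d), n_events = n_events,
                          screen_p = screen_p,
                          note = "full multivariate fit did not converge"),
                     class = "cox_screen"))
  }
  aic <- backward_eliminate(d, retained, k = 2)
  bic <- backward_eliminate(d, retained, k = log(n_events))

  lrt <- bind_rows(
    map_dfr(retained, function(v) {
      f1 <- survival::coxph(
        reformulate(v, response = "survival::Surv(time, as.integer(event))"),
        data = d)
      cox_lrt(NULL, f1) |>
        mutate(comparison = paste0("null vs ", v), .before = 1)
    }),
    if (length(retained) > 1) {
      map_dfr(retained, function(v) {
        f_red <- survival::coxph(
          reformulate(setdiff(retained, v),
                      response = "survival::Surv(time, as.integer(event))"),
          data = d)
        cox_lrt(f_red, full) |>
          mutate(comparison = paste0("full vs full - ", v), .before = 1)
      })
    }
  )
  zph <- tryCatch({
    z <- survival::cox.zph(full)
    as_tibble(as.data.frame(z$table), rownames = "variable")
  }, error = function(e) tibble())

  structure(list(univariate = univariate, fit = full,
                 aic = aic, bic = bic, lrt = lrt, schoenfeld = zph,
                 n = nrow(d), n_events = n_events, screen_p = screen_p,
                 note = NA_character_),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat("<cox_screen> n =", x$n, "patients,", x$n_events, "events\n")
  cat("  univariate screen (p <", x$screen_p, "): retained",
      paste(x$univariate$variable[x$univariate$retained], collapse = ", "), "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$aic)) {
    cat("  backward AIC kept:", paste(x$aic$variables, collapse = ", "), "\n")
    cat("  backward BIC kept:", paste(x$bic$variables, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cox_screen <- function(x, ...) {
  if (is.null(x$fit)) return(tibble())
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "coef"],
         hr = exp(sm[, "coef"]), std_error = sm[, "se(coef)"],
         statistic = sm[, "z"], p_value = sm[, "Pr(>|z|)"])
}

#' @export
glance.cox_screen <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         n_retained = sum(x$univariate$retained),
         loglik = if (is.null(x$fit)) NA_real_ else as.numeric(logLik(x$fit)),
         aic_kept = if (is.null(x$aic)) NA_character_ else
           paste(x$aic$variables, collapse = ","),
         bic_kept = if (is.null(x$bic)) NA_character_ else
           paste(x$bic$variables, collapse = ","))
}
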