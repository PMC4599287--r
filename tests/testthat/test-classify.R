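sig6 <- signature_genes(positive = c("P_1", "P_2", "P_3"),
                        negative = c("N_1", "N_2", "N_3"))

# all 64 boolean six-gene patterns as a call matrix
pattern_calls <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(grid) <- c("P_1", "P_2", "P_3", "N_1", "N_2", "N_3")
  m <- t(as.matrix(grid))
  colnames(m) <- sprintf("pat%02d", seq_len(ncol(m)))
  list(calls = calls_tbl(m), grid = grid)
}

test_that("the published combination rules map to P1, P2 and P3", {
  pat <- function(npos, nneg) {
    m <- matrix(c(seq_len(3) <= npos, seq_len(3) <= nneg), 6, 1,
                dimnames = list(c("P_1", "P_2", "P_3", "N_1", "N_2", "N_3"), "x"))
    assign_prognosis(calls_tbl(m), sig6)
  }
  expect_equal(as.character(pat(2, 0)$klass), "P1")
  expect_equal(as.character(pat(1, 1)$klass), "P3")
  expect_equal(as.character(pat(3, 2)$klass), "P2")
  expect_equal(as.character(pat(0, 0)$klass), "P2")
  expect_equal(as.character(pat(0, 3)$klass), "P3")
  expect_error(
    assign_prognosis(calls_tbl(matrix(TRUE, 1, 1,
                                      dimnames = list("P_1", "x"))), sig6),
    "N_1"
  )
})

test_that("the 64-pattern truth table satisfies the classifier invariants", {
  p <- pattern_calls()
  a <- assign_prognosis(p$calls, sig6)
  npos <- rowSums(p$grid[, 1:3])
  nneg <- rowSums(p$grid[, 4:6])
  expect_equal(a$npos, unname(npos))
  expect_equal(a$nneg, unname(nneg))
  # exhaustive + exclusive definitions
  expect_identical(a$klass == "P3", unname(nneg >= 1 & npos <= 1))
  expect_identical(a$klass == "P1", unname(nneg == 0 & npos >= 2))
  expect_identical(a$klass == "P2",
                   unname(!(nneg >= 1 & npos <= 1) & !(nneg == 0 & npos >= 2)))
  expect_identical(a$group == "P1&2", a$klass %in% c("P1", "P2"))
  expect_false(any(is.na(a$klass)))
})

test_that("adding expressed genes moves patients monotonically", {
  p <- pattern_calls()
  m <- prognosix:::expr_to_matrix(p$calls, what = "call")
  a <- assign_prognosis(p$calls, sig6)
  for (j in seq_len(ncol(m))) {
    base <- as.character(a$group[j])
    for (g in rownames(m)) {
      if (m[g, j]) next
      m2 <- m
      m2[g, j] <- TRUE
      a2 <- assign_prognosis(calls_tbl(m2[, j, drop = FALSE]), sig6)
      if (g %in% sig6$negative && base == "P3") {
        expect_equal(as.character(a2$group), "P3")  # never leaves P3
      }
      if (g %in% sig6$positive && base == "P1&2") {
        expect_equal(as.character(a2$group), "P1&2")  # never falls to P3
      }
    }
  }
})

test_that("KM comparison separates planted prognosis groups and honors strata", {
  cfg <- sim_config(seed = 41, n_genes = 300, cohort_sizes = c(a = 200))
  b <- simulate_bundle(cfg)
  co <- b$cohorts$a
  calls <- binarize_expression(co$expression, b$truth$thresholds)
  a <- assign_prognosis(calls, b$truth$signature)
  km <- compare_groups_km(a, co$survival)
  expect_true(km$testable)
  expect_lt(km$p, 0.05)
  expect_gt(km$hr, 1)  # P3 dies faster by construction

  # stratification bookkeeping: stratum size equals the covariate count
  km_mll <- compare_groups_km(a, co$survival, stratum = MLL == 0)
  expect_equal(sum(km_mll$n), sum(co$survival$MLL == 0))

  # all-P3 input is untestable, not an error
  a3 <- dplyr::mutate(a,
                      klass = factor("P3", levels = levels(klass)),
                      group = factor("P3", levels = levels(group)))
  km3 <- compare_groups_km(a3, co$survival)
  expect_false(km3$testable)

  td <- tidy(km)
  expect_true(all(c("group", "time", "estimate") %in% names(td)))
  expect_s3_class(autoplot(km), "ggplot")
})

test_that("subtype tabulation preserves row sums and fractions", {
  a <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                      npos = 0L, nneg = 0L,
                      klass = factor(c("P3", "P3", "P1", "P2", "P3", "P1"),
                                     levels = c("P1", "P2", "P3")),
                      group = factor(c("P3", "P3", "P1&2", "P1&2", "P3", "P1&2"),
                                     levels = c("P1&2", "P3")))
  st <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                       subtype = c("MLL", "MLL", "MLL", "ETV6", "ETV6", "ETV6"))
  tab <- tabulate_subtypes(a, st)
  expect_equal(tab$n, c(3, 3))
  expect_equal(tab$n_p12 + tab$n_p3, tab$n)
  expect_equal(tab$frac_p12 + tab$frac_p3, c(1, 1))
  expect_equal(tab$frac_p3[tab$subtype == "MLL"], 2 / 3)

  # single subtype, all P3 -> fraction 1
  tab2 <- tabulate_subtypes(a[a$group == "P3", ],
                            st[a$group == "P3", ])
  expect_equal(tab2$frac_p3, c(1, 1))
  expect_error(tabulate_subtypes(a, st[-1, ]), "unlabelled")
})

test_that("nested Cox models with identical likelihood give LRT p = 1", {
  set.seed(51)
  d <- tibble::tibble(time = rexp(60, 0.1), event = rep(TRUE, 60),
                      x = rbinom(60, 1, 0.5))
  f1 <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
  lrt <- cox_lrt(f1, f1)
  expect_equal(lrt$p_value, 1)
  expect_equal(lrt$statistic, 0)
})

test_that("the multivariate workflow screens, eliminates and diagnoses", {
  cfg <- sim_config(seed = 61, n_genes = 300, cohort_sizes = c(a = 300))
  b <- simulate_bundle(cfg)
  co <- b$cohorts$a
  calls <- binarize_expression(co$expression, b$truth$thresholds)
  a <- assign_prognosis(calls, b$truth$signature)

  surv <- co$survival
  surv$constant <- 1L  # identical for all patients -> excluded at the screen
  res <- multivariate_cox(surv, a, screen_p = 0.20)
  uni <- res$univariate
  expect_false(uni$retained[uni$variable == "constant"])
  expect_true(is.na(uni$logrank_p[uni$variable == "constant"]))
  # the planted effect is the prognosis indicator and must survive the screen
  expect_true(uni$retained[uni$variable == "P3vsP12"])
  expect_true("P3vsP12" %in% res$aic$variables)
  expect_true("P3vsP12" %in% res$bic$variables)
  expect_true(nrow(res$lrt) >= 1)
  expect_true(all(res$lrt$p_value >= 0 & res$lrt$p_value <= 1))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_events, sum(surv$event))
})

test_that("backward elimination retains only the P3 indicator when it alone drives hazard", {
  set.seed(301)
  hits <- 0
  n <- 250
  for (s in 1:10) {
    grp <- runif(n) < 0.35
    a <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)), npos = 0L, nneg = 0L,
      klass = factor(ifelse(grp, "P3", "P2"), levels = c("P1", "P2", "P3")),
      group = factor(ifelse(grp, "P3", "P1&2"), levels = c("P1&2", "P3"))
    )
    h <- 0.01 * ifelse(grp, 3, 1)
    tt <- rexp(n, h)
    cc <- rexp(n, 0.002)
    surv <- tibble::tibble(sample_id = a$sample_id,
                           time = pmin(tt, cc), event = tt <= cc,
                           MLL = rbinom(n, 1, 0.05),
                           MRD_d29 = rbinom(n, 1, 0.3),
                           CRLF2_high = rbinom(n, 1, 0.23),
                           age_ge10 = rbinom(n, 1, 0.5),
                           WBC_ge50 = rbinom(n, 1, 0.4),
                           CNS = rbinom(n, 1, 0.1),
                           male = rbinom(n, 1, 0.55))
    res <- multivariate_cox(surv, a)
    if (identical(res$bic$variables, "P3vsP12")) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
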