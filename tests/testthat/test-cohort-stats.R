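test_that("standardization and the Bonferroni gate follow their contracts", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(rep(2, 5)), "constant")
  x <- rnorm(50)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)

  g <- bonferroni_gate(c(0.0071, 0.0072, 0.05), alpha = 0.05, m = 7)
  expect_equal(round(g$threshold, 4), 0.0071)
  expect_equal(unname(g$decisions), c(TRUE, FALSE, FALSE))
  expect_equal(bonferroni_gate(0.04, m = 1)$threshold, 0.05)
  # boundary: p equal to the threshold passes
  expect_true(bonferroni_gate(0.05 / 7, m = 7)$decisions)
})

test_that("continuous Cox inverts under marker negation and flags nulls", {
  co <- generate_cohort(cohort_spec(
    n_patients = 250, true_log_hr_per_sd = list(MVP_mu = c(log(1.5), log(1.5))),
    censoring_fraction_target = 0.4, seed = 9))
  f <- fit_continuous_cox(co, "MVP_mu", "ddfs")
  co$neg <- -co$MVP_mu
  g <- fit_continuous_cox(co, "neg", "ddfs")
  expect_equal(g$hr_per_sd, 1 / f$hr_per_sd, tolerance = 1e-6)
  # no events: flagged, not an error
  co0 <- co; co0$ddfs_event <- 0L
  expect_false(fit_continuous_cox(co0, "MVP_mu", "ddfs")$ok)
})

test_that("median dichotomization reproduces the odd-n split and tie rule", {
  expect_equal(as.vector(table(dichotomize_median(c(1, 2, 3, 4)))), c(2, 2))
  d <- dichotomize_median(c(1, 2, 2, 3))
  expect_equal(as.vector(table(d)), c(3, 1))        # ties at the median go low
  # odd n = 293 gives the 147/146 split
  v <- vesselmorph:::with_seed(1, stats::rnorm(293))
  expect_equal(as.vector(table(dichotomize_median(v))), c(147, 146))
  expect_error(dichotomize_median(rep(1, 10)), "identical")
})

test_that("Kaplan-Meier / log-rank recovers an exactly doubled hazard", {
  hits <- 0L
  for (s in 1:15) {
    vesselmorph:::with_seed(700 + s, {
      n <- 1000
      grp <- factor(rep(c("low", "high"), each = n / 2),
                    levels = c("low", "high"))
      lam <- ifelse(grp == "high", 0.008, 0.004)
      tev <- stats::rexp(n, lam)
      cens <- stats::runif(n, 0, 500)
      co <- data.frame(ddfs_months = pmin(tev, cens),
                       ddfs_event = as.integer(tev <= cens))
      r <- km_logrank(co, grp, "ddfs")
      if (r$hr >= 1.8 && r$hr <= 2.2) hits <- hits + 1L
    })
  }
  expect_gte(hits, 12L)
  # exchangeable groups give HR near 1 and non-significant log-rank
  vesselmorph:::with_seed(3, {
    n <- 800
    co <- data.frame(ddfs_months = stats::rexp(n, 0.01),
                     ddfs_event = rep(1L, n))
    grp <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
    r <- km_logrank(co, grp, "ddfs")
    expect_lt(abs(log(r$hr)), 0.25)
  })
  # all-censored input errors
  co <- generate_cohort(cohort_spec(n_patients = 40,
                                    censoring_fraction_target = 1, seed = 1))
  expect_error(km_logrank(co, dichotomize_median(co$MVP_mu), "ddfs"),
               "no events")
})

test_that("exact association tests reproduce the reference table and nulls", {
  # necrosis x marker group reference table: p about 0.001
  grp <- factor(c(rep("low", 5), rep("high", 22), rep("low", 142),
                  rep("high", 124)), levels = c("low", "high"))
  nec <- factor(c(rep("presence", 27), rep("absence", 266)))
  at <- association_test(grp, nec, ordered = FALSE, seed = 3)
  expect_lt(at$p, 0.005)
  expect_gt(at$p, 1e-5)
  # identical rows: p = 1
  g2 <- factor(rep(c("a", "b"), each = 20))
  c2 <- factor(rep(c("x", "y"), times = 20))
  expect_gt(association_test(g2, c2, seed = 1)$p, 0.5)
  # independent labels: p roughly uniform over replicates
  pv <- vapply(1:30, function(s) {
    vesselmorph:::with_seed(1000 + s, {
      g <- factor(sample(c("a", "b"), 80, TRUE))
      cv <- factor(sample(c("x", "y", "z"), 80, TRUE))
      association_test(g, cv, seed = s, n_draws = 2000)$p
    })
  }, numeric(1))
  expect_gt(mean(pv), 0.3)
  expect_lte(mean(pv < 0.05), 0.2)
  # ordered covariates use the trend statistic
  g3 <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  c3 <- factor(c(rep("I", 20), rep("II", 8), rep("III", 2),
                 rep("I", 5), rep("II", 10), rep("III", 15)),
               levels = c("I", "II", "III"), ordered = TRUE)
  expect_lt(association_test(g3, c3, seed = 2)$p, 0.01)
})

test_that("squared correlations behave as rank and linear statistics", {
  x <- seq(1, 50)
  expect_equal(marker_correlations(x, 3 * x + 2)$r_squared, 1)
  mono <- marker_correlations(x, x^3, categorized = FALSE)
  expect_equal(mono$tau_squared, 1)
  expect_lt(mono$r_squared, 1)
  ind <- vesselmorph:::with_seed(5, marker_correlations(rnorm(1000), rnorm(1000)))
  expect_lt(ind$r_squared, 0.01)
  # categorized variant works on the median-split coding
  cat_ <- marker_correlations(x, 3 * x, categorized = TRUE)
  expect_equal(cat_$tau_squared, 1)
  expect_error(marker_correlations(rep(1, 10), rnorm(10)), "variance")
})

test_that("subgroup analysis localizes a stratum-specific effect", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(cohort_spec(n_patients = 500,
                                      censoring_fraction_target = 0.3,
                                      seed = 1200 + s))
    # factor prognostic (HR 4) only in stratum A (low marker)
    strat <- dichotomize_median(co$MVP_mu)
    fac <- co$dtc
    lam <- 0.004 * exp(ifelse(strat == "low" & fac == "positive", log(4), 0))
    tev <- vesselmorph:::with_seed(s, stats::rexp(500, lam))
    cens <- vesselmorph:::with_seed(s + 1, stats::runif(500, 0, 400))
    co$ddfs_months <- pmin(tev, cens)
    co$ddfs_event <- as.integer(tev <= cens)
    r <- subgroup_survival(co, strat, "dtc", "ddfs")
    sig_low <- r$logrank_p[r$stratum == "low"] < 0.05
    sig_high <- r$logrank_p[r$stratum == "high"] < 0.05
    if (isTRUE(sig_low) && isFALSE(sig_high)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
  # swapping strata swaps rows exactly
  co <- generate_cohort(cohort_spec(n_patients = 300,
                                    censoring_fraction_target = 0.3, seed = 77))
  strat <- dichotomize_median(co$MVP_mu)
  r1 <- subgroup_survival(co, strat, "vi", "ddfs")
  r2 <- subgroup_survival(co, factor(strat, levels = c("high", "low")),
                          "vi", "ddfs")
  expect_equal(r1[1, c("hr", "logrank_p")], r2[2, c("hr", "logrank_p")],
               ignore_attr = TRUE)
})

test_that("multivariate Cox reduces to univariate and warns on sparse events", {
  co <- generate_cohort(cohort_spec(n_patients = 400,
                                    censoring_fraction_target = 0.3,
                                    covariate_log_hr = list(vi = log(2)),
                                    seed = 33))
  uni <- multivariate_cox(co, NULL, "vi", "ddfs")
  fit <- survival::coxph(survival::Surv(ddfs_months, ddfs_event) ~ vi,
                         data = co, ties = "efron")
  expect_equal(uni$hr[1], unname(exp(coef(fit)[1])), tolerance = 1e-8)
  # two simulated effects both recovered within their CIs
  co2 <- generate_cohort(cohort_spec(n_patients = 600,
                                     censoring_fraction_target = 0.3,
                                     covariate_log_hr = list(vi = log(2),
                                                             dtc = log(1.8)),
                                     seed = 34))
  mv <- multivariate_cox(co2, NULL, c("vi", "dtc"), "ddfs")
  expect_equal(mv$hr[grepl("vi", mv$term)], 2, tolerance = 0.35)
  expect_equal(mv$hr[grepl("dtc", mv$term)], 1.8, tolerance = 0.35)
  # sparse events trigger the 1-per-10-events warning
  co3 <- co[1:60, ]
  expect_warning(multivariate_cox(co3, NULL,
                                  c("vi", "dtc", "grade", "pt_status",
                                    "ln_status", "hor_status"), "ddfs"),
                 "10")
})

test_that("the dual-endpoint rule is more conservative than either endpoint", {
  co <- generate_cohort(cohort_spec(
    n_patients = 350, censoring_fraction_target = 0.4,
    true_log_hr_per_sd = list(MVP_mu = c(log(1.6), log(1.6)),
                              MVS_mu = c(log(0.6), 0)),
    seed = 55))
  panel <- evaluate_marker_panel(co, c("MVP_mu", "MVS_mu", "MVA_CV",
                                       "MV_luminal", "MV_scale", "MVA_rx4",
                                       "ICD"))
  thr <- panel$threshold[1]
  expect_true(all(panel$prognostic ==
                  (panel$p_ddfs <= thr & panel$p_bcss <= thr)))
  expect_true(all(which(panel$prognostic) %in% which(panel$p_ddfs <= thr)))
  expect_true(all(which(panel$prognostic) %in% which(panel$p_bcss <= thr)))
})
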