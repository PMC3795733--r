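#' Marker-validation statistics
#'
#' The evaluation protocol for a panel of candidate prognostic markers:
#' each marker is standardized and screened by continuous Cox regression
#' against both survival endpoints, with a Bonferroni-corrected threshold
#' shared by the panel; a marker is called prognostic only if its Wald
#' p-value passes the threshold for *both* endpoints. Prognostic markers
#' are then dichotomized at the median and examined by Kaplan-Meier /
#' log-rank analysis, exact association tests against clinico-pathological
#' covariates, subgroup survival analysis and multivariate adjustment.
#'
#' @name cohort_stats
NULL

#' Standardize a numeric vector
#'
#' Centres to mean 0 and scales to sample SD 1 on complete cases.
#'
#' @param values Numeric vector; `NA`s are preserved in place.
#' @return Standardized vector.
#' @export
standardize <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("standardize() needs at least 2 non-missing values")
  s <- stats::sd(v)
  if (s == 0) stop("standardize() is undefined for a constant vector")
  (values - mean(v)) / s
}

#' Bonferroni panel gate
#'
#' @param p_values Numeric vector of per-test p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of tests in the panel (default 7).
#' @return List with `threshold` (`alpha/m`) and logical `decisions`
#'   (`p <= threshold`; the boundary passes).
#' @export
bonferroni_gate <- function(p_values, alpha = 0.05, m = 7) {
  stopifnot(m >= 1, alpha > 0)
  threshold <- alpha / m
  list(threshold = threshold, decisions = p_values <= threshold)
}

#' Continuous Cox regression of a standardized marker
#'
#' Fits a proportional-hazards model (partial likelihood, Efron tie
#' handling) to the standardized marker, so the hazard ratio corresponds
#' to a one-standard-deviation increase.
#'
#' @param cohort Data frame with the marker and endpoint columns.
#' @param marker Marker column name.
#' @param endpoint `"ddfs"` or `"bcss"` (expects `<endpoint>_months` and
#'   `<endpoint>_event` columns).
#' @return List with `hr_per_sd`, `p` (Wald), `n`, `n_events`, and `ok`
#'   (`FALSE` when there are no events or the fit failed).
#' @export
fit_continuous_cox <- function(cohort, marker, endpoint = c("ddfs", "bcss")) {
  endpoint <- match.arg(endpoint)
  d <- data.frame(time = cohort[[paste0(endpoint, "_months")]],
                  event = cohort[[paste0(endpoint, "_event")]],
                  x = cohort[[marker]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 2 || sum(d$event) < 1)
    return(list(hr_per_sd = NA_real_, p = NA_real_, n = nrow(d),
                n_events = sum(d$event), ok = FALSE))
  d$z <- standardize(d$x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ z, data = d,
                    ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ z,
                                       data = d, ties = "efron"))
    })
  if (is.null(fit) || !is.finite(stats::coef(fit)[1]))
    return(list(hr_per_sd = NA_real_, p = NA_real_, n = nrow(d),
                n_events = sum(d$event), ok = FALSE))
  s <- summary(fit)
  list(hr_per_sd = unname(exp(stats::coef(fit)[1])),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       n = nrow(d), n_events = sum(d$event), ok = TRUE)
}

#' Evaluate a marker panel
#'
#' Screens every marker against both endpoints by standardized continuous
#' Cox regression and applies the Bonferroni dual-endpoint rule: a marker
#' is prognostic iff its Wald p is at or below `alpha/m` for *both*
#' endpoints, where `m` is the panel size.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for schema).
#' @param markers Character vector of marker column names.
#' @param alpha Family-wise level (default 0.05).
#' @return A `panel_result` data frame: per marker, HR/SD and p for each
#'   endpoint, the shared `threshold`, and the `prognostic` flag.
#' @export
evaluate_marker_panel <- function(cohort, markers, alpha = 0.05) {
  m <- length(markers)
  res <- do.call(rbind, lapply(markers, function(mk) {
    dd <- fit_continuous_cox(cohort, mk, "ddfs")
    bc <- fit_continuous_cox(cohort, mk, "bcss")
    data.frame(marker = mk, hr_ddfs = dd$hr_per_sd, p_ddfs = dd$p,
               n_ddfs = dd$n, hr_bcss = bc$hr_per_sd, p_bcss = bc$p,
               n_bcss = bc$n)
  }))
  gate <- bonferroni_gate(pmax(res$p_ddfs, res$p_bcss), alpha = alpha, m = m)
  res$threshold <- gate$threshold
  res$prognostic <- !is.na(res$p_ddfs) & !is.na(res$p_bcss) &
    res$p_ddfs <= gate$threshold & res$p_bcss <= gate$threshold
  class(res) <- c("panel_result", class(res))
  res
}

#' Median dichotomization
#'
#' Splits values at the sample median; values at or below the median form
#' the `"low"` group, the rest `"high"`. With an odd number of complete
#' cases this yields the (n+1)/2 vs (n-1)/2 split.
#'
#' @param values Numeric vector (`NA`s yield `NA` labels).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_median <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("dichotomize_median() needs at least 2 values")
  med <- stats::median(v)
  if (all(v == v[1])) stop("dichotomize_median(): all values identical")
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier / log-rank comparison of two groups
#'
#' Product-limit curves per group, the two-sided log-rank test, and the
#' group hazard ratio (with 95% CI) from a binary-covariate Cox model.
#'
#' @param cohort Cohort data frame.
#' @param groups Factor with two levels aligned with `cohort` rows; the
#'   second level is treated as the high-risk group.
#' @param endpoint `"ddfs"` or `"bcss"`.
#' @return List with `fit` (a `survfit`), `logrank_p`, `hr`, `hr_ci`
#'   (length-2), `n`, `n_events`.
#' @export
km_logrank <- function(cohort, groups, endpoint = c("ddfs", "bcss")) {
  endpoint <- match.arg(endpoint)
  d <- data.frame(time = cohort[[paste0(endpoint, "_months")]],
                  event = cohort[[paste0(endpoint, "_event")]],
                  g = groups)
  d <- d[stats::complete.cases(d), ]
  d$g <- droplevels(d$g)
  if (nlevels(d$g) != 2) stop("km_logrank() needs exactly 2 non-empty groups")
  if (sum(d$event) < 1) stop("km_logrank(): no events in either group")
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ g, data = d,
                        ties = "efron")
  ci <- summary(cx)$conf.int
  list(fit = sf, logrank_p = p, hr = unname(exp(stats::coef(cx)[1])),
       hr_ci = c(ci[1, "lower .95"], ci[1, "upper .95"]),
       n = nrow(d), n_events = sum(d$event))
}

#' Exact association test between a grouping and a categorical covariate
#'
#' Pearson chi-square for nominal covariates, linear-by-linear association
#' for ordered ones; p-values come from the exact conditional distribution
#' given the table margins, approximated by seeded Monte Carlo sampling
#' (Patefield's algorithm).
#'
#' @param group_labels Factor (e.g. a median-dichotomized marker).
#' @param covariate Factor; use an ordered factor or `ordered = TRUE` for
#'   the trend test.
#' @param ordered Force the linear-by-linear trend test.
#' @param n_draws Monte Carlo draws (default 1e5).
#' @param seed Seed for the Monte Carlo sampler.
#' @return List with `p`, `statistic`, `method`, `table`.
#' @export
association_test <- function(group_labels, covariate, ordered = NULL,
                             n_draws = 1e5, seed = 1L) {
  g <- droplevels(as.factor(group_labels))
  cv <- droplevels(if (is.factor(covariate)) covariate else factor(covariate))
  keep <- !is.na(g) & !is.na(cv)
  tab <- table(cv[keep], g[keep])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty covariate levels")
    tab <- tab[!empty, , drop = FALSE]
  }
  if (is.null(ordered)) ordered <- is.ordered(cv)
  if (ordered) {
    # linear-by-linear association with integer scores
    u <- seq_len(nrow(tab)); v <- seq_len(ncol(tab))
    stat_fun <- function(tt) {
      n <- sum(tt)
      ui <- rep(u, times = ncol(tt)); vi <- rep(v, each = nrow(tt))
      w <- as.vector(tt)
      su <- sum(w * ui) / n; sv <- sum(w * vi) / n
      num <- sum(w * (ui - su) * (vi - sv))
      den <- sqrt(sum(w * (ui - su)^2) * sum(w * (vi - sv)^2))
      if (den == 0) 0 else (num / den)^2 * (n - 1)   # M^2 statistic
    }
    method <- "linear-by-linear association (exact, Monte Carlo)"
  } else {
    stat_fun <- function(tt) {
      e <- outer(rowSums(tt), colSums(tt)) / sum(tt)
      sum((tt - e)^2 / e)
    }
    method <- "Pearson chi-square (exact, Monte Carlo)"
  }
  obs <- stat_fun(tab)
  sims <- with_seed(seed, {
    tabs <- stats::r2dtable(n_draws, rowSums(tab), colSums(tab))
    vapply(tabs, stat_fun, numeric(1))
  })
  # exact-style estimate including the observed table
  p <- (sum(sims >= obs - 1e-12) + 1) / (n_draws + 1)
  list(p = p, statistic = obs, method = method, table = tab)
}

#' Squared correlation between two markers
#'
#' Pearson r^2 on the raw values and Kendall tau^2 on (optionally
#' categorized) values, following the squared-coefficient reporting
#' convention.
#'
#' @param marker_a,marker_b Numeric vectors.
#' @param categorized Compute Kendall's tau on median-dichotomized values.
#' @return List with `r_squared`, `tau_squared`, `n`.
#' @export
marker_correlations <- function(marker_a, marker_b, categorized = FALSE) {
  keep <- !is.na(marker_a) & !is.na(marker_b)
  a <- marker_a[keep]; b <- marker_b[keep]
  if (length(a) < 3) stop("marker_correlations() needs >= 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("marker_correlations(): zero variance")
  ka <- if (categorized) as.integer(dichotomize_median(a)) else a
  kb <- if (categorized) as.integer(dichotomize_median(b)) else b
  list(r_squared = stats::cor(a, b, method = "pearson")^2,
       tau_squared = stats::cor(ka, kb, method = "kendall")^2,
       n = length(a))
}

#' Subgroup survival analysis of a binary factor within marker strata
#'
#' Runs [km_logrank()] for the factor within each stratum of a
#' dichotomized marker, and reports whether each stratum's hazard ratio
#' lies outside the other stratum's confidence interval (the criterion for
#' a stratum-specific effect).
#'
#' @param cohort Cohort data frame.
#' @param stratifier_groups Factor (two levels) defining the strata.
#' @param factor_col Column name of the binary factor (e.g. `"dtc"`,
#'   `"vi"`).
#' @param endpoint `"ddfs"` or `"bcss"`.
#' @return Data frame with one row per stratum: `stratum`, `hr`,
#'   `hr_lo`, `hr_hi`, `logrank_p`, `n`, `n_events`,
#'   `hr_outside_other_ci`.
#' @export
subgroup_survival <- function(cohort, stratifier_groups, factor_col,
                              endpoint = c("ddfs", "bcss")) {
  endpoint <- match.arg(endpoint)
  strata <- droplevels(as.factor(stratifier_groups))
  stopifnot(nlevels(strata) == 2)
  res <- lapply(levels(strata), function(sl) {
    sel <- !is.na(strata) & strata == sl
    sub <- cohort[sel, , drop = FALSE]
    fac <- droplevels(as.factor(sub[[factor_col]]))
    r <- tryCatch(km_logrank(sub, fac, endpoint), error = function(e) NULL)
    if (is.null(r))
      return(data.frame(stratum = sl, hr = NA_real_, hr_lo = NA_real_,
                        hr_hi = NA_real_, logrank_p = NA_real_,
                        n = nrow(sub), n_events = NA_integer_))
    data.frame(stratum = sl, hr = r$hr, hr_lo = r$hr_ci[1],
               hr_hi = r$hr_ci[2], logrank_p = r$logrank_p, n = r$n,
               n_events = r$n_events)
  })
  out <- do.call(rbind, res)
  out$hr_outside_other_ci <- c(
    !is.na(out$hr[1]) && !is.na(out$hr_lo[2]) &&
      (out$hr[1] < out$hr_lo[2] || out$hr[1] > out$hr_hi[2]),
    !is.na(out$hr[2]) && !is.na(out$hr_lo[1]) &&
      (out$hr[2] < out$hr_lo[1] || out$hr[2] > out$hr_hi[1]))
  out
}

#' Multivariate Cox regression
#'
#' Joint proportional-hazards fit of a marker group variable and
#' clinico-pathological covariates. Warns when there are fewer than ten
#' events per variable (the usual rule of thumb) and flags collinear
#' covariates dropped by the fit.
#'
#' @param cohort Cohort data frame.
#' @param marker_group Optional column name (or `NULL`) of the
#'   dichotomized marker entering the model.
#' @param covariates Character vector of covariate column names.
#' @param endpoint `"ddfs"` or `"bcss"`.
#' @return Data frame: one row per model term with `term`, `hr`, `p`,
#'   plus attributes `"n"`, `"n_events"`.
#' @export
multivariate_cox <- function(cohort, marker_group = NULL, covariates,
                             endpoint = c("ddfs", "bcss")) {
  endpoint <- match.arg(endpoint)
  vars <- c(marker_group, covariates)
  d <- cohort[, c(paste0(endpoint, "_months"), paste0(endpoint, "_event"),
                  vars), drop = FALSE]
  names(d)[1:2] <- c("time", "event")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_ev <- sum(d$event)
  if (n_ev < 10 * length(vars))
    warning(sprintf(paste("%d events for %d variables: fewer than 10",
                          "events per variable"), n_ev, length(vars)))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  cf <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit))))
    warning("collinear covariates: some coefficients are not estimable")
  out <- data.frame(term = rownames(cf), hr = exp(cf[, "coef"]),
                    p = cf[, "Pr(>|z|)"], row.names = NULL)
  attr(out, "n") <- nrow(d)
  attr(out, "n_events") <- n_ev
  out
}

#' Seeded pilot/validation split
#'
#' Random 25/75 split of a cohort into pilot and validation subsets.
#'
#' @param cohort Cohort data frame.
#' @param pilot_fraction Fraction assigned to the pilot set (default
#'   0.25).
#' @param seed Integer seed.
#' @return List with `pilot` and `validation` data frames.
#' @export
pilot_validation_split <- function(cohort, pilot_fraction = 0.25, seed = 1L) {
  n <- nrow(cohort)
  idx <- with_seed(seed, sample.int(n, round(pilot_fraction * n)))
  list(pilot = cohort[idx, , drop = FALSE],
       validation = cohort[-idx, , drop = FALSE])
}
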