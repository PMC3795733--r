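#' Synthetic survival cohorts with known marker effects
#'
#' Emulates the cohort structure used to validate angiogenesis markers:
#' continuous per-patient marker values, two survival endpoints - distant
#' disease-free survival (DDFS) and breast-cancer-specific survival
#' (BCSS), in months from surgery - with event indicators, and the usual
#' categorical covariates. Event times follow an exponential
#' proportional-hazards model in which each marker's log hazard ratio is
#' expressed per standard deviation; censoring is independent and uniform,
#' with its upper bound calibrated so the realized censoring fraction
#' matches the target.
#'
#' @name synthetic_cohort
NULL

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param markers Data frame (or named list) with columns/fields `name`,
#'   `mean`, `sd` describing the marker distributions.
#' @param true_log_hr_per_sd Named list mapping marker name to
#'   `c(ddfs, bcss)` log hazard ratios per +1 SD. Unlisted markers have no
#'   effect.
#' @param baseline_hazard Baseline event rate per month (exponential).
#' @param censoring_fraction_target Target fraction of censored records in
#'   `[0, 1]`, per endpoint.
#' @param covariates Named list of covariate samplers: each entry is a
#'   vector of category probabilities (names become levels) - the default
#'   emulates a breast-carcinoma cohort's mix of grade, nodal status,
#'   tumour stage, vascular invasion, disseminated tumour cells, hormone
#'   receptor status and systemic therapy.
#' @param covariate_log_hr Named list mapping covariate name to the log HR
#'   of its non-reference level(s) (applied to both endpoints).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 300,
                        markers = data.frame(
                          name = c("MVP_mu", "MVS_mu", "MVA_CV", "MV_luminal",
                                   "MV_scale", "MVA_rx4", "ICD"),
                          mean = c(85, 0.86, 0.9, 0.45, 1.3, 6, 60),
                          sd = c(25, 0.06, 0.3, 0.15, 0.2, 2.5, 15)),
                        true_log_hr_per_sd = list(),
                        baseline_hazard = 0.004,
                        censoring_fraction_target = 0.79,
                        covariates = default_covariates(),
                        covariate_log_hr = list(),
                        seed = 1L) {
  markers <- as.data.frame(markers)
  stopifnot(n_patients >= 1, all(markers$sd > 0), baseline_hazard > 0,
            censoring_fraction_target >= 0, censoring_fraction_target <= 1)
  structure(list(n_patients = as.integer(n_patients), markers = markers,
                 true_log_hr_per_sd = true_log_hr_per_sd,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction_target = censoring_fraction_target,
                 covariates = covariates, covariate_log_hr = covariate_log_hr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_covariates <- function() {
  # category frequencies typical of an operable breast-carcinoma cohort
  list(grade = c("I" = 0.21, "II" = 0.49, "III" = 0.30),
       ln_status = c("N0" = 0.62, "Npos" = 0.38),
       pt_status = c("T1" = 0.54, "T2" = 0.39, "T3T4" = 0.07),
       vi = c("absent" = 0.75, "present" = 0.25),
       dtc = c("negative" = 0.88, "positive" = 0.12),
       hor_status = c("positive" = 0.80, "negative" = 0.20),
       systemic_therapy = c("no" = 0.46, "yes" = 0.54))
}

# calibrate the uniform censoring bound u so that the expected censored
# fraction matches q, given per-patient hazards lam: P(C < T) with
# C ~ U(0, u) is E[(1 - exp(-lam*u)) / (lam*u)] ... averaged over patients
censor_bound <- function(lam, q) {
  f <- function(u) mean((1 - exp(-lam * u)) / (lam * u)) - q
  lo <- 1e-6; hi <- 1e6
  if (f(hi) > 0) return(hi)   # even very long follow-up censors more than q
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Generate a synthetic cohort
#'
#' Marker values are drawn from their specified normal distributions;
#' event times for each endpoint are exponential with hazard
#' `baseline_hazard * exp(sum(beta_m * z_m) + covariate effects)`, where
#' `z_m` is the marker standardized by its *specified* mean and SD so the
#' effects are exactly per-SD; censoring is uniform and independent.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `patient_id`, one column per marker, per
#'   covariate, and `ddfs_months`, `ddfs_event`, `bcss_months`,
#'   `bcss_event`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    out <- data.frame(patient_id = seq_len(n))
    z <- matrix(stats::rnorm(n * nrow(spec$markers)), n)
    colnames(z) <- spec$markers$name
    for (i in seq_len(nrow(spec$markers)))
      out[[spec$markers$name[i]]] <-
        spec$markers$mean[i] + spec$markers$sd[i] * z[, i]
    for (cv in names(spec$covariates)) {
      pr <- spec$covariates[[cv]]
      out[[cv]] <- factor(sample(names(pr), n, replace = TRUE, prob = pr),
                          levels = names(pr))
    }
    lp_cov <- rep(0, n)
    for (cv in names(spec$covariate_log_hr)) {
      lev <- levels(out[[cv]])
      beta <- spec$covariate_log_hr[[cv]]
      beta <- c(0, rep_len(beta, length(lev) - 1))
      lp_cov <- lp_cov + beta[as.integer(out[[cv]])]
    }
    for (ep in c("ddfs", "bcss")) {
      idx <- if (ep == "ddfs") 1L else 2L
      lp <- lp_cov
      for (mk in names(spec$true_log_hr_per_sd)) {
        beta <- spec$true_log_hr_per_sd[[mk]]
        lp <- lp + rep_len(beta, 2)[idx] * z[, mk]
      }
      lam <- spec$baseline_hazard * exp(lp)
      tev <- stats::rexp(n, lam)
      q <- spec$censoring_fraction_target
      if (q >= 1) {
        time <- stats::runif(n, 1, 125); event <- rep(0L, n)
      } else if (q <= 0) {
        time <- tev; event <- rep(1L, n)
      } else {
        u <- censor_bound(lam, q)
        cens <- stats::runif(n, 0, u)
        event <- as.integer(tev <= cens)
        time <- pmin(tev, cens)
      }
      out[[paste0(ep, "_months")]] <- pmax(time, 1e-3)
      out[[paste0(ep, "_event")]] <- event
    }
    out
  })
}
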