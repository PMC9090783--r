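# Endpoint construction, Kaplan-Meier and reverse Kaplan-Meier summaries,
# and Cox proportional-hazards models with a treatment-by-marker
# interaction. Model fitting is delegated to the survival package
# (coxph/survfit/cox.zph); this module defines the endpoint semantics, the
# interaction parameterization, and the Table-2-style reporting.

#' Derive recurrence-free and overall survival endpoints
#'
#' RFS is the time from randomization to recurrence or death from any
#' cause, whichever comes first, censored at the end of follow-up; OS is
#' time to death from any cause, censored likewise.
#'
#' @param records Cohort `data.frame` with `time_to_recurrence`,
#'   `time_to_death` (NA when the event did not occur) and `followup_time`.
#' @return `data.frame` with `rfs_time`, `rfs_event`, `os_time`,
#'   `os_event`, one row per input record.
#' @export
derive_endpoints <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time_to_recurrence", "time_to_death", "followup_time")
                %in% names(records)))
  fu <- records$followup_time
  if (any(!is.finite(fu) | fu <= 0))
    stop("followup_time must be positive for every record", call. = FALSE)
  tr <- records$time_to_recurrence
  td <- records$time_to_death
  if (any(tr > fu, na.rm = TRUE) || any(td > fu, na.rm = TRUE))
    stop("event times after the end of follow-up are inconsistent",
         call. = FALSE)
  rfs_time <- pmin(tr, td, fu, na.rm = TRUE)
  rfs_event <- as.integer(!is.na(tr) & tr <= rfs_time |
                          !is.na(td) & td <= rfs_time)
  os_time <- pmin(td, fu, na.rm = TRUE)
  os_event <- as.integer(!is.na(td))
  data.frame(rfs_time = rfs_time, rfs_event = rfs_event,
             os_time = os_time, os_event = os_event)
}

#' Kaplan-Meier estimate with a risk table
#'
#' Product-limit estimate of the survival function, plus numbers at risk
#' and cumulative events at requested grid times (the layout used under
#' published survival curves).
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param risk_times Optional numeric grid for the risk table.
#' @return List of class `km_estimate` with `time`, `surv`, `n_risk`,
#'   `n_event` step coordinates and `risk_table`.
#' @export
km_estimate <- function(time, event, risk_times = NULL) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event)
  if (!is.null(risk_times)) {
    sm <- summary(fit, times = risk_times, extend = TRUE)
    out$risk_table <- data.frame(time = sm$time, n_risk = sm$n.risk,
                                 n_event = cumsum(sm$n.event),
                                 surv = sm$surv)
  }
  class(out) <- "km_estimate"
  out
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Runs the Kaplan-Meier estimator with the censoring indicator flipped
#' (censored observations become "events"), so the curve estimates the
#' follow-up distribution; the median follow-up is the first time that
#' curve drops to 0.5 or below.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return Median follow-up in the input time unit, or `NA` when the
#'   reverse curve never reaches 0.5 (reported as not reached).
#' @export
reverse_km_median_followup <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  drop_idx <- which(fit$surv <= 0.5)
  if (!length(drop_idx)) return(NA_real_)
  fit$time[drop_idx[1]]
}

#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around `survival::coxph` that returns coefficients, hazard
#' ratios, 95% Wald confidence intervals and p-values in a fixed layout,
#' and raises on non-convergence or (near-)complete separation. Efron's
#' ties correction is the default; Breslow is available for comparison
#' against closed-form partial-likelihood oracles.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param design `data.frame` of model terms (factors are dummy-coded
#'   against their first level).
#' @param ties `"efron"` or `"breslow"`.
#' @param strata Optional vector defining baseline-hazard strata.
#' @return Object of class `cox_fit`: `data.frame` `terms` (term, coef, se,
#'   hr, ci_lower, ci_upper, p), `loglik`, `ties`, `n`, `n_event`, and the
#'   underlying `coxph` object in `fit`.
#' @export
fit_cox <- function(time, event, design, ties = c("efron", "breslow"),
                    strata = NULL) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(design), nrow(design) == length(time))
  if (sum(event) < 1) stop("no events; cannot fit a Cox model",
                           call. = FALSE)
  dat <- cbind(data.frame(.time = time, .event = event), design)
  rhs <- paste(names(design), collapse = " + ")
  if (!is.null(strata)) {
    dat$.strata <- strata
    rhs <- paste(rhs, "+ survival::strata(.strata)")
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    stop("Cox model did not converge", call. = FALSE)
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || any(abs(co) > 15))
    stop("Cox model shows (near-)complete separation; coefficient ",
         "estimates are unstable", call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  terms <- data.frame(term = names(co),
                      coef = unname(co),
                      se = unname(se),
                      hr = exp(unname(co)),
                      ci_lower = exp(unname(co) - z * se),
                      ci_upper = exp(unname(co) + z * se),
                      p = 2 * stats::pnorm(-abs(unname(co) / se)),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms,
                 loglik = fit$loglik[length(fit$loglik)],
                 ties = ties,
                 n = fit$n, n_event = fit$nevent,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): %d patients, %d events, loglik %.3f\n",
              x$ties, x$n, x$n_event, x$loglik))
  tf <- x$terms
  tf[, -1] <- lapply(tf[, -1], function(v) signif(v, 3))
  print(tf, row.names = FALSE)
  invisible(x)
}

# linear-combination HR with Wald CI from a coxph fit
lincom_hr <- function(fit, weights) {
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  est <- sum(weights * co)
  se <- sqrt(drop(t(weights) %*% V %*% weights))
  z <- stats::qnorm(0.975)
  c(hr = exp(est), ci_lower = exp(est - z * se),
    ci_upper = exp(est + z * se), p = 2 * stats::pnorm(-abs(est / se)))
}

#' Treatment-by-marker interaction analysis
#'
#' Fits a Cox model with a treatment term, a treatment-by-marker
#' interaction term and a marker-stratified baseline hazard (plus at most
#' one adjustment covariate at a time — with few events, full
#' multivariable adjustment is not supported) on the chosen endpoint, and
#' reports the within-stratum treatment hazard ratios with Wald CIs
#' (linear combinations of the coefficients), the interaction Wald
#' p-value, and a per-cell events/patients table. Stratifying the baseline
#' on the marker makes the within-stratum treatment HRs identical to
#' marker-subset Cox fits, matching the usual presentation of per-stratum
#' hazard ratios; the marker's own prognostic HR is obtained from a
#' separate marker-only model via [fit_cox()].
#'
#' @param records Cohort `data.frame` (see [simulate_cohort()]) with `arm`
#'   and `marker` columns.
#' @param endpoint `"rfs"` or `"os"`.
#' @param adjust_for Name of a single covariate column, or `NULL`.
#' @param ties Ties correction passed to the Cox fit.
#' @return Object of class `interaction_fit`: stratum HRs, interaction
#'   coefficient/p, cell table, and the underlying `cox_fit`.
#' @export
interaction_analysis <- function(records, endpoint = c("rfs", "os"),
                                 adjust_for = NULL,
                                 ties = c("efron", "breslow")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  stopifnot(all(c("arm", "marker") %in% names(records)))
  arm <- factor(records$arm, ARM_LEVELS)
  marker <- factor(records$marker, CLASS_LEVELS)
  cells <- table(arm, marker)
  if (any(cells == 0))
    stop("every arm x marker cell must be non-empty", call. = FALSE)

  ep <- derive_endpoints(records)
  time <- if (endpoint == "rfs") ep$rfs_time else ep$os_time
  event <- if (endpoint == "rfs") ep$rfs_event else ep$os_event

  treated <- as.integer(arm == ARM_LEVELS[2])
  pos <- as.integer(marker == BRCA1_LIKE)
  design <- data.frame(treated = treated,
                       treated_x_marker = treated * pos)
  if (!is.null(adjust_for)) {
    stopifnot(length(adjust_for) == 1, adjust_for %in% names(records))
    cov <- records[[adjust_for]]
    design[[adjust_for]] <- if (is.character(cov)) factor(cov) else cov
  }
  cfit <- fit_cox(time, event, design, ties = ties, strata = pos)
  co <- stats::coef(cfit$fit)
  k <- length(co)
  w_neg <- as.numeric(names(co) == "treated")
  w_pos <- w_neg + as.numeric(names(co) == "treated_x_marker")

  cell_tab <- data.frame(
    marker = rep(CLASS_LEVELS, each = 2),
    arm = rep(ARM_LEVELS, 2),
    n_event = as.vector(vapply(CLASS_LEVELS, function(m)
      vapply(ARM_LEVELS, function(a)
        sum(event[arm == a & marker == m]), numeric(1)), numeric(2))),
    n = as.vector(vapply(CLASS_LEVELS, function(m)
      vapply(ARM_LEVELS, function(a)
        sum(arm == a & marker == m), numeric(1)), numeric(2))),
    stringsAsFactors = FALSE
  )
  int_row <- cfit$terms[cfit$terms$term == "treated_x_marker", ]
  structure(list(endpoint = toupper(endpoint),
                 adjusted_for = adjust_for,
                 hr_treatment_marker_neg = lincom_hr(cfit$fit, w_neg),
                 hr_treatment_marker_pos = lincom_hr(cfit$fit, w_pos),
                 interaction_coef = int_row$coef,
                 interaction_p = int_row$p,
                 cell_table = cell_tab,
                 cox = cfit),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Treatment-by-marker interaction, %s%s (%s ties)\n",
              x$endpoint,
              if (is.null(x$adjusted_for)) "" else
                paste0(", adjusted for ", x$adjusted_for),
              x$cox$ties))
  fmt <- function(h) sprintf("%.2f (95%% CI %.2f-%.2f)",
                             h["hr"], h["ci_lower"], h["ci_upper"])
  tab <- x$cell_table
  for (m in unique(tab$marker)) {
    cat(sprintf("%s tumours\n", m))
    sub <- tab[tab$marker == m, ]
    cat(sprintf("  %-8s %d/%d  (reference)\n",
                sub$arm[1], sub$n_event[1], sub$n[1]))
    h <- if (m == NON_BRCA1_LIKE) x$hr_treatment_marker_neg
         else x$hr_treatment_marker_pos
    cat(sprintf("  %-8s %d/%d  HR %s\n",
                sub$arm[2], sub$n_event[2], sub$n[2], fmt(h)))
  }
  cat(sprintf("P-interaction = %.2f\n", x$interaction_p))
  invisible(x)
}

#' Interaction p-values adjusted for one covariate at a time
#'
#' Refits the interaction model once per covariate (never all covariates at
#' once) and reports each adjusted interaction p-value plus the range.
#'
#' @param records Cohort `data.frame`.
#' @param covariates Character vector of covariate column names.
#' @param ... Passed to [interaction_analysis()].
#' @return List with `fits` (named list of `interaction_fit`), `p_values`
#'   and `p_range`.
#' @export
adjust_one_at_a_time <- function(records, covariates, ...) {
  fits <- lapply(covariates, function(cv)
    interaction_analysis(records, adjust_for = cv, ...))
  names(fits) <- covariates
  p <- vapply(fits, function(f) f$interaction_p, numeric(1))
  list(fits = fits, p_values = p, p_range = range(p))
}

#' Schoenfeld proportional-hazards check
#'
#' Correlates the scaled Schoenfeld residuals with event time (identity
#' time transform) and reports the per-term chi-square statistics — the
#' standard diagnostic for the proportional-hazards assumption.
#'
#' @param fit A `cox_fit` (see [fit_cox()]) or an `interaction_fit`.
#' @return `data.frame` with `term`, `chisq`, `df`, `p` (the last row is
#'   the global test).
#' @export
schoenfeld_check <- function(fit) {
  if (inherits(fit, "interaction_fit")) fit <- fit$cox
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_event < 2)
    stop("the Schoenfeld test needs at least 2 events", call. = FALSE)
  z <- survival::cox.zph(fit$fit, transform = "identity")
  data.frame(term = rownames(z$table),
             chisq = z$table[, "chisq"],
             df = z$table[, "df"],
             p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}
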