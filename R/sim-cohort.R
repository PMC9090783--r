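# Randomized two-arm survival cohorts with marker-dependent treatment
# effects: the structure of a capecitabine trial biomarker analysis, with
# exponential event times, administrative censoring, and clinicopathologic
# covariates drawn from configurable categorical distributions (defaults
# reflect an early-stage TNBC trial population).

ARM_LEVELS <- c("T+CEF", "TX+CEX")  # control, capecitabine-containing

default_covariate_dists <- function() {
  list(
    age = list(mean = 53, sd = 8, min = 25, max = 64),
    who_ps = list(levels = c("0", "1"), prob = c(0.845, 0.155)),
    surgery = list(levels = c("breast-conserving", "mastectomy"),
                   prob = c(0.333, 0.667)),
    axillary = list(levels = c("dissection", "sentinel"),
                    prob = c(0.860, 0.140)),
    t_stage = list(levels = c("pT1", "pT2", "pT3"),
                   prob = c(0.248, 0.674, 0.078)),
    nodes = list(levels = c("<=3", ">3"), prob = c(0.752, 0.248)),
    histology = list(levels = c("ductal", "lobular", "other"),
                     prob = c(0.930, 0.023, 0.047)),
    grade = list(levels = c("1", "2", "3"), prob = c(0.008, 0.116, 0.876))
  )
}

#' Configure a two-arm survival cohort simulation
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hr_marker^(marker positive) * stratum treatment HR`,
#' censored administratively at `admin_censor_time`. The default treatment
#' hazard ratios (0.23 in the marker-negative stratum, 0.66 in the
#' marker-positive stratum) give a cohort with a strong
#' treatment-by-marker interaction structure.
#'
#' @param n_per_cell Patients per arm-by-marker cell: a single number or a
#'   length-4 vector ordered (control/neg, treated/neg, control/pos,
#'   treated/pos).
#' @param baseline_hazard Events per person-year in the reference cell.
#' @param hr_treatment_in_marker_neg,hr_treatment_in_marker_pos Treatment
#'   hazard ratios within each marker stratum; must be positive.
#' @param hr_marker Hazard ratio of marker-positive vs -negative under
#'   control treatment.
#' @param admin_censor_time Administrative censoring time in years.
#' @param p_death_first Probability that the simulated first event is a
#'   death rather than a recurrence.
#' @param post_recurrence_death_rate Hazard (per year) of death after a
#'   recurrence, used to give overall survival its own times.
#' @param covariate_dists Categorical covariate distributions; see
#'   `default_covariate_dists` in the package source.
#' @param seed Integer seed.
#' @return Object of class `survival_sim_config`.
#' @export
survival_sim_config <- function(n_per_cell = 500,
                                baseline_hazard = 0.05,
                                hr_treatment_in_marker_neg = 0.23,
                                hr_treatment_in_marker_pos = 0.66,
                                hr_marker = 1.0,
                                admin_censor_time = 12,
                                p_death_first = 0.25,
                                post_recurrence_death_rate = 0.3,
                                covariate_dists = NULL,
                                seed = NULL) {
  n_per_cell <- rep_len(as.integer(n_per_cell), 4)
  if (any(n_per_cell < 0)) stop("n_per_cell must be >= 0", call. = FALSE)
  check_number(baseline_hazard, "baseline_hazard", 0, strict_lower = TRUE)
  check_number(hr_treatment_in_marker_neg, "hr_treatment_in_marker_neg",
               0, strict_lower = TRUE)
  check_number(hr_treatment_in_marker_pos, "hr_treatment_in_marker_pos",
               0, strict_lower = TRUE)
  check_number(hr_marker, "hr_marker", 0, strict_lower = TRUE)
  check_number(admin_censor_time, "admin_censor_time", 0,
               strict_lower = TRUE)
  check_number(p_death_first, "p_death_first", 0, 1)
  structure(list(n_per_cell = n_per_cell,
                 baseline_hazard = baseline_hazard,
                 hr_treatment_in_marker_neg = hr_treatment_in_marker_neg,
                 hr_treatment_in_marker_pos = hr_treatment_in_marker_pos,
                 hr_marker = hr_marker,
                 admin_censor_time = admin_censor_time,
                 p_death_first = p_death_first,
                 post_recurrence_death_rate = post_recurrence_death_rate,
                 covariate_dists = covariate_dists %||%
                   default_covariate_dists(),
                 seed = seed),
            class = "survival_sim_config")
}

#' Simulate a randomized two-arm cohort
#'
#' @param config A [survival_sim_config()].
#' @return `data.frame` of patient records: `id`, `arm`, `marker`,
#'   `time_to_recurrence`, `time_to_death` (NA when the event did not occur
#'   before censoring), `followup_time`, and the clinicopathologic
#'   covariates.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  cells <- expand.grid(arm = ARM_LEVELS, marker = CLASS_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n <- config$n_per_cell
  n <- sum(cells$n)
  arm <- rep(cells$arm, cells$n)
  marker <- rep(cells$marker, cells$n)
  treated <- arm == "TX+CEX"
  pos <- marker == BRCA1_LIKE
  hazard <- config$baseline_hazard *
    ifelse(pos, config$hr_marker, 1) *
    ifelse(treated,
           ifelse(pos, config$hr_treatment_in_marker_pos,
                  config$hr_treatment_in_marker_neg),
           1)

  with_seed(config$seed, {
    t_event <- stats::rexp(n, hazard)
    is_death_first <- stats::runif(n) < config$p_death_first
    cens <- config$admin_censor_time
    observed <- t_event <= cens

    time_to_recurrence <- rep(NA_real_, n)
    time_to_death <- rep(NA_real_, n)
    recur <- observed & !is_death_first
    time_to_recurrence[recur] <- t_event[recur]
    time_to_death[observed & is_death_first] <-
      t_event[observed & is_death_first]
    # deaths following an observed recurrence
    post <- t_event + stats::rexp(n, config$post_recurrence_death_rate)
    later_death <- recur & post <= cens
    time_to_death[later_death] <- post[later_death]

    cd <- config$covariate_dists
    age <- pmin(pmax(round(stats::rnorm(n, cd$age$mean, cd$age$sd)),
                     cd$age$min), cd$age$max)
    draw <- function(d) sample(d$levels, n, replace = TRUE, prob = d$prob)
    data.frame(id = paste0("pt", seq_len(n)),
               arm = factor(arm, ARM_LEVELS),
               marker = factor(marker, CLASS_LEVELS),
               time_to_recurrence = time_to_recurrence,
               time_to_death = time_to_death,
               followup_time = rep(cens, n),
               age = age,
               who_ps = draw(cd$who_ps),
               surgery = draw(cd$surgery),
               axillary = draw(cd$axillary),
               t_stage = draw(cd$t_stage),
               nodes = draw(cd$nodes),
               histology = draw(cd$histology),
               grade = draw(cd$grade),
               stringsAsFactors = FALSE)
  })
}
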