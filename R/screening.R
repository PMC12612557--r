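#' Screening policy: strategy rule + adherence + test performance
#'
#' Bundles everything the simulator needs to run screening for one
#' strategy: the [strategy_rule()], the (derived) [adherence_profile()],
#' per-modality [test_performance()], the per-colonoscopy complication
#' probability, and surveillance intervals by adenoma-history tier.
#' Routine screening and surveillance both stop after age
#' `screening_stop` (75).
#'
#' @param rule [strategy_rule()]
#' @param profile [adherence_profile()] (already derived for the strategy)
#' @param perf named list of [test_performance()] per modality
#' @param complication_prob per-colonoscopy complication probability
#' @param surveillance_intervals years between surveillance colonoscopies
#'   by tier (`low`, `high`)
#' @param screening_start,screening_stop first and last eligible ages
#' @return object of class `screening_policy`
#' @export
screening_policy <- function(rule, profile,
                             perf = default_test_performance(),
                             complication_prob = 0.002,
                             surveillance_intervals = c(low = 5L, high = 3L),
                             screening_start = 45L, screening_stop = 75L) {
  stopifnot(inherits(rule, "strategy_rule"),
            inherits(profile, "adherence_profile"))
  structure(list(rule = rule, profile = profile, perf = perf,
                 complication_prob = complication_prob,
                 surveillance_intervals = surveillance_intervals,
                 screening_start = as.integer(screening_start),
                 screening_stop = as.integer(screening_stop)),
            class = "screening_policy")
}

#' Policy under which nobody is ever screened
#' @param group one of [crc_groups()]
#' @return `screening_policy` with the no-screening rule
#' @export
no_screening_policy <- function(group) {
  sq <- default_status_quo_profile(group)
  screening_policy(strategy_rule("no_screening"),
                   derive_strategy_profile(sq, strategy_rule("no_screening")))
}

# positive probability and whether a positive reflects a real lesion,
# by health state (vectorised); clinical and dead states are invalid
test_positive_prob <- function(perf, state) {
  if (any(is_clinical(state) | is_dead(state))) {
    stop("tests only apply to non-clinical, living states", call. = FALSE)
  }
  p <- numeric(length(state))
  lesion <- rep(TRUE, length(state))
  p[state == STATES[["NO_LESION"]]] <- 1 - perf$specificity
  lesion[state == STATES[["NO_LESION"]]] <- FALSE
  p[state == STATES[["ADENOMA_DIMINUTIVE"]]] <- perf$sens_diminutive
  p[state == STATES[["ADENOMA_SMALL"]]] <- perf$sens_small
  p[state == STATES[["ADENOMA_LARGE"]]] <- perf$sens_large
  p[is_preclinical(state)] <- perf$sens_crc
  list(p = p, lesion = lesion)
}

#' Run one screening test on one or more persons
#'
#' Returns `positive_lesion` with the size/stage-matched sensitivity when
#' a detectable lesion (adenoma or preclinical CRC) is present,
#' `positive_false` with 1 - specificity when none is, else `negative`.
#'
#' @param modality one of `colonoscopy`, `ctc`, `fit`, `mtsdna`
#' @param state health-state code(s), non-clinical and alive
#' @param perf [test_performance()] for the modality
#' @param u uniform draw(s) in [0, 1); defaults to `runif`
#' @return character vector in \{negative, positive_lesion, positive_false\}
#' @export
run_test <- function(modality, state, perf, u = stats::runif(length(state))) {
  stopifnot(modality %in% MODALITIES, inherits(perf, "test_performance"))
  if (any(is.na(match(state, STATES)))) stop("unknown state", call. = FALSE)
  th <- test_positive_prob(perf, state)
  out <- rep("negative", length(state))
  pos <- u < th$p
  out[pos & th$lesion] <- "positive_lesion"
  out[pos & !th$lesion] <- "positive_false"
  out
}

band_initial <- function(age) findInterval(age, c(45, 50, 55, 60, 65, 70))
band_repeat <- function(age) ifelse(age < 65, 1L, 2L)

#' Annual routine-screening decision for one person
#'
#' No action after age `screening_stop` (75). Persons with an adenoma
#' history follow the surveillance pathway instead of routine screening.
#' Uninitiated persons draw against the age-band initial probability for
#' their origin modality; initiated persons draw against the repeat
#' probability once the modality interval has elapsed (retried annually
#' while overdue). Under the status quo a switching draw may change
#' modality at the due date.
#'
#' @param person list with `age`, `state`, `adenoma_history_tier` (0/1/2),
#'   `origin` ("colonoscopy" or "fit"), `initiated`, `next_due`,
#'   `modality` (current), `surv_due`
#' @param profile [adherence_profile()]
#' @param strategy [strategy_rule()]
#' @param u named uniforms (`initial`, `repeat`, `switch`, `surveillance`);
#'   defaults to fresh draws
#' @return list(action = one of none/screen/surveillance_colonoscopy,
#'   modality, person = updated person)
#' @export
annual_screening_decision <- function(person, profile, strategy,
                                      u = c(initial = stats::runif(1),
                                            "repeat" = stats::runif(1),
                                            switch = stats::runif(1),
                                            surveillance = stats::runif(1))) {
  a <- person$age
  if (is_dead(person$state)) stop("person must be alive", call. = FALSE)
  if (a > 75 || a < 45 || strategy$name == "no_screening" ||
      is_clinical(person$state)) {
    return(list(action = "none", modality = NA_character_, person = person))
  }
  if (person$adenoma_history_tier > 0L) {
    act <- surveillance_decision(person, profile, u[["surveillance"]])
    return(list(action = act, modality = "colonoscopy", person = person))
  }
  if (!isTRUE(person$initiated)) {
    p <- profile$initial[band_initial(a), person$origin]
    if (u[["initial"]] < p) {
      mod <- if (is.na(strategy$modality)) person$origin else strategy$modality
      person$initiated <- TRUE
      person$modality <- mod
      person$next_due <- a + modality_intervals()[[mod]]
      return(list(action = "screen", modality = mod, person = person))
    }
    return(list(action = "none", modality = NA_character_, person = person))
  }
  if (!is.null(person$next_due) && a >= person$next_due) {
    if (is.na(strategy$modality) && u[["switch"]] < profile$switch_prob) {
      person$modality <- if (person$modality == "colonoscopy") "fit" else "colonoscopy"
    }
    p <- profile$repeat_prob[band_repeat(a), person$modality]
    if (u[["repeat"]] < p) {
      person$next_due <- a + modality_intervals()[[person$modality]]
      return(list(action = "screen", modality = person$modality, person = person))
    }
  }
  list(action = "none", modality = NA_character_, person = person)
}

#' Diagnostic follow-up after a positive non-colonoscopy test
#'
#' Attendance is drawn at the modality-specific follow-up probability
#' (CTC 97.7%, FIT 48.7%, MT-sDNA 66.6% in the base case); attenders
#' receive a colonoscopy with colonoscopy performance in the same cycle.
#'
#' @param modality triggering modality (not colonoscopy)
#' @param profile [adherence_profile()]
#' @param u uniform draw(s)
#' @return logical: attends follow-up colonoscopy
#' @export
diagnostic_follow_up <- function(modality, profile, u = stats::runif(1)) {
  if (identical(modality, "colonoscopy")) {
    stop("colonoscopy needs no diagnostic follow-up", call. = FALSE)
  }
  stopifnot(modality %in% c("ctc", "fit", "mtsdna"))
  u < profile$followup[[modality]]
}

#' Surveillance-colonoscopy decision for a person with adenoma history
#'
#' At each due date (every 5 years for the low-risk tier, 3 for high-risk,
#' by default) a colonoscopy occurs with the tier-specific adherence;
#' non-attenders are retried at the next annual cycle while overdue.
#'
#' @param person list with `adenoma_history_tier` (1 = low, 2 = high) and
#'   `surv_due`, `age`
#' @param profile [adherence_profile()]
#' @param u uniform draw
#' @return "surveillance_colonoscopy" or "none"
#' @export
surveillance_decision <- function(person, profile, u = stats::runif(1)) {
  tier <- person$adenoma_history_tier
  if (is.null(tier) || tier == 0L) {
    stop("surveillance requires an adenoma history", call. = FALSE)
  }
  if (!is.null(person$surv_due) && !is.na(person$surv_due) &&
      person$age < person$surv_due) {
    return("none")
  }
  p <- profile$surveillance[[if (tier == 2L) "high" else "low"]]
  if (u < p) "surveillance_colonoscopy" else "none"
}

#' Resolve colonoscopy findings for one person
#'
#' Detected adenomas are removed (state returns to no-lesion) and the
#' adenoma-history tier is updated monotonically (small at least low-risk,
#' large high-risk). Detected preclinical cancer is diagnosed at its
#' current stage.
#'
#' @param person list with `state`, `adenoma_history_tier`, `age`
#' @param finding result of [run_test()] for the colonoscopy
#' @return updated person; `$events` lists what happened
#' @export
colonoscopy_resolution <- function(person, finding) {
  events <- character(0)
  if (finding == "positive_lesion") {
    s <- person$state
    if (is_adenoma(s)) {
      if (s == STATES[["ADENOMA_SMALL"]]) {
        person$adenoma_history_tier <- max(person$adenoma_history_tier, 1L)
      }
      if (s == STATES[["ADENOMA_LARGE"]]) {
        person$adenoma_history_tier <- 2L
      }
      person$state <- STATES[["NO_LESION"]]
      events <- c(events, "polypectomy")
    } else if (is_preclinical(s)) {
      person$state <- s + 4L
      person$dx_age <- person$age
      person$dx_stage <- state_stage(person$state)
      events <- c(events, "crc_diagnosis")
    }
  }
  person$events <- events
  person
}
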