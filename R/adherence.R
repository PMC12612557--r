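#' Screening modalities and their guideline intervals
#'
#' Colonoscopy every 10 years, CT colonography (CTC) every 5, FIT annually,
#' multitarget stool DNA (MT-sDNA) every 3 years.
#'
#' @return named integer vector of recommended intervals in years
#' @export
modality_intervals <- function() {
  c(colonoscopy = 10L, ctc = 5L, fit = 1L, mtsdna = 3L)
}

MODALITIES <- c("colonoscopy", "ctc", "fit", "mtsdna")
AGE_BANDS_INITIAL <- c("45-49", "50-54", "55-59", "60-64", "65-69", "70-75")
AGE_BANDS_REPEAT <- c("<65", ">=65")

#' Patient-level test performance
#'
#' Sensitivity by lesion class (adenomas by size; preclinical CRC) and
#' specificity. In the base case CTC has zero sensitivity for diminutive
#' adenomas because lesions under 6 mm are not referred for follow-up.
#'
#' @param sens_diminutive,sens_small,sens_large,sens_crc sensitivities
#' @param specificity test specificity
#' @return object of class `test_performance`
#' @export
test_performance <- function(sens_diminutive, sens_small, sens_large,
                             sens_crc, specificity) {
  p <- c(sens_diminutive = sens_diminutive, sens_small = sens_small,
         sens_large = sens_large, sens_crc = sens_crc,
         specificity = specificity)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("test performance values must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(p), class = "test_performance")
}

#' Base-case test characteristics for all four modalities
#'
#' @return named list of [test_performance()] objects
#'   (colonoscopy, ctc, fit, mtsdna)
#' @export
default_test_performance <- function() {
  list(
    colonoscopy = test_performance(0.75, 0.85, 0.95, 0.95, 0.86),
    ctc         = test_performance(0.00, 0.786, 0.879, 0.961, 0.88),
    fit         = test_performance(0.076, 0.076, 0.238, 0.738, 0.964),
    mtsdna      = test_performance(0.172, 0.172, 0.424, 0.923, 0.898)
  )
}

#' Adherence schedule for one demographic group under one strategy
#'
#' Holds the three-component behavioural model: annual initial-screening
#' probabilities by age band and by the modality the person would have
#' chosen under the status quo (their "origin"), annual repeat-screening
#' probabilities by age band (<65, >=65) and current modality, the
#' probability of switching modality at a due date (status quo only),
#' diagnostic follow-up adherence after a positive non-colonoscopy test,
#' and surveillance-colonoscopy adherence by adenoma-history tier.
#'
#' @param group one of [crc_groups()]
#' @param pre45 named vector (`colonoscopy`, `fit`): fraction of the
#'   population already screened before 45, by origin modality
#' @param initial 6 x 2 matrix of annual initial-screening probabilities;
#'   rows are age bands 45-49 ... 70-75, columns origins (colonoscopy, fit)
#' @param repeat_prob 2 x m matrix of annual repeat probabilities; rows are
#'   age bands (<65, >=65), columns the modalities usable under the strategy
#' @param switch_prob probability of switching modality at the next due
#'   date (status quo only; calibrated, default 0)
#' @param followup diagnostic-colonoscopy adherence after a positive
#'   non-colonoscopy test, named by modality
#' @param surveillance surveillance adherence by tier (`low`, `high`)
#' @param origin_frac_colonoscopy fraction of the never-screened population
#'   whose origin modality is colonoscopy (default: the pre-45 split)
#' @return object of class `adherence_profile`
#' @export
adherence_profile <- function(group, pre45, initial, repeat_prob,
                              switch_prob = 0,
                              followup = c(ctc = 0.977, fit = 0.487, mtsdna = 0.666),
                              surveillance = c(low = 0.447, high = 0.546),
                              origin_frac_colonoscopy =
                                unname(pre45[["colonoscopy"]] / sum(pre45))) {
  check_group(group)
  probs <- c(pre45, initial, repeat_prob, switch_prob, followup,
             surveillance, origin_frac_colonoscopy)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all adherence probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(identical(dim(initial), c(6L, 2L)),
            nrow(repeat_prob) == 2L)
  if (any(apply(initial, 2, function(col) any(diff(col) > 1e-9)))) {
    stop("initial probabilities must be non-increasing across age bands",
         call. = FALSE)
  }
  dimnames(initial) <- list(AGE_BANDS_INITIAL, c("colonoscopy", "fit"))
  rownames(repeat_prob) <- AGE_BANDS_REPEAT
  structure(list(group = group, pre45 = pre45, initial = initial,
                 repeat_prob = repeat_prob, switch_prob = switch_prob,
                 followup = followup, surveillance = surveillance,
                 origin_frac_colonoscopy = origin_frac_colonoscopy),
            class = "adherence_profile")
}

#' Status-quo adherence schedules by race and gender
#'
#' Packaged annual probabilities of initial and repeat screening under the
#' real-world mix of colonoscopy and FIT, by demographic group: percent
#' screened before 45, initial probabilities by age band and origin
#' modality, and repeat probabilities by age band and modality.
#'
#' @param group one of [crc_groups()]
#' @return [adherence_profile()] for the status quo strategy
#' @export
default_status_quo_profile <- function(group) {
  check_group(group)
  pre45 <- list(
    "White men"   = c(colonoscopy = 0.224, fit = 0.087),
    "Black men"   = c(colonoscopy = 0.243, fit = 0.090),
    "White women" = c(colonoscopy = 0.239, fit = 0.091),
    "Black women" = c(colonoscopy = 0.202, fit = 0.103)
  )[[group]]
  initial <- list(
    "White men"   = cbind(colonoscopy = c(0.081, 0.042, 0.024, 0.013, 0.007, 0.007),
                          fit         = c(0.031, 0.016, 0.008, 0.004, 0.002, 0.002)),
    "Black men"   = cbind(colonoscopy = c(0.063, 0.032, 0.021, 0.012, 0.007, 0.007),
                          fit         = c(0.026, 0.012, 0.006, 0.004, 0.002, 0.002)),
    "White women" = cbind(colonoscopy = c(0.081, 0.039, 0.017, 0.008, 0.004, 0.004),
                          fit         = c(0.035, 0.016, 0.007, 0.004, 0.002, 0.002)),
    "Black women" = cbind(colonoscopy = c(0.070, 0.039, 0.020, 0.011, 0.006, 0.006),
                          fit         = c(0.020, 0.009, 0.004, 0.002, 0.001, 0.001))
  )[[group]]
  repeat_prob <- list(
    "White men"   = cbind(colonoscopy = c(0.239, 0.565), fit = c(0.280, 0.561)),
    "Black men"   = cbind(colonoscopy = c(0.202, 0.647), fit = c(0.284, 0.587)),
    "White women" = cbind(colonoscopy = c(0.304, 0.566), fit = c(0.322, 0.616)),
    "Black women" = cbind(colonoscopy = c(0.260, 0.587), fit = c(0.339, 0.641))
  )[[group]]
  adherence_profile(group, pre45, initial, repeat_prob)
}

#' Screening strategy rules
#'
#' Each rule names the modality offered (none for no-screening; the
#' status-quo keeps the real-world colonoscopy/FIT mix), the relative-risk
#' multipliers applied to status-quo initial adherence by origin modality,
#' and where repeat adherence comes from. For the CTC-only strategy Black
#' groups' repeat adherence is odds-adjusted upward (OR 1.83).
#'
#' @param name one of `no_screening`, `status_quo`, `ctc_only`,
#'   `colonoscopy_only`, `fit_only`, `mtsdna_only`
#' @return object of class `strategy_rule`
#' @export
strategy_rule <- function(name = c("no_screening", "status_quo", "ctc_only",
                                   "colonoscopy_only", "fit_only", "mtsdna_only")) {
  name <- match.arg(name)
  spec <- switch(name,
    no_screening     = list(modality = NA_character_, mult = c(colonoscopy = 0, fit = 0),
                            repeat_source = NA_character_, or_black = 1),
    status_quo       = list(modality = NA_character_, mult = c(colonoscopy = 1, fit = 1),
                            repeat_source = "own", or_black = 1),
    ctc_only         = list(modality = "ctc", mult = c(colonoscopy = 1.80, fit = 0.53),
                            repeat_source = "colonoscopy", or_black = 1.83),
    colonoscopy_only = list(modality = "colonoscopy", mult = c(colonoscopy = 1.00, fit = 0.29),
                            repeat_source = "colonoscopy", or_black = 1),
    fit_only         = list(modality = "fit", mult = c(colonoscopy = 3.45, fit = 1.00),
                            repeat_source = "fit", or_black = 1),
    mtsdna_only      = list(modality = "mtsdna", mult = c(colonoscopy = 3.45, fit = 1.00),
                            repeat_source = "fit", or_black = 1)
  )
  structure(c(list(name = name), spec), class = "strategy_rule")
}

#' All six strategies compared in the analysis
#' @return named list of [strategy_rule()] objects
#' @export
strategy_rules <- function() {
  nm <- c("no_screening", "status_quo", "ctc_only", "colonoscopy_only",
          "fit_only", "mtsdna_only")
  stats::setNames(lapply(nm, strategy_rule), nm)
}

#' Apply a relative-risk multiplier to an initial-screening probability
#'
#' Initial adherence under a single-modality strategy is the status-quo
#' probability times the origin-specific relative risk, clipped at 1.
#'
#' @param p status-quo annual probability in [0, 1]
#' @param rr relative-risk multiplier (> 0, or 0 to disable screening)
#' @return min(1, p * rr)
#' @export
apply_initial_multiplier <- function(p, rr) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr < 0)) stop("rr must be >= 0", call. = FALSE)
  pmin(1, p * rr)
}

#' Odds-ratio adjustment of a repeat-screening probability
#'
#' Converts the probability to odds, multiplies by the odds ratio, and
#' converts back: (or * p / (1 - p)) / (1 + or * p / (1 - p)).
#'
#' @param p probability in [0, 1)
#' @param or odds ratio (> 0)
#' @return adjusted probability
#' @export
apply_repeat_odds_ratio <- function(p, or) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("p must lie in [0, 1); p = 1 has infinite odds", call. = FALSE)
  }
  if (any(!is.finite(or)) || any(or <= 0)) stop("or must be > 0", call. = FALSE)
  o <- or * p / (1 - p)
  o / (1 + o)
}

#' Derive a strategy's adherence profile from the status quo
#'
#' Initial schedules are the status-quo schedules times the rule's
#' origin-specific multiplier (clipped at 1). Repeat schedules follow the
#' rule's source: single-modality strategies use the status-quo repeat
#' adherence of the stated source modality for all origins (CTC additionally
#' odds-adjusts Black groups by OR 1.83). The pre-45 screened fractions
#' carry over unchanged and switching is disabled for single-modality
#' strategies.
#'
#' @param status_quo [adherence_profile()] for the group
#' @param rule [strategy_rule()]
#' @param group one of [crc_groups()]
#' @return derived [adherence_profile()]
#' @export
derive_strategy_profile <- function(status_quo, rule, group = status_quo$group) {
  stopifnot(inherits(status_quo, "adherence_profile"))
  if (!inherits(rule, "strategy_rule")) stop("unknown rule", call. = FALSE)
  check_group(group)
  if (rule$name == "status_quo") return(status_quo)
  if (rule$name == "no_screening") {
    prof <- status_quo
    prof$initial[] <- 0
    prof$repeat_prob[] <- 0
    prof$switch_prob <- 0
    return(prof)
  }
  initial <- status_quo$initial
  initial[, "colonoscopy"] <- apply_initial_multiplier(
    initial[, "colonoscopy"], rule$mult[["colonoscopy"]])
  initial[, "fit"] <- apply_initial_multiplier(
    initial[, "fit"], rule$mult[["fit"]])
  rep_src <- status_quo$repeat_prob[, rule$repeat_source]
  if (rule$or_black != 1 && group_race(group) == "Black") {
    rep_src <- apply_repeat_odds_ratio(rep_src, rule$or_black)
  }
  repeat_prob <- matrix(rep_src, ncol = 1,
                        dimnames = list(AGE_BANDS_REPEAT, rule$modality))
  adherence_profile(group, status_quo$pre45, initial, repeat_prob,
                    switch_prob = 0, followup = status_quo$followup,
                    surveillance = status_quo$surveillance,
                    origin_frac_colonoscopy = status_quo$origin_frac_colonoscopy)
}

#' Write / read an adherence profile as keyed text
#'
#' Mirrors the panel structure of the published adherence tables: one key
#' per cell (`initial_45-49_colonoscopy`, `repeat_<65_fit`, ...).
#'
#' @param profile [adherence_profile()]
#' @param path file path
#' @return path invisibly; the reader returns an `adherence_profile`
#' @export
write_adherence_profile <- function(profile, path) {
  stopifnot(inherits(profile, "adherence_profile"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  ini <- expand.grid(band = rownames(profile$initial),
                     origin = colnames(profile$initial), stringsAsFactors = FALSE)
  band_key <- c("<65" = "lt65", ">=65" = "ge65")
  rep_g <- expand.grid(band = rownames(profile$repeat_prob),
                       modality = colnames(profile$repeat_prob),
                       stringsAsFactors = FALSE)
  lines <- c(
    paste0("group = ", profile$group),
    paste0("pre45_", names(profile$pre45), " = ", num(profile$pre45)),
    paste0("initial_", ini$band, "_", ini$origin, " = ",
           num(profile$initial[cbind(ini$band, ini$origin)])),
    paste0("repeat_", band_key[rep_g$band], "_", rep_g$modality, " = ",
           num(profile$repeat_prob[cbind(rep_g$band, rep_g$modality)])),
    paste0("switch_prob = ", num(profile$switch_prob)),
    paste0("followup_", names(profile$followup), " = ", num(profile$followup)),
    paste0("surveillance_", names(profile$surveillance), " = ",
           num(profile$surveillance)),
    paste0("origin_frac_colonoscopy = ", num(profile$origin_frac_colonoscopy))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_adherence_profile
#' @export
read_adherence_profile <- function(path) {
  kv <- read_keyed_config(path)
  getn <- function(k) as.numeric(kv[[k]])
  initial <- matrix(0, 6, 2, dimnames = list(AGE_BANDS_INITIAL,
                                             c("colonoscopy", "fit")))
  for (b in AGE_BANDS_INITIAL) for (o in c("colonoscopy", "fit")) {
    initial[b, o] <- getn(paste0("initial_", b, "_", o))
  }
  band_key <- c("<65" = "lt65", ">=65" = "ge65")
  rep_keys <- grep("^repeat_", names(kv), value = TRUE)
  mods <- unique(sub("^repeat_(lt65|ge65)_", "", rep_keys))
  repeat_prob <- matrix(0, 2, length(mods),
                        dimnames = list(AGE_BANDS_REPEAT, mods))
  for (b in AGE_BANDS_REPEAT) for (m in mods) {
    repeat_prob[b, m] <- getn(paste0("repeat_", band_key[[b]], "_", m))
  }
  adherence_profile(
    group = kv$group,
    pre45 = c(colonoscopy = getn("pre45_colonoscopy"), fit = getn("pre45_fit")),
    initial = initial, repeat_prob = repeat_prob,
    switch_prob = getn("switch_prob"),
    followup = c(ctc = getn("followup_ctc"), fit = getn("followup_fit"),
                 mtsdna = getn("followup_mtsdna")),
    surveillance = c(low = getn("surveillance_low"),
                     high = getn("surveillance_high")),
    origin_frac_colonoscopy = getn("origin_frac_colonoscopy")
  )
}
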