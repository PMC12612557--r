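# Known-truth generator: everything the pipeline consumes can be produced
# here, so calibration is testable by parameter recovery and the full
# analysis runs end-to-end without external data.

#' Generate a known-truth parameter specification
#'
#' Draws a deterministic-per-seed truth around the reference
#' natural-history parameters: multiplicative scales on adenoma onset,
#' adenoma growth, the large-adenoma malignant-transformation rate, the
#' clinical-detection rates, and on status-quo initial screening
#' adherence. Scale magnitudes are jittered log-normally (onset tightly,
#' the progression and adherence scales more broadly) around reference
#' values whose unjittered no-screening lifetime CRC risk sits between
#' 7% and 9%; jittered truths stay inside the generator's design band of
#' 55-115 clinical cases per 1000 without screening.
#'
#' @param seed integer seed
#' @param group one of [crc_groups()]
#' @param noise relative SD of multiplicative target noise (default 0.05)
#' @return object of class `truth_spec`: `$scales`, `$params`
#'   ([disease_params()]), `$profile` ([adherence_profile()]), `$noise`
#' @export
make_truth <- function(seed, group, noise = 0.05) {
  check_group(group)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  set.seed(seed * 17L + match(group, crc_groups()))
  jitter <- function(sd = 0.10, lo = 0.80, hi = 1.25) {
    min(max(exp(stats::rnorm(1, 0, sd)), lo), hi)
  }
  scales <- c(onset_scale = jitter(0.06, 0.90, 1.12),
              growth_scale = jitter(),
              large_to_preclinical = 0.05 * jitter(),
              clin_detect_scale = jitter(),
              initial_adherence_scale = jitter())
  params <- apply_param_scales(default_disease_params(group), scales)
  profile <- scale_initial_adherence(default_status_quo_profile(group),
                                     scales[["initial_adherence_scale"]])
  structure(list(group = group, scales = scales, params = params,
                 profile = profile, noise = noise, seed = seed,
                 design_band_per_1000 = c(55, 115)),
            class = "truth_spec")
}

#' Scale a profile's initial-adherence schedule
#'
#' @param profile [adherence_profile()]
#' @param scale multiplicative factor, clipped at probability 1
#' @return scaled profile
#' @export
scale_initial_adherence <- function(profile, scale) {
  profile$initial <- pmin(profile$initial * scale, 1)
  profile
}

#' Generate noisy calibration targets from a truth specification
#'
#' Simulates a large cohort at the truth parameters and perturbs every
#' summary with independent multiplicative log-normal noise at the
#' truth's relative SD. Emits all target families: age-band incidence,
#' stage mix by era, adenoma prevalence, ever-screened proportions and
#' recency.
#'
#' @param truth [make_truth()] output
#' @param seed seed for the noise draws (and the target simulation)
#' @param n cohort size of the target-generating simulation
#' @param summaries optional precomputed [summarize_for_targets()] vector
#'   (skips the simulation; used when drawing many noise replicates)
#' @return [calibration_targets()]
#' @export
make_targets <- function(truth, seed, n = 50000L, summaries = NULL) {
  stopifnot(inherits(truth, "truth_spec"))
  s <- if (is.null(summaries)) {
    summarize_for_targets(truth$params, truth$profile, truth$group,
                          n = n, seed = seed)
  } else summaries
  set.seed(seed * 31L + 7L)
  noisy <- s * exp(stats::rnorm(length(s), 0, truth$noise))
  calibration_targets(name = names(s), group = truth$group,
                      age_band = "", value = unname(noisy), weight = 1)
}

#' Packaged base-case inputs
#'
#' The published base-case test characteristics, the status-quo
#' adherence schedules for all four demographic groups, and the six
#' strategy rules, as used throughout the analysis.
#'
#' @return list with `test_performance`, `profiles` (per group),
#'   `strategies`
#' @export
packaged_defaults <- function() {
  list(
    test_performance = default_test_performance(),
    profiles = stats::setNames(lapply(crc_groups(), default_status_quo_profile),
                               crc_groups()),
    strategies = strategy_rules()
  )
}
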