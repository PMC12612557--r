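#' Annual other-cause mortality life table
#'
#' Packaged illustrative gender-specific life table built from a
#' Gompertz-Makeham hazard, giving remaining life expectancy at age 40 of
#' roughly 38 years for men and 42 for women. It is a stand-in for a
#' national life table and is swappable through the `life_table` field of
#' [disease_params()].
#'
#' @param gender "men" or "women"
#' @param ages integer ages covered (default 20-110)
#' @return data.frame with columns `age` and `qx` (annual death probability)
#' @export
default_life_table <- function(gender = c("men", "women"), ages = 20:110) {
  gender <- match.arg(gender)
  A <- 5e-4
  B <- if (gender == "men") 2.5e-5 else 1.5e-5
  theta <- 0.095
  qx <- pmin(1, A + B * exp(theta * ages))
  data.frame(age = as.integer(ages), qx = qx)
}

#' Natural-history parameters of the adenoma-carcinoma sequence
#'
#' Bundles all annual transition probabilities of the disease model for one
#' demographic group: adenoma onset by age band, adenoma growth by size,
#' malignant transformation of large adenomas, preclinical stage
#' progression, clinical (symptomatic) detection by preclinical stage, and
#' stage-specific excess CRC mortality applied for a fixed number of years
#' after diagnosis, on top of an other-cause life table.
#'
#' @param group one of [crc_groups()]
#' @param onset named annual onset probabilities; names are the lower bounds
#'   of the age bands (e.g. `"20"`, `"30"`, ...)
#' @param growth_dim_small,growth_small_large annual adenoma growth probabilities
#' @param large_to_preclinical annual probability a large adenoma becomes
#'   preclinical stage-I cancer
#' @param stage_progression annual preclinical progression probabilities
#'   (I to II, II to III, III to IV)
#' @param clinical_detection annual probability a preclinical cancer of each
#'   stage presents clinically (geometric sojourn model)
#' @param crc_excess_mortality annual excess death probability by clinical
#'   stage, applied for `crc_mortality_years` after diagnosis
#' @param crc_mortality_years years of excess mortality post-diagnosis
#' @param life_table data.frame (`age`, `qx`) of other-cause mortality
#' @return object of class `disease_params`
#' @export
disease_params <- function(group,
                           onset,
                           growth_dim_small,
                           growth_small_large,
                           large_to_preclinical,
                           stage_progression,
                           clinical_detection,
                           crc_excess_mortality,
                           crc_mortality_years = 10L,
                           life_table = default_life_table(group_gender(group))) {
  check_group(group)
  p <- list(
    group = group,
    onset = onset,
    growth_dim_small = growth_dim_small,
    growth_small_large = growth_small_large,
    large_to_preclinical = large_to_preclinical,
    stage_progression = stage_progression,
    clinical_detection = clinical_detection,
    crc_excess_mortality = crc_excess_mortality,
    crc_mortality_years = as.integer(crc_mortality_years),
    life_table = life_table
  )
  class(p) <- "disease_params"
  validate_disease_params(p)
}

validate_disease_params <- function(p) {
  stopifnot(inherits(p, "disease_params"))
  probs <- c(p$onset, p$growth_dim_small, p$growth_small_large,
             p$large_to_preclinical, p$stage_progression,
             p$clinical_detection, p$crc_excess_mortality, p$life_table$qx)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all disease-model rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(names(p$onset)) || any(is.na(suppressWarnings(as.numeric(names(p$onset)))))) {
    stop("onset must be named by age-band lower bounds", call. = FALSE)
  }
  if (length(p$stage_progression) != 3L || length(p$clinical_detection) != 4L ||
      length(p$crc_excess_mortality) != 4L) {
    stop("stage_progression needs 3 entries; clinical_detection and ",
         "crc_excess_mortality need 4", call. = FALSE)
  }
  qx40 <- p$life_table$qx[p$life_table$age >= 40]
  if (any(diff(qx40) < -1e-12)) {
    stop("other-cause mortality must be non-decreasing beyond age 40", call. = FALSE)
  }
  p
}

# onset probability at integer ages (vectorised)
onset_at_age <- function(params, age) {
  lo <- as.numeric(names(params$onset))
  idx <- findInterval(age, lo)
  out <- numeric(length(age))
  out[idx >= 1] <- unname(params$onset)[idx[idx >= 1]]
  out
}

# other-cause death probability at integer ages (clamped to table range)
qx_at_age <- function(params, age) {
  lt <- params$life_table
  idx <- pmin(pmax(age, min(lt$age)), max(lt$age)) - min(lt$age) + 1L
  lt$qx[idx]
}

#' Reference natural-history parameters per demographic group
#'
#' Central parameter values used as the anchor of the synthetic-truth
#' generator and as the baseline that calibration scales. Magnitudes were
#' chosen once so that lifetime clinical CRC risk without screening lands
#' in the 6.7%-8.4% range across groups, with adenoma prevalence rising to
#' roughly a third of the population by the sixties.
#'
#' @param group one of [crc_groups()]
#' @return `disease_params` object
#' @export
default_disease_params <- function(group) {
  check_group(group)
  onset_scale <- c("White men" = 0.83, "Black men" = 0.64,
                   "White women" = 0.64, "Black women" = 0.60)[[group]]
  disease_params(
    group = group,
    onset = c("20" = 0.002, "30" = 0.005, "40" = 0.010,
              "50" = 0.014, "60" = 0.017, "70" = 0.018) * onset_scale,
    growth_dim_small = 0.08,
    growth_small_large = 0.06,
    large_to_preclinical = 0.05,
    stage_progression = c(0.35, 0.45, 0.50),
    clinical_detection = c(0.22, 0.36, 0.60, 0.88),
    crc_excess_mortality = c(0.02, 0.06, 0.14, 0.45)
  )
}

#' Scale free natural-history / adherence parameters
#'
#' Applies the calibration search's scale vector to a baseline parameter
#' set. Recognised names: `onset_scale` (multiplies every onset band),
#' `growth_scale` (both adenoma growth rates), `large_to_preclinical`
#' (replaces the value), `clin_detect_scale` (multiplies all clinical
#' detection probabilities). All products are clipped to [0, 1].
#'
#' @param params baseline `disease_params`
#' @param scales named numeric vector
#' @return scaled `disease_params`
#' @export
apply_param_scales <- function(params, scales) {
  stopifnot(inherits(params, "disease_params"))
  s <- function(name, default = 1) if (name %in% names(scales)) scales[[name]] else default
  params$onset <- pmin(params$onset * s("onset_scale"), 1)
  params$growth_dim_small <- min(1, params$growth_dim_small * s("growth_scale"))
  params$growth_small_large <- min(1, params$growth_small_large * s("growth_scale"))
  if ("large_to_preclinical" %in% names(scales)) {
    params$large_to_preclinical <- min(1, scales[["large_to_preclinical"]])
  }
  params$clinical_detection <- pmin(params$clinical_detection * s("clin_detect_scale"), 1)
  validate_disease_params(params)
}

#' Read / write disease parameters as flat keyed text
#'
#' One rate per `key = value` line; age bands are explicit in the key
#' (`onset_40`, `qx_73`, ...). Round-trips bit-identically through
#' [read_disease_params()].
#'
#' @param params `disease_params` object
#' @param path file path
#' @return `write_disease_params` returns `path` invisibly;
#'   `read_disease_params` returns a `disease_params` object.
#' @export
write_disease_params <- function(params, path) {
  stopifnot(inherits(params, "disease_params"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("group = ", params$group),
    paste0("onset_", names(params$onset), " = ", num(params$onset)),
    paste0("growth_dim_small = ", num(params$growth_dim_small)),
    paste0("growth_small_large = ", num(params$growth_small_large)),
    paste0("large_to_preclinical = ", num(params$large_to_preclinical)),
    paste0("stage_progression_", 1:3, " = ", num(params$stage_progression)),
    paste0("clinical_detection_", 1:4, " = ", num(params$clinical_detection)),
    paste0("crc_excess_mortality_", 1:4, " = ", num(params$crc_excess_mortality)),
    paste0("crc_mortality_years = ", params$crc_mortality_years),
    paste0("qx_", params$life_table$age, " = ", num(params$life_table$qx))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_disease_params
#' @export
read_disease_params <- function(path) {
  kv <- read_keyed_config(path)
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "_[0-9]+$"), names(kv), value = TRUE)
    ord <- order(as.numeric(sub(paste0("^", prefix, "_"), "", keys)))
    v <- as.numeric(unlist(kv[keys[ord]]))
    names(v) <- sub(paste0("^", prefix, "_"), "", keys[ord])
    v
  }
  qx <- pick("qx")
  disease_params(
    group = kv$group,
    onset = pick("onset"),
    growth_dim_small = as.numeric(kv$growth_dim_small),
    growth_small_large = as.numeric(kv$growth_small_large),
    large_to_preclinical = as.numeric(kv$large_to_preclinical),
    stage_progression = unname(pick("stage_progression")),
    clinical_detection = unname(pick("clinical_detection")),
    crc_excess_mortality = unname(pick("crc_excess_mortality")),
    crc_mortality_years = as.integer(kv$crc_mortality_years),
    life_table = data.frame(age = as.integer(names(qx)), qx = unname(qx))
  )
}
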