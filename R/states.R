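#' Health-state codes for the adenoma-carcinoma natural history
#'
#' The model tracks the single most advanced lesion per person: no lesion,
#' adenomas by size (diminutive 1-5 mm, small 6-9 mm, large >= 10 mm),
#' preclinical and clinical colorectal cancer by stage I-IV, and two
#' absorbing death states (CRC death, other-cause death).
#'
#' @format Named integer vector of state codes.
#' @export
STATES <- c(
  NO_LESION          = 1L,
  ADENOMA_DIMINUTIVE = 2L,
  ADENOMA_SMALL      = 3L,
  ADENOMA_LARGE      = 4L,
  PRECLINICAL_CRC_I  = 5L,
  PRECLINICAL_CRC_II = 6L,
  PRECLINICAL_CRC_III = 7L,
  PRECLINICAL_CRC_IV = 8L,
  CLINICAL_CRC_I     = 9L,
  CLINICAL_CRC_II    = 10L,
  CLINICAL_CRC_III   = 11L,
  CLINICAL_CRC_IV    = 12L,
  DEAD_CRC           = 13L,
  DEAD_OTHER         = 14L
)

#' @rdname STATES
#' @export
state_label <- function(code) names(STATES)[match(code, STATES)]

is_alive      <- function(s) s < STATES[["DEAD_CRC"]]
is_adenoma    <- function(s) s >= STATES[["ADENOMA_DIMINUTIVE"]] & s <= STATES[["ADENOMA_LARGE"]]
is_preclinical <- function(s) s >= STATES[["PRECLINICAL_CRC_I"]] & s <= STATES[["PRECLINICAL_CRC_IV"]]
is_clinical   <- function(s) s >= STATES[["CLINICAL_CRC_I"]] & s <= STATES[["CLINICAL_CRC_IV"]]
is_dead       <- function(s) s >= STATES[["DEAD_CRC"]]

# stage number (1-4) of a preclinical or clinical state, NA otherwise
state_stage <- function(s) {
  out <- rep(NA_integer_, length(s))
  pre <- is_preclinical(s)
  cli <- is_clinical(s)
  out[pre] <- s[pre] - STATES[["PRECLINICAL_CRC_I"]] + 1L
  out[cli] <- s[cli] - STATES[["CLINICAL_CRC_I"]] + 1L
  out
}

#' Demographic groups modelled
#'
#' Screening adherence and disease progression are stratified by race
#' (Black, White) and gender (men, women).
#'
#' @return Character vector of the four group labels.
#' @export
crc_groups <- function() {
  c("White men", "Black men", "White women", "Black women")
}

group_race   <- function(group) ifelse(grepl("^Black", group), "Black", "White")
group_gender <- function(group) ifelse(grepl("men$", group) & !grepl("women$", group), "men", "women")

check_group <- function(group) {
  if (length(group) != 1L || !group %in% crc_groups()) {
    stop("unknown demographic group: ", paste(group, collapse = ", "),
         " (expected one of: ", paste(crc_groups(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(group)
}

# draw-purpose channel codes for the counter-based RNG
CH <- list(
  burnin_prog   = 1L,
  onset         = 2L,
  progression   = 3L,
  clin_detect   = 4L,
  death_other   = 5L,
  death_crc     = 6L,
  screen_initial = 7L,
  screen_repeat = 8L,
  screen_switch = 9L,
  test_result   = 10L,
  followup      = 11L,
  followup_test = 12L,
  surveillance  = 13L,
  complication  = 14L,
  assign_origin = 15L,
  assign_pre45  = 16L
)
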