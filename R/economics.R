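#' Discounting specification
#'
#' @param rate annual discount rate (default 3%)
#' @param reference_age age from which years are counted (cohort start)
#' @return object of class `discount_spec`
#' @export
discount_spec <- function(rate = 0.03, reference_age = 40L) {
  if (!is.numeric(rate) || rate < 0) stop("rate must be >= 0", call. = FALSE)
  structure(list(rate = rate, reference_age = as.integer(reference_age)),
            class = "discount_spec")
}

#' Discount a value to the reference year
#'
#' @param amount value(s)
#' @param years_from_reference non-negative year offset(s)
#' @param spec [discount_spec()]
#' @return amount * (1 + rate)^(-years)
#' @export
discount <- function(amount, years_from_reference, spec = discount_spec()) {
  if (any(years_from_reference < 0)) {
    stop("years_from_reference must be >= 0", call. = FALSE)
  }
  amount * (1 + spec$rate)^(-years_from_reference)
}

#' Per-event cost schedule (2024 USD)
#'
#' Screening costs bundle procedure, bowel preparation and patient (and,
#' for facility procedures, escort) time; stool tests carry the kit plus
#' one hour of patient time. Cancer-care costs follow the usual
#' three-phase structure: initial year after diagnosis, continuing years,
#' and a terminal year preceding CRC death, each by stage. The packaged
#' values are illustrative placeholders on realistic scales, editable via
#' [write_cost_schedule()] config files.
#'
#' @param screen named vector of per-test screening costs by modality
#' @param diagnostic_colonoscopy,surveillance_colonoscopy,polypectomy,complication scalars
#' @param cancer_initial,cancer_continuing,cancer_terminal stage I-IV vectors
#' @return object of class `cost_schedule`
#' @export
cost_schedule <- function(screen = c(colonoscopy = 1600, ctc = 600,
                                     fit = 50, mtsdna = 535),
                          diagnostic_colonoscopy = 1800,
                          surveillance_colonoscopy = 1700,
                          polypectomy = 250,
                          complication = 9000,
                          cancer_initial = c(95000, 130000, 175000, 235000),
                          cancer_continuing = c(5000, 7000, 10000, 16000),
                          cancer_terminal = c(140000, 155000, 170000, 185000)) {
  vals <- c(screen, diagnostic_colonoscopy, surveillance_colonoscopy,
            polypectomy, complication, cancer_initial, cancer_continuing,
            cancer_terminal)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all costs must be non-negative", call. = FALSE)
  }
  structure(list(screen = screen,
                 diagnostic_colonoscopy = diagnostic_colonoscopy,
                 surveillance_colonoscopy = surveillance_colonoscopy,
                 polypectomy = polypectomy, complication = complication,
                 cancer_initial = cancer_initial,
                 cancer_continuing = cancer_continuing,
                 cancer_terminal = cancer_terminal),
            class = "cost_schedule")
}

#' @rdname cost_schedule
#' @export
default_cost_schedule <- function() cost_schedule()

#' Utility schedule: baseline by age and disutility decrements
#'
#' Baseline utility is age-banded. Each transient event carries a
#' disutility magnitude and duration (in years, at most one cycle); the
#' QALY loss booked at the event is magnitude x duration. Diagnosed
#' cancer carries a stage-specific annual utility decrement for every year
#' lived after diagnosis. Packaged values are illustrative placeholders.
#'
#' @param baseline named vector of utilities; names are age-band lower bounds
#' @param decrements data.frame(event, magnitude, duration_years)
#' @param cancer_annual stage I-IV annual utility decrements
#' @return object of class `utility_schedule`
#' @export
utility_schedule <- function(baseline = c("40" = 0.92, "50" = 0.90, "60" = 0.87,
                                          "70" = 0.84, "80" = 0.79, "90" = 0.74),
                             decrements = data.frame(
                               event = c("screen_colonoscopy", "screen_ctc",
                                         "screen_fit", "screen_mtsdna",
                                         "diagnostic_colonoscopy",
                                         "surveillance_colonoscopy",
                                         "polypectomy", "complication"),
                               magnitude = c(0.12, 0.06, 0.006, 0.006,
                                             0.12, 0.12, 0, 0.20),
                               duration_years = c(2 / 365, 2 / 365, 1 / 12,
                                                  1 / 12, 2 / 365, 2 / 365,
                                                  0, 1 / 12)),
                             cancer_annual = c(0.05, 0.10, 0.18, 0.30)) {
  if (any(baseline < 0) || any(baseline > 1)) {
    stop("baseline utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(decrements$magnitude < 0) || any(decrements$duration_years < 0) ||
      any(cancer_annual < 0)) {
    stop("disutility decrements must be >= 0", call. = FALSE)
  }
  structure(list(baseline = baseline, decrements = decrements,
                 cancer_annual = cancer_annual),
            class = "utility_schedule")
}

#' @rdname utility_schedule
#' @export
default_utility_schedule <- function() utility_schedule()

baseline_utility_at_age <- function(utilities, age) {
  lo <- as.numeric(names(utilities$baseline))
  idx <- pmax(findInterval(age, lo), 1L)
  unname(utilities$baseline)[idx]
}

event_decrement <- function(utilities, event) {
  d <- utilities$decrements
  dec <- d$magnitude * d$duration_years
  out <- dec[match(event, d$event)]
  out[is.na(out)] <- 0
  out
}

#' Accumulate discounted outcomes from an event ledger
#'
#' Converts a strategy's [simulate_lifetime()] ledger into per-1000
#' discounted costs and QALYs plus the secondary counts: CRC cases, all
#' screening tests, non-colonoscopy tests, screening colonoscopies, all
#' colonoscopies (screening + diagnostic + surveillance), and initial
#' screening uptake by 75 (share of persons alive at 45 who ever
#' screened). Events are booked at cycle start; a person who dies in a
#' cycle accrues that year's utility. QALYs gained (`qalyg`) are a paired
#' per-person subtraction against a seed-matched no-screening ledger when
#' `baseline` is supplied.
#'
#' @param ledger [simulate_lifetime()] output with `collect = "ledger"`
#' @param costs [cost_schedule()]
#' @param utilities [utility_schedule()]
#' @param spec [discount_spec()]
#' @param baseline optional no-screening `event_ledger` from the same
#'   cohort (same n and seed) for the QALYG pairing
#' @return one-row data.frame of class `strategy_outcome`
#' @export
accumulate_outcomes <- function(ledger, costs = default_cost_schedule(),
                                utilities = default_utility_schedule(),
                                spec = discount_spec(),
                                baseline = NULL) {
  stopifnot(inherits(ledger, "event_ledger"))
  if (attr(ledger, "collect") != "ledger") {
    stop("ledger was collected in summary mode; rerun with collect = 'ledger'",
         call. = FALSE)
  }
  n <- attr(ledger, "n")
  start_age <- attr(ledger, "start_age")
  max_age <- attr(ledger, "max_age")
  ref <- spec$reference_age
  p <- ledger$persons
  ev <- ledger$events

  # cumulative discounted (utility-weighted) year sums, ages start..max-1
  ages <- start_age:(max_age - 1L)
  dfac <- (1 + spec$rate)^(-(ages - ref))
  cum_util <- cumsum(baseline_utility_at_age(utilities, ages) * dfac)
  cum_year <- cumsum(dfac)
  # value of sums over ages start..A inclusive, A < start gives 0
  upto <- function(cum, A) {
    idx <- A - start_age + 1L
    out <- numeric(length(A))
    ok <- !is.na(idx) & idx >= 1L
    out[ok] <- cum[pmin(idx[ok], length(cum))]
    out
  }
  last_year <- ifelse(is.na(p$death_age), max_age - 1L, p$death_age)

  ## QALYs ------------------------------------------------------------
  qaly <- upto(cum_util, last_year)
  has_dx <- !is.na(p$dx_age)
  if (any(has_dx)) {
    dec <- utilities$cancer_annual[p$dx_stage[has_dx]]
    qaly[has_dx] <- qaly[has_dx] -
      dec * (upto(cum_year, last_year[has_dx]) -
             upto(cum_year, p$dx_age[has_dx] - 1L))
  }
  ev_dec <- event_decrement(utilities, ev$event)
  if (nrow(ev) && any(ev_dec > 0)) {
    loss <- discount(ev_dec, ev$age - ref, spec)
    loss_by_person <- rowsum(loss, ev$person_id, reorder = FALSE)
    qaly[match(as.integer(rownames(loss_by_person)), p$id)] <-
      qaly[match(as.integer(rownames(loss_by_person)), p$id)] - loss_by_person[, 1]
  }

  ## costs ------------------------------------------------------------
  cost_map <- c(screen_colonoscopy = costs$screen[["colonoscopy"]],
                screen_ctc = costs$screen[["ctc"]],
                screen_fit = costs$screen[["fit"]],
                screen_mtsdna = costs$screen[["mtsdna"]],
                diagnostic_colonoscopy = costs$diagnostic_colonoscopy,
                surveillance_colonoscopy = costs$surveillance_colonoscopy,
                polypectomy = costs$polypectomy,
                complication = costs$complication)
  ev_cost <- cost_map[ev$event]
  ev_cost[is.na(ev_cost)] <- 0
  total_cost <- sum(discount(ev_cost, ev$age - ref, spec))
  if (any(has_dx)) {
    stg <- p$dx_stage[has_dx]
    dxa <- p$dx_age[has_dx]
    lst <- last_year[has_dx]
    crc_death <- !is.na(p$death_cause[has_dx]) & p$death_cause[has_dx] == "crc"
    total_cost <- total_cost +
      sum(discount(costs$cancer_initial[stg], dxa - ref, spec)) +
      sum(discount(costs$cancer_terminal[stg][crc_death],
                   lst[crc_death] - ref, spec))
    # continuing years: dx+1 .. last, minus the terminal year for CRC deaths
    cont <- costs$cancer_continuing[stg] * (upto(cum_year, lst) - upto(cum_year, dxa))
    term_adj <- ifelse(crc_death, costs$cancer_continuing[stg] *
                         discount(1, lst - ref, spec), 0)
    total_cost <- total_cost + sum(pmax(cont - term_adj, 0))
  }

  ## counts -----------------------------------------------------------
  tab <- table(factor(ev$event, levels = c(
    "screen_colonoscopy", "screen_ctc", "screen_fit", "screen_mtsdna",
    "diagnostic_colonoscopy", "surveillance_colonoscopy")))
  tests_all <- sum(tab[c("screen_colonoscopy", "screen_ctc",
                         "screen_fit", "screen_mtsdna")])
  tests_noncolo <- sum(tab[c("screen_ctc", "screen_fit", "screen_mtsdna")])
  screen_colos <- tab[["screen_colonoscopy"]]
  colos_all <- screen_colos + tab[["diagnostic_colonoscopy"]] +
    tab[["surveillance_colonoscopy"]]
  alive45 <- is.na(p$death_age) | p$death_age >= 45L
  uptake75 <- mean(p$ever_initiated[alive45])

  qalyg <- NA_real_
  if (!is.null(baseline)) {
    if (attr(baseline, "n") != n || attr(baseline, "seed") != attr(ledger, "seed")) {
      stop("QALYG pairing requires a no-screening ledger with the same ",
           "cohort size and seed", call. = FALSE)
    }
    base_out <- accumulate_outcomes(baseline, costs, utilities, spec)
    qalyg <- sum(qaly) * 1000 / n - base_out$qaly
  }

  out <- data.frame(
    strategy = attr(ledger, "strategy"),
    group = attr(ledger, "group"),
    n = n,
    cost = total_cost * 1000 / n,
    qaly = sum(qaly) * 1000 / n,
    qalyg = qalyg,
    crc_cases = sum(has_dx) * 1000 / n,
    tests_all = tests_all * 1000 / n,
    tests_noncolo = tests_noncolo * 1000 / n,
    screen_colos = screen_colos * 1000 / n,
    colos_all = colos_all * 1000 / n,
    uptake75 = uptake75,
    stringsAsFactors = FALSE
  )
  class(out) <- c("strategy_outcome", "data.frame")
  out
}

#' Write / read a cost schedule as flat keyed text
#'
#' One cost per `key = value` line (`screen_ctc`, `cancer_initial_2`, ...).
#'
#' @param costs [cost_schedule()]
#' @param path file path
#' @return path invisibly; the reader returns a `cost_schedule`
#' @export
write_cost_schedule <- function(costs, path) {
  stopifnot(inherits(costs, "cost_schedule"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("screen_", names(costs$screen), " = ", num(costs$screen)),
    paste0("diagnostic_colonoscopy = ", num(costs$diagnostic_colonoscopy)),
    paste0("surveillance_colonoscopy = ", num(costs$surveillance_colonoscopy)),
    paste0("polypectomy = ", num(costs$polypectomy)),
    paste0("complication = ", num(costs$complication)),
    paste0("cancer_initial_", 1:4, " = ", num(costs$cancer_initial)),
    paste0("cancer_continuing_", 1:4, " = ", num(costs$cancer_continuing)),
    paste0("cancer_terminal_", 1:4, " = ", num(costs$cancer_terminal))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cost_schedule
#' @export
read_cost_schedule <- function(path) {
  kv <- read_keyed_config(path)
  getn <- function(k) as.numeric(kv[[k]])
  stage <- function(prefix) vapply(1:4, function(i) getn(paste0(prefix, "_", i)),
                                   numeric(1))
  cost_schedule(
    screen = c(colonoscopy = getn("screen_colonoscopy"),
               ctc = getn("screen_ctc"), fit = getn("screen_fit"),
               mtsdna = getn("screen_mtsdna")),
    diagnostic_colonoscopy = getn("diagnostic_colonoscopy"),
    surveillance_colonoscopy = getn("surveillance_colonoscopy"),
    polypectomy = getn("polypectomy"),
    complication = getn("complication"),
    cancer_initial = stage("cancer_initial"),
    cancer_continuing = stage("cancer_continuing"),
    cancer_terminal = stage("cancer_terminal")
  )
}
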