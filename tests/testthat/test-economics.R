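test_that("discounting matches identities and the iterated-division oracle", {
  spec <- discount_spec(0.03)
  expect_equal(discount(100, 0, spec), 100)
  expect_equal(discount(100, 1, discount_spec(0)), 100)
  loop <- 100
  for (i in 1:10) loop <- loop / 1.03
  expect_equal(discount(100, 10, spec), loop)
  expect_error(discount(100, -1, spec), ">= 0")
})

test_that("empty and single-event ledgers accumulate exactly", {
  costs <- default_cost_schedule()
  # immediate end, no events: zero costs, zero QALYs
  led0 <- synthetic_ledger(no_events(), blank_persons(3, death_age = 39L))
  out0 <- accumulate_outcomes(led0, costs)
  expect_equal(out0$cost, 0)
  expect_equal(out0$qaly, 0)
  # exactly one FIT at year 0 -> cost is the FIT cost
  ev <- data.frame(person_id = 1L, age = 40L, event = "screen_fit",
                   detail = 0L)
  led1 <- synthetic_ledger(ev, blank_persons(1, death_age = 40L))
  out1 <- accumulate_outcomes(led1, costs)
  expect_equal(out1$cost / 1000, costs$screen[["fit"]])
})

test_that("scripted ledger totals equal an independent hand summation", {
  costs <- default_cost_schedule()
  utils_ <- default_utility_schedule()
  spec <- discount_spec(0.03)
  # person 1: colonoscopy at 50 and 60, dies other cause at 70
  # person 2: CTC at 47 (FP) + diagnostic colonoscopy at 47; censored
  # person 3: diagnosed stage II at 55, CRC death at 58
  ev <- data.frame(
    person_id = c(1L, 1L, 2L, 2L, 3L),
    age = c(50L, 60L, 47L, 47L, 55L),
    event = c("screen_colonoscopy", "screen_colonoscopy", "screen_ctc",
              "diagnostic_colonoscopy", "crc_diagnosis"),
    detail = c(0L, 0L, 0L, 0L, 2L))
  per <- blank_persons(3)
  per$death_age <- c(70L, NA, 58L)
  per$death_cause <- c("other", NA, "crc")
  per$dx_age[3] <- 55L
  per$dx_stage[3] <- 2L
  led <- synthetic_ledger(ev, per)
  out <- accumulate_outcomes(led, costs, utils_, spec)

  dfac <- function(a) 1.03^(-(a - 40))
  cost_hand <-
    costs$screen[["colonoscopy"]] * (dfac(50) + dfac(60)) +
    costs$screen[["ctc"]] * dfac(47) +
    costs$diagnostic_colonoscopy * dfac(47) +
    costs$cancer_initial[2] * dfac(55) +
    costs$cancer_continuing[2] * (dfac(56) + dfac(57)) +
    costs$cancer_terminal[2] * dfac(58)
  expect_equal(out$cost, cost_hand * 1000 / 3)

  ub <- function(a) crcscreen:::baseline_utility_at_age(utils_, a)
  dec <- function(e) {
    d <- utils_$decrements
    d$magnitude[d$event == e] * d$duration_years[d$event == e]
  }
  qaly_hand <-
    sum(ub(40:70) * dfac(40:70)) -
    dec("screen_colonoscopy") * (dfac(50) + dfac(60)) +
    sum(ub(40:99) * dfac(40:99)) -
    dec("screen_ctc") * dfac(47) - dec("diagnostic_colonoscopy") * dfac(47) +
    sum(ub(40:58) * dfac(40:58)) -
    utils_$cancer_annual[2] * sum(dfac(55:58))
  expect_equal(out$qaly, qaly_hand * 1000 / 3)
})

test_that("costs and QALYs are additive over disjoint person subsets", {
  coh <- initialize_cohort(1000, "White men", seed = 33)
  truth <- make_truth(1, "White men")
  pol <- screening_policy(strategy_rule("status_quo"), truth$profile)
  led <- simulate_lifetime(coh, truth$params, pol)
  idx_a <- led$persons$id <= 500
  split_ledger <- function(keep) {
    l <- led
    l$persons <- led$persons[keep, ]
    l$events <- led$events[led$events$person_id %in% l$persons$id, ]
    attr(l, "n") <- nrow(l$persons)
    l
  }
  out_all <- accumulate_outcomes(led)
  out_a <- accumulate_outcomes(split_ledger(idx_a))
  out_b <- accumulate_outcomes(split_ledger(!idx_a))
  expect_equal(out_all$cost * 1000, out_a$cost * 500 + out_b$cost * 500)
  expect_equal(out_all$qaly * 1000, out_a$qaly * 500 + out_b$qaly * 500)
})

test_that("zero disutilities make QALYs equal discounted life-years", {
  flat <- utility_schedule(
    baseline = c("40" = 1),
    decrements = data.frame(event = "screen_fit", magnitude = 0,
                            duration_years = 0),
    cancer_annual = c(0, 0, 0, 0))
  coh <- initialize_cohort(800, "Black men", seed = 35)
  led <- simulate_lifetime(coh)
  out <- accumulate_outcomes(led, utilities = flat)
  last <- ifelse(is.na(led$persons$death_age), 99L, led$persons$death_age)
  ly <- vapply(last, function(l) sum(1.03^(-(40:l - 40))), numeric(1))
  expect_equal(out$qaly, sum(ly) * 1000 / 800)
})

test_that("no-screening accrues no screening-pathway costs; discounting bounds", {
  coh <- initialize_cohort(1500, "White women", seed = 37)
  led <- simulate_lifetime(coh)
  ev <- led$events
  expect_equal(sum(ev$event %in% c("screen_colonoscopy", "screen_ctc",
                                   "screen_fit", "screen_mtsdna",
                                   "diagnostic_colonoscopy",
                                   "surveillance_colonoscopy")), 0L)
  disc <- accumulate_outcomes(led, spec = discount_spec(0.03))
  undisc <- accumulate_outcomes(led, spec = discount_spec(0))
  expect_lt(disc$cost, undisc$cost)
  expect_equal(accumulate_outcomes(led, spec = discount_spec(0))$cost,
               undisc$cost)
})

test_that("QALYG pairing requires a seed-matched cohort", {
  coh <- initialize_cohort(300, "White men", seed = 41)
  truth <- make_truth(1, "White men")
  pol <- screening_policy(strategy_rule("fit_only"),
                          derive_strategy_profile(truth$profile,
                                                  strategy_rule("fit_only")))
  led <- simulate_lifetime(coh, truth$params, pol)
  base_other <- simulate_lifetime(initialize_cohort(301, "White men", seed = 41),
                                  truth$params)
  expect_error(accumulate_outcomes(led, baseline = base_other), "same")
  base <- simulate_lifetime(coh, truth$params)
  out <- accumulate_outcomes(led, baseline = base)
  expect_false(is.na(out$qalyg))
})

test_that("cost schedules round-trip through keyed text", {
  costs <- cost_schedule(screen = c(colonoscopy = 1500.5, ctc = 601,
                                    fit = 49, mtsdna = 510))
  f <- withr::local_tempfile(fileext = ".cfg")
  write_cost_schedule(costs, f)
  back <- read_cost_schedule(f)
  expect_equal(back, costs)
})
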