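test_that("initial-screening multiplier clips at 1 and validates inputs", {
  expect_equal(round(apply_initial_multiplier(0.063, 1.80), 3), 0.113)
  expect_equal(round(apply_initial_multiplier(0.035, 0.29), 3), 0.010)
  expect_equal(apply_initial_multiplier(0.5, 1.0), 0.5)
  expect_equal(apply_initial_multiplier(0.9, 3.45), 1)
  expect_error(apply_initial_multiplier(1.2, 1), "\\[0, 1\\]")
  expect_error(apply_initial_multiplier(0.5, -1), ">= 0")
})

test_that("odds-ratio adjustment matches published cells and is monotone", {
  expect_equal(round(apply_repeat_odds_ratio(0.587, 1.83), 3), 0.722)
  expect_equal(round(apply_repeat_odds_ratio(0.202, 1.83), 3), 0.317)
  expect_equal(apply_repeat_odds_ratio(0.37, 1), 0.37)
  # strictly increasing in both arguments
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(apply_repeat_odds_ratio(p, 1.83)) > 0))
  ors <- seq(0.5, 3, by = 0.25)
  expect_true(all(diff(apply_repeat_odds_ratio(0.3, ors)) > 0))
  # inverts exactly with OR -> 1/OR
  q <- apply_repeat_odds_ratio(0.42, 2.5)
  expect_equal(apply_repeat_odds_ratio(q, 1 / 2.5), 0.42)
  expect_error(apply_repeat_odds_ratio(1, 2), "infinite odds")
})

test_that("status-quo passthrough and unknown rules behave per contract", {
  sq <- default_status_quo_profile("White men")
  expect_identical(derive_strategy_profile(sq, strategy_rule("status_quo")), sq)
  expect_error(derive_strategy_profile(sq, list(name = "bogus")), "unknown rule")
  # no-screening derivation zeroes every schedule
  none <- derive_strategy_profile(sq, strategy_rule("no_screening"))
  expect_true(all(none$initial == 0) && all(none$repeat_prob == 0))
})

test_that("derived schedules reproduce the published panels within 0.1 point", {
  # CTC panel, initial: rows 45-49..70-75, (colonoscopy, fit) origins
  printed_ctc <- list(
    "White men"   = cbind(c(14.5, 7.6, 4.4, 2.4, 1.3, 1.3),
                          c(1.7, 0.8, 0.4, 0.2, 0.1, 0.1)),
    "Black men"   = cbind(c(11.3, 5.8, 3.7, 2.2, 1.3, 1.3),
                          c(1.4, 0.6, 0.3, 0.2, 0.1, 0.1)),
    "White women" = cbind(c(14.6, 7.1, 3.0, 1.5, 0.7, 0.7),
                          c(1.8, 0.9, 0.4, 0.2, 0.1, 0.1)),
    "Black women" = cbind(c(12.6, 7.0, 3.6, 2.0, 1.1, 1.1),
                          c(1.0, 0.5, 0.2, 0.1, 0.1, 0.1)))
  printed_ctc_repeat <- list(
    "White men" = c(23.9, 56.5), "Black men" = c(31.7, 77.1),
    "White women" = c(30.4, 56.6), "Black women" = c(39.2, 72.2))
  for (g in crc_groups()) {
    d <- derive_strategy_profile(default_status_quo_profile(g),
                                 strategy_rule("ctc_only"), g)
    expect_true(all(abs(round(100 * unname(d$initial), 1) -
                          printed_ctc[[g]]) <= 0.1 + 1e-9), label = g)
    expect_true(all(abs(round(100 * unname(d$repeat_prob[, "ctc"]), 1) -
                          printed_ctc_repeat[[g]]) <= 0.1 + 1e-9), label = g)
  }
  # colonoscopy-only and FIT-only panels, 45-49 row (colonoscopy, fit origins)
  printed_colo_4549 <- list(
    "White men" = c(8.1, 0.9), "Black men" = c(6.3, 0.7),
    "White women" = c(8.1, 1.0), "Black women" = c(7.0, 0.6))
  printed_fit_4549 <- list(
    "White men" = c(27.8, 3.1), "Black men" = c(21.7, 2.6),
    "White women" = c(28.0, 3.5), "Black women" = c(24.2, 2.0))
  for (g in crc_groups()) {
    sq <- default_status_quo_profile(g)
    colo <- derive_strategy_profile(sq, strategy_rule("colonoscopy_only"), g)
    fit <- derive_strategy_profile(sq, strategy_rule("fit_only"), g)
    expect_true(all(abs(round(100 * unname(colo$initial["45-49", ]), 1) -
                          printed_colo_4549[[g]]) <= 0.1 + 1e-9), label = g)
    expect_true(all(abs(round(100 * unname(fit$initial["45-49", ]), 1) -
                          printed_fit_4549[[g]]) <= 0.1 + 1e-9), label = g)
  }
})

test_that("repeat-rule sourcing follows the strategy definitions", {
  ww <- default_status_quo_profile("White women")
  # CTC-only for White groups keeps status-quo colonoscopy repeat unchanged
  d <- derive_strategy_profile(ww, strategy_rule("ctc_only"), "White women")
  expect_equal(unname(d$repeat_prob["<65", "ctc"]), 0.304)
  # FIT-only and MT-sDNA-only share the FIT repeat schedule
  f <- derive_strategy_profile(ww, strategy_rule("fit_only"), "White women")
  m <- derive_strategy_profile(ww, strategy_rule("mtsdna_only"), "White women")
  expect_equal(unname(f$repeat_prob[, "fit"]), unname(m$repeat_prob[, "mtsdna"]))
  # colonoscopy-only uses colonoscopy repeat for all origins
  cm <- derive_strategy_profile(default_status_quo_profile("Black men"),
                                strategy_rule("colonoscopy_only"), "Black men")
  expect_equal(unname(cm$repeat_prob[, "colonoscopy"]), c(0.202, 0.647))
  # pre-45 fractions carry over unchanged; switching disabled
  expect_equal(d$pre45, ww$pre45)
  expect_equal(d$switch_prob, 0)
})

test_that("adherence profiles validate ranges and monotone age structure", {
  sq <- default_status_quo_profile("White men")
  bad <- sq$initial
  bad["50-54", "colonoscopy"] <- 0.99   # increases across bands
  expect_error(adherence_profile("White men", sq$pre45, bad, sq$repeat_prob),
               "non-increasing")
  bad2 <- sq$initial
  bad2[1, 1] <- 1.5
  expect_error(adherence_profile("White men", sq$pre45, bad2, sq$repeat_prob),
               "\\[0, 1\\]")
})

test_that("profiles and disease parameters round-trip through keyed text", {
  prof <- derive_strategy_profile(default_status_quo_profile("Black women"),
                                  strategy_rule("ctc_only"), "Black women")
  f <- withr::local_tempfile(fileext = ".cfg")
  write_adherence_profile(prof, f)
  back <- read_adherence_profile(f)
  expect_equal(back$initial, prof$initial)
  expect_equal(back$repeat_prob, prof$repeat_prob)
  expect_equal(back$followup, prof$followup)
  expect_equal(back$origin_frac_colonoscopy, prof$origin_frac_colonoscopy)

  params <- make_truth(5, "White men")$params
  f2 <- withr::local_tempfile(fileext = ".cfg")
  write_disease_params(params, f2)
  back2 <- read_disease_params(f2)
  expect_equal(back2$onset, params$onset)
  expect_equal(back2$life_table, params$life_table)
  expect_equal(back2$stage_progression, params$stage_progression)
})
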