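test_that("test results follow the state-matched sensitivity and specificity", {
  perf <- default_test_performance()
  # CTC never flags diminutive adenomas in the base case
  u <- seq(0, 0.999, by = 0.001)
  res <- run_test("ctc", rep(STATES[["ADENOMA_DIMINUTIVE"]], length(u)),
                  perf$ctc, u)
  expect_true(all(res == "negative"))
  # FIT false-positive rate on no-lesion = 1 - 0.964
  n <- 100000
  set.seed(1)
  res <- run_test("fit", rep(STATES[["NO_LESION"]], n), perf$fit)
  fp <- mean(res == "positive_false")
  se <- sqrt(0.036 * 0.964 / n)
  expect_lt(abs(fp - 0.036), 3 * se)
  expect_false(any(res == "positive_lesion"))
  # perfect test is a deterministic classifier
  perfect <- test_performance(1, 1, 1, 1, 1)
  states <- c(STATES[["NO_LESION"]], STATES[["ADENOMA_SMALL"]],
              STATES[["PRECLINICAL_CRC_III"]])
  expect_equal(run_test("colonoscopy", states, perfect, c(0.5, 0.5, 0.5)),
               c("negative", "positive_lesion", "positive_lesion"))
  expect_error(run_test("colonoscopy", STATES[["CLINICAL_CRC_I"]], perfect, 0.5),
               "non-clinical")
  expect_error(run_test("colonoscopy", 99L, perfect, 0.5), "unknown state")
})

test_that("routine screening decisions respect age, initiation and intervals", {
  prof <- default_status_quo_profile("White men")
  sq <- strategy_rule("status_quo")
  base <- list(id = 1L, age = 45L, state = STATES[["NO_LESION"]],
               adenoma_history_tier = 0L, origin = "colonoscopy",
               initiated = FALSE, next_due = NA, modality = NA,
               surv_due = NA)
  u <- c(initial = 0.5, "repeat" = 0.5, switch = 0.99, surveillance = 0.5)

  over75 <- base; over75$age <- 80L
  expect_equal(annual_screening_decision(over75, prof, sq, u)$action, "none")

  forced <- prof; forced$initial[] <- 1
  dec <- annual_screening_decision(base, forced, sq, u)
  expect_equal(dec$action, "screen")
  expect_equal(dec$modality, "colonoscopy")
  expect_equal(dec$person$next_due, 55L)

  # initiated but not yet due: nothing happens
  due <- base; due$initiated <- TRUE; due$modality <- "colonoscopy"
  due$next_due <- 50L
  expect_equal(annual_screening_decision(due, prof, sq, u)$action, "none")
  # overdue with favourable draw: repeat screen
  due$age <- 51L
  u2 <- u; u2[["repeat"]] <- 0.01
  expect_equal(annual_screening_decision(due, prof, sq, u2)$action, "screen")
  expect_error(annual_screening_decision(
    list(age = 50, state = STATES[["DEAD_OTHER"]]), prof, sq, u), "alive")
})

test_that("engine-level initiation fraction matches the binomial oracle", {
  # uninitiated 45-year-olds against a single age-band probability
  prof <- default_status_quo_profile("White men")
  prof$pre45[] <- 0
  prof$origin_frac_colonoscopy <- 1
  p <- prof$initial["45-49", "colonoscopy"]  # 0.081
  n <- 100000L
  p0 <- zero_disease_params(immortal = TRUE)
  coh <- initialize_cohort(n, "White men", params = p0, seed = 31,
                           start_age = 45L)
  pol <- screening_policy(strategy_rule("status_quo"), prof)
  led <- simulate_lifetime(coh, p0, pol, max_age = 46L)
  screened <- sum(led$events$event == "screen_colonoscopy" &
                    led$events$age == 45L)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(screened / n - p), 3 * se)
})

test_that("diagnostic follow-up attends at the modality-specific rate", {
  prof <- default_status_quo_profile("Black men")
  n <- 100000
  set.seed(2)
  for (m in c("ctc", "mtsdna")) {
    rate <- prof$followup[[m]]
    att <- mean(diagnostic_follow_up(m, prof, stats::runif(n)))
    expect_lt(abs(att - rate), 3 * sqrt(rate * (1 - rate) / n))
  }
  forced <- prof; forced$followup[["fit"]] <- 0
  expect_false(any(diagnostic_follow_up("fit", forced, stats::runif(1000))))
  expect_error(diagnostic_follow_up("colonoscopy", prof), "no diagnostic follow-up")
})

test_that("surveillance attends at tier-specific rates and rejects tier none", {
  prof <- default_status_quo_profile("White women")
  person <- list(age = 60L, adenoma_history_tier = 2L, surv_due = 60L)
  n <- 100000
  set.seed(3)
  u <- stats::runif(n)
  att <- mean(vapply(u, function(ui) {
    surveillance_decision(person, prof, ui) == "surveillance_colonoscopy"
  }, logical(1)))
  expect_lt(abs(att - 0.546), 3 * sqrt(0.546 * 0.454 / n))
  person$adenoma_history_tier <- 0L
  expect_error(surveillance_decision(person, prof), "adenoma history")
  low <- list(age = 60L, adenoma_history_tier = 1L, surv_due = 60L)
  forced <- prof; forced$surveillance[["low"]] <- 1
  expect_equal(surveillance_decision(low, forced, 0.999999),
               "surveillance_colonoscopy")
})

test_that("colonoscopy findings resolve states and update history tiers", {
  person <- list(age = 60L, state = STATES[["ADENOMA_LARGE"]],
                 adenoma_history_tier = 0L)
  out <- colonoscopy_resolution(person, "positive_lesion")
  expect_equal(out$state, STATES[["NO_LESION"]])
  expect_equal(out$adenoma_history_tier, 2L)
  expect_true("polypectomy" %in% out$events)

  person$state <- STATES[["PRECLINICAL_CRC_II"]]
  out <- colonoscopy_resolution(person, "positive_lesion")
  expect_equal(out$state, STATES[["CLINICAL_CRC_II"]])
  expect_equal(out$dx_stage, 2L)

  # tiers never downgrade
  person <- list(age = 60L, state = STATES[["ADENOMA_SMALL"]],
                 adenoma_history_tier = 2L)
  out <- colonoscopy_resolution(person, "positive_lesion")
  expect_equal(out$adenoma_history_tier, 2L)
})

test_that("zero complication rate yields no complication events", {
  truth <- make_truth(2, "White men")
  coh <- initialize_cohort(2000, "White men", params = truth$params, seed = 17)
  pol <- screening_policy(strategy_rule("colonoscopy_only"),
                          derive_strategy_profile(truth$profile,
                                                  strategy_rule("colonoscopy_only")),
                          complication_prob = 0)
  led <- simulate_lifetime(coh, truth$params, pol)
  expect_equal(sum(led$events$event == "complication"), 0L)
  expect_gt(sum(led$events$event == "screen_colonoscopy"), 0L)
})

test_that("diagnostic colonoscopies never exceed positive non-colonoscopy tests", {
  truth <- make_truth(4, "Black women")
  coh <- initialize_cohort(4000, "Black women", params = truth$params, seed = 19)
  for (snm in c("fit_only", "mtsdna_only", "ctc_only", "status_quo")) {
    pol <- screening_policy(strategy_rules()[[snm]],
                            derive_strategy_profile(truth$profile,
                                                    strategy_rules()[[snm]]))
    ev <- simulate_lifetime(coh, truth$params, pol)$events
    n_diag <- sum(ev$event == "diagnostic_colonoscopy")
    n_noncolo <- sum(ev$event %in% c("screen_ctc", "screen_fit", "screen_mtsdna"))
    expect_lte(n_diag, n_noncolo)
  }
})
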