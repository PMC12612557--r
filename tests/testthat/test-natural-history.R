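test_that("cohort initialization respects zero-rate and closed-form limits", {
  p0 <- zero_disease_params()
  coh <- initialize_cohort(10, "White men", params = p0, seed = 1)
  expect_equal(coh$state, rep(STATES[["NO_LESION"]], 10))
  expect_equal(coh$age, 40L)

  # geometric accumulation: one nonzero onset rate, no growth
  p1 <- zero_disease_params()
  p1$onset[] <- 0.01
  coh1 <- initialize_cohort(50000, "White men", params = p1, seed = 2)
  frac <- mean(coh1$state == STATES[["ADENOMA_DIMINUTIVE"]])
  expected <- 1 - (1 - 0.01)^20
  se <- sqrt(expected * (1 - expected) / 50000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("identical inputs give identical cohorts; bad inputs rejected", {
  a <- initialize_cohort(500, "Black women", seed = 9)
  b <- initialize_cohort(500, "Black women", seed = 9)
  expect_identical(a, b)
  expect_error(initialize_cohort(0, "White men"), "positive count")
  expect_error(initialize_cohort(10, "Purple men"), "unknown demographic group")
})

test_that("one annual step moves at most one link along the chain", {
  p0 <- zero_disease_params(immortal = TRUE)
  person <- list(id = 1L, age = 50L, state = STATES[["NO_LESION"]],
                 years_since_diagnosis = 0L)
  out <- step_year(person, p0)
  expect_equal(out$state, STATES[["NO_LESION"]])
  expect_equal(out$age, 51L)

  p1 <- zero_disease_params(immortal = TRUE)
  p1$large_to_preclinical <- 1
  person$state <- STATES[["ADENOMA_LARGE"]]
  out <- step_year(person, p1)
  expect_equal(out$state, STATES[["PRECLINICAL_CRC_I"]])

  person$state <- STATES[["DEAD_CRC"]]
  expect_error(step_year(person, p1), "dead")
})

test_that("single-step transition fraction matches the binomial oracle", {
  p <- zero_disease_params(immortal = TRUE)
  p$growth_dim_small <- 0.1
  n <- 100000L
  st <- rep(STATES[["ADENOMA_DIMINUTIVE"]], n)
  new <- crcscreen:::nh_chain_move(1:n, st, 50L, p, seed = 7)
  frac <- mean(new == STATES[["ADENOMA_SMALL"]])
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("lifetime simulation conserves the population and is reproducible", {
  coh <- initialize_cohort(2000, "White men", seed = 5)
  pol <- screening_policy(strategy_rule("status_quo"),
                          default_status_quo_profile("White men"))
  l1 <- simulate_lifetime(coh, policy = pol)
  l2 <- simulate_lifetime(coh, policy = pol)
  expect_identical(l1, l2)
  expect_true(check_conservation(l1))
  p <- l1$persons
  dead <- sum(!is.na(p$death_age))
  alive <- sum(is.na(p$death_age) & p$final_state < 13L)
  expect_equal(dead + alive, 2000L)
})

test_that("zero-disease no-screening ledger contains only other-cause deaths", {
  p0 <- zero_disease_params()
  coh <- initialize_cohort(3000, "White men", params = p0, seed = 6)
  led <- simulate_lifetime(coh, p0)
  expect_true(all(led$events$event %in% c("death_other", "censored")))
  expect_equal(sum(!is.na(led$persons$dx_age)), 0L)
})

test_that("no-screening CRC cases equal first clinical entries, definitionally", {
  coh <- initialize_cohort(5000, "White women", seed = 8)
  led <- simulate_lifetime(coh)
  dx_events <- sum(led$events$event == "crc_diagnosis")
  expect_equal(dx_events, sum(!is.na(led$persons$dx_age)))
})

test_that("zero-disease life years match the life-table closed form", {
  p0 <- zero_disease_params()
  n <- 50000L
  coh <- initialize_cohort(n, "White men", params = p0, seed = 4)
  led <- simulate_lifetime(coh, p0)
  death_age <- led$persons$death_age
  years <- ifelse(is.na(death_age), 100L - 40L, death_age - 40L + 1L)
  lt <- p0$life_table
  surv <- cumprod(1 - lt$qx[lt$age %in% 40:98])
  expected <- 1 + sum(surv)
  se <- stats::sd(years) / sqrt(n)
  expect_lt(abs(mean(years) - expected), 3 * se)
})

test_that("permuting person storage order leaves summaries unchanged", {
  coh <- initialize_cohort(1500, "Black men", seed = 11)
  perm <- sample(1500)
  coh2 <- coh
  for (f in c("id", "state", "tier", "ys_dx", "dx_age", "dx_stage")) {
    coh2[[f]] <- coh[[f]][perm]
  }
  pol <- screening_policy(strategy_rule("ctc_only"),
                          derive_strategy_profile(
                            default_status_quo_profile("Black men"),
                            strategy_rule("ctc_only")))
  l1 <- simulate_lifetime(coh, policy = pol)
  l2 <- simulate_lifetime(coh2, policy = pol)
  for (stat in c("dx_age", "death_age", "tier")) {
    expect_identical(sort(l1$persons[[stat]], na.last = TRUE)[1:1500],
                     sort(l2$persons[[stat]], na.last = TRUE)[1:1500])
  }
  expect_equal(nrow(l1$events), nrow(l2$events))
})

test_that("more screening cannot raise clinical incidence under common random numbers", {
  truth <- make_truth(3, "White men")
  coh <- initialize_cohort(5000, "White men", params = truth$params, seed = 13)
  cases <- function(pol) {
    sum(!is.na(simulate_lifetime(coh, truth$params, pol)$persons$dx_age))
  }
  none <- cases(NULL)
  sq <- cases(screening_policy(strategy_rule("status_quo"), truth$profile))
  ctc <- cases(screening_policy(strategy_rule("ctc_only"),
                                derive_strategy_profile(truth$profile,
                                                        strategy_rule("ctc_only"))))
  expect_lte(sq, none)
  expect_lte(ctc, none)

  # higher test sensitivity, seed-aligned: no more clinical cases
  perf_lo <- default_test_performance()
  perf_lo$colonoscopy$sens_large <- 0.5
  perf_lo$colonoscopy$sens_crc <- 0.5
  prof <- derive_strategy_profile(truth$profile, strategy_rule("colonoscopy_only"))
  hi <- cases(screening_policy(strategy_rule("colonoscopy_only"), prof))
  lo <- cases(screening_policy(strategy_rule("colonoscopy_only"), prof,
                               perf = perf_lo))
  expect_lte(hi, lo)
})

test_that("event ledgers export as delimited text and round-trip", {
  coh <- initialize_cohort(200, "White men", seed = 21)
  led <- simulate_lifetime(coh)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_ledger(led, path)
  back <- read_table_file(path)
  expect_equal(names(back), c("person_id", "age", "event", "detail"))
  expect_equal(nrow(back), nrow(led$events))
})
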