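test_that("MSE score matches hand arithmetic and algebraic properties", {
  tg <- calibration_targets(name = c("a", "b", "c"), value = c(10, 0.5, 100),
                            weight = c(1, 2, 4))
  s <- c(a = 10, b = 0.5, c = 100)
  expect_equal(mse_score(s, tg), 0)
  # single target, relative deviation d -> d^2
  tg1 <- calibration_targets(name = "a", value = 10, weight = 1)
  expect_equal(mse_score(c(a = 12), tg1), 0.2^2)
  # three unequal weights, hand-computed
  s2 <- c(a = 11, b = 0.6, c = 90)
  hand <- (1 * 0.1^2 + 2 * 0.2^2 + 4 * 0.1^2) / 7
  expect_equal(mse_score(s2, tg), hand)
  # invariant to target ordering, linear in weights
  expect_equal(mse_score(s2, tg[c(3, 1, 2), ]), hand)
  tg_scaled <- tg; tg_scaled$weight <- tg$weight * 5
  expect_equal(mse_score(s2, tg_scaled), hand)
  expect_error(mse_score(c(a = 1), tg), "missing summaries")
  expect_error(calibration_targets("a", value = 1, weight = 0), "> 0")
})

test_that("top-k selection is a stable sort-then-slice", {
  log_df <- data.frame(eval = 1:50, x = runif(50),
                       score = rep(c(0.3, 0.1, 0.2), length.out = 50))
  res <- structure(list(log = log_df), class = "calibration_result")
  top1 <- select_top_k(res, 1)
  expect_equal(top1$score, min(log_df$score))
  expect_equal(top1$eval, min(log_df$eval[log_df$score == min(log_df$score)]))
  all50 <- select_top_k(res, 50)
  ord <- order(log_df$score, log_df$eval)
  expect_equal(all50$eval, log_df$eval[ord])
  expect_error(select_top_k(res, 51), "exceeds")
})

test_that("search spaces validate bounds and transform both scales", {
  expect_error(search_space("x", 1, 1), "low < high")
  expect_error(search_space("x", 0, Inf), "finite")
  sp <- search_space(c("lin", "lg"), c(0, 0.1), c(10, 10),
                     scale = c("linear", "log"))
  u <- crcscreen:::to_unit(sp, c(5, 1))
  expect_equal(u[1], 0.5)
  expect_equal(u[2], 0.5)  # log midpoint of [0.1, 10] is 1
  expect_equal(crcscreen:::from_unit(sp, c(0.5, 0.5)), c(5, 1))
})

test_that("calibration on a quadratic toy finds the optimum, reproducibly", {
  sp <- search_space("x", 0.01, 1, scale = "linear")
  tg <- calibration_targets("y", value = 0.6, weight = 1)
  sfn <- function(p) c(y = unname(p[["x"]]))
  res <- calibrate(sp, tg, sfn, budget = 120, sampler = "adaptive",
                   seed = 3, top_k = 10)
  expect_lt(abs(res$top$x[1] - 0.6), 0.05)
  expect_true(all(diff(res$top$score) >= 0))
  res2 <- calibrate(sp, tg, sfn, budget = 120, sampler = "adaptive",
                    seed = 3, top_k = 10)
  expect_identical(res$log, res2$log)
  # random sampler with budget == top_k is just the evaluated sets sorted
  r <- calibrate(sp, tg, sfn, budget = 30, sampler = "random", seed = 4,
                 top_k = 30)
  expect_equal(nrow(r$top), 30)
  expect_equal(sort(r$log$score), r$top$score)
  expect_error(calibrate(sp, tg, sfn, budget = 5, top_k = 10), ">= top_k")
})

test_that("adaptive search is no worse than random at equal budget (median)", {
  sp <- search_space(c("x", "y"), c(0, 0), c(1, 1), scale = "linear")
  tg <- calibration_targets("z", value = 0.05, weight = 1)
  sfn <- function(p) c(z = 0.05 + (p[["x"]] - 0.3)^2 + (p[["y"]] - 0.7)^2)
  best <- function(sampler, seed) {
    min(calibrate(sp, tg, sfn, budget = 80, sampler = sampler, seed = seed,
                  top_k = 1)$log$score)
  }
  seeds <- 1:5
  med_a <- stats::median(vapply(seeds, function(s) best("adaptive", s), 1))
  med_r <- stats::median(vapply(seeds, function(s) best("random", s), 1))
  expect_lte(med_a, med_r)
})

test_that("summaries vanish in the zero-rate and zero-adherence limits", {
  g <- "White men"
  p0 <- zero_disease_params(g)
  prof <- default_status_quo_profile(g)
  s <- summarize_for_targets(p0, prof, g, n = 1500, seed = 2)
  expect_true(all(s[grepl("incidence|adenoma_prev", names(s))] == 0))
  # adherence forced to zero: nobody is ever screened
  prof0 <- prof
  prof0$pre45[] <- 0
  prof0$initial[] <- 0
  s0 <- summarize_for_targets(default_disease_params(g), prof0, g,
                              n = 1500, seed = 2)
  expect_true(all(s0[c("ever_colonoscopy_60", "ever_stool_60",
                       "ever_any_70", "recent_test_65")] == 0))
})

test_that("summaries at truth agree with the generator's targets (CRN)", {
  truth <- make_truth(6, "White women", noise = 0)
  tg <- make_targets(truth, seed = 21, n = 4000)
  s <- summarize_for_targets(truth$params, truth$profile, truth$group,
                             n = 4000, seed = 21)
  expect_equal(unname(s[tg$name]), tg$value)
})

test_that("targets round-trip through the delimited reader and writer", {
  truth <- make_truth(2, "Black men")
  tg <- make_targets(truth, seed = 5, n = 2000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_targets(tg, f)
  back <- read_targets(f)
  expect_equal(as.data.frame(back), as.data.frame(tg))
  expect_identical(readLines(f), {
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_targets(back, f2)
    readLines(f2)
  })
})
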