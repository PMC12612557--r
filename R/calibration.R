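#' Calibration targets
#'
#' A target is a named, optionally stratified summary statistic with an
#' observed value and a weight. Targets serialize as tab-delimited text
#' via [write_targets()] / [read_targets()].
#'
#' @param name target names
#' @param group demographic group labels
#' @param age_band stratum label (free text)
#' @param value observed values
#' @param weight positive weights (default 1)
#' @return data.frame of class `calibration_targets`
#' @export
calibration_targets <- function(name, group = "", age_band = "", value,
                                weight = 1) {
  if (any(weight <= 0)) stop("weights must be > 0", call. = FALSE)
  out <- data.frame(name = name, group = group, age_band = age_band,
                    value = value, weight = weight, stringsAsFactors = FALSE)
  class(out) <- c("calibration_targets", "data.frame")
  out
}

#' @rdname calibration_targets
#' @param targets `calibration_targets` object
#' @param path file path
#' @export
write_targets <- function(targets, path) {
  write_table(as.data.frame(targets),
              c("name", "group", "age_band", "value", "weight"), path)
}

#' @rdname calibration_targets
#' @export
read_targets <- function(path) {
  df <- read_table_file(path)
  df$group[is.na(df$group)] <- ""
  df$age_band[is.na(df$age_band)] <- ""
  calibration_targets(df$name, df$group, df$age_band, df$value, df$weight)
}

#' Model summaries for the calibration targets
#'
#' Runs the candidate parameters through a status-quo simulation (and a
#' screening-disabled one for the non-screening-era stage mix) and
#' returns every target-named statistic: age-band clinical CRC incidence
#' per 100,000 person-years, stage distribution (stages I-III shares) in
#' the screening and non-screening eras, cross-sectional adenoma
#' prevalence at ages 50/60/70, ever-screened proportions, and test
#' recency. Uses common random numbers: the same seed across candidate
#' parameter sets.
#'
#' @param params [disease_params()] candidate
#' @param profile status-quo [adherence_profile()] (possibly scaled)
#' @param group one of [crc_groups()]
#' @param n evaluation cohort size (default 20000)
#' @param seed common-random-number seed
#' @param perf [default_test_performance()]-style list
#' @return named numeric vector of summaries
#' @export
summarize_for_targets <- function(params, profile, group, n = 20000L,
                                  seed = 1L, perf = default_test_performance()) {
  pol <- screening_policy(strategy_rule("status_quo"), profile, perf)
  coh <- initialize_cohort(n, group, params = params, seed = seed)
  led <- simulate_lifetime(coh, params, pol, collect = "summary",
                           snapshot_ages = c(50L, 60L, 70L))
  led0 <- simulate_lifetime(coh, params, NULL, collect = "summary")
  p <- led$persons
  # person-years in an age band [lo, hi]: alive years are start..death_age
  last <- ifelse(is.na(p$death_age), attr(led, "max_age") - 1L, p$death_age)
  py_band <- function(lo, hi) {
    sum(pmax(0, pmin(last, hi) - lo + 1L))
  }
  dx_band <- function(lo, hi) sum(!is.na(p$dx_age) & p$dx_age >= lo & p$dx_age <= hi)
  bands <- list(c(45, 54), c(55, 64), c(65, 74), c(75, 84))
  inc <- vapply(bands, function(b) {
    1e5 * dx_band(b[1], b[2]) / max(py_band(b[1], b[2]), 1)
  }, numeric(1))
  names(inc) <- vapply(bands, function(b) paste0("incidence_", b[1], "_", b[2]), "")
  stage_mix <- function(persons) {
    s <- persons$dx_stage[!is.na(persons$dx_stage)]
    if (!length(s)) return(c(0, 0, 0))
    as.numeric(table(factor(s, levels = 1:4))[1:3] / length(s))
  }
  snaps <- attr(led, "snapshots")
  alive_at <- function(age) is.na(p$death_age) | p$death_age >= age
  a60 <- alive_at(60); a65 <- alive_at(65); a70 <- alive_at(70)
  recent <- !is.na(p$last_test_age) & p$last_test_age >= 55
  c(inc,
    stats::setNames(stage_mix(p), paste0("stage_screenera_", 1:3)),
    stats::setNames(stage_mix(led0$persons), paste0("stage_noscreen_", 1:3)),
    adenoma_prev_50 = unname(snaps[["50"]][["any"]]),
    adenoma_prev_60 = unname(snaps[["60"]][["any"]]),
    adenoma_prev_70 = unname(snaps[["70"]][["any"]]),
    adenoma_prev_large_60 = unname(snaps[["60"]][["large"]]),
    adenoma_prev_large_70 = unname(snaps[["70"]][["large"]]),
    ever_colonoscopy_60 = mean(p$ever_colonoscopy[a60]),
    ever_stool_60 = mean(p$ever_stool[a60]),
    ever_any_70 = mean((p$ever_colonoscopy | p$ever_stool)[a70]),
    recent_test_65 = mean(recent[a65]))
}

#' Weighted mean-squared-error score against targets
#'
#' Deviations are relative (scaled by the observed value) when the
#' observed value is nonzero, so incidence rates and proportions are
#' commensurable; zero-valued targets contribute absolute deviations.
#'
#' @param summaries named numeric vector (e.g. [summarize_for_targets()])
#' @param targets [calibration_targets()]
#' @return weighted mean of squared (relative) deviations
#' @export
mse_score <- function(summaries, targets) {
  missing <- setdiff(targets$name, names(summaries))
  if (length(missing)) {
    stop("missing summaries for targets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- summaries[targets$name]
  d <- ifelse(targets$value != 0,
              (s - targets$value) / targets$value,
              s - targets$value)
  sum(targets$weight * d^2) / sum(targets$weight)
}

#' Calibration search space
#'
#' @param param parameter names
#' @param low,high finite bounds, low < high
#' @param scale "linear" or "log" sampling scale
#' @return data.frame of class `search_space`
#' @export
search_space <- function(param, low, high, scale = "log") {
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low >= high)) {
    stop("bounds must be finite with low < high", call. = FALSE)
  }
  out <- data.frame(param = param, low = low, high = high, scale = scale,
                    stringsAsFactors = FALSE)
  class(out) <- c("search_space", "data.frame")
  out
}

to_unit <- function(space, x) {
  lo <- ifelse(space$scale == "log", log(space$low), space$low)
  hi <- ifelse(space$scale == "log", log(space$high), space$high)
  v <- ifelse(space$scale == "log", log(x), x)
  (v - lo) / (hi - lo)
}

from_unit <- function(space, u) {
  lo <- ifelse(space$scale == "log", log(space$low), space$low)
  hi <- ifelse(space$scale == "log", log(space$high), space$high)
  v <- lo + u * (hi - lo)
  ifelse(space$scale == "log", exp(v), v)
}

# Adaptive sampler in the tree-structured-Parzen-estimator family:
# after a random startup phase, observed points are split at the gamma
# quantile of the score; both subsets are modelled with per-dimension
# Gaussian kernel densities and the candidate maximising the
# good-to-bad density ratio among `n_cand` samples from the good model
# is proposed. Dimensions are treated independently in the unit cube.
tpe_propose <- function(U, scores, n_cand = 24L, gamma = 0.25) {
  n <- nrow(U); d <- ncol(U)
  n_good <- max(2L, ceiling(gamma * n))
  ord <- order(scores)
  good <- U[ord[seq_len(n_good)], , drop = FALSE]
  bad <- U[ord[-seq_len(n_good)], , drop = FALSE]
  if (nrow(bad) < 2L) bad <- U
  bw <- function(x) max(1.06 * stats::sd(x) * length(x)^(-0.2), 0.05)
  cand <- matrix(0, n_cand, d)
  for (j in seq_len(d)) {
    h <- bw(good[, j])
    centers <- good[sample.int(nrow(good), n_cand, replace = TRUE), j]
    cand[, j] <- pmin(pmax(stats::rnorm(n_cand, centers, h), 0), 1)
  }
  kde <- function(x, pts, h) {
    rowMeans(outer(x, pts, function(a, b) stats::dnorm(a, b, h))) + 1e-12
  }
  ratio <- numeric(n_cand)
  for (j in seq_len(d)) {
    ratio <- ratio + log(kde(cand[, j], good[, j], bw(good[, j]))) -
      log(kde(cand[, j], bad[, j], bw(bad[, j])))
  }
  cand[which.max(ratio), ]
}

#' Calibrate free parameters to targets by black-box search
#'
#' Evaluates `budget` candidate parameter sets, scoring each with the
#' weighted relative MSE against the targets, and retains the full
#' evaluation log. The adaptive sampler (default) proposes candidates
#' from a Parzen-estimator model of the good-score region; the `random`
#' sampler draws uniformly on each parameter's (log) scale.
#'
#' @param space [search_space()]
#' @param targets [calibration_targets()]
#' @param summarize_fn function(named parameter vector) returning named
#'   summaries comparable to the targets (bind cohort size and the
#'   common-random-number seed into this closure)
#' @param budget number of evaluations (must be >= `top_k`)
#' @param sampler "adaptive" or "random"
#' @param seed RNG seed for the search
#' @param top_k size of the retained elite set (default 100)
#' @return object of class `calibration_result`: `$log` (eval, params,
#'   score), `$top` (the `top_k` best rows, score-sorted, ties stable by
#'   evaluation index)
#' @export
calibrate <- function(space, targets, summarize_fn, budget,
                      sampler = c("adaptive", "random"), seed = 1L,
                      top_k = 100L) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(space, "search_space"))
  if (budget < top_k) stop("budget must be >= top_k", call. = FALSE)
  d <- nrow(space)
  set.seed(seed)
  n_startup <- max(10L, budget %/% 5L)
  U <- matrix(NA_real_, budget, d)
  scores <- numeric(budget)
  for (i in seq_len(budget)) {
    u <- if (sampler == "random" || i <= n_startup || all(!is.finite(scores[seq_len(i - 1)]))) {
      stats::runif(d)
    } else {
      tpe_propose(U[seq_len(i - 1), , drop = FALSE], scores[seq_len(i - 1)])
    }
    U[i, ] <- u
    x <- stats::setNames(from_unit(space, u), space$param)
    s <- summarize_fn(x)
    scores[i] <- mse_score(s, targets)
  }
  X <- t(apply(U, 1, function(u) from_unit(space, u)))
  if (d == 1L) X <- matrix(X, ncol = 1L)
  colnames(X) <- space$param
  log_df <- data.frame(eval = seq_len(budget), X, score = scores,
                       check.names = FALSE)
  res <- structure(list(log = log_df, space = space, sampler = sampler,
                        seed = seed),
                   class = "calibration_result")
  res$top <- select_top_k(res, min(top_k, budget))
  res
}

#' Select the k best-scoring parameter sets
#'
#' @param result [calibrate()] output
#' @param k number of sets (default 100)
#' @return data.frame of the k lowest-score rows, ties stable by
#'   evaluation index
#' @export
select_top_k <- function(result, k = 100L) {
  log_df <- if (inherits(result, "calibration_result")) result$log else result
  if (k > nrow(log_df)) stop("k exceeds evaluated count", call. = FALSE)
  ord <- order(log_df$score, log_df$eval)
  out <- log_df[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
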