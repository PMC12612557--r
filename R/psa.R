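#' Sample from a PERT distribution
#'
#' The PERT distribution is a Beta stretched to [min, max] with shapes
#' alpha = 1 + lambda (mode - min)/(max - min) and
#' beta = 1 + lambda (max - mode)/(max - min), lambda = 4, so its mean is
#' (min + 4 mode + max) / 6. Degenerate min = max returns the constant.
#'
#' @param n number of draws
#' @param mode,min,max distribution parameters, min <= mode <= max
#' @param lambda shape concentration (default 4)
#' @return numeric vector of draws
#' @export
sample_pert <- function(n, mode, min, max, lambda = 4) {
  if (!(min <= mode && mode <= max)) {
    stop("need min <= mode <= max", call. = FALSE)
  }
  if (min == max) return(rep(min, n))
  a <- 1 + lambda * (mode - min) / (max - min)
  b <- 1 + lambda * (max - mode) / (max - min)
  min + (max - min) * stats::rbeta(n, a, b)
}

#' Uncertainty distributions for probabilistic sensitivity analysis
#'
#' The narrower-range uncertainty distributions of the behavioural and
#' test-performance parameters: Beta with the published shape pairs for
#' sensitivities, follow-up and surveillance adherence, and the
#' FIT-origin CTC multiplier; PERT (min, mode, max) for the relative-risk
#' multipliers published as ranges.
#'
#' @return named list of distribution specs
#'   (`list(dist = "beta", a=, b=)`, `list(dist = "pert", mode=, min=, max=)`,
#'    or `list(dist = "fixed", value=)`)
#' @export
psa_distributions <- function() {
  beta <- function(a, b) list(dist = "beta", a = a, b = b)
  pert <- function(mode, min, max) list(dist = "pert", mode = mode,
                                        min = min, max = max)
  list(
    colo_sens_diminutive = beta(229, 76),
    colo_sens_small      = beta(187, 33),
    colo_sens_large      = beta(559, 29),
    colo_sens_crc        = beta(559, 29),
    ctc_sens_diminutive  = beta(0.03, 3.01),
    ctc_sens_small       = beta(38, 10),
    ctc_sens_large       = beta(126, 17),
    ctc_sens_crc         = beta(126, 17),
    fit_sens_diminutive  = beta(218, 2645),
    fit_sens_small       = beta(218, 2645),
    fit_sens_large       = beta(169, 541),
    fit_sens_crc         = beta(46, 16),
    mtsdna_sens_diminutive = beta(495, 2385),
    mtsdna_sens_small    = beta(495, 2385),
    mtsdna_sens_large    = beta(278, 378),
    mtsdna_sens_crc      = beta(51, 4),
    rr_colonoscopy_from_fit = beta(112.99, 276.62),
    rr_fit_from_colonoscopy = pert(3.45, 2.94, 4),
    rr_ctc_from_colonoscopy = pert(1.8, 1.46, 2.35),
    rr_ctc_from_fit      = beta(89.64, 79.49),
    followup_ctc         = beta(7.46, 0.18),
    followup_fit         = beta(2076.84, 2187.72),
    followup_mtsdna      = beta(2528.77, 1268.18),
    surveillance_low     = beta(8.81, 10.76),
    surveillance_high    = beta(30.39, 24.87)
  )
}

#' Draw one parameter set from PSA distributions
#'
#' @param dists as returned by [psa_distributions()]
#' @return named numeric vector; probability parameters are guaranteed to
#'   lie in [0, 1] (Beta draws do by construction)
#' @export
sample_psa_draw <- function(dists) {
  vapply(dists, function(d) {
    switch(d$dist,
           beta = stats::rbeta(1, d$a, d$b),
           pert = sample_pert(1, d$mode, d$min, d$max),
           fixed = d$value,
           stop("invalid distribution spec: ", d$dist, call. = FALSE))
  }, numeric(1))
}

#' Probabilistic sensitivity analysis: CEAC and frontier
#'
#' Samples `n_draws` parameter sets from the uncertainty distributions;
#' for each draw, evaluates every strategy's (cost, qalyg) averaged over
#' the supplied calibrated parameter sets, then computes at each
#' willingness-to-pay value the fraction of draws in which each strategy
#' maximises net monetary benefit (the cost-effectiveness acceptability
#' curve) and the strategy with the highest mean NMB (the frontier).
#'
#' @param outcome_fn function(draw, calib_set, seed) returning a
#'   data.frame with columns `strategy`, `cost`, `qalyg`
#' @param n_draws number of PSA parameter sets (paper analysis: 5000;
#'   desk scale: 200)
#' @param dists [psa_distributions()]-style list
#' @param calib_sets list of calibrated parameter sets to average over
#' @param wtp_grid willingness-to-pay grid (default $10k-$500k)
#' @param seed master seed; draw d uses `seed + d` for its own stream
#' @return list with `ceac` (wtp, strategy, probability), `frontier`
#'   (wtp, strategy), and `draws` (per-draw mean outcomes)
#' @export
run_psa <- function(outcome_fn, n_draws = 200L,
                    dists = psa_distributions(),
                    calib_sets = list(NULL),
                    wtp_grid = seq(10000, 500000, by = 10000),
                    seed = 1L) {
  stopifnot(is.function(outcome_fn), n_draws >= 1L, length(calib_sets) >= 1L)
  draw_out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(seed + d)
    par_d <- sample_psa_draw(dists)
    per_set <- lapply(seq_along(calib_sets), function(k) {
      outcome_fn(par_d, calib_sets[[k]], seed + d)
    })
    strat <- per_set[[1]]$strategy
    cost <- rowMeans(vapply(per_set, function(x) x$cost, numeric(length(strat))))
    qalyg <- rowMeans(vapply(per_set, function(x) x$qalyg, numeric(length(strat))))
    draw_out[[d]] <- data.frame(draw = d, strategy = strat,
                                cost = cost, qalyg = qalyg)
  }
  draws <- do.call(rbind, draw_out)
  strategies <- unique(draws$strategy)
  ceac <- expand.grid(wtp = wtp_grid, strategy = strategies,
                      stringsAsFactors = FALSE)
  ceac$probability <- 0
  frontier <- data.frame(wtp = wtp_grid, strategy = NA_character_)
  cost_m <- matrix(draws$cost, nrow = length(strategies))
  qaly_m <- matrix(draws$qalyg, nrow = length(strategies))
  for (w in seq_along(wtp_grid)) {
    nmb_m <- wtp_grid[w] * qaly_m - cost_m   # strategies x draws
    winner <- strategies[apply(nmb_m, 2, which.max)]
    pr <- table(factor(winner, levels = strategies)) / n_draws
    ceac$probability[ceac$wtp == wtp_grid[w]] <- as.numeric(pr)
    frontier$strategy[w] <- strategies[which.max(rowMeans(nmb_m))]
  }
  list(ceac = ceac, frontier = frontier, draws = draws)
}
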