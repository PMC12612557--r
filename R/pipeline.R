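#' Simulate a set of strategies for one group, seed-aligned
#'
#' Initializes one cohort and runs every requested strategy on it with
#' common random numbers, pairing each strategy's QALYs against the
#' no-screening run of the same cohort, so strategy comparisons are not
#' swamped by Monte-Carlo noise.
#'
#' @param group one of [crc_groups()]
#' @param params [disease_params()]
#' @param n cohort size
#' @param seed master seed
#' @param strategies character vector of strategy names
#' @param sq_profile status-quo [adherence_profile()]
#' @param perf per-modality [test_performance()] list
#' @param rules list of [strategy_rule()] (overridable for sensitivity
#'   analyses)
#' @param costs,utilities,dspec economic inputs
#' @return data.frame of strategy-outcome rows (one per strategy)
#' @export
simulate_strategies <- function(group, params = default_disease_params(group),
                                n = 2000L, seed = 1L,
                                strategies = names(strategy_rules()),
                                sq_profile = default_status_quo_profile(group),
                                perf = default_test_performance(),
                                rules = strategy_rules(),
                                costs = default_cost_schedule(),
                                utilities = default_utility_schedule(),
                                dspec = discount_spec()) {
  coh <- initialize_cohort(n, group, params = params, seed = seed)
  base_ledger <- simulate_lifetime(coh, params, NULL)
  base_out <- accumulate_outcomes(base_ledger, costs, utilities, dspec)
  base_out$qalyg <- 0
  rows <- lapply(strategies, function(snm) {
    if (snm == "no_screening") return(base_out)
    rule <- rules[[snm]]
    prof <- derive_strategy_profile(sq_profile, rule, group)
    pol <- screening_policy(rule, prof, perf)
    led <- simulate_lifetime(coh, params, pol)
    accumulate_outcomes(led, costs, utilities, dspec, baseline = base_ledger)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Map named behavioural/test overrides (PSA draws, one-way SA endpoints)
# onto the model's inputs. Recognised names follow psa_distributions()
# plus cost_<item> entries.
apply_overrides <- function(overrides,
                            perf = default_test_performance(),
                            rules = strategy_rules(),
                            profile, costs = default_cost_schedule()) {
  ov <- as.list(overrides)
  for (nm in names(ov)) {
    v <- ov[[nm]]
    if (grepl("^(colo|ctc|fit|mtsdna)_sens_|^(colo|ctc|fit|mtsdna)_spec", nm)) {
      mod <- sub("_.*", "", nm)
      mod <- c(colo = "colonoscopy", ctc = "ctc", fit = "fit",
               mtsdna = "mtsdna")[[mod]]
      field <- sub("^[a-z]+_", "", nm)
      if (field == "spec") field <- "specificity"
      perf[[mod]][[field]] <- v
    } else if (nm == "rr_ctc_from_colonoscopy") {
      rules$ctc_only$mult[["colonoscopy"]] <- v
    } else if (nm == "rr_ctc_from_fit") {
      rules$ctc_only$mult[["fit"]] <- v
    } else if (nm == "rr_colonoscopy_from_fit") {
      rules$colonoscopy_only$mult[["fit"]] <- v
    } else if (nm == "rr_fit_from_colonoscopy") {
      rules$fit_only$mult[["colonoscopy"]] <- v
      rules$mtsdna_only$mult[["colonoscopy"]] <- v
    } else if (nm == "or_repeat_ctc_black") {
      rules$ctc_only$or_black <- v
    } else if (grepl("^followup_", nm)) {
      profile$followup[[sub("followup_", "", nm)]] <- v
    } else if (grepl("^surveillance_", nm)) {
      profile$surveillance[[sub("surveillance_", "", nm)]] <- v
    } else if (grepl("^cost_screen_", nm)) {
      costs$screen[[sub("cost_screen_", "", nm)]] <- v
    } else if (grepl("^cost_", nm)) {
      costs[[sub("cost_", "", nm)]] <- v
    } else {
      stop("unrecognised override: ", nm, call. = FALSE)
    }
  }
  list(perf = perf, rules = rules, profile = profile, costs = costs)
}

#' Base-case configuration for the one-way sensitivity analysis
#'
#' Named base values for the behavioural and cost parameters varied in
#' the tornado analysis (wide ranges are supplied separately).
#'
#' @return named list
#' @export
crc_sa_config <- function() {
  list(rr_ctc_from_colonoscopy = 1.80, rr_ctc_from_fit = 0.53,
       rr_fit_from_colonoscopy = 3.45, rr_colonoscopy_from_fit = 0.29,
       or_repeat_ctc_black = 1.83,
       followup_ctc = 0.977, followup_fit = 0.487, followup_mtsdna = 0.666,
       surveillance_low = 0.447, surveillance_high = 0.546,
       ctc_sens_large = 0.879, ctc_sens_crc = 0.961,
       cost_screen_colonoscopy = 1600, cost_screen_ctc = 600)
}

#' Evaluator comparing CTC-only and the status quo for one-way SA
#'
#' Builds an evaluation function over configs from [crc_sa_config()]
#' that reruns the two focal strategies seed-aligned and returns their
#' (cost, qalyg) rows, CTC-only first.
#'
#' @param group one of [crc_groups()]
#' @param params [disease_params()]
#' @param n cohort size per evaluation
#' @param seed common-random-number seed
#' @return function(config) -> data.frame(strategy, cost, qalyg)
#' @export
crc_sa_evaluator <- function(group, params = default_disease_params(group),
                             n = 1000L, seed = 1L) {
  function(config) {
    mapped <- apply_overrides(config, profile = default_status_quo_profile(group))
    simulate_strategies(group, params, n = n, seed = seed,
                        strategies = c("ctc_only", "status_quo"),
                        sq_profile = mapped$profile, perf = mapped$perf,
                        rules = mapped$rules, costs = mapped$costs)
  }
}

#' Outcome function for the probabilistic sensitivity analysis
#'
#' Returns a closure suitable for [run_psa()]: each PSA draw is mapped
#' onto test performance, multipliers, follow-up and surveillance
#' adherence, the calibrated set (a `disease_params` object, or NULL for
#' the base parameters) selects the natural history, and all strategies
#' are simulated seed-aligned.
#'
#' @param group one of [crc_groups()]
#' @param base_params default [disease_params()] when a calibrated set is
#'   not supplied
#' @param n cohort size per simulation
#' @param strategies strategies to evaluate
#' @return function(draw, calib_set, seed) -> data.frame(strategy, cost, qalyg)
#' @export
crc_psa_outcome_fn <- function(group, base_params = default_disease_params(group),
                               n = 500L,
                               strategies = c("ctc_only", "status_quo",
                                              "colonoscopy_only", "fit_only",
                                              "mtsdna_only")) {
  function(draw, calib_set, seed) {
    params <- if (is.null(calib_set)) base_params else calib_set
    mapped <- apply_overrides(draw, profile = default_status_quo_profile(group))
    simulate_strategies(group, params, n = n, seed = seed %% 2147483587L,
                        strategies = strategies,
                        sq_profile = mapped$profile, perf = mapped$perf,
                        rules = mapped$rules, costs = mapped$costs)
  }
}

#' Experiment configuration
#'
#' @param groups demographic groups to run
#' @param strategies strategy names
#' @param cohort_n persons per strategy simulation (paper scale 500,000;
#'   desk preset 20,000)
#' @param calib_sets number of calibrated parameter sets carried into
#'   simulation (paper: 100)
#' @param calib_budget calibration evaluations (0 = use truth directly)
#' @param calib_n cohort size per calibration evaluation
#' @param discount_rate annual discount rate
#' @param wtp willingness-to-pay threshold
#' @param psa_draws PSA parameter draws (0 = skip)
#' @param psa_n cohort size per PSA simulation
#' @param owsa run the one-way sensitivity analysis
#' @param owsa_n cohort size per one-way evaluation
#' @param seed master seed
#' @param out_dir output directory
#' @return validated config list of class `run_config`
#' @export
run_config <- function(groups = crc_groups(),
                       strategies = names(strategy_rules()),
                       cohort_n = 2000L, calib_sets = 1L, calib_budget = 0L,
                       calib_n = 5000L, discount_rate = 0.03, wtp = 1e5,
                       psa_draws = 0L, psa_n = 500L, owsa = FALSE,
                       owsa_n = 1000L, seed = 1L, out_dir = "results") {
  cfg <- list(groups = groups, strategies = strategies,
              cohort_n = as.integer(cohort_n),
              calib_sets = as.integer(calib_sets),
              calib_budget = as.integer(calib_budget),
              calib_n = as.integer(calib_n),
              discount_rate = discount_rate, wtp = wtp,
              psa_draws = as.integer(psa_draws),
              psa_n = as.integer(psa_n), owsa = isTRUE(owsa),
              owsa_n = as.integer(owsa_n),
              seed = as.integer(seed), out_dir = out_dir)
  bad <- character(0)
  if (!all(cfg$groups %in% crc_groups())) bad <- c(bad, "groups: unknown group")
  if (!all(cfg$strategies %in% names(strategy_rules()))) {
    bad <- c(bad, "strategies: unknown strategy")
  }
  for (f in c("cohort_n", "calib_sets", "calib_n", "psa_n", "owsa_n")) {
    if (cfg[[f]] < 1L) bad <- c(bad, paste0(f, ": must be >= 1"))
  }
  if (cfg$discount_rate < 0) bad <- c(bad, "discount_rate: must be >= 0")
  if (cfg$wtp <= 0) bad <- c(bad, "wtp: must be > 0")
  if (length(bad)) {
    stop("invalid config:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full experiment: derive adherence, calibrate, simulate, CEA,
#' sensitivity analyses
#'
#' Emits, per group: the derived initial/repeat adherence table, the
#' strategy-outcome table, the CEA ladder, and (when configured) tornado
#' and CEAC tables, plus a manifest recording the seed, a config hash and
#' the package version. Rerunning with the same config reproduces all
#' tables bit-identically.
#'
#' @param config [run_config()]
#' @return invisible list of the tables written, by group
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(config$out_dir, paste0(...))
  rules <- strategy_rules()
  out_all <- list()
  for (group in config$groups) {
    gtag <- gsub(" ", "_", tolower(group))
    truth <- make_truth(config$seed, group)
    # Table-2-style derived adherence
    adh <- do.call(rbind, lapply(config$strategies, function(snm) {
      prof <- derive_strategy_profile(truth$profile, rules[[snm]], group)
      ini <- as.data.frame(as.table(prof$initial), stringsAsFactors = FALSE)
      names(ini) <- c("age_band", "origin", "probability")
      cbind(strategy = snm, schedule = "initial", ini)
    }))
    write_table(adh, path = fp("adherence_", gtag, ".tsv"))
    # calibrated parameter sets (or truth passthrough)
    if (config$calib_budget > 0) {
      targets <- make_targets(truth, config$seed, n = config$calib_n)
      space <- default_search_space()
      sfn <- function(x) summarize_for_targets(
        apply_param_scales(default_disease_params(group), x),
        scale_initial_adherence(default_status_quo_profile(group),
                                x[["initial_adherence_scale"]]),
        group, n = config$calib_n, seed = config$seed)
      calib <- calibrate(space, targets, sfn, budget = config$calib_budget,
                         seed = config$seed, top_k = config$calib_sets)
      write_table(calib$log, path = fp("calibration_log_", gtag, ".tsv"))
      sets <- lapply(seq_len(nrow(calib$top)), function(i) {
        x <- unlist(calib$top[i, space$param])
        apply_param_scales(default_disease_params(group), x)
      })
    } else {
      sets <- list(truth$params)
    }
    # simulate strategies over parameter sets, average
    dspec <- discount_spec(config$discount_rate)
    per_set <- lapply(seq_along(sets), function(k) {
      simulate_strategies(group, sets[[k]], n = config$cohort_n,
                          seed = config$seed + k,
                          strategies = config$strategies,
                          sq_profile = truth$profile, dspec = dspec)
    })
    outcomes <- per_set[[1]]
    num <- vapply(outcomes, is.numeric, logical(1))
    for (cn in names(outcomes)[num]) {
      vals <- matrix(unlist(lapply(per_set, function(x) x[[cn]])),
                     nrow = nrow(outcomes))
      outcomes[[cn]] <- rowMeans(vals)
    }
    write_table(outcomes, path = fp("outcomes_", gtag, ".tsv"))
    tables <- list(adherence = adh, outcomes = outcomes)
    if (nrow(outcomes) >= 2L) {
      ladder <- build_icer_ladder(outcomes[, c("strategy", "cost", "qalyg")],
                                  wtp = config$wtp)
      write_table(as.data.frame(ladder), path = fp("cea_", gtag, ".tsv"))
      tables$ladder <- ladder
    } else {
      message("CEA skipped for ", group, ": nothing to compare")
    }
    if (config$owsa) {
      ev <- crc_sa_evaluator(group, truth$params, n = config$owsa_n,
                             seed = config$seed)
      tor <- one_way_sa(crc_sa_config(), default_owsa_ranges(), ev,
                        wtp = config$wtp)
      write_table(tor, path = fp("tornado_", gtag, ".tsv"))
      tables$tornado <- tor
    }
    if (config$psa_draws > 0) {
      fn <- crc_psa_outcome_fn(group, truth$params, n = config$psa_n)
      psa <- run_psa(fn, n_draws = config$psa_draws,
                     calib_sets = utils::head(sets, config$calib_sets),
                     seed = config$seed)
      write_table(psa$ceac, path = fp("ceac_", gtag, ".tsv"))
      tables$ceac <- psa$ceac
    }
    out_all[[group]] <- tables
  }
  manifest <- c(paste0("package_version = ", as.character(utils::packageVersion("crcscreen"))),
                paste0("seed = ", config$seed),
                paste0("config_hash = ", config_hash(config)))
  writeLines(manifest, fp("manifest.txt"))
  invisible(out_all)
}

#' Default calibration search space
#'
#' Log-scale bounds around the reference parameters for the five free
#' scales recovered by calibration.
#'
#' @return [search_space()]
#' @export
default_search_space <- function() {
  search_space(
    param = c("onset_scale", "growth_scale", "large_to_preclinical",
              "clin_detect_scale", "initial_adherence_scale"),
    low = c(0.4, 0.4, 0.02, 0.4, 0.4),
    high = c(2.5, 2.5, 0.125, 2.5, 2.5),
    scale = "log"
  )
}

#' Wide ranges for the one-way sensitivity analysis
#' @return data.frame(param, low, high)
#' @export
default_owsa_ranges <- function() {
  data.frame(
    param = c("rr_ctc_from_colonoscopy", "rr_ctc_from_fit", "followup_ctc",
              "followup_fit", "or_repeat_ctc_black", "ctc_sens_large",
              "ctc_sens_crc", "cost_screen_colonoscopy", "cost_screen_ctc",
              "surveillance_high"),
    low = c(1.46, 0.46, 0.80, 0.20, 1.0, 0.821, 0.821, 1000, 300, 0.40),
    high = c(2.35, 0.61, 1.00, 1.00, 2.5, 0.920, 1.000, 2500, 1200, 0.70)
  )
}
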