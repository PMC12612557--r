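# Annual-cycle cohort engine. All stochastic decisions use the
# counter-based generator keyed by (seed, person id, cycle, channel), so a
# person's trajectory is independent of cohort storage order and draws are
# seed-aligned ("common random numbers") across policies and parameter
# candidates that share a seed.
#
# Within-cycle order (fixed for determinism):
#   1. screening / surveillance decision and testing,
#   2. treatment effects (polypectomy, diagnosis of detected cancer),
#   3. disease progression (at most one forward transition),
#   4. mortality (other-cause for all; CRC excess for clinical stages).

#' Initialize a cohort at the start age
#'
#' Disease states at the start age come from the model's own accumulation:
#' each person starts lesion-free at the seeding age (default 20) and the
#' progression chain is run forward to the start age with screening,
#' symptomatic detection and mortality disabled, so the cohort is alive
#' and undiagnosed at the start age with a realistic lesion mix.
#'
#' @param n cohort size (>= 1)
#' @param group one of [crc_groups()]
#' @param start_age cohort age at the start of follow-up (default 40)
#' @param params [disease_params()]
#' @param seed master seed; identical (n, group, params, seed) give an
#'   identical cohort
#' @param seeding_age age at which lesion-free accumulation starts
#' @return object of class `crc_cohort`
#' @export
initialize_cohort <- function(n, group, start_age = 40L,
                              params = default_disease_params(group),
                              seed = 1L, seeding_age = 20L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  check_group(group)
  stopifnot(inherits(params, "disease_params"), seeding_age <= start_age)
  n <- as.integer(n)
  id <- seq_len(n)
  st <- rep(STATES[["NO_LESION"]], n)
  for (a in seq.int(seeding_age, start_age - 1L)) {
    st <- nh_chain_move(id, st, a, params, seed, channel = CH$burnin_prog)
  }
  structure(list(id = id, age = as.integer(start_age), state = st,
                 tier = rep(0L, n), ys_dx = rep(0L, n),
                 dx_age = rep(NA_integer_, n), dx_stage = rep(NA_integer_, n)),
            class = "crc_cohort",
            group = group, seed = seed, params = params,
            start_age = as.integer(start_age),
            seeding_age = as.integer(seeding_age))
}

# one forward move along the progression chain (single uniform per person)
nh_chain_move <- function(id, st, age, params, seed, channel = CH$progression) {
  u <- cb_uniform(seed, id, age, channel)
  new <- st
  i <- st == 1L; new[i & u < onset_at_age(params, age)] <- 2L
  i <- st == 2L; new[i & u < params$growth_dim_small] <- 3L
  i <- st == 3L; new[i & u < params$growth_small_large] <- 4L
  i <- st == 4L; new[i & u < params$large_to_preclinical] <- 5L
  for (k in 1:3) {
    i <- st == 4L + k
    new[i & u < params$stage_progression[k]] <- 4L + k + 1L
  }
  new
}

# symptomatic (clinical) detection of preclinical cancer; returns logical
nh_detect <- function(id, st, age, params, seed) {
  det <- rep(FALSE, length(id))
  pre <- is_preclinical(st)
  if (any(pre)) {
    u <- cb_uniform(seed, id[pre], age, CH$clin_detect)
    det[pre] <- u < params$clinical_detection[st[pre] - 4L]
  }
  det
}

# mortality draws; returns list of logicals (other first, then CRC excess
# among other-cause survivors with clinical disease inside the excess window)
nh_mortality <- function(id, st, ys, age, params, seed) {
  u_o <- cb_uniform(seed, id, age, CH$death_other)
  dead_other <- u_o < qx_at_age(params, rep(age, length(id)))
  dead_crc <- rep(FALSE, length(id))
  cli <- !dead_other & is_clinical(st) & ys < params$crc_mortality_years
  if (any(cli)) {
    u_c <- cb_uniform(seed, id[cli], age, CH$death_crc)
    dead_crc[cli] <- u_c < params$crc_excess_mortality[st[cli] - 8L]
  }
  list(other = dead_other, crc = dead_crc)
}

#' Advance one person by one annual cycle (natural history only)
#'
#' Applies clinical detection, at most one forward progression step, and
#' mortality, then increments age. Screening is handled by
#' [simulate_lifetime()]; this operation is the disease clock alone.
#'
#' @param person list with `id`, `age`, `state`, `years_since_diagnosis`
#' @param params [disease_params()]
#' @param rng list with `seed` (the cohort master seed)
#' @return updated person
#' @export
step_year <- function(person, params, rng = list(seed = 1L)) {
  if (is_dead(person$state)) stop("person is dead; filter before stepping",
                                  call. = FALSE)
  a <- person$age
  ys <- if (is.null(person$years_since_diagnosis)) 0L else person$years_since_diagnosis
  st <- person$state
  if (is_preclinical(st) && nh_detect(person$id, st, a, params, rng$seed)) {
    st <- st + 4L
    person$dx_age <- a
    ys <- 0L
  } else if (!is_clinical(st)) {
    st <- nh_chain_move(person$id, st, a, params, rng$seed)
  }
  m <- nh_mortality(person$id, st, ys, a, params, rng$seed)
  if (m$other) st <- STATES[["DEAD_OTHER"]]
  else if (m$crc) st <- STATES[["DEAD_CRC"]]
  if (is_clinical(st)) ys <- ys + 1L
  person$state <- st
  person$years_since_diagnosis <- ys
  person$age <- a + 1L
  person
}

#' Simulate a cohort over its lifetime under a screening policy
#'
#' Runs annual cycles from the cohort's start age to `max_age`, recording
#' a per-person ledger of timed events (screening tests by modality,
#' diagnostic and surveillance colonoscopies, polypectomies, CRC
#' diagnoses with stage, complications, deaths). Every person ends in a
#' death state or is censored alive at `max_age`.
#'
#' @param cohort [initialize_cohort()] output
#' @param params [disease_params()] (defaults to the cohort's)
#' @param policy [screening_policy()] or `NULL` for no screening
#' @param max_age end of follow-up (default 100)
#' @param collect `"ledger"` for the full event table, `"summary"` to skip
#'   event rows (calibration mode; person-level end states are always kept)
#' @param snapshot_ages ages at which cross-sectional adenoma prevalence
#'   among the living is recorded
#' @return object of class `event_ledger`: `$events` (person_id, age,
#'   event, detail), `$persons` (end states, diagnosis, screening history),
#'   plus cohort metadata
#' @export
simulate_lifetime <- function(cohort, params = attr(cohort, "params"),
                              policy = NULL, max_age = 100L,
                              collect = c("ledger", "summary"),
                              snapshot_ages = integer(0)) {
  stopifnot(inherits(cohort, "crc_cohort"))
  collect <- match.arg(collect)
  start_age <- attr(cohort, "start_age")
  if (max_age < start_age) stop("max_age must be >= start age", call. = FALSE)
  n <- length(cohort$id)
  seed <- attr(cohort, "seed")
  id_all <- cohort$id
  st <- cohort$state
  tier <- cohort$tier
  ys <- cohort$ys_dx
  dx_age <- cohort$dx_age
  dx_stage <- cohort$dx_stage
  death_age <- rep(NA_integer_, n)
  death_cause <- rep(NA_character_, n)

  scr_on <- !is.null(policy) && policy$rule$name != "no_screening"
  strategy_name <- if (is.null(policy)) "no_screening" else policy$rule$name
  origin <- rep(1L, n)          # 1 = colonoscopy, 2 = fit
  initiated <- rep(FALSE, n)
  modality <- rep(NA_integer_, n)  # index into MODALITIES
  next_due <- rep(NA_integer_, n)
  surv_due <- rep(NA_integer_, n)
  ever_colo <- rep(FALSE, n)
  ever_stool <- rep(FALSE, n)
  ever_init <- rep(FALSE, n)
  last_test <- rep(NA_integer_, n)

  # event recorder (lists of column chunks; concatenated once at the end)
  ledger_mode <- collect == "ledger"
  ev_id <- list(); ev_age <- list(); ev_event <- list(); ev_detail <- list()
  k <- 0L
  rec <- function(ids, age, event, detail = 0L) {
    if (!ledger_mode || length(ids) == 0L) return(invisible())
    k <<- k + 1L
    ev_id[[k]] <<- ids
    ev_age[[k]] <<- rep.int(age, length(ids))
    ev_event[[k]] <<- rep.int(event, length(ids))
    ev_detail[[k]] <<- if (length(detail) == 1L) rep.int(detail, length(ids)) else detail
  }

  if (scr_on) {
    prof <- policy$profile
    rule <- policy$rule
    perf <- policy$perf
    intervals <- modality_intervals()
    mod_idx <- function(name) match(name, MODALITIES)
    # origin modality and pre-45 screening history
    u_p <- cb_uniform(seed, id_all, 0L, CH$assign_pre45)
    pre_any <- u_p < sum(prof$pre45)
    origin[!pre_any] <- NA_integer_
    origin[pre_any] <- ifelse(u_p[pre_any] < prof$pre45[["colonoscopy"]], 1L, 2L)
    u_o <- cb_uniform(seed, id_all, 0L, CH$assign_origin)
    origin[!pre_any] <- ifelse(u_o[!pre_any] < prof$origin_frac_colonoscopy, 1L, 2L)
    initiated[pre_any] <- TRUE
    ever_init[pre_any] <- TRUE
    ever_colo[pre_any & origin == 1L] <- TRUE
    ever_stool[pre_any & origin == 2L] <- TRUE
    modality[pre_any] <- if (is.na(rule$modality)) {
      ifelse(origin[pre_any] == 1L, 1L, 3L)
    } else mod_idx(rule$modality)
    # due date spread uniformly within one interval after 45
    iv0 <- intervals[modality[pre_any]]
    next_due[pre_any] <- 45L + as.integer(floor(u_o[pre_any] * iv0))
  }

  snapshots <- stats::setNames(
    rep(list(c(any = NA_real_, large = NA_real_)), length(snapshot_ages)),
    as.character(snapshot_ages))

  # vectorised colonoscopy: test with colonoscopy performance, resolve
  # findings, log events; returns indices whose tier is now > 0
  do_colonoscopy <- function(idx, a, event, channel) {
    rec(id_all[idx], a, event)
    th <- test_positive_prob(policy$perf$colonoscopy, st[idx])
    u <- cb_uniform(seed, id_all[idx], a, channel)
    hit <- idx[u < th$p & th$lesion]
    # complications at the configured per-procedure rate
    uc <- cb_uniform(seed, id_all[idx], a, CH$complication)
    rec(id_all[idx[uc < policy$complication_prob]], a, "complication")
    if (length(hit)) {
      ad <- hit[is_adenoma(st[hit])]
      if (length(ad)) {
        tier[ad[st[ad] == 3L]] <<- pmax(tier[ad[st[ad] == 3L]], 1L)
        tier[ad[st[ad] == 4L]] <<- 2L
        st[ad] <<- STATES[["NO_LESION"]]
        rec(id_all[ad], a, "polypectomy")
      }
      pc <- hit[is_preclinical(st[hit])]
      if (length(pc)) {
        st[pc] <<- st[pc] + 4L
        dx_age[pc] <<- a
        dx_stage[pc] <<- st[pc] - 8L
        ys[pc] <<- 0L
        rec(id_all[pc], a, "crc_diagnosis", st[pc] - 8L)
      }
    }
    ever_colo[idx] <<- TRUE
    idx
  }

  a <- start_age
  alive <- rep(TRUE, n)
  while (a < max_age && any(alive)) {
    if (length(snapshot_ages) && a %in% snapshot_ages) {
      snapshots[[as.character(a)]] <- c(
        any = mean(is_adenoma(st[alive])),
        large = mean(st[alive] == STATES[["ADENOMA_LARGE"]]))
    }
    ## 1. screening ---------------------------------------------------
    if (scr_on && a >= policy$screening_start && a <= policy$screening_stop) {
      prof <- policy$profile
      rule <- policy$rule
      intervals <- modality_intervals()
      el <- which(alive & st <= 8L)
      had_colo <- integer(0)
      # surveillance pathway
      sv <- el[tier[el] > 0L]
      sv <- sv[!is.na(surv_due[sv]) & surv_due[sv] <= a]
      if (length(sv)) {
        u <- cb_uniform(seed, id_all[sv], a, CH$surveillance)
        p <- prof$surveillance[ifelse(tier[sv] == 2L, "high", "low")]
        att <- sv[u < p]
        if (length(att)) {
          had_colo <- c(had_colo, do_colonoscopy(att, a, "surveillance_colonoscopy",
                                                 CH$test_result))
          last_test[att] <- a
        }
      }
      # routine pathway (no adenoma history)
      rt <- el[tier[el] == 0L]
      screeners <- integer(0); scr_mod <- integer(0)
      un <- rt[!initiated[rt]]
      if (length(un)) {
        u <- cb_uniform(seed, id_all[un], a, CH$screen_initial)
        p <- prof$initial[band_initial(a), ][origin[un]]
        go <- un[u < p]
        if (length(go)) {
          m <- if (is.na(rule$modality)) ifelse(origin[go] == 1L, 1L, 3L)
               else rep(match(rule$modality, MODALITIES), length(go))
          initiated[go] <- TRUE
          ever_init[go] <- TRUE
          modality[go] <- m
          next_due[go] <- a + intervals[m]
          screeners <- c(screeners, go); scr_mod <- c(scr_mod, m)
        }
      }
      du <- rt[initiated[rt] & !is.na(next_due[rt]) & next_due[rt] <= a]
      if (length(du)) {
        if (is.na(rule$modality) && prof$switch_prob > 0) {
          us <- cb_uniform(seed, id_all[du], a, CH$screen_switch)
          sw <- du[us < prof$switch_prob]
          modality[sw] <- ifelse(modality[sw] == 1L, 3L, 1L)
        }
        u <- cb_uniform(seed, id_all[du], a, CH$screen_repeat)
        p <- prof$repeat_prob[band_repeat(a), MODALITIES[modality[du]]]
        go <- u < p
        if (any(go)) {
          g <- du[go]
          next_due[g] <- a + intervals[modality[g]]
          screeners <- c(screeners, g); scr_mod <- c(scr_mod, modality[g])
        }
      }
      if (length(screeners)) {
        last_test[screeners] <- a
        ever_colo[screeners[scr_mod == 1L]] <- TRUE
        ever_stool[screeners[scr_mod %in% c(3L, 4L)]] <- TRUE
        # colonoscopy screeners: test + resolve immediately
        cidx <- screeners[scr_mod == 1L]
        if (length(cidx)) {
          had_colo <- c(had_colo, do_colonoscopy(cidx, a, "screen_colonoscopy",
                                                 CH$test_result))
        }
        # non-colonoscopy screeners: test, then diagnostic follow-up
        for (mi in c(2L, 3L, 4L)) {
          midx <- screeners[scr_mod == mi]
          if (!length(midx)) next
          mname <- MODALITIES[mi]
          rec(id_all[midx], a, paste0("screen_", mname))
          th <- test_positive_prob(policy$perf[[mname]], st[midx])
          u <- cb_uniform(seed, id_all[midx], a, CH$test_result)
          pos <- midx[u < th$p]
          if (length(pos)) {
            uf <- cb_uniform(seed, id_all[pos], a, CH$followup)
            fu <- pos[uf < prof$followup[[mname]]]
            if (length(fu)) {
              had_colo <- c(had_colo, do_colonoscopy(fu, a, "diagnostic_colonoscopy",
                                                     CH$followup_test))
            }
          }
        }
      }
      ## 2. treatment effects happened inside do_colonoscopy; schedule
      ## surveillance for anyone who had a colonoscopy and now has history
      hs <- had_colo[tier[had_colo] > 0L & st[had_colo] <= 8L]
      if (length(hs)) {
        surv_due[hs] <- a + policy$surveillance_intervals[
          ifelse(tier[hs] == 2L, "high", "low")]
      }
    }
    ## 3. disease progression -----------------------------------------
    li <- which(alive & st <= 8L)
    if (length(li)) {
      det <- nh_detect(id_all[li], st[li], a, params, seed)
      dd <- li[det]
      if (length(dd)) {
        st[dd] <- st[dd] + 4L
        dx_age[dd] <- a
        dx_stage[dd] <- st[dd] - 8L
        ys[dd] <- 0L
        rec(id_all[dd], a, "crc_diagnosis", st[dd] - 8L)
      }
      mv <- li[!det]
      st[mv] <- nh_chain_move(id_all[mv], st[mv], a, params, seed)
    }
    ## 4. mortality ----------------------------------------------------
    li <- which(alive)
    m <- nh_mortality(id_all[li], st[li], ys[li], a, params, seed)
    do <- li[m$other]; dc <- li[m$crc]
    if (length(do)) {
      st[do] <- STATES[["DEAD_OTHER"]]
      death_age[do] <- a; death_cause[do] <- "other"
      rec(id_all[do], a, "death_other")
    }
    if (length(dc)) {
      st[dc] <- STATES[["DEAD_CRC"]]
      death_age[dc] <- a; death_cause[dc] <- "crc"
      rec(id_all[dc], a, "death_crc")
    }
    alive <- st < 13L
    cli <- which(alive & is_clinical(st))
    ys[cli] <- ys[cli] + 1L
    a <- a + 1L
  }
  rec(id_all[alive], max_age, "censored")

  events <- if (ledger_mode) {
    data.frame(person_id = unlist(ev_id, use.names = FALSE),
               age = unlist(ev_age, use.names = FALSE),
               event = unlist(ev_event, use.names = FALSE),
               detail = unlist(ev_detail, use.names = FALSE))
  } else {
    data.frame(person_id = integer(0), age = integer(0),
               event = character(0), detail = integer(0))
  }
  persons <- data.frame(
    id = id_all,
    origin = c("colonoscopy", "fit")[origin],
    ever_initiated = ever_init,
    ever_colonoscopy = ever_colo,
    ever_stool = ever_stool,
    last_test_age = last_test,
    tier = tier,
    dx_age = dx_age,
    dx_stage = dx_stage,
    death_age = death_age,
    death_cause = death_cause,
    final_state = st
  )
  structure(list(events = events, persons = persons),
            class = "event_ledger",
            n = n, group = attr(cohort, "group"), seed = seed,
            start_age = start_age, max_age = as.integer(max_age),
            strategy = strategy_name, collect = collect,
            snapshots = snapshots)
}

#' Conservation check for an event ledger
#'
#' Verifies that every person either died (CRC or other cause) or is
#' censored alive at the maximum age, i.e. alive + dead = n.
#'
#' @param ledger [simulate_lifetime()] output
#' @return TRUE invisibly; errors if conservation fails
#' @export
check_conservation <- function(ledger) {
  stopifnot(inherits(ledger, "event_ledger"))
  p <- ledger$persons
  dead <- !is.na(p$death_age)
  alive_end <- is.na(p$death_age) & p$final_state < 13L
  if (!all(dead | alive_end) || any(dead & alive_end)) {
    stop("conservation violated: persons neither dead nor censored alive",
         call. = FALSE)
  }
  if (sum(dead) + sum(alive_end) != attr(ledger, "n")) {
    stop("conservation violated: person count mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

#' Export an event ledger as delimited text
#'
#' @param ledger [simulate_lifetime()] output
#' @param path output path
#' @return path invisibly
#' @export
write_event_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "event_ledger"))
  write_table(ledger$events, c("person_id", "age", "event", "detail"), path)
}
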