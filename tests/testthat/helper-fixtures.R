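# Shared fixtures: hand-built event ledgers and tiny parameter sets.

# a ledger assembled in code, for economics tests
synthetic_ledger <- function(events, persons, n = nrow(persons),
                             seed = 1L, strategy = "scripted",
                             group = "White men",
                             start_age = 40L, max_age = 100L) {
  structure(list(events = events, persons = persons),
            class = "event_ledger",
            n = n, group = group, seed = seed,
            start_age = start_age, max_age = as.integer(max_age),
            strategy = strategy, collect = "ledger",
            snapshots = NULL)
}

blank_persons <- function(n, death_age = NA_integer_) {
  data.frame(id = seq_len(n), origin = "colonoscopy",
             ever_initiated = FALSE, ever_colonoscopy = FALSE,
             ever_stool = FALSE, last_test_age = NA_integer_,
             tier = 0L, dx_age = NA_integer_, dx_stage = NA_integer_,
             death_age = death_age, death_cause = NA_character_,
             final_state = 1L)
}

no_events <- function() {
  data.frame(person_id = integer(0), age = integer(0),
             event = character(0), detail = integer(0))
}

# disease parameters with every rate forced to zero (immortal variant
# optionally keeps the life table)
zero_disease_params <- function(group = "White men", immortal = FALSE) {
  p <- default_disease_params(group)
  p$onset[] <- 0
  p$growth_dim_small <- 0
  p$growth_small_large <- 0
  p$large_to_preclinical <- 0
  p$stage_progression[] <- 0
  p$clinical_detection[] <- 0
  p$crc_excess_mortality[] <- 0
  if (immortal) p$life_table$qx[] <- 0
  p
}

# brute-force dominance + convex-frontier oracle for the ICER ladder
oracle_frontier <- function(df) {
  n <- nrow(df)
  dominated <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qalyg >= df$qalyg[i] &
          (df$cost < df$cost[i] | df$qalyg > df$qalyg[i]))
  }, logical(1))
  und <- which(!dominated)
  ext <- rep(FALSE, n)
  for (i in und) {
    for (j in und) for (k in und) {
      if (j == i || k == i) next
      if (df$qalyg[j] < df$qalyg[i] && df$qalyg[i] < df$qalyg[k]) {
        lam <- (df$qalyg[i] - df$qalyg[j]) / (df$qalyg[k] - df$qalyg[j])
        if ((1 - lam) * df$cost[j] + lam * df$cost[k] < df$cost[i]) {
          ext[i] <- TRUE
        }
      }
    }
  }
  frontier <- und[!ext[und]]
  frontier <- frontier[order(df$cost[frontier])]
  icer <- if (length(frontier) > 1) {
    diff(df$cost[frontier]) / diff(df$qalyg[frontier])
  } else numeric(0)
  list(frontier = df$strategy[frontier], icer = icer)
}
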