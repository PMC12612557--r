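#' Build an ICER ladder with simple and extended dominance
#'
#' Strategies are ranked by ascending cost (cost ties broken by higher
#' QALYG first; exact ties in both keep stable input order, the later row
#' being marked dominated). A strategy is (simply) dominated when a
#' cheaper-or-equal alternative yields at least as many QALYG; extended
#' dominance then removes rows until the ICER sequence between
#' consecutive undominated rows is strictly increasing. ICERs are
#' incremental cost over incremental QALYG versus the previous undominated
#' row. A strategy that beats every alternative on both axes is flagged
#' dominant, and the cost-effective strategy is the undominated row with
#' the largest ICER at or below the willingness-to-pay threshold.
#'
#' @param outcomes data.frame with columns `strategy`, `cost`, `qalyg`
#'   (unique strategy names, >= 2 rows)
#' @param wtp willingness-to-pay threshold in USD/QALYG
#' @return data.frame of class `cea_ladder`: input rows plus `status`
#'   (undominated / dominated / extended-dominated), `icer`, `dominant`,
#'   `cost_effective`; ordered by ascending cost
#' @export
build_icer_ladder <- function(outcomes, wtp = 1e5) {
  stopifnot(is.data.frame(outcomes),
            all(c("strategy", "cost", "qalyg") %in% names(outcomes)))
  if (nrow(outcomes) < 2L) stop("need at least 2 strategies", call. = FALSE)
  if (anyDuplicated(outcomes$strategy)) {
    stop("strategy names must be unique", call. = FALSE)
  }
  df <- outcomes[order(outcomes$cost, -outcomes$qalyg), , drop = FALSE]
  m <- nrow(df)
  status <- rep("undominated", m)
  # simple dominance: fewer (or equal) QALYG than a cheaper-or-tied row
  best <- df$qalyg[1]
  for (i in 2:m) {
    if (df$qalyg[i] <= best) status[i] <- "dominated" else best <- df$qalyg[i]
  }
  # extended dominance: enforce increasing ICERs among survivors
  repeat {
    und <- which(status == "undominated")
    if (length(und) < 3L) break
    ic <- diff(df$cost[und]) / diff(df$qalyg[und])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[und[bad[1] + 1L]] <- "extended-dominated"
  }
  und <- which(status == "undominated")
  icer <- rep(NA_real_, m)
  if (length(und) > 1L) {
    icer[und[-1]] <- diff(df$cost[und]) / diff(df$qalyg[und])
  }
  dominant <- vapply(seq_len(m), function(i) {
    all(df$cost[i] < df$cost[-i]) && all(df$qalyg[i] > df$qalyg[-i])
  }, logical(1))
  # decision rule: largest ICER <= wtp among undominated rows (the
  # cheapest undominated row acts as the reference with ICER 0)
  eff_icer <- icer[und]
  eff_icer[1] <- 0
  ce <- und[max(which(eff_icer <= wtp))]
  df$status <- status
  df$icer <- icer
  df$dominant <- dominant
  df$cost_effective <- seq_len(m) == ce
  rownames(df) <- NULL
  class(df) <- c("cea_ladder", "data.frame")
  attr(df, "wtp") <- wtp
  df
}

#' Net monetary benefit
#'
#' @param outcome data.frame with `cost` and `qalyg` (per 1000), or a
#'   single strategy-outcome row
#' @param wtp willingness-to-pay in USD/QALYG
#' @return wtp * qalyg - cost
#' @export
nmb <- function(outcome, wtp = 1e5) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * outcome$qalyg - outcome$cost
}

#' One-way sensitivity analysis (tornado rows)
#'
#' For each parameter, re-evaluates the comparison at the low and high
#' endpoint (all other parameters at base case) and reports the
#' incremental net monetary benefit between the two focal strategies
#' (by convention CTC-only minus status quo: positive favours CTC-only).
#' Rows are sorted by absolute swing; the top `top` are returned.
#'
#' @param base_config named list of base-case parameter values
#' @param params data.frame(param, low, high); each `param` must name an
#'   entry of `base_config`, with low <= high
#' @param eval_fn function(config) returning a data.frame with columns
#'   `strategy`, `cost`, `qalyg` for the two strategies compared; the
#'   first row is the focal strategy
#' @param wtp willingness-to-pay
#' @param top number of rows to report
#' @return data.frame(param, low, high, inmb_base, inmb_low, inmb_high,
#'   swing), sorted by decreasing |swing|
#' @export
one_way_sa <- function(base_config, params, eval_fn, wtp = 1e5, top = 10L) {
  stopifnot(is.list(base_config), is.data.frame(params),
            all(c("param", "low", "high") %in% names(params)))
  if (any(!params$param %in% names(base_config))) {
    stop("unknown parameter(s): ",
         paste(setdiff(params$param, names(base_config)), collapse = ", "),
         call. = FALSE)
  }
  if (any(params$low > params$high)) {
    stop("invalid range: low > high", call. = FALSE)
  }
  inmb <- function(config) {
    out <- eval_fn(config)
    nmb(out[1, ], wtp) - nmb(out[2, ], wtp)
  }
  base_val <- inmb(base_config)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    cfg_lo <- base_config; cfg_lo[[params$param[i]]] <- params$low[i]
    cfg_hi <- base_config; cfg_hi[[params$param[i]]] <- params$high[i]
    lo <- inmb(cfg_lo); hi <- inmb(cfg_hi)
    data.frame(param = params$param[i], low = params$low[i],
               high = params$high[i], inmb_base = base_val,
               inmb_low = lo, inmb_high = hi, swing = abs(hi - lo))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$swing), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top)
}
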