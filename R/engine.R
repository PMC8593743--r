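#' PASI75 review schedule for a treatment line
#'
#' Reviews fall 12 weeks after the line starts (end of induction) and then at
#' the end of every 24-week maintenance period (with default timeline
#' settings). By default only reviews strictly inside the horizon are
#' returned, matching the PBS assessment cadence; the engine additionally
#' applies the review coinciding with the horizon when the reward convention
#' requests it.
#'
#' @param line_start_week week offset at which the line starts.
#' @param timeline a [timeline()].
#' @param include_horizon include a review falling exactly at the horizon?
#' @return numeric vector of review week offsets (possibly empty).
#' @export
review_schedule <- function(line_start_week, timeline, include_horizon = FALSE) {
  stopifnot(inherits(timeline, "psor_timeline"))
  H <- timeline$horizon_weeks
  if (line_start_week < 0 || line_start_week > H)
    stop("line start must lie within the horizon", call. = FALSE)
  first <- line_start_week + timeline$cycle_weeks
  if (first > H) return(numeric(0))
  mri <- timeline$maintenance_review_interval_weeks
  out <- seq(first, H + mri, by = mri)
  if (include_horizon) out[out <= H] else out[out < H]
}

## ---- per-cycle state costs ------------------------------------------------

# cost of one cycle (cycle j of a line, 1-based; j = 1 is induction)
line_cycle_cost <- function(drug, j, config) {
  tl <- config$timeline
  cw <- tl$cycle_weeks
  units <- dose_units_in_interval(drug$schedule, cw * (j - 1), cw * j)
  drug_cost <- units * drug$cost_per_dispense / drug$doses_per_dispense
  mon <- config$monitoring
  mon_cost <- if (j == 1) mon$visit_induction + mon$investigations_induction
  else (mon$visit_maintenance + mon$investigations_maintenance) *
    cw / tl$maintenance_review_interval_weeks
  drug_cost + mon_cost
}

# cost of one BSC cycle (j = 1 is the entry cycle with induction-level
# cyclosporine/foam costs; monitoring at maintenance rates throughout)
bsc_cycle_cost <- function(j, config) {
  tl <- config$timeline
  cw <- tl$cycle_weeks
  bsc <- config$bsc
  mon <- config$monitoring
  mon_cost <- (mon$visit_maintenance + mon$investigations_maintenance) *
    cw / tl$maintenance_review_interval_weeks
  core <- if (j == 1) bsc$cyclosporine_induction + bsc$foam_induction
  else (bsc$cyclosporine_maintenance + bsc$foam_maintenance) *
    cw / tl$maintenance_review_interval_weeks
  core + mon_cost
}

# is a review applied at the end of line-cycle j?
is_review_cycle <- function(j, mri_cycles) {
  j == 1 || (j > 1 && (j - 1) %% mri_cycles == 0)
}

## ---- cohort engine --------------------------------------------------------

#' Evaluate one strategy as a cohort state-transition model
#'
#' Runs the whole cohort through the treatment pathway over the model horizon,
#' applying PASI75 review gates at the end of induction and of each
#' maintenance period, and accrues costs and QALYs under the chosen
#' [reward_convention()]. Responders in maintenance earn the controlled
#' utility; everyone else (induction, post-failure, BSC) earns the
#' uncontrolled utility. BSC is absorbing.
#'
#' @param strategy a [strategy()].
#' @param config a `psor_scenario`.
#' @param convention a [reward_convention()].
#' @return object of class `psor_arm`: list with `strategy`, `lines`,
#'   `total_cost`, `total_qaly`, `trace` (a data frame with one row per cohort
#'   state per cycle boundary: `boundary`, `week`, `state`, `fraction`,
#'   `weight`, `cycle_cost`, `cycle_qaly`) and the convention used.
#' @export
evaluate_arm <- function(strategy, config, convention = reward_convention()) {
  stopifnot(inherits(strategy, "psor_strategy"))
  validate_scenario(config)
  stopifnot(inherits(convention, "psor_convention"))
  missing <- setdiff(strategy$lines, names(config$drugs))
  if (length(missing))
    stop("strategy references unknown drug(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  tl <- config$timeline
  cw <- tl$cycle_weeks
  NB <- tl$horizon_weeks / cw
  mri_cycles <- tl$maintenance_review_interval_weeks / cw
  L <- length(strategy$lines)
  w <- boundary_weights(convention, NB)
  u <- config$utilities

  # state keys: "L<i>.<j>" on line i cycle j; "B.<j>" BSC cycle j;
  # "T.<i>.<j>" failed at horizon while on line i cycle j (terminal only)
  state <- c("L1.1" = 1)
  advance <- function(state, at_horizon) {
    nxt <- numeric(0)
    add <- function(key, fr) nxt[key] <<- (if (is.na(nxt[key])) 0 else nxt[key]) + fr
    for (key in names(state)) {
      fr <- state[[key]]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (parts[1] == "B") { add(paste0("B.", as.integer(parts[2]) + 1), fr); next }
      if (parts[1] == "T") { add(key, fr); next }
      i <- as.integer(sub("L", "", parts[1])); j <- as.integer(parts[2])
      review <- is_review_cycle(j, mri_cycles) &&
        (!at_horizon || convention$horizon_review)
      if (!review) {
        # un-reviewed induction completion at the horizon: still uncontrolled
        key_next <- if (j == 1 && is_review_cycle(j, mri_cycles))
          sprintf("U.%d.%d", i, j + 1) else sprintf("L%d.%d", i, j + 1)
        add(key_next, fr); next
      }
      d <- config$drugs[[strategy$lines[i]]]
      p <- if (j == 1) d$p_induction else d$p_maintenance
      add(sprintf("L%d.%d", i, j + 1), fr * p)
      fail_key <- if (at_horizon) sprintf("T.%d.%d", i, j + 1)
      else if (i < L) sprintf("L%d.1", i + 1) else "B.1"
      add(fail_key, fr * (1 - p))
    }
    nxt[nxt > 0]
  }

  state_reward <- function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "B") {
      return(c(cost = bsc_cycle_cost(as.integer(parts[2]), config),
               util = u$u_uncontrolled))
    }
    if (parts[1] == "U") {
      i <- as.integer(parts[2]); j <- as.integer(parts[3])
      return(c(cost = line_cycle_cost(config$drugs[[strategy$lines[i]]], j, config),
               util = u$u_uncontrolled))
    }
    if (parts[1] == "T") {
      i <- as.integer(parts[2]); j <- as.integer(parts[3])
      cost <- switch(convention$terminal_cost,
        incumbent = line_cycle_cost(config$drugs[[strategy$lines[i]]], j, config),
        none = 0,
        next_line = if (i < L)
          line_cycle_cost(config$drugs[[strategy$lines[i + 1]]], 1, config)
        else bsc_cycle_cost(1, config))
      return(c(cost = cost, util = u$u_uncontrolled))
    }
    i <- as.integer(sub("L", "", parts[1])); j <- as.integer(parts[2])
    c(cost = line_cycle_cost(config$drugs[[strategy$lines[i]]], j, config),
      util = if (j >= 2) u$u_controlled else u$u_uncontrolled)
  }

  trace <- vector("list", NB + 1)
  total_cost <- total_qaly <- 0
  r <- tl$annual_discount_rate
  for (k in 0:NB) {
    if (k > 0) state <- advance(state, at_horizon = (k == NB))
    disc <- if (r > 0) (1 + r)^(-(k * cw) / tl$weeks_per_year) else 1
    rew <- vapply(names(state), state_reward, c(cost = 0, util = 0))
    frac <- unname(state)
    ccost <- w[k + 1] * disc * frac * rew["cost", ]
    cqaly <- w[k + 1] * disc * frac * rew["util", ] * cw / tl$weeks_per_year
    total_cost <- total_cost + sum(ccost)
    total_qaly <- total_qaly + sum(cqaly)
    trace[[k + 1]] <- data.frame(boundary = k, week = k * cw,
                                 state = names(state), fraction = frac,
                                 weight = w[k + 1], cycle_cost = unname(ccost),
                                 cycle_qaly = unname(cqaly),
                                 row.names = NULL)
  }
  structure(list(strategy = strategy$name, lines = strategy$lines,
                 total_cost = total_cost, total_qaly = total_qaly,
                 trace = do.call(rbind, trace), convention = convention),
            class = "psor_arm")
}

#' @export
print.psor_arm <- function(x, ...) {
  cat(sprintf("<arm %s> cost AUD %.0f, %.3f QALYs (%s -> BSC)\n",
              x$strategy, x$total_cost, x$total_qaly,
              paste(x$lines, collapse = " -> ")))
  invisible(x)
}

#' Evaluate all strategies of a scenario
#'
#' Convenience wrapper: [build_strategies()] then [evaluate_arm()] for each.
#'
#' @inheritParams evaluate_arm
#' @param config a `psor_scenario`.
#' @param rule optional sequencing-rule override.
#' @return named list of `psor_arm` results.
#' @export
evaluate_all_arms <- function(config, convention = reward_convention(),
                              rule = NULL) {
  strategies <- build_strategies(config, rule)
  lapply(strategies, evaluate_arm, config = config, convention = convention)
}
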