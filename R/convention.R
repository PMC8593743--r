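#' Reward accrual convention
#'
#' The PBS review cadence fixes *when* transitions can happen; it does not fix
#' how within-cycle rewards are attributed around a transition, nor how the
#' terminal half cycle at the horizon is treated. Both choices are explicit
#' here and are applied identically to costs and utilities.
#'
#' State rewards are accrued at cycle boundaries `k = 0, ..., n` (weeks
#' `k * cycle_weeks`), each boundary carrying the post-review state, with
#' weights determined by `accrual`:
#' \describe{
#'   \item{`half_cycle`}{trapezoid weights 1/2, 1, ..., 1, 1/2 — the classic
#'     half-cycle correction: every transition effectively occurs halfway
#'     through a cycle. The default; reproduces the reference results.}
#'   \item{`cycle_start`}{weights 1, ..., 1, 0 — each cycle earns the reward of
#'     the state occupied at its start.}
#'   \item{`cycle_end`}{weights 0, 1, ..., 1 — each cycle earns the reward of
#'     the state occupied at its end.}
#' }
#'
#' @param accrual boundary weighting, see above.
#' @param horizon_review apply the PASI75 review that falls exactly at the
#'   horizon (it affects only the terminal boundary reward)? Default `TRUE`.
#' @param terminal_cost cost carried by a patient who fails a review exactly at
#'   the horizon: `"incumbent"` (default) continues the failing line's drug and
#'   monitoring through the terminal half cycle (no new line is started inside
#'   it); `"none"` accrues nothing; `"next_line"` charges the next line's
#'   induction (or BSC entry) costs.
#' @return object of class `psor_convention`.
#' @export
reward_convention <- function(accrual = c("half_cycle", "cycle_start", "cycle_end"),
                              horizon_review = TRUE,
                              terminal_cost = c("incumbent", "none", "next_line")) {
  structure(list(accrual = match.arg(accrual),
                 horizon_review = isTRUE(horizon_review),
                 terminal_cost = match.arg(terminal_cost)),
            class = "psor_convention")
}

#' @export
print.psor_convention <- function(x, ...) {
  cat(sprintf("<reward convention> accrual=%s, horizon_review=%s, terminal_cost=%s\n",
              x$accrual, x$horizon_review, x$terminal_cost))
  invisible(x)
}

boundary_weights <- function(convention, n_cycles) {
  switch(convention$accrual,
         half_cycle = c(0.5, rep(1, n_cycles - 1), 0.5),
         cycle_start = c(rep(1, n_cycles), 0),
         cycle_end = c(0, rep(1, n_cycles)))
}
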