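#' Specification for a random synthetic scenario
#'
#' Controls the generator of structurally valid but random scenarios used for
#' property testing (there is no patient-level data in this model; scenarios
#' are the only input). Ranges must respect the type invariants of the target
#' fields.
#'
#' @param seed integer seed; the same spec yields the same scenario.
#' @param n_drugs number of drugs (>= 3 so three-line strategies exist).
#' @param cost_range per-dispense cost range (AUD).
#' @param efficacy_range range for induction/maintenance PASI75 probabilities.
#' @param ci_halfwidth_range range of CI half-widths (truncated to (0,1)).
#' @param utility_range range for the uncontrolled utility.
#' @param utility_gap_range range of the controlled-minus-uncontrolled gap
#'   (controlled utility truncated at 1).
#' @param schedule_menu list of loading/interval patterns to draw from;
#'   defaults to the menu observed on the PBS (front-loaded, weekly, q2w, q4w,
#'   q8w, q12w).
#' @return object of class `psor_synth_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_drugs = 8,
                           cost_range = c(500, 6000),
                           efficacy_range = c(0.3, 0.95),
                           ci_halfwidth_range = c(0.01, 0.08),
                           utility_range = c(0.4, 0.75),
                           utility_gap_range = c(0.05, 0.3),
                           schedule_menu = default_schedule_menu()) {
  stopifnot(n_drugs >= 3, cost_range[1] > 0,
            efficacy_range[1] > 0, efficacy_range[2] < 1,
            ci_halfwidth_range[1] > 0,
            utility_range[1] >= 0, utility_gap_range[1] > 0)
  if (utility_range[2] + utility_gap_range[2] > 1 + 1e-9 &&
      utility_range[2] >= 1)
    stop("utility ranges infeasible", call. = FALSE)
  structure(list(seed = seed, n_drugs = n_drugs, cost_range = cost_range,
                 efficacy_range = efficacy_range,
                 ci_halfwidth_range = ci_halfwidth_range,
                 utility_range = utility_range,
                 utility_gap_range = utility_gap_range,
                 schedule_menu = schedule_menu),
            class = "psor_synth_spec")
}

#' The PBS dosing-pattern menu
#'
#' Front-loaded, weekly, fortnightly, four-, eight- and twelve-weekly
#' patterns, mirroring the variety of real schedules.
#'
#' @return list of `list(loading, units, interval)` entries.
#' @export
default_schedule_menu <- function() {
  list(front_loaded_q4 = list(loading = c(0, 1, 2, 3, 4), units = NULL, interval = 4),
       weekly = list(loading = 0, units = NULL, interval = 1),
       double_start_q2 = list(loading = c(0, 1), units = c(2, 1), interval = 2),
       long_load_q4 = list(loading = c(0, 2, 4, 6, 8, 10, 12),
                           units = c(2, 1, 1, 1, 1, 1, 1), interval = 4),
       q8 = list(loading = c(0, 4), units = NULL, interval = 8),
       q12 = list(loading = c(0, 4), units = NULL, interval = 12))
}

#' Generate a random, structurally valid scenario
#'
#' Uniform sampling within the spec's ranges; the result always passes
#' [validate_scenario()]. Drugs are named `drug01`, `drug02`, ... and cycle
#' through the schedule menu so every pattern is exercised.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated `psor_scenario`.
#' @export
generate_scenario <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "psor_synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  runif1 <- function(r) stats::runif(1, r[1], r[2])
  menu <- spec$schedule_menu
  drugs <- list()
  for (i in seq_len(spec$n_drugs)) {
    nm <- sprintf("drug%02d", i)
    m <- menu[[(i - 1) %% length(menu) + 1]]
    p_i <- runif1(spec$efficacy_range)
    p_m <- runif1(spec$efficacy_range)
    hw_i <- runif1(spec$ci_halfwidth_range)
    hw_m <- runif1(spec$ci_halfwidth_range)
    eps <- 1e-6
    drugs[[nm]] <- drug_profile(
      nm, cost_per_dispense = runif1(spec$cost_range),
      schedule = dosing_schedule(m$loading, m$interval, m$units),
      p_induction = p_i,
      p_induction_ci = c(max(eps, p_i - hw_i), min(1 - eps, p_i + hw_i)),
      p_maintenance = p_m,
      p_maintenance_ci = c(max(eps, p_m - hw_m), min(1 - eps, p_m + hw_m)),
      doses_per_dispense = sample(c(1, 1, 1, 2, 4), 1))
  }
  uu <- runif1(spec$utility_range)
  uc <- min(1, uu + runif1(spec$utility_gap_range))
  cfg <- scenario_config(
    drugs = drugs,
    monitoring = monitoring_costs(stats::runif(1, 50, 200), stats::runif(1, 30, 120),
                                  stats::runif(1, 100, 900), stats::runif(1, 30, 150)),
    bsc = bsc_costs(stats::runif(1, 500, 3000), stats::runif(1, 1000, 7000),
                    stats::runif(1, 50, 300), stats::runif(1, 100, 500)),
    utilities = utility_set(uu, uc, sd_uncontrolled = 0.3 * uu,
                            sd_controlled = 0.1 * uc),
    timeline = timeline(),
    sequencing_rule = "base",
    notes = sprintf("synthetic scenario, seed %d", spec$seed))
  cfg
}

#' Random three-line strategies for a synthetic scenario
#'
#' Helper for property tests: draws strategies of three distinct drugs from a
#' scenario's drug list.
#'
#' @param config a `psor_scenario`.
#' @param n number of strategies.
#' @param seed integer seed.
#' @return named list of [strategy()] objects.
#' @export
random_strategies <- function(config, n = 3, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    lines <- sample(names(config$drugs), min(3, length(config$drugs)))
    strategy(paste0("s", i, "_", lines[1]), lines)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Degenerate scenarios with closed-form results
#'
#' Three corner cases whose outcomes are checkable in closed form:
#' \describe{
#'   \item{`flat_utility`}{both utilities 0.5 — every arm accrues exactly
#'     `horizon/weeks_per_year * 0.5` QALYs.}
#'   \item{`zero_efficacy`}{every review fails — the whole cohort is in BSC
#'     after the three induction periods.}
#'   \item{`perfect_efficacy`}{every review passes — the cohort never leaves
#'     the first line.}
#' }
#'
#' @param kind one of `"flat_utility"`, `"zero_efficacy"`,
#'   `"perfect_efficacy"`.
#' @param base scenario to modify (default: the bundled base case).
#' @return a `psor_scenario`.
#' @export
degenerate_scenario <- function(kind = c("flat_utility", "zero_efficacy",
                                         "perfect_efficacy"),
                                base = builtin_base_case()) {
  kind <- match.arg(kind)
  cfg <- base
  if (kind == "flat_utility") {
    cfg$utilities <- utility_set(0.5, 0.5)
  } else {
    p <- if (kind == "zero_efficacy") 0 else 1
    for (nm in names(cfg$drugs)) {
      cfg$drugs[[nm]]$p_induction <- p
      cfg$drugs[[nm]]$p_induction_ci <- c(p, p)
      cfg$drugs[[nm]]$p_maintenance <- p
      cfg$drugs[[nm]]$p_maintenance_ci <- c(p, p)
    }
  }
  validate_scenario(cfg)
  cfg
}
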