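#' Drug profile
#'
#' One biologic's economics and efficacy: PBS acquisition cost per dispense
#' (2020 AUD, net of the AUD 41.00 patient co-payment), dosing schedule, and
#' PASI75 response probabilities for the induction and maintenance review
#' gates with their 95% confidence intervals.
#'
#' @param name drug identifier (lower-case generic name).
#' @param cost_per_dispense positive cost to the health system per dispense.
#' @param schedule a [dosing_schedule()].
#' @param p_induction probability in (0,1) of PASI75 at the end of the 12-week
#'   induction period.
#' @param p_induction_ci length-2 numeric, 95% CI for `p_induction`.
#' @param p_maintenance probability in (0,1) of retaining PASI75 at each
#'   24-week maintenance review (assumed equal across reviews).
#' @param p_maintenance_ci length-2 numeric, 95% CI for `p_maintenance`.
#' @param doses_per_dispense doses covered by one dispense of the maximum PBS
#'   quantity (e.g. 2 for 2 x 40 mg adalimumab syringes). Drug cost per dose
#'   unit is `cost_per_dispense / doses_per_dispense`.
#' @return object of class `psor_drug`.
#' @export
drug_profile <- function(name, cost_per_dispense, schedule,
                         p_induction, p_induction_ci,
                         p_maintenance, p_maintenance_ci,
                         doses_per_dispense = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(schedule, "psor_schedule"))
    stop("schedule must be a dosing_schedule()", call. = FALSE)
  if (cost_per_dispense <= 0)
    stop(sprintf("%s: cost_per_dispense must be > 0", name), call. = FALSE)
  if (doses_per_dispense <= 0)
    stop(sprintf("%s: doses_per_dispense must be > 0", name), call. = FALSE)
  chk_p <- function(p, ci, lbl) {
    # boundary values 0/1 are tolerated so closed-form degenerate scenarios
    # (zero/perfect efficacy) can be expressed; realistic data lies in (0,1)
    if (p < 0 || p > 1)
      stop(sprintf("%s: %s must be in [0,1]", name, lbl), call. = FALSE)
    if (length(ci) != 2L || ci[1] > p || ci[2] < p)
      stop(sprintf("%s: %s CI must satisfy low <= point <= high", name, lbl),
           call. = FALSE)
    if (ci[1] < 0 || ci[2] > 1)
      stop(sprintf("%s: %s CI must lie in [0,1]", name, lbl), call. = FALSE)
  }
  chk_p(p_induction, p_induction_ci, "p_induction")
  chk_p(p_maintenance, p_maintenance_ci, "p_maintenance")
  structure(list(name = name,
                 cost_per_dispense = as.numeric(cost_per_dispense),
                 doses_per_dispense = as.numeric(doses_per_dispense),
                 schedule = schedule,
                 p_induction = as.numeric(p_induction),
                 p_induction_ci = as.numeric(p_induction_ci),
                 p_maintenance = as.numeric(p_maintenance),
                 p_maintenance_ci = as.numeric(p_maintenance_ci)),
            class = "psor_drug")
}

#' Monitoring costs (dermatologist visits and investigations)
#'
#' @param visit_induction,visit_maintenance AUD per induction period / per
#'   24-week maintenance period.
#' @param investigations_induction,investigations_maintenance AUD per period.
#' @return object of class `psor_monitoring`.
#' @export
monitoring_costs <- function(visit_induction, visit_maintenance,
                             investigations_induction, investigations_maintenance) {
  v <- c(visit_induction, visit_maintenance,
         investigations_induction, investigations_maintenance)
  if (any(v < 0)) stop("monitoring costs must be >= 0", call. = FALSE)
  structure(list(visit_induction = visit_induction,
                 visit_maintenance = visit_maintenance,
                 investigations_induction = investigations_induction,
                 investigations_maintenance = investigations_maintenance),
            class = "psor_monitoring")
}

#' Best-supportive-care costs
#'
#' Cyclosporine plus calcipotriol/betamethasone foam spray. Induction figures
#' cover the first 12 weeks in BSC; maintenance figures are per subsequent
#' 24-week period.
#'
#' @param cyclosporine_induction,cyclosporine_maintenance AUD.
#' @param foam_induction,foam_maintenance AUD.
#' @return object of class `psor_bsc`.
#' @export
bsc_costs <- function(cyclosporine_induction, cyclosporine_maintenance,
                      foam_induction, foam_maintenance) {
  v <- c(cyclosporine_induction, cyclosporine_maintenance,
         foam_induction, foam_maintenance)
  if (any(v < 0)) stop("BSC costs must be >= 0", call. = FALSE)
  structure(list(cyclosporine_induction = cyclosporine_induction,
                 cyclosporine_maintenance = cyclosporine_maintenance,
                 foam_induction = foam_induction,
                 foam_maintenance = foam_maintenance),
            class = "psor_bsc")
}

#' Health-state utilities
#'
#' Annual utilities for the two PASI health states with their standard
#' deviations (time trade-off derived). The uncontrolled state (PASI 16.5,
#' below PASI75 response) applies during induction, after treatment failure,
#' and in BSC; the controlled state (PASI 4.1, PASI75 response) applies to
#' responders in maintenance.
#'
#' @param u_uncontrolled,u_controlled utilities in `[0, 1]` with
#'   `u_uncontrolled <= u_controlled` (equality permitted for degenerate test
#'   scenarios).
#' @param sd_uncontrolled,sd_controlled non-negative standard deviations.
#' @return object of class `psor_utility`.
#' @export
utility_set <- function(u_uncontrolled, u_controlled,
                        sd_uncontrolled = 0, sd_controlled = 0) {
  if (u_uncontrolled < 0 || u_controlled > 1)
    stop("utilities must lie in [0, 1]", call. = FALSE)
  if (u_controlled < u_uncontrolled)
    stop("u_controlled must be >= u_uncontrolled", call. = FALSE)
  if (sd_uncontrolled < 0 || sd_controlled < 0)
    stop("utility SDs must be >= 0", call. = FALSE)
  structure(list(u_uncontrolled = u_uncontrolled, u_controlled = u_controlled,
                 sd_uncontrolled = sd_uncontrolled, sd_controlled = sd_controlled),
            class = "psor_utility")
}

#' Model timeline
#'
#' @param cycle_weeks Markov cycle length (weeks).
#' @param horizon_weeks model horizon, a multiple of `cycle_weeks`.
#' @param maintenance_review_interval_weeks PASI75 review interval after
#'   induction, a multiple of `cycle_weeks`.
#' @param weeks_per_year annualisation constant for QALYs.
#' @param annual_discount_rate discount rate (0 = none, the base case).
#' @return object of class `psor_timeline`.
#' @export
timeline <- function(cycle_weeks = 12, horizon_weeks = 96,
                     maintenance_review_interval_weeks = 24,
                     weeks_per_year = 52, annual_discount_rate = 0) {
  if (horizon_weeks %% cycle_weeks != 0)
    stop("horizon_weeks must be divisible by cycle_weeks", call. = FALSE)
  if (maintenance_review_interval_weeks %% cycle_weeks != 0)
    stop("maintenance_review_interval_weeks must be divisible by cycle_weeks",
         call. = FALSE)
  if (weeks_per_year <= 0) stop("weeks_per_year must be > 0", call. = FALSE)
  if (annual_discount_rate < 0)
    stop("annual_discount_rate must be >= 0", call. = FALSE)
  structure(list(cycle_weeks = cycle_weeks, horizon_weeks = horizon_weeks,
                 maintenance_review_interval_weeks = maintenance_review_interval_weeks,
                 weeks_per_year = weeks_per_year,
                 annual_discount_rate = annual_discount_rate),
            class = "psor_timeline")
}

#' Scenario configuration
#'
#' Bundles the full data set for one analysis: drug profiles, monitoring and
#' BSC costs, utilities, timeline and the sequencing rule used by
#' [build_strategies()].
#'
#' @param drugs named list of [drug_profile()] objects (names must match each
#'   profile's `name`).
#' @param monitoring a [monitoring_costs()].
#' @param bsc a [bsc_costs()].
#' @param utilities a [utility_set()].
#' @param timeline a [timeline()].
#' @param sequencing_rule `"base"` (second/third line risankizumab then
#'   ixekizumab) or `"alternative"` (guselkumab then ixekizumab).
#' @param notes free-text provenance notes.
#' @return object of class `psor_scenario`.
#' @export
scenario_config <- function(drugs, monitoring, bsc, utilities,
                            timeline = psorpath::timeline(),
                            sequencing_rule = c("base", "alternative"),
                            notes = character()) {
  sequencing_rule <- match.arg(sequencing_rule)
  cfg <- structure(list(drugs = drugs, monitoring = monitoring, bsc = bsc,
                        utilities = utilities, timeline = timeline,
                        sequencing_rule = sequencing_rule, notes = notes),
                   class = "psor_scenario")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks every type invariant (probabilities and CIs in (0,1), positive costs,
#' ordered utilities, timeline divisibility, resolvable drug names) and throws
#' a classed error (`psor_validation_error`) naming the offending field.
#'
#' @param config a `psor_scenario`.
#' @return `config`, invisibly, if valid.
#' @export
validate_scenario <- function(config) {
  fail <- function(field, msg) {
    stop(structure(class = c("psor_validation_error", "error", "condition"),
                   list(message = sprintf("scenario field '%s': %s", field, msg),
                        call = NULL, field = field)))
  }
  if (!inherits(config, "psor_scenario")) fail("<root>", "not a psor_scenario")
  if (!length(config$drugs)) fail("drugs", "at least one drug required")
  nm <- names(config$drugs)
  if (is.null(nm) || any(!nzchar(nm))) fail("drugs", "must be a named list")
  for (d in config$drugs) {
    if (!inherits(d, "psor_drug")) fail("drugs", "entries must be drug_profile()s")
    if (!identical(config$drugs[[d$name]]$name, d$name))
      fail(paste0("drugs.", d$name), "list name does not match profile name")
    if (d$cost_per_dispense <= 0)
      fail(paste0("drugs.", d$name, ".cost_per_dispense"), "must be > 0")
    for (p in c("p_induction", "p_maintenance")) {
      ci <- d[[paste0(p, "_ci")]]
      if (d[[p]] < 0 || d[[p]] > 1) fail(paste0("drugs.", d$name, ".", p),
                                         "must be in [0,1]")
      if (ci[1] > d[[p]] || ci[2] < d[[p]])
        fail(paste0("drugs.", d$name, ".", p, "_ci"),
             "must satisfy low <= point <= high")
    }
  }
  if (!inherits(config$monitoring, "psor_monitoring"))
    fail("monitoring", "must be monitoring_costs()")
  if (!inherits(config$bsc, "psor_bsc")) fail("bsc", "must be bsc_costs()")
  u <- config$utilities
  if (!inherits(u, "psor_utility")) fail("utilities", "must be utility_set()")
  if (u$u_controlled < u$u_uncontrolled)
    fail("utilities", "u_controlled must be >= u_uncontrolled")
  tl <- config$timeline
  if (!inherits(tl, "psor_timeline")) fail("timeline", "must be timeline()")
  if (tl$horizon_weeks %% tl$cycle_weeks != 0)
    fail("timeline.horizon_weeks", "must be divisible by cycle_weeks")
  if (!config$sequencing_rule %in% c("base", "alternative"))
    fail("sequencing_rule", "must be 'base' or 'alternative'")
  invisible(config)
}

#' @export
print.psor_scenario <- function(x, ...) {
  cat(sprintf("<psoriasis biologic scenario> %d drugs, rule '%s', horizon %g weeks\n",
              length(x$drugs), x$sequencing_rule, x$timeline$horizon_weeks))
  for (d in x$drugs)
    cat(sprintf("  %-14s AUD %7.0f/dispense (%g dose/dispense)  pI %.3f  pM %.3f\n",
                d$name, d$cost_per_dispense, d$doses_per_dispense,
                d$p_induction, d$p_maintenance))
  invisible(x)
}

## ---- serialisation -------------------------------------------------------

scenario_to_list <- function(config) {
  list(
    format = "psorpath-scenario",
    currency = "AUD-2020",
    notes = config$notes,
    sequencing_rule = config$sequencing_rule,
    timeline = unclass(config$timeline),
    monitoring = unclass(config$monitoring),
    bsc = unclass(config$bsc),
    utilities = unclass(config$utilities),
    drugs = lapply(unname(config$drugs), function(d)
      list(name = d$name,
           cost_per_dispense = d$cost_per_dispense,
           doses_per_dispense = d$doses_per_dispense,
           loading_dose_weeks = d$schedule$loading_dose_weeks,
           loading_dose_units = d$schedule$loading_dose_units,
           steady_interval_weeks = d$schedule$steady_interval_weeks,
           p_induction = d$p_induction,
           p_induction_ci = d$p_induction_ci,
           p_maintenance = d$p_maintenance,
           p_maintenance_ci = d$p_maintenance_ci))
  )
}

scenario_from_list <- function(x) {
  need <- function(f) {
    if (is.null(x[[f]])) stop(structure(
      class = c("psor_validation_error", "error", "condition"),
      list(message = sprintf("scenario field '%s': missing", f), call = NULL,
           field = f)))
    x[[f]]
  }
  drugs <- lapply(need("drugs"), function(d)
    drug_profile(d$name, d$cost_per_dispense,
                 dosing_schedule(unlist(d$loading_dose_weeks),
                                 d$steady_interval_weeks,
                                 if (is.null(d$loading_dose_units)) NULL
                                 else unlist(d$loading_dose_units)),
                 d$p_induction, unlist(d$p_induction_ci),
                 d$p_maintenance, unlist(d$p_maintenance_ci),
                 doses_per_dispense = if (is.null(d$doses_per_dispense)) 1
                 else d$doses_per_dispense))
  names(drugs) <- vapply(drugs, `[[`, "", "name")
  tl <- need("timeline"); mo <- need("monitoring"); bs <- need("bsc")
  ut <- need("utilities")
  scenario_config(
    drugs = drugs,
    monitoring = monitoring_costs(mo$visit_induction, mo$visit_maintenance,
                                  mo$investigations_induction,
                                  mo$investigations_maintenance),
    bsc = bsc_costs(bs$cyclosporine_induction, bs$cyclosporine_maintenance,
                    bs$foam_induction, bs$foam_maintenance),
    utilities = utility_set(ut$u_uncontrolled, ut$u_controlled,
                            ut$sd_uncontrolled %||% 0, ut$sd_controlled %||% 0),
    timeline = timeline(tl$cycle_weeks, tl$horizon_weeks,
                        tl$maintenance_review_interval_weeks,
                        tl$weeks_per_year %||% 52,
                        tl$annual_discount_rate %||% 0),
    sequencing_rule = x$sequencing_rule %||% "base",
    notes = as.character(x$notes %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario file
#'
#' Reads and validates a scenario document (JSON, or YAML when the yaml
#' package is available). All currency fields are 2020 AUD; all durations are
#' weeks.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` scenario file.
#' @return a validated `psor_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML scenarios requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  scenario_from_list(x)
}

#' Write a scenario file
#'
#' @param config a `psor_scenario`.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  x <- scenario_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML scenarios requires the 'yaml' package", call. = FALSE)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' The bundled Australian 2020 base-case scenario
#'
#' The reference data set: eight PBS-subsidised outpatient biologics with
#' per-dispense costs net of the AUD 41.00 co-payment, PASI75 induction and
#' maintenance probabilities with 95% CIs, PBS dosing schedules, monitoring
#' and best-supportive-care costs, and the two health-state utilities
#' (0.64 at PASI 16.5; 0.89 at PASI 4.1). Ustekinumab is priced at the single
#' 45 mg dispense suitable for an 85 kg patient.
#'
#' @return a validated `psor_scenario`.
#' @export
builtin_base_case <- function() {
  path <- system.file("extdata", "base_case_au_2020.json", package = "psorpath")
  if (!nzchar(path)) stop("bundled scenario not found; is psorpath installed?",
                          call. = FALSE)
  load_scenario(path)
}
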