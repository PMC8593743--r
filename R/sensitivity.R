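#' Beta distribution from a mean and 95% confidence interval
#'
#' Method-of-moments fit: the standard error is `(ci_high - ci_low) / (2 * 1.96)`
#' and `alpha = mean * (mean(1-mean)/se^2 - 1)`, `beta = (1-mean) * (same)`.
#' The fitted distribution's mean equals the input mean. An infeasible fit
#' (`se^2 >= mean(1-mean)`) falls back to a point mass with a warning.
#'
#' @param mean probability in (0,1).
#' @param ci_low,ci_high confidence-interval bounds, `ci_low <= ci_high`.
#' @return a `psor_distribution`: list with `family` (`"beta"` or
#'   `"point_mass"`), `pars`, `mean`, `note`.
#' @export
beta_from_mean_ci <- function(mean, ci_low, ci_high) {
  stopifnot(mean > 0, mean < 1, ci_low <= ci_high)
  se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  if (se == 0)
    return(distribution_spec("point_mass", list(value = mean), mean,
                             "degenerate CI"))
  v <- se^2
  if (v >= mean * (1 - mean)) {
    warning("beta_from_mean_ci: infeasible variance, using point mass")
    return(distribution_spec("point_mass", list(value = mean), mean,
                             "infeasible variance"))
  }
  n <- mean * (1 - mean) / v - 1
  distribution_spec("beta", list(alpha = mean * n, beta = (1 - mean) * n), mean,
                    sprintf("method of moments, se = %.5f", se))
}

#' Beta distribution from a mean and standard deviation
#'
#' Method-of-moments fit. When `sd^2 >= mean(1-mean)` no Beta distribution has
#' these moments; `infeasible` selects the fallback — `"clamp"` (default)
#' shrinks the SD to 99% of the feasible maximum and records it in the note,
#' `"point_mass"` holds the parameter fixed.
#'
#' @param mean probability in (0,1).
#' @param sd non-negative standard deviation.
#' @param infeasible fallback for infeasible moments.
#' @return a `psor_distribution`.
#' @export
beta_from_mean_sd <- function(mean, sd, infeasible = c("clamp", "point_mass")) {
  if (mean <= 0 || mean >= 1) stop("mean must be in (0,1)", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  infeasible <- match.arg(infeasible)
  if (sd == 0)
    return(distribution_spec("point_mass", list(value = mean), mean, "sd = 0"))
  max_sd <- sqrt(mean * (1 - mean))
  note <- sprintf("method of moments, sd = %.4f", sd)
  if (sd >= max_sd) {
    if (infeasible == "point_mass")
      return(distribution_spec("point_mass", list(value = mean), mean,
                               sprintf("infeasible sd %.3f >= %.3f, held fixed",
                                       sd, max_sd)))
    sd <- 0.99 * max_sd
    note <- sprintf("infeasible sd clamped to %.4f", sd)
  }
  n <- mean * (1 - mean) / sd^2 - 1
  distribution_spec("beta", list(alpha = mean * n, beta = (1 - mean) * n), mean,
                    note)
}

#' Gamma distribution from a mean and coefficient of variation
#'
#' `shape = 1/cv^2`, `scale = mean * cv^2`; the distribution mean equals the
#' input mean.
#'
#' @param mean positive mean (AUD).
#' @param cv positive coefficient of variation.
#' @return a `psor_distribution`.
#' @export
gamma_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  distribution_spec("gamma", list(shape = 1 / cv^2, scale = mean * cv^2), mean,
                    sprintf("cv = %g", cv))
}

distribution_spec <- function(family, pars, mean, note = "") {
  structure(list(family = family, pars = pars, mean = mean, note = note),
            class = "psor_distribution")
}

#' @export
print.psor_distribution <- function(x, ...) {
  cat(sprintf("<%s distribution> mean %.4g (%s) %s\n", x$family, x$mean,
              paste(sprintf("%s=%.4g", names(x$pars), unlist(x$pars)),
                    collapse = ", "), x$note))
  invisible(x)
}

#' Sample from a fitted distribution
#'
#' @param dist a `psor_distribution`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n) {
  switch(dist$family,
         beta = stats::rbeta(n, dist$pars$alpha, dist$pars$beta),
         gamma = stats::rgamma(n, shape = dist$pars$shape,
                               scale = dist$pars$scale),
         point_mass = rep(dist$pars$value, n),
         stop("unknown distribution family: ", dist$family))
}

## ---- one-way sensitivity analysis ----------------------------------------

#' One-way sensitivity parameter set
#'
#' The tornado parameters: every drug's induction and maintenance PASI75
#' probability varied over its 95% CI, both health-state utilities and the
#' four BSC cost components varied by +/-20%. Utilities are not clamped at
#' 1.0 by default (the mechanical +20% on the controlled utility exceeds
#' perfect health; set `clamp_utilities = TRUE` to cap at 1).
#'
#' @param config a `psor_scenario`.
#' @param rel_adjust relative adjustment for parameters without CIs.
#' @param clamp_utilities cap utility bounds at 1.0?
#' @return data frame: `parameter`, `kind`, `target`, `base`, `low`, `high`.
#' @export
owsa_parameters <- function(config, rel_adjust = 0.2, clamp_utilities = FALSE) {
  rows <- list()
  for (d in config$drugs) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0(d$name, ".p_induction"), kind = "efficacy_induction",
      target = d$name, base = d$p_induction,
      low = d$p_induction_ci[1], high = d$p_induction_ci[2])
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0(d$name, ".p_maintenance"), kind = "efficacy_maintenance",
      target = d$name, base = d$p_maintenance,
      low = d$p_maintenance_ci[1], high = d$p_maintenance_ci[2])
  }
  u <- config$utilities
  ub <- function(x) if (clamp_utilities) min(1, x * (1 + rel_adjust))
  else x * (1 + rel_adjust)
  rows[[length(rows) + 1]] <- data.frame(
    parameter = "u_controlled", kind = "utility", target = "u_controlled",
    base = u$u_controlled, low = u$u_controlled * (1 - rel_adjust),
    high = ub(u$u_controlled))
  rows[[length(rows) + 1]] <- data.frame(
    parameter = "u_uncontrolled", kind = "utility", target = "u_uncontrolled",
    base = u$u_uncontrolled, low = u$u_uncontrolled * (1 - rel_adjust),
    high = ub(u$u_uncontrolled))
  for (f in c("cyclosporine_induction", "cyclosporine_maintenance",
              "foam_induction", "foam_maintenance")) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("bsc.", f), kind = "bsc_cost", target = f,
      base = config$bsc[[f]], low = config$bsc[[f]] * (1 - rel_adjust),
      high = config$bsc[[f]] * (1 + rel_adjust))
  }
  do.call(rbind, rows)
}

# scenario with one parameter replaced (bypasses the u_controlled >= u_uncontrolled
# and utility <= 1 checks deliberately: OWSA perturbations are mechanical)
perturb_scenario <- function(config, kind, target, value) {
  cfg <- config
  if (kind == "efficacy_induction") {
    cfg$drugs[[target]]$p_induction <- value
    cfg$drugs[[target]]$p_induction_ci <-
      range(c(value, cfg$drugs[[target]]$p_induction_ci))
  } else if (kind == "efficacy_maintenance") {
    cfg$drugs[[target]]$p_maintenance <- value
    cfg$drugs[[target]]$p_maintenance_ci <-
      range(c(value, cfg$drugs[[target]]$p_maintenance_ci))
  } else if (kind == "utility") {
    cfg$utilities[[sub("^u_", "u_", target)]] <- value
  } else if (kind == "bsc_cost") {
    cfg$bsc[[target]] <- value
  } else stop("unknown parameter kind: ", kind)
  cfg
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates every arm with each parameter set to its low and high bound in
#' turn and records each non-reference strategy's ICUR versus the reference at
#' both ends.
#'
#' @param config a `psor_scenario`.
#' @param convention a [reward_convention()].
#' @param reference reference strategy name (default `"tildrakizumab"`).
#' @param parameters parameter table from [owsa_parameters()].
#' @param rule optional sequencing-rule override.
#' @return a `psor_owsa`: list with `tornado` (long data frame: `parameter`,
#'   `strategy`, `low_value`, `high_value`, `icur_low`, `icur_high`),
#'   `ranges` (per-strategy min/max ICUR over all parameters), `base_icur`,
#'   and the inputs used.
#' @export
run_owsa <- function(config, convention = reward_convention(),
                     reference = "tildrakizumab",
                     parameters = owsa_parameters(config),
                     rule = NULL) {
  validate_scenario(config)
  strategies <- build_strategies(config, rule)
  if (!reference %in% names(strategies))
    stop("reference strategy not found: ", reference, call. = FALSE)
  others <- setdiff(names(strategies), reference)

  arm_icurs <- function(cfg) {
    arms <- lapply(strategies, evaluate_arm, config = cfg,
                   convention = convention)
    ref <- arms[[reference]]
    vapply(arms[others], function(a)
      icur(a$total_cost, a$total_qaly, ref$total_cost, ref$total_qaly), 0)
  }
  base_icur <- arm_icurs(config)

  rows <- vector("list", nrow(parameters))
  for (i in seq_len(nrow(parameters))) {
    p <- parameters[i, ]
    lo <- arm_icurs(perturb_scenario(config, p$kind, p$target, p$low))
    hi <- arm_icurs(perturb_scenario(config, p$kind, p$target, p$high))
    rows[[i]] <- data.frame(parameter = p$parameter, strategy = others,
                            low_value = p$low, high_value = p$high,
                            icur_low = unname(lo), icur_high = unname(hi),
                            row.names = NULL)
  }
  tornado <- do.call(rbind, rows)
  ranges <- do.call(rbind, lapply(others, function(s) {
    v <- c(tornado$icur_low[tornado$strategy == s],
           tornado$icur_high[tornado$strategy == s])
    data.frame(strategy = s, icur_min = min(v), icur_max = max(v),
               parameter_min = tornado$parameter[tornado$strategy == s &
                 (tornado$icur_low == min(v) | tornado$icur_high == min(v))][1],
               parameter_max = tornado$parameter[tornado$strategy == s &
                 (tornado$icur_low == max(v) | tornado$icur_high == max(v))][1],
               row.names = NULL)
  }))
  structure(list(tornado = tornado, ranges = ranges, base_icur = base_icur,
                 reference = reference, parameters = parameters,
                 convention = convention),
            class = "psor_owsa")
}

#' @export
print.psor_owsa <- function(x, ...) {
  cat(sprintf("<one-way sensitivity analysis> reference: %s, %d parameters\n",
              x$reference, nrow(x$parameters)))
  print(within(x$ranges, {icur_min <- round(icur_min); icur_max <- round(icur_max)}))
  invisible(x)
}
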