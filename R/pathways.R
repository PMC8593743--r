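# Exhaustive pathway enumeration: every root-to-leaf sequence of review
# outcomes over the horizon. Used both as the verification oracle for the
# cohort engine and (in compiled form) as the fast evaluation basis for the
# probabilistic sensitivity analysis.

# enumerate raw pathway structures (independent of probabilities/costs)
# stint outcomes: "fail_induction", "fail_maintenance" (end < = horizon),
# "horizon" (censored on drug). `bsc_entry` = week BSC starts, or NA.
enumerate_structures <- function(lines, timeline, horizon_review) {
  cw <- timeline$cycle_weeks
  H <- timeline$horizon_weeks
  mri <- timeline$maintenance_review_interval_weeks
  paths <- list()
  rec <- function(idx, s, stints, events) {
    if (s >= H) {
      paths[[length(paths) + 1]] <<- list(stints = stints, bsc_entry = NA,
                                          events = events)
      return()
    }
    if (idx > length(lines)) {
      paths[[length(paths) + 1]] <<- list(stints = stints, bsc_entry = s,
                                          events = events)
      return()
    }
    dg <- lines[idx]
    r <- s + cw
    review_fits <- if (horizon_review) r <= H else r < H
    if (!review_fits) { # induction review does not fit: censored un-reviewed
      rec(idx, H, c(stints, list(list(drug = dg, start = s, end = H,
                                      outcome = "horizon_induction"))), events)
      return()
    }
    # fail at induction review
    rec(idx + 1, r,
        c(stints, list(list(drug = dg, start = s, end = r,
                            outcome = "fail_induction"))),
        c(events, list(list(drug = dg, phase = "induction", pass = FALSE))))
    # pass induction, then fail at the m-th maintenance review / survive all
    revs <- seq(r + mri, H + mri, by = mri)
    revs <- if (horizon_review) revs[revs <= H] else revs[revs < H]
    for (m in seq_along(revs)) {
      ev <- c(events, list(list(drug = dg, phase = "induction", pass = TRUE)))
      if (m > 1) for (z in 1:(m - 1))
        ev <- c(ev, list(list(drug = dg, phase = "maintenance", pass = TRUE)))
      ev <- c(ev, list(list(drug = dg, phase = "maintenance", pass = FALSE)))
      rec(idx + 1, revs[m],
          c(stints, list(list(drug = dg, start = s, end = revs[m],
                              outcome = "fail_maintenance"))), ev)
    }
    ev <- c(events, list(list(drug = dg, phase = "induction", pass = TRUE)))
    if (length(revs)) for (z in seq_along(revs))
      ev <- c(ev, list(list(drug = dg, phase = "maintenance", pass = TRUE)))
    paths[[length(paths) + 1]] <<- list(
      stints = c(stints, list(list(drug = dg, start = s, end = H,
                                   outcome = "horizon"))),
      bsc_entry = NA, events = ev)
  }
  rec(1, 0, list(), list())
  paths
}

# reward components of one pathway under the boundary-weight convention:
#   fixed      weighted drug + monitoring cost (incl. BSC monitoring)
#   bsc_entry_w   weight on the BSC entry-cycle cyclosporine+foam block
#   bsc_maint_w   multiplier of (cyclosporine_maintenance + foam_maintenance)
#   controlled_ww controlled weight-weeks
#   total_ww      total weight-weeks
path_components <- function(path, strategy, config, convention) {
  tl <- config$timeline
  cw <- tl$cycle_weeks
  NB <- tl$horizon_weeks / cw
  w <- boundary_weights(convention, NB)
  r <- tl$annual_discount_rate
  if (r > 0) w <- w * (1 + r)^(-(0:NB) * cw / tl$weeks_per_year)
  mon <- config$monitoring
  mon_cyc <- (mon$visit_maintenance + mon$investigations_maintenance) *
    cw / tl$maintenance_review_interval_weeks
  fixed <- 0; controlled <- 0; bsc1 <- 0; bsc2 <- 0; total_ww <- sum(w) * cw

  for (st in path$stints) {
    k0 <- st$start / cw; k1 <- st$end / cw
    if (k1 > k0) for (k in k0:(k1 - 1)) {
      j <- k - k0 + 1
      fixed <- fixed +
        w[k + 1] * line_cycle_cost(config$drugs[[st$drug]], j, config)
      if (j > 1) controlled <- controlled + w[k + 1] * cw
    }
    if (st$outcome %in% c("horizon", "horizon_induction") && k1 == NB) {
      # final boundary: the line continues (review passed, or none scheduled)
      j <- NB - k0 + 1
      fixed <- fixed +
        w[NB + 1] * line_cycle_cost(config$drugs[[st$drug]], j, config)
      if (st$outcome == "horizon") # responder at the horizon
        controlled <- controlled + w[NB + 1] * cw
    }
  }
  # failure exactly at the horizon: terminal boundary reward
  last <- path$stints[[length(path$stints)]]
  if (last$end == tl$horizon_weeks &&
      last$outcome %in% c("fail_induction", "fail_maintenance")) {
    idx <- match(last$drug, strategy$lines)
    if (convention$terminal_cost == "incumbent") {
      fixed <- fixed + w[NB + 1] *
        line_cycle_cost(config$drugs[[last$drug]],
                        NB - last$start / cw + 1, config)
    } else if (convention$terminal_cost == "next_line") {
      if (idx < length(strategy$lines)) {
        fixed <- fixed + w[NB + 1] *
          line_cycle_cost(config$drugs[[strategy$lines[idx + 1]]], 1, config)
      } else {
        # BSC entry block is a sampled quantity in the PSA: book through bsc1
        bsc1 <- bsc1 + w[NB + 1]
        fixed <- fixed + w[NB + 1] * mon_cyc
      }
    }
  }
  if (!is.na(path$bsc_entry) && path$bsc_entry < tl$horizon_weeks) {
    for (k in (path$bsc_entry / cw):NB) {
      j <- k - path$bsc_entry / cw + 1
      if (j == 1) bsc1 <- bsc1 + w[k + 1] else bsc2 <- bsc2 + w[k + 1]
      fixed <- fixed + w[k + 1] * mon_cyc
    }
  }
  list(fixed = fixed,
       bsc_entry_w = bsc1,
       bsc_maint_w = bsc2 * cw / tl$maintenance_review_interval_weeks,
       controlled_ww = controlled,
       total_ww = total_ww)
}

#' Enumerate all cohort pathways of a strategy
#'
#' The verification oracle for [evaluate_arm()]: exhaustively enumerates every
#' root-to-leaf sequence of PASI75 review outcomes over the horizon, with the
#' pathway probability as the product of branch probabilities and per-pathway
#' cost/QALY accrual under the identical reward convention. The
#' probability-weighted sums equal the cohort totals.
#'
#' @inheritParams evaluate_arm
#' @return data frame with one row per pathway: `probability`, `cost`, `qaly`
#'   and a compact `label` of the review outcomes.
#' @export
enumerate_pathways <- function(strategy, config, convention = reward_convention()) {
  stopifnot(inherits(strategy, "psor_strategy"))
  validate_scenario(config)
  comp <- compile_pathways(strategy, config, convention)
  pr <- pathway_probabilities(comp, efficacy_vector(config))
  u <- config$utilities
  costs <- pathway_costs(comp,
                         config$bsc$cyclosporine_induction + config$bsc$foam_induction,
                         config$bsc$cyclosporine_maintenance + config$bsc$foam_maintenance)
  qalys <- pathway_qalys(comp, u$u_uncontrolled, u$u_controlled,
                         config$timeline$weeks_per_year)
  data.frame(label = comp$labels, probability = pr, cost = costs, qaly = qalys,
             row.names = NULL)
}

## ---- compiled basis (shared by the oracle and the PSA) --------------------

# named efficacy vector c("<drug>.induction", "<drug>.maintenance")
efficacy_vector <- function(config) {
  out <- numeric(0)
  for (d in config$drugs) {
    out[paste0(d$name, ".induction")] <- d$p_induction
    out[paste0(d$name, ".maintenance")] <- d$p_maintenance
  }
  out
}

compile_pathways <- function(strategy, config, convention = reward_convention()) {
  tl <- config$timeline
  structures <- enumerate_structures(strategy$lines, tl, convention$horizon_review)
  pnames <- unlist(lapply(names(config$drugs), function(n)
    paste0(n, c(".induction", ".maintenance"))))
  A <- B <- matrix(0, length(structures), length(pnames),
                   dimnames = list(NULL, pnames))
  comp <- matrix(0, length(structures), 5,
                 dimnames = list(NULL, c("fixed", "bsc_entry_w", "bsc_maint_w",
                                         "controlled_ww", "total_ww")))
  labels <- character(length(structures))
  for (i in seq_along(structures)) {
    p <- structures[[i]]
    for (ev in p$events) {
      col <- paste0(ev$drug, ".",
                    if (ev$phase == "induction") "induction" else "maintenance")
      if (ev$pass) A[i, col] <- A[i, col] + 1 else B[i, col] <- B[i, col] + 1
    }
    cc <- path_components(p, strategy, config, convention)
    comp[i, ] <- unlist(cc)
    labels[i] <- paste(vapply(p$stints, function(st)
      sprintf("%s[%g-%g:%s]", st$drug, st$start, st$end, st$outcome), ""),
      collapse = " ")
  }
  list(A = A, B = B, components = comp, labels = labels,
       strategy = strategy$name)
}

# probabilities for one parameter vector (or a matrix of vectors in columns)
pathway_probabilities <- function(comp, p) {
  if (is.matrix(p)) {
    lp <- log(pmax(p, .Machine$double.xmin))
    lq <- log(pmax(1 - p, .Machine$double.xmin))
    P <- exp(comp$A %*% lp[colnames(comp$A), , drop = FALSE] +
             comp$B %*% lq[colnames(comp$B), , drop = FALSE])
    # exact zeros: a factor with p == 0 (or 1) must kill the pathway
    zero_p <- p == 0; zero_q <- p == 1
    if (any(zero_p) || any(zero_q)) {
      for (jc in seq_len(ncol(p))) {
        kill <- (comp$A %*% (zero_p[, jc] + 0) + comp$B %*% (zero_q[, jc] + 0)) > 0
        P[kill, jc] <- 0
      }
    }
    P
  } else {
    pr <- rep(1, nrow(comp$A))
    for (cn in colnames(comp$A)) {
      pv <- p[[cn]]
      a <- comp$A[, cn]; b <- comp$B[, cn]
      pr <- pr * ifelse(a > 0, pv^a, 1) * ifelse(b > 0, (1 - pv)^b, 1)
    }
    pr
  }
}

pathway_costs <- function(comp, bsc_entry_cost, bsc_maint_cost) {
  comp$components[, "fixed"] +
    comp$components[, "bsc_entry_w"] * bsc_entry_cost +
    comp$components[, "bsc_maint_w"] * bsc_maint_cost
}

pathway_qalys <- function(comp, u_uncontrolled, u_controlled, weeks_per_year) {
  cw <- comp$components[, "controlled_ww"]
  (cw * u_controlled + (comp$components[, "total_ww"] - cw) * u_uncontrolled) /
    weeks_per_year
}

#' Arm totals from the pathway oracle
#'
#' Probability-weighted totals over [enumerate_pathways()]; equals
#' [evaluate_arm()] up to numerical tolerance.
#'
#' @inheritParams evaluate_arm
#' @return list with `total_cost`, `total_qaly` and `n_pathways`.
#' @export
arm_from_pathways <- function(strategy, config, convention = reward_convention()) {
  pw <- enumerate_pathways(strategy, config, convention)
  list(total_cost = sum(pw$probability * pw$cost),
       total_qaly = sum(pw$probability * pw$qaly),
       n_pathways = nrow(pw),
       probability_total = sum(pw$probability))
}
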