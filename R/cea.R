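#' Incremental cost-utility ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`, sign preserved (dominated
#' comparators yield negative ratios). Equal QALYs make the ratio undefined
#' and return `NA` rather than infinity.
#'
#' @param cost_a,qaly_a totals of the strategy of interest.
#' @param cost_b,qaly_b totals of the comparator.
#' @return AUD per QALY, or `NA_real_` when the QALYs are equal.
#' @export
icur <- function(cost_a, qaly_a, cost_b, qaly_b) {
  dq <- qaly_a - qaly_b
  ifelse(dq == 0, NA_real_, (cost_a - cost_b) / dq)
}

#' Dominance classification and cost-utility frontier
#'
#' Classifies each strategy as on the frontier, strictly dominated (another
#' strategy costs no more and yields no fewer QALYs, with at least one strict
#' inequality), or extendedly dominated (removed because the frontier ICUR
#' sequence would otherwise not be increasing). ICURs versus the least-cost
#' strategy are reported for every strategy, dominated ones included
#' (negative values preserved); frontier members additionally carry the ICUR
#' versus the previous frontier strategy.
#'
#' @param results list of `psor_arm` objects (or any list with `strategy`,
#'   `total_cost`, `total_qaly`).
#' @return a `psor_frontier` data frame: `strategy`, `cost`, `qaly`, `status`,
#'   `icur_vs_reference`, `icur_vs_next_on_frontier`.
#' @export
classify_strategies <- function(results) {
  if (!length(results)) stop("need at least one arm result", call. = FALSE)
  df <- data.frame(
    strategy = vapply(results, function(r) r$strategy, ""),
    cost = vapply(results, function(r) r$total_cost, 0),
    qaly = vapply(results, function(r) r$total_qaly, 0),
    stringsAsFactors = FALSE)
  # deterministic order: cost, then QALY desc, then name
  df <- df[order(df$cost, -df$qaly, df$strategy), , drop = FALSE]
  n <- nrow(df)
  status <- rep("frontier", n)

  # strict dominance (ties on both dimensions are kept, not dominated)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    if (df$cost[k] <= df$cost[i] && df$qaly[k] >= df$qaly[i] &&
        (df$cost[k] < df$cost[i] || df$qaly[k] > df$qaly[i]))
      status[i] <- "strictly_dominated"
  }

  # extended dominance: walk the candidates in cost order, repeatedly removing
  # members that break the increasing-ICUR property of the frontier
  cand <- which(status == "frontier")
  repeat {
    if (length(cand) <= 2) break
    icurs <- diff(df$cost[cand]) / diff(df$qaly[cand])
    bad <- which(diff(icurs) <= 0)
    if (!length(bad)) break
    drop_idx <- cand[bad[1] + 1]
    status[drop_idx] <- "extendedly_dominated"
    cand <- setdiff(cand, drop_idx)
  }

  ref <- which.min(df$cost)  # least-cost strategy (first by ordering)
  df$status <- status
  df$icur_vs_reference <- icur(df$cost, df$qaly, df$cost[ref], df$qaly[ref])
  df$icur_vs_next_on_frontier <- NA_real_
  fr <- which(df$status == "frontier")
  if (length(fr) > 1)
    df$icur_vs_next_on_frontier[fr[-1]] <-
      diff(df$cost[fr]) / diff(df$qaly[fr])
  rownames(df) <- NULL
  class(df) <- c("psor_frontier", "data.frame")
  df
}

#' @export
print.psor_frontier <- function(x, ...) {
  y <- as.data.frame(x)
  y$cost <- round(y$cost)
  y$qaly <- round(y$qaly, 3)
  y$icur_vs_reference <- round(y$icur_vs_reference)
  y$icur_vs_next_on_frontier <- round(y$icur_vs_next_on_frontier)
  print(y)
  invisible(x)
}
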