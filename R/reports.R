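# CSV / JSON report writers used by the analysis scripts.

#' Write base-case arm results with frontier classification
#'
#' Mirrors the reference table's columns: strategy, cost, QALYs, dominance
#' status and ICUR versus the least-cost strategy.
#'
#' @param frontier a `psor_frontier` from [classify_strategies()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_arm_results <- function(frontier, path) {
  df <- as.data.frame(frontier)
  names(df)[names(df) == "cost"] <- "cost_aud"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort trace as tidy CSV
#'
#' @param arm a `psor_arm` from [evaluate_arm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(arm, path) {
  tr <- arm$trace
  tr$strategy <- arm$strategy
  utils::write.csv(tr[, c("strategy", "boundary", "week", "state", "fraction",
                          "weight", "cycle_cost", "cycle_qaly")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the tornado table
#'
#' @param owsa a `psor_owsa` from [run_owsa()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(owsa, path) {
  utils::write.csv(owsa$tornado, path, row.names = FALSE)
  invisible(path)
}

#' Write PSA summary and CEAC tables
#'
#' @param psa a `psor_psa` from [run_psa()].
#' @param summary_path,ceac_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_psa <- function(psa, summary_path, ceac_path) {
  utils::write.csv(psa$means, summary_path, row.names = FALSE)
  utils::write.csv(psa$ceac, ceac_path, row.names = FALSE)
  invisible(c(summary_path, ceac_path))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: scenario source,
#' sequencing rule, reward convention, seed, iteration count, WTP grid and
#' package version.
#'
#' @param path output JSON path.
#' @param scenario scenario description (path or `"builtin_base_case"`).
#' @param rule sequencing rule.
#' @param convention a [reward_convention()].
#' @param seed,n_iterations PSA settings (optional).
#' @param wtp_max,wtp_step CEAC grid (optional).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, scenario, rule, convention,
                           seed = NULL, n_iterations = NULL,
                           wtp_max = NULL, wtp_step = NULL) {
  manifest <- list(
    tool = "psorpath",
    version = as.character(utils::packageVersion("psorpath")),
    scenario = scenario,
    sequencing_rule = rule,
    convention = unclass(convention),
    seed = seed, n_iterations = n_iterations,
    wtp_max = wtp_max, wtp_step = wtp_step)
  manifest <- manifest[!vapply(manifest, is.null, TRUE)]
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
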