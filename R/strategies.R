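#' Treatment strategy
#'
#' An ordered sequence of treatment lines (drug names) ending in best
#' supportive care. No drug may appear twice.
#'
#' @param name strategy identifier (conventionally the first-line drug).
#' @param lines character vector of drug names in treatment order.
#' @return object of class `psor_strategy`.
#' @export
strategy <- function(name, lines) {
  lines <- as.character(lines)
  if (!length(lines)) stop("a strategy needs at least one line", call. = FALSE)
  if (anyDuplicated(lines))
    stop("no drug may appear twice in a strategy", call. = FALSE)
  structure(list(name = name, lines = lines), class = "psor_strategy")
}

#' @export
print.psor_strategy <- function(x, ...) {
  cat(sprintf("<strategy %s> %s -> BSC\n", x$name, paste(x$lines, collapse = " -> ")))
  invisible(x)
}

#' Build the treatment strategies for a scenario
#'
#' One strategy per drug as first line. Under the base sequencing rule the
#' second and third lines are risankizumab then ixekizumab (the two most
#' effective induction agents, maximising the probability of remaining on a
#' biologic); a pathway starting on one of those two uses the other second and
#' guselkumab third. The alternative rule swaps in guselkumab then ixekizumab
#' (with risankizumab third for the pathways starting on guselkumab or
#' ixekizumab). Every strategy ends in BSC.
#'
#' @param config a `psor_scenario` (its `sequencing_rule` is used unless
#'   overridden).
#' @param rule optional override, `"base"` or `"alternative"`.
#' @return named list of [strategy()] objects, one per drug.
#' @export
build_strategies <- function(config, rule = NULL) {
  validate_scenario(config)
  rule <- rule %||% config$sequencing_rule
  if (!rule %in% c("base", "alternative"))
    stop("unknown sequencing_rule: ", rule, call. = FALSE)
  pick <- function(first) {
    if (rule == "base") {
      second <- "risankizumab"; third <- "ixekizumab"; backup <- "guselkumab"
    } else {
      second <- "guselkumab"; third <- "ixekizumab"; backup <- "risankizumab"
    }
    if (first == second) c(first, third, backup)
    else if (first == third) c(first, second, backup)
    else c(first, second, third)
  }
  drugs <- names(config$drugs)
  out <- lapply(drugs, function(d) {
    lines <- pick(d)
    missing <- setdiff(lines, drugs)
    if (length(missing))
      stop("sequencing rule '", rule, "' references drugs absent from the scenario: ",
           paste(missing, collapse = ", "), call. = FALSE)
    strategy(d, lines)
  })
  stats::setNames(out, drugs)
}
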