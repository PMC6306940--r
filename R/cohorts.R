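# Outcome-rate comparison between two disjoint patient cohorts: the
# "virtual perturbation experiment" primitive.

#' Compare an outcome between two cohorts
#'
#' Builds the 2x2 table with rows = exposed/unexposed cohort and columns =
#' outcome/no outcome, reports the per-cohort outcome rates, their risk
#' ratio and a Fisher exact p-value (two-sided by default).  Rates are kept
#' at full precision internally; the print method rounds to one decimal in
#' percent.
#'
#' @param cohort_exposed,cohort_unexposed Two disjoint `ae_corpus` objects
#'   (no shared `case_id`).
#' @param outcome One of the seven codes of [outcome_codes()].
#' @param sided Sidedness of the Fisher test, `"two"` (default) or
#'   `"one"`.
#' @return A `cohort_comparison`: outcome, the [contingency_table()]
#'   (a = outcome cases in the exposed cohort), `rate_exposed` and
#'   `rate_unexposed` in percent, `risk_ratio`, `p`.
#' @export
compare_outcome <- function(cohort_exposed, cohort_unexposed, outcome,
                            sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(inherits(cohort_exposed, "ae_corpus"),
            inherits(cohort_unexposed, "ae_corpus"))
  if (!outcome %in% .OUTCOME_CODES)
    stop(sprintf("unknown outcome code: %s", outcome), call. = FALSE)
  if (nrow(cohort_exposed) == 0L || nrow(cohort_unexposed) == 0L)
    stop("both cohorts must be non-empty", call. = FALSE)
  shared <- intersect(cohort_exposed$case_id, cohort_unexposed$case_id)
  if (length(shared))
    stop(sprintf("cohorts are not disjoint (e.g. case %s)", shared[1]),
         call. = FALSE)
  a <- sum(vapply(cohort_exposed$outcomes, function(o) outcome %in% o,
                  logical(1)))
  c_ <- sum(vapply(cohort_unexposed$outcomes, function(o) outcome %in% o,
                   logical(1)))
  compare_outcome_counts(a, nrow(cohort_exposed), c_, nrow(cohort_unexposed),
                         outcome = outcome, sided = sided)
}

#' @rdname compare_outcome
#' @param n_outcome_exposed,n_exposed,n_outcome_unexposed,n_unexposed Raw
#'   counts for building the comparison directly from a printed 2x2 (e.g.
#'   published cohort totals) without case-level data.
#' @export
compare_outcome_counts <- function(n_outcome_exposed, n_exposed,
                                   n_outcome_unexposed, n_unexposed,
                                   outcome = "DE", sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_exposed <= 0 || n_unexposed <= 0)
    stop("both cohorts must be non-empty", call. = FALSE)
  if (n_outcome_exposed > n_exposed || n_outcome_unexposed > n_unexposed)
    stop("outcome count exceeds cohort size", call. = FALSE)
  tab <- contingency_table(n_outcome_exposed, n_exposed - n_outcome_exposed,
                           n_outcome_unexposed,
                           n_unexposed - n_outcome_unexposed)
  rate_exp <- 100 * tab$a / (tab$a + tab$b)
  rate_une <- 100 * tab$c / (tab$c + tab$d)
  structure(list(outcome = outcome, table = tab,
                 rate_exposed = rate_exp, rate_unexposed = rate_une,
                 risk_ratio = if (rate_une > 0) rate_exp / rate_une else Inf,
                 p = .fisher_p(tab$a, tab$b, tab$c, tab$d, sided),
                 sided = sided),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> outcome %s\n", x$outcome))
  cat(sprintf("  exposed:   %.0f/%.0f (%.1f%%)\n", x$table$a,
              x$table$a + x$table$b, x$rate_exposed))
  cat(sprintf("  unexposed: %.0f/%.0f (%.1f%%)\n", x$table$c,
              x$table$c + x$table$d, x$rate_unexposed))
  cat(sprintf("  risk ratio %.3f, Fisher %s-sided p = %.2g\n",
              x$risk_ratio, x$sided, x$p))
  invisible(x)
}

#' Flatten a cohort comparison to a one-row table
#'
#' @param comparison A `cohort_comparison`.
#' @return A one-row `data.table`.
#' @export
comparison_record <- function(comparison) {
  stopifnot(inherits(comparison, "cohort_comparison"))
  with(comparison, data.table(
    outcome = outcome, a = table$a, b = table$b, c = table$c, d = table$d,
    rate_exposed = rate_exposed, rate_unexposed = rate_unexposed,
    risk_ratio = risk_ratio, p = p, sided = sided))
}
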