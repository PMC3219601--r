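#' Survival cohort with fixed follow-up statuses
#'
#' Per-sample expression plus metastasis-free status at fixed follow-up
#' years (1, 3, 5): `"event"`, `"event-free"` or `"unknown"`. Statuses must
#' be monotone where known (an event by year 1 implies an event by years
#' 3 and 5). Optional `time`/`event` columns support Kaplan-Meier curves.
#'
#' @param df data frame with columns `id`, `expression`, `status_y1`,
#'   `status_y3`, `status_y5` and optionally `time`, `event` (0/1,
#'   1 = event observed, 0 = censored).
#' @param years the declared follow-up years (default `c(1, 3, 5)`).
#' @return A `survival_cohort`.
#' @export
survival_cohort <- function(df, years = c(1, 3, 5)) {
  need <- c("id", "expression", paste0("status_y", years))
  .assert(all(need %in% names(df)), "survival_cohort: missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  .assert(!anyDuplicated(df$id), "survival_cohort: duplicated sample id")
  statcols <- paste0("status_y", years)
  for (cl in statcols) {
    .assert(all(df[[cl]] %in% c("event", "event-free", "unknown")),
            "survival_cohort: %s has values outside event/event-free/unknown", cl)
  }
  # monotone consistency across known statuses
  for (i in seq_along(years)[-1]) {
    earlier <- df[[statcols[i - 1]]]; later <- df[[statcols[i]]]
    bad <- earlier == "event" & later == "event-free"
    .assert(!any(bad),
            "survival_cohort: sample '%s' has an event at year %d but is event-free at year %d",
            df$id[which(bad)[1]], years[i - 1], years[i])
  }
  structure(df, class = c("survival_cohort", "data.frame"), years = years)
}

#' @export
print.survival_cohort <- function(x, ...) {
  yrs <- attr(x, "years")
  ev <- vapply(paste0("status_y", yrs), function(cl) sum(x[[cl]] == "event"), 0L)
  cat(sprintf("<survival_cohort> %d samples; events by year: %s\n", nrow(x),
              paste(sprintf("y%d=%d", yrs, ev), collapse = ", ")))
  invisible(x)
}

#' Stratify a cohort by expression
#'
#' Ranks samples by expression from highest to lowest and returns the top
#' and bottom `floor(n * fraction)` as the high and low strata. The default
#' fraction 0.10 gives the top/bottom deciles; 0.25 gives the quartile
#' split used for Kaplan-Meier displays. Ties are broken by stable input
#' order, with a warning.
#'
#' @param cohort a [survival_cohort()].
#' @param fraction stratum size as a fraction of the cohort, in (0, 0.5].
#' @return List with character vectors `high` and `low` of sample ids.
#' @export
stratify <- function(cohort, fraction = 0.10) {
  .assert(fraction > 0 && fraction <= 0.5, "stratify: fraction must be in (0, 0.5]")
  n <- nrow(cohort)
  k <- floor(n * fraction)
  .assert(k >= 1, "stratify: cohort too small for fraction %.2f", fraction)
  o <- order(-cohort$expression)  # stable: ties keep input order
  ranked <- cohort$id[o]
  expr_sorted <- cohort$expression[o]
  if (expr_sorted[k] == expr_sorted[k + 1] ||
      expr_sorted[n - k] == expr_sorted[n - k + 1]) {
    warning("stratify: ties at a stratum boundary broken by input order")
  }
  list(high = ranked[seq_len(k)], low = ranked[seq.int(n - k + 1, n)])
}

#' Fisher exact comparison of event-free status between strata
#'
#' Builds the 2x2 table (stratum x event/event-free) at one follow-up year,
#' dropping samples with unknown status (complete case; counts reported),
#' and tests it with the two-sided Fisher exact test. The odds ratio is
#' `ad/bc`, with the Haldane 0.5 correction when a cell is zero (display
#' only; the exact p never uses the correction).
#'
#' @param cohort a [survival_cohort()].
#' @param strata result of [stratify()] (list with `high`, `low` ids).
#' @param year one of the cohort's follow-up years.
#' @return A `stratified_comparison`: list with `year`, `high`/`low`
#'   (n, events, unknown_dropped), `odds_ratio`, `or_corrected`, `p_value`.
#' @export
fisher_outcome <- function(cohort, strata, year) {
  .assert(year %in% attr(cohort, "years"), "fisher_outcome: year %s not in cohort", year)
  col <- paste0("status_y", year)
  grab <- function(ids) {
    st <- cohort[[col]][match(ids, cohort$id)]
    .assert(!anyNA(st), "fisher_outcome: unknown sample id in stratum")
    known <- st != "unknown"
    list(n = sum(known), events = sum(st == "event"),
         dropped = sum(!known))
  }
  hi <- grab(strata$high); lo <- grab(strata$low)
  .assert(hi$n > 0 && lo$n > 0,
          "fisher_outcome: a stratum is empty after dropping unknown statuses")
  tab <- matrix(c(hi$events, hi$n - hi$events, lo$events, lo$n - lo$events), 2,
                dimnames = list(c("event", "event-free"), c("high", "low")))
  p <- stats::fisher.test(tab)$p.value
  or <- .odds_ratio(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  structure(list(year = year, high = hi, low = lo, table = tab,
                 odds_ratio = or$or, or_corrected = or$corrected,
                 p_value = p),
            class = "stratified_comparison")
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat(sprintf("<stratified_comparison> year %d: high %d/%d vs low %d/%d events; OR = %.2f%s, p = %.3g\n",
              x$year, x$high$events, x$high$n, x$low$events, x$low$n,
              x$odds_ratio, if (x$or_corrected) " (Haldane-corrected)" else "",
              x$p_value))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; samples
#' censored at `t` remain at risk through `t`. Estimation delegates to
#' `survival::survfit`.
#'
#' @param time event/censoring times (>= 0).
#' @param event 1 = event observed, 0 = censored.
#' @return A `km_curve`: list with `times` (unique event times), `survival`,
#'   `at_risk`, `n`.
#' @export
km_estimate <- function(time, event) {
  .assert(length(time) == length(event) && all(time >= 0),
          "km_estimate: need equal-length time/event with time >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s); final S = %.3f\n",
              x$n, length(x$times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  f <- stats::stepfun(x$times, c(1, x$survival), right = FALSE)
  graphics::plot(f, do.points = FALSE, verticals = TRUE, ylim = c(0, 1),
                 xlab = "time", ylab = "metastasis-free fraction", ...)
  invisible(x)
}

#' Evaluate survival at given times
#' @param x a `km_curve`.
#' @param t times.
#' @return `S(t)` for each `t`.
#' @export
km_survival_at <- function(x, t) {
  vapply(t, function(tt) {
    i <- which(x$times <= tt)
    if (!length(i)) 1 else x$survival[max(i)]
  }, 0)
}

#' Association between two gene signatures
#'
#' 2x2 overlap table of two signatures against a gene universe, Fisher exact
#' p and odds ratio; the association is called significant when `p < p_cut`
#' and `OR > or_cut` (defaults 0.01 and 2).
#'
#' @param sig_a,sig_b non-empty character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene ids.
#' @param p_cut,or_cut significance filters.
#' @return List with `odds_ratio`, `or_corrected`, `p_value`, `significant`,
#'   `table`.
#' @export
signature_association <- function(sig_a, sig_b, universe,
                                  p_cut = 0.01, or_cut = 2.0) {
  .assert(length(sig_a) > 0 && length(sig_b) > 0,
          "signature_association: empty signature")
  .assert(all(sig_a %in% universe) && all(sig_b %in% universe),
          "signature_association: signatures must be subsets of the universe")
  a <- length(intersect(sig_a, sig_b))
  b <- length(setdiff(sig_a, sig_b))
  c <- length(setdiff(sig_b, sig_a))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2,
                dimnames = list(c("in_b", "not_b"), c("in_a", "not_a")))
  p <- stats::fisher.test(tab)$p.value
  or <- .odds_ratio(a, b, c, d)
  list(odds_ratio = or$or, or_corrected = or$corrected, p_value = p,
       significant = p < p_cut && or$or > or_cut, table = tab)
}

#' Read/write the cohort text format
#'
#' TSV with columns `id`, `expression`, `status_y1`, `status_y3`,
#' `status_y5` and optionally `time`, `event`.
#'
#' @param path file path.
#' @return A [survival_cohort()].
#' @export
read_cohort <- function(path) {
  survival_cohort(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort a [survival_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
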