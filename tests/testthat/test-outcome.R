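mk_cohort <- function(n, events1 = integer(0), events3 = integer(0),
                      events5 = integer(0), expr = NULL) {
  # eventsY: sample indices with an event by year Y (cumulative supersets)
  status <- function(ev) ifelse(seq_len(n) %in% ev, "event", "event-free")
  survival_cohort(data.frame(
    id = sprintf("s%03d", 1:n),
    expression = if (is.null(expr)) rev(seq_len(n)) else expr,
    status_y1 = status(events1), status_y3 = status(events3),
    status_y5 = status(events5), stringsAsFactors = FALSE))
}

test_that("cohort validation enforces status vocabulary and monotone events", {
  expect_no_error(mk_cohort(10, 1, 1:2, 1:3))
  df <- data.frame(id = "a", expression = 1, status_y1 = "event",
                   status_y3 = "event-free", status_y5 = "event-free")
  expect_error(survival_cohort(df), "event-free at year 3")
  df2 <- data.frame(id = "a", expression = 1, status_y1 = "dead",
                    status_y3 = "event", status_y5 = "event")
  expect_error(survival_cohort(df2), "outside")
})

test_that("stratification: decile and quartile splits, ties warn", {
  co <- mk_cohort(100)
  s <- stratify(co, 0.10)
  expect_length(s$high, 10); expect_length(s$low, 10)
  expect_equal(s$high, sprintf("s%03d", 1:10))   # expression is descending
  expect_equal(s$low, sprintf("s%03d", 91:100))
  sq <- stratify(co, 0.25)
  expect_length(sq$high, 25); expect_length(sq$low, 25)
  co2 <- mk_cohort(20, expr = rep(1, 20))
  expect_warning(s2 <- stratify(co2, 0.25), "ties")
  expect_equal(s2$high, sprintf("s%03d", 1:5))   # deterministic input order
  expect_error(stratify(mk_cohort(5), 0.1), "too small")
})

test_that("fisher_outcome matches exact enumeration and inverts under swap", {
  co <- mk_cohort(20, events5 = c(1:8, 11))  # high: 8/10 events, low: 1/10
  s <- stratify(co, 0.5)
  fc <- fisher_outcome(co, s, 5)
  expect_equal(fc$p_value, oracle_fisher_p(8, 2, 1, 9), tolerance = 1e-12)
  expect_equal(fc$odds_ratio, (8 * 9) / (2 * 1))
  # swap strata: OR inverts, p unchanged
  fc_sw <- fisher_outcome(co, list(high = s$low, low = s$high), 5)
  expect_equal(fc_sw$odds_ratio, 1 / fc$odds_ratio)
  expect_equal(fc_sw$p_value, fc$p_value)
  # identical event counts: OR 1, p 1
  co2 <- mk_cohort(20, events5 = c(1:3, 11:13))
  f2 <- fisher_outcome(co2, stratify(co2, 0.5), 5)
  expect_equal(f2$odds_ratio, 1); expect_equal(f2$p_value, 1)
  # zero cell: Haldane-corrected OR is finite and flagged
  co3 <- mk_cohort(20, events5 = 1:5)
  f3 <- fisher_outcome(co3, stratify(co3, 0.5), 5)
  expect_true(f3$or_corrected && is.finite(f3$odds_ratio))
})

test_that("unknown statuses are dropped per year with counts", {
  df <- data.frame(id = sprintf("s%02d", 1:20),
                   expression = rev(1:20),
                   status_y1 = "event-free",
                   status_y3 = "event-free",
                   status_y5 = c(rep("event", 4), rep("unknown", 2),
                                 rep("event-free", 14)))
  co <- survival_cohort(df)
  s <- stratify(co, 0.5)
  fc <- fisher_outcome(co, s, 5)
  expect_equal(fc$high$dropped, 2)
  expect_equal(fc$high$n, 8)
})

test_that("Kaplan-Meier equals closed forms and the hand-worked censored case", {
  # no censoring: S is the empirical survival function
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  set.seed(139)
  t <- round(rexp(40, 0.3), 3)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- sapply(km2$times, function(tt) mean(t > tt))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
  o <- oracle_km(t, rep(1, 40))
  expect_equal(km2$times, o$times)
  expect_equal(km2$survival, o$survival, tolerance = 1e-12)

  # all censored: S stays at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km3$times, 0)
  expect_equal(km_survival_at(km3, 5), 1)

  # hand-worked: n=5, event t=1, censored t=2, event t=3 -> S(3) = (4/5)(2/3)
  km4 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))
  expect_equal(km_survival_at(km4, 3), (4 / 5) * (2 / 3), tolerance = 1e-12)

  # random censored data against the hand product-limit oracle
  set.seed(149)
  for (i in 1:10) {
    tt <- sample(1:8, 30, TRUE); ev <- rbinom(30, 1, 0.6)
    if (!any(ev == 1)) ev[1] <- 1
    km5 <- km_estimate(tt, ev)
    o5 <- oracle_km(tt, ev)
    expect_equal(km5$times, o5$times)
    expect_equal(km5$survival, o5$survival, tolerance = 1e-12)
  }
})

test_that("signature association: identity, exact oracle, filters", {
  uni <- sprintf("g%04d", 1:10000)
  sa <- signature_association(uni[1:100], uni[1:100], uni)
  expect_true(sa$significant)
  # overlap 30 of 100 x 100 in 10000: exact hypergeometric and ad/bc odds
  r <- signature_association(uni[1:100], uni[c(1:30, 201:270)], uni)
  expect_equal(r$p_value, oracle_fisher_p(30, 70, 70, 9830), tolerance = 1e-9)
  expect_equal(r$odds_ratio, (30 * 9830) / (70 * 70))
  expect_true(r$significant)
  # the OR > 2 filter can veto a merely significant association
  weak <- signature_association(uni[1:2000], uni[c(1:500, 2001:3000)], uni,
                                or_cut = 10)
  expect_false(weak$significant && weak$odds_ratio <= 10)
  expect_error(signature_association(character(0), uni[1:5], uni), "empty")
  expect_error(signature_association("nope", uni[1:5], uni), "subsets")
})

test_that("cohort text format round-trips", {
  co <- gen_cohort(synthetic_design(seed = 151, cohort_n = 60))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, p)
  co2 <- read_cohort(p)
  expect_equal(co2$expression, co$expression, tolerance = 1e-6)
  expect_equal(co2$status_y5, co$status_y5)
})
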