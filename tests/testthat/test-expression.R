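test_that("median-reference normalization removes array shifts exactly", {
  set.seed(71)
  g <- 400
  base <- rnorm(g, 8, 1)
  shifts <- c(0, 0.7, -1.2, 0.3, 2.0, -0.4, 0, 0, 0, 0, 0, 0)
  mat <- sapply(shifts, function(s) base + s)
  dimnames(mat) <- list(sprintf("g%03d", 1:g), sprintf("s%02d", 1:12))
  design <- data.frame(sample = colnames(mat),
                       sirna = rep(c("siCTRL", "siPBX1"), each = 6),
                       treatment = rep(rep(c("O", "E2"), each = 3), 2))
  st <- expression_study(mat, design)
  nm <- median_reference_normalize(st)
  ref <- attr(nm, "reference")
  # pure shifts are removed exactly; all arrays collapse onto the baseline
  expect_equal(unname(nm$matrix), matrix(base, g, 12), tolerance = 1e-12)
  # defining property: per-array median difference to the reference is 0
  for (j in 1:12) expect_equal(median(nm$matrix[, j] - ref), 0)
  # idempotence is exact in the pure-shift case
  nm2 <- median_reference_normalize(nm)
  expect_equal(nm2$matrix, nm$matrix, tolerance = 1e-12)
  # identical arrays are left untouched
  same <- expression_study(matrix(base, g, 12, dimnames = dimnames(mat)), design)
  expect_equal(median_reference_normalize(same)$matrix, same$matrix)
})

test_that("normalization's median-zero property holds on noisy data, idempotence approximately", {
  set.seed(73)
  mat <- matrix(rnorm(1000 * 12, 8, 1), 1000, 12,
                dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:12)))
  mat <- sweep(mat, 2, rnorm(12, 0, 1), "+")
  design <- data.frame(sample = colnames(mat),
                       sirna = rep(c("siCTRL", "siPBX1"), each = 6),
                       treatment = rep(rep(c("O", "E2"), each = 3), 2))
  nm <- median_reference_normalize(expression_study(mat, design))
  ref <- attr(nm, "reference")
  for (j in 1:12) expect_equal(median(nm$matrix[, j] - ref), 0)
  # a second pass only moves arrays by the noise-level residual shift
  nm2 <- median_reference_normalize(nm)
  expect_lt(max(abs(nm2$matrix - nm$matrix)), 0.15)
})

test_that("detection filtering drops exactly the under-detected genes", {
  set.seed(79)
  st <- toy_study(rep(8, 50), rep(8, 50), rep(8, 50), rep(8, 50), sd = 0.1)
  det <- st$detected
  det[1:10, ] <- FALSE                  # never detected
  det[11:20, 1:11] <- FALSE             # detected once
  st2 <- expression_study(st$matrix, st$design, det)
  expect_equal(nrow(filter_detected(st2, 1)$matrix), 40)
  expect_equal(nrow(filter_detected(st2, 2)$matrix), 30)
  expect_equal(nrow(filter_detected(st2, 0)$matrix), 50)
  # counting oracle on random flags
  det[] <- runif(length(det)) < 0.5
  st3 <- expression_study(st$matrix, st$design, det)
  for (k in c(1, 6, 12)) {
    expect_equal(nrow(filter_detected(st3, k)$matrix),
                 sum(rowSums(det) >= k))
  }
})

test_that("two-class t-test: conventions, level and power", {
  # a constant gene is never responsive
  st <- toy_study(c(8, 8), c(8, 10), c(8, 8), c(8, 8), sd = 0)
  de <- two_class_ttest(st)
  expect_equal(de$significant, c(FALSE, TRUE))
  expect_equal(de$p[1], 1)         # identical values in both classes
  expect_equal(de$direction[2], "up")

  # level: exact alpha under the equal-variance Gaussian null
  set.seed(83)
  n_genes <- 6000
  st0 <- toy_study(rep(8, n_genes), rep(8, n_genes),
                   rep(8, n_genes), rep(8, n_genes), sd = 0.5, seed = 83)
  de0 <- two_class_ttest(st0, alpha = 0.01)
  rate <- mean(de0$significant)
  ci <- qbinom(c(0.0025, 0.9975), n_genes, 0.01) / n_genes
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])

  # power at delta 2, sd 0.5, n = 3/3 equals the closed-form noncentral t
  st1 <- toy_study(rep(8, 2000), rep(10, 2000),
                   rep(8, 2000), rep(8, 2000), sd = 0.5, seed = 89)
  de1 <- two_class_ttest(st1, alpha = 0.01)
  ncp <- 2 / (0.5 * sqrt(2 / 3))
  pow <- 1 - pt(qt(0.995, 4), 4, ncp) + pt(-qt(0.995, 4), 4, ncp)
  expect_equal(mean(de1$significant), pow, tolerance = 0.05)

  # responsive sets shrink monotonically in alpha
  for (alphas in list(c(0.1, 0.01), c(0.01, 0.001))) {
    s1 <- sum(two_class_ttest(st1, alpha = alphas[1])$significant)
    s2 <- sum(two_class_ttest(st1, alpha = alphas[2])$significant)
    expect_gte(s1, s2)
  }
})

test_that("four-class ANOVA: calibration, sensitivity, constant-gene convention", {
  set.seed(97)
  st0 <- toy_study(rep(8, 4000), rep(8, 4000), rep(8, 4000), rep(8, 4000),
                   sd = 0.5, seed = 97)
  a0 <- four_class_anova(st0, alpha = 0.01)
  rate <- mean(a0$significant)
  ci <- qbinom(c(0.0025, 0.9975), 4000, 0.01) / 4000
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
  # one cell shifted by 3 sigma: empirical power matches the closed-form
  # noncentral-F value (lambda = n * sum((mu - mubar)^2) / sigma^2)
  st1 <- toy_study(rep(8, 2000), rep(9.5, 2000), rep(8, 2000), rep(8, 2000),
                   sd = 0.5, seed = 101)
  lambda <- 3 * ((1.5 - 0.375)^2 + 3 * 0.375^2) / 0.25
  pow <- pf(qf(0.99, 3, 8), 3, 8, ncp = lambda, lower.tail = FALSE)
  expect_equal(mean(four_class_anova(st1, alpha = 0.01)$significant), pow,
               tolerance = 0.06)
  # constant gene
  stc <- toy_study(8, 8, 8, 8, sd = 0)
  expect_equal(four_class_anova(stc)$p, 1)
})

test_that("dependent-gene calls: boundary conventions and both criteria", {
  # knockdown abolishes the effect for genes 1-7 of 10 responsive
  mu_o <- rep(8, 12)
  mu_e <- c(rep(10, 10), 8, 8)
  mu_ke <- c(rep(8, 7), rep(10, 3), 8, 8)
  st <- toy_study(mu_o, mu_e, mu_o, mu_ke, sd = 0.25, seed = 103)
  de_c <- two_class_ttest(st, list(c("siCTRL", "O"), c("siCTRL", "E2")))
  de_k <- two_class_ttest(st, list(c("siPBX1", "O"), c("siPBX1", "E2")))
  rg <- dependent_genes(de_c, de_k)
  expect_setequal(rg$responsive_all, sprintf("g%03d", 1:10))
  expect_setequal(rg$dependent, sprintf("g%03d", 1:7))
  expect_equal(rg$dependent_fraction, 0.7)
  # significance-loss criterion agrees on this clean separation
  rg2 <- dependent_genes(de_c, de_k, method = "significance")
  expect_setequal(rg2$dependent, sprintf("g%03d", 1:7))

  # kd arm identical to ctrl arm: nothing is dependent
  st_same <- toy_study(mu_o, mu_e, mu_o, mu_e, sd = 0.25, seed = 107)
  d1 <- two_class_ttest(st_same, list(c("siCTRL", "O"), c("siCTRL", "E2")))
  d2 <- two_class_ttest(st_same, list(c("siPBX1", "O"), c("siPBX1", "E2")))
  expect_equal(dependent_genes(d1, d2)$dependent_fraction, 0,
               tolerance = 1e-12)
  # kd arm flat: everything responsive is dependent
  st_flat <- toy_study(mu_o, mu_e, mu_o, mu_o, sd = 0.25, seed = 109)
  d3 <- two_class_ttest(st_flat, list(c("siCTRL", "O"), c("siCTRL", "E2")))
  d4 <- two_class_ttest(st_flat, list(c("siPBX1", "O"), c("siPBX1", "E2")))
  expect_equal(dependent_genes(d3, d4)$dependent_fraction, 1)
})

test_that("study text interchange round-trips", {
  st <- toy_study(rep(8, 20), rep(9, 20), rep(8, 20), rep(8, 20),
                  sd = 0.3, seed = 113)
  dir <- withr::local_tempdir()
  write_expression_study(st, dir)
  st2 <- read_expression_study(file.path(dir, "expression.tsv"),
                               file.path(dir, "design.tsv"),
                               file.path(dir, "detected.tsv"))
  expect_equal(st2$matrix, st$matrix, tolerance = 1e-6)
  expect_equal(st2$design$sirna, st$design$sirna)
  expect_equal(st2$detected, st$detected)
})
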