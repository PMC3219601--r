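# Independent oracles and small fixture builders, deliberately naive:
# every oracle recomputes its quantity by direct enumeration, per-base
# bookkeeping or closed form, never through the package's own fast paths.

# Random interval set on small toy chromosomes.
rand_ivset <- function(n, chroms = c("c1", "c2"), chrom_len = 10000,
                       max_width = 300, label = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_len - max_width))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  interval_set(chrom, start, start + width, label = label)
}

# O(n^2) member-overlap oracle: does row i of a overlap any row of b?
oracle_overlaps_any <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    any(sapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])
    }))
  })
}

# Per-base boolean-vector AND oracle for base-pair overlap (toy chroms).
oracle_bp_overlap <- function(a, b, chrom_len = 10000) {
  total <- 0
  for (ch in union(a$chrom, b$chrom)) {
    va <- logical(chrom_len); vb <- logical(chrom_len)
    for (i in which(a$chrom == ch)) va[(a$start[i] + 1):a$end[i]] <- TRUE
    for (i in which(b$chrom == ch)) vb[(b$start[i] + 1):b$end[i]] <- TRUE
    total <- total + sum(va & vb)
  }
  total
}

# Exact two-sided Fisher p by enumeration over all 2x2 tables with the
# observed margins, summing tables no more probable than the observed one
# (point-probability rule, with the same 1e-7 slack R's fisher.test uses).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator (no package calls).
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    ni <- sum(time >= ut[i])
    di <- sum(time == ut[i] & event == 1)
    s <- s * (1 - di / ni)
    out[i] <- s
  }
  list(times = ut, survival = out)
}

# Naive window scanner: scores every window explicitly via score_window,
# handling the reverse strand by complementing the window string itself.
oracle_best_score <- function(seq, pwm, both_strands = TRUE) {
  L <- pwm_length(pwm)
  n <- nchar(seq)
  if (n < L) return(-Inf)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  best <- -Inf
  for (i in 1:(n - L + 1)) {
    w <- substr(seq, i, i + L - 1)
    best <- max(best, score_window(w, pwm))
    if (both_strands) best <- max(best, score_window(revcomp(w), pwm))
  }
  best
}

# Toy degenerate PWM: counts 10 on the consensus base per position.
toy_pwm <- function(consensus = "TGAT", counts = 10) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, nchar(consensus), 4, dimnames = list(NULL, bases))
  for (i in seq_len(nchar(consensus))) {
    m[i, substr(consensus, i, i)] <- counts
  }
  new_pwm("toy", m)
}

# A tiny deterministic expression study: 4 cells x n reps, given gene means.
toy_study <- function(mu_ctrl_O, mu_ctrl_E2, mu_kd_O, mu_kd_E2, n = 3,
                      sd = 0, seed = 1) {
  set.seed(seed)
  g <- length(mu_ctrl_O)
  cells <- list(c("siCTRL", "O"), c("siCTRL", "E2"),
                c("siPBX1", "O"), c("siPBX1", "E2"))
  mus <- list(mu_ctrl_O, mu_ctrl_E2, mu_kd_O, mu_kd_E2)
  cols <- list(); samp <- sirna <- treat <- character(0)
  for (i in 1:4) {
    for (r in 1:n) {
      cols[[length(cols) + 1]] <- rnorm(g, mus[[i]], sd)
      samp <- c(samp, sprintf("%s_%s_%d", cells[[i]][1], cells[[i]][2], r))
      sirna <- c(sirna, cells[[i]][1]); treat <- c(treat, cells[[i]][2])
    }
  }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(sprintf("g%03d", 1:g), samp)
  expression_study(mat, data.frame(sample = samp, sirna = sirna,
                                   treatment = treat))
}
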