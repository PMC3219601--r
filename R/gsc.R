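#' Genome-structure-corrected overlap significance (block resampling)
#'
#' Tests whether the base-pair overlap between two cistromes exceeds what
#' their chromosomal clustering alone would produce. The observed statistic
#' is [basepair_overlap()] (`basepair_overlap_marginal`). The null is a
#' GSC-style block translocation: each chromosome is tiled (with a random
#' phase per iteration) by blocks of length
#' `subregion_fraction * region_fraction * chrom_length`; the second set's
#' content is cut at block boundaries and each block is moved, as a unit and
#' preserving its internal structure, to a uniformly random position on the
#' same chromosome. Clustering at scales below the block length is thereby
#' preserved under the null, which is what distinguishes this test from a
#' naive binomial/uniform null. The defaults `region_fraction = 0.2`,
#' `subregion_fraction = 0.4` follow the conventional GSC settings for
#' cistrome comparisons.
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (n_samples + 1)`, so it is never 0 and is
#' bounded below by `1/(n_samples + 1)`.
#'
#' @param a,b `interval_set`s; `b` is the translocated set.
#' @param domain a [genome_domain()] containing both sets.
#' @param region_fraction,subregion_fraction block-size parameters in (0, 1].
#' @param n_samples number of null samples (>= 100 recommended).
#' @param seed integer seed for reproducibility.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A `gsc_result`: list with `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value`, `n_samples`, `alternative`, `degenerate`, `params`.
#' @examples
#' dom <- genome_domain(c(chrT = 100000))
#' set.seed(1)
#' a <- interval_set("chrT", s <- sort(sample(99000, 50)), s + 500)
#' gsc_test(a, a, dom, n_samples = 99, seed = 1)$p_value  # minimal p
#' @export
gsc_test <- function(a, b, domain,
                     region_fraction = 0.2, subregion_fraction = 0.4,
                     n_samples = 1000, seed = 1,
                     alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(region_fraction > 0 && region_fraction <= 1 &&
            subregion_fraction > 0 && subregion_fraction <= 1,
          "gsc_test: fractions must be in (0, 1]")
  .assert(n_samples >= 1, "gsc_test: n_samples must be positive")
  params <- list(region_fraction = region_fraction,
                 subregion_fraction = subregion_fraction,
                 n_samples = n_samples, seed = seed,
                 statistic = "basepair_overlap_marginal")
  if (!nrow(a) || !nrow(b)) {
    return(structure(list(observed = 0, null_mean = NA_real_,
                          null_sd = NA_real_, z = NA_real_, p_value = 1,
                          n_samples = n_samples, alternative = alternative,
                          degenerate = TRUE, params = params),
                     class = "gsc_result"))
  }
  .check_in_domain(a, domain, "gsc_test: set a")
  .check_in_domain(b, domain, "gsc_test: set b")
  ma <- .merge_intervals(a)
  mb <- .merge_intervals(b)
  chroms <- names(domain)
  blk <- pmax(1, round(subregion_fraction * region_fraction * as.numeric(domain)))
  names(blk) <- chroms
  .assert(all(blk <= domain),
          "gsc_test: block length exceeds a chromosome length")
  a_by <- split(ma, ma$chrom)
  b_by <- split(mb, mb$chrom)
  observed <- basepair_overlap(a, b)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_stats <- numeric(n_samples)
  for (it in seq_len(n_samples)) {
    tot <- 0
    for (ch in names(b_by)) {
      if (is.null(a_by[[ch]])) next
      L <- as.numeric(domain[[ch]]); bl <- blk[[ch]]
      d <- b_by[[ch]]
      phase <- stats::runif(1, 0, bl)
      # split intervals at block boundaries: block index of each covered run
      s <- d$start; e <- d$end
      i0 <- floor((s - phase) / bl); i1 <- floor((e - 1e-9 - phase) / bl)
      span <- which(i1 > i0)
      if (length(span)) {
        for (j in span) {
          cuts <- phase + bl * seq.int(i0[j] + 1, i1[j])
          ss <- c(s[j], cuts); ee <- c(cuts, e[j])
          s <- c(s, ss); e <- c(e, ee)
        }
        s <- s[-span]; e <- e[-span]
        i0 <- floor((s - phase) / bl)
      }
      # one uniform translocation per occupied block, shared by its fragments
      ublk <- unique(i0)
      newstart <- stats::runif(length(ublk), 0, max(L - bl, 1))
      shift <- newstart[match(i0, ublk)] - (phase + bl * i0)
      ns <- pmax(0, s + shift); ne <- pmin(L, e + shift)
      keep <- ne > ns
      ns <- ns[keep]; ne <- ne[keep]
      # merge the translocated fragments (blocks may land on each other)
      o <- order(ns)
      ns <- ns[o]; ne <- ne[o]
      if (length(ns) > 1) {
        newgrp <- c(TRUE, ns[-1] > cummax(ne[-length(ne)]))
        grp <- cumsum(newgrp)
        ne <- as.numeric(tapply(ne, grp, max))
        ns <- ns[newgrp]
      }
      da <- a_by[[ch]]
      tot <- tot + .bp_intersect(da$start, da$end, ns, ne)
    }
    null_stats[it] <- tot
  }
  null_mean <- mean(null_stats)
  null_sd <- stats::sd(null_stats)
  z <- if (is.na(null_sd) || null_sd == 0) NA_real_ else
    (observed - null_mean) / null_sd
  p_ge <- (1 + sum(null_stats >= observed)) / (n_samples + 1)
  p_le <- (1 + sum(null_stats <= observed)) / (n_samples + 1)
  p <- switch(alternative,
              greater = p_ge,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_value = p,
                 n_samples = n_samples, alternative = alternative,
                 degenerate = FALSE, params = params),
            class = "gsc_result")
}

#' @export
print.gsc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<gsc_result> degenerate (an input set is empty): observed 0, p = 1\n")
    return(invisible(x))
  }
  cat(sprintf("<gsc_result> observed %s bp, null %.1f +/- %.1f, z = %.2f, p %s %.4g (%s, %d samples)\n",
              format(x$observed, big.mark = ","), x$null_mean, x$null_sd, x$z,
              if (x$p_value <= 1 / (x$n_samples + 1)) "<=" else "=",
              x$p_value, x$alternative, x$n_samples))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1,
#' as used for families of cistrome-overlap tests (e.g. 12 comparisons).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param m number of comparisons; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  .assert(all(p_values > 0 & p_values <= 1), "bonferroni_adjust: p outside (0, 1]")
  .assert(m >= length(p_values), "bonferroni_adjust: m < number of p-values")
  pmin(1, m * p_values)
}
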