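#' Binned signal tracks (chromatin accessibility / occupancy)
#'
#' A `signal_track` holds one numeric vector per chromosome at a fixed bin
#' width: bin `i` covers bases `[(i-1)*bin_width, i*bin_width)` and the
#' vector length is `ceiling(chrom_length / bin_width)`. Values are finite
#' and non-negative; positions a WIG file does not specify are 0.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_width bin width in bp.
#' @param domain a [genome_domain()].
#' @return A `signal_track`.
#' @export
signal_track <- function(values, bin_width, domain) {
  .assert(is.list(values) && !is.null(names(values)),
          "signal_track: values must be a named list")
  .assert(all(names(values) %in% names(domain)),
          "signal_track: chromosome absent from domain")
  for (ch in names(values)) {
    .assert(length(values[[ch]]) == ceiling(domain[[ch]] / bin_width),
            "signal_track: %s has %d bins, expected %d", ch,
            length(values[[ch]]), ceiling(domain[[ch]] / bin_width))
    .assert(all(is.finite(values[[ch]])) && all(values[[ch]] >= 0),
            "signal_track: values must be finite and >= 0")
  }
  structure(list(values = values, bin_width = bin_width, domain = domain),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chromosome(s), bin width %d bp, mean signal %.3f\n",
              length(x$values), x$bin_width, mean(unlist(x$values))))
  invisible(x)
}

#' Read and write wiggle (WIG) tracks
#'
#' Supports `fixedStep` and `variableStep` sections. Values are averaged
#' into the track's fixed bins (per-bp weighting when a WIG span straddles a
#' bin boundary); unspecified positions are 0. `write_wig()` emits one
#' `fixedStep` section per chromosome at the track's bin width, and
#' `read_wig()` of that output reproduces the values exactly.
#'
#' @param path WIG file path.
#' @param domain a [genome_domain()].
#' @param bin_width target bin width in bp (default 10).
#' @return `read_wig()`: a [signal_track()].
#' @export
read_wig <- function(path, domain, bin_width = 10) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  nb <- stats::setNames(ceiling(as.numeric(domain) / bin_width), names(domain))
  sums <- lapply(stats::setNames(nb, names(domain)), numeric)
  cov <- lapply(stats::setNames(nb, names(domain)), numeric)
  mode <- NULL; chrom <- NULL; step <- 1; span <- 1; nextpos <- 1
  .hdr_field <- function(l, f, default = NULL) {
    m <- regmatches(l, regexpr(paste0(f, "=\\S+"), l))
    if (!length(m)) return(default)
    sub(paste0(f, "="), "", m)
  }
  add_run <- function(ch, p0, p1, val) {
    # p0..p1 inclusive, 1-based genome positions
    b0 <- (p0 - 1) %/% bin_width + 1
    b1 <- (p1 - 1) %/% bin_width + 1
    for (bi in b0:b1) {
      lo <- max(p0, (bi - 1) * bin_width + 1)
      hi <- min(p1, bi * bin_width)
      w <- hi - lo + 1
      sums[[ch]][bi] <<- sums[[ch]][bi] + val * w
      cov[[ch]][bi] <<- cov[[ch]][bi] + w
    }
  }
  for (l in lines) {
    if (grepl("^fixedStep", l)) {
      mode <- "fixed"
      chrom <- .hdr_field(l, "chrom")
      nextpos <- as.numeric(.hdr_field(l, "start"))
      step <- as.numeric(.hdr_field(l, "step", "1"))
      span <- as.numeric(.hdr_field(l, "span", "1"))
      .assert(!is.null(chrom) && !is.na(nextpos), "read_wig: malformed header: %s", l)
      .assert(chrom %in% names(domain), "read_wig: unknown chromosome '%s'", chrom)
    } else if (grepl("^variableStep", l)) {
      mode <- "variable"
      chrom <- .hdr_field(l, "chrom")
      span <- as.numeric(.hdr_field(l, "span", "1"))
      .assert(!is.null(chrom), "read_wig: malformed header: %s", l)
      .assert(chrom %in% names(domain), "read_wig: unknown chromosome '%s'", chrom)
    } else {
      .assert(!is.null(mode), "read_wig: data line before any step header")
      f <- strsplit(trimws(l), "\\s+")[[1]]
      if (mode == "fixed") {
        v <- suppressWarnings(as.numeric(f[1]))
        .assert(!is.na(v), "read_wig: non-numeric value '%s'", l)
        add_run(chrom, nextpos, min(nextpos + span - 1, domain[[chrom]]), v)
        nextpos <- nextpos + step
      } else {
        .assert(length(f) >= 2, "read_wig: variableStep line needs pos value")
        p <- suppressWarnings(as.numeric(f[1]))
        v <- suppressWarnings(as.numeric(f[2]))
        .assert(!is.na(p) && !is.na(v), "read_wig: malformed line '%s'", l)
        add_run(chrom, p, min(p + span - 1, domain[[chrom]]), v)
      }
    }
  }
  vals <- lapply(names(domain), function(ch) {
    out <- numeric(nb[[ch]])
    nz <- cov[[ch]] > 0
    out[nz] <- sums[[ch]][nz] / cov[[ch]][nz]
    out
  })
  signal_track(stats::setNames(vals, names(domain)), bin_width, domain)
}

#' @rdname read_wig
#' @param track a [signal_track()].
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track$bin_width
  for (ch in names(track$values)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, bw, bw), con)
    writeLines(formatC(track$values[[ch]], format = "g", digits = 15), con)
  }
  invisible(path)
}

#' Mean signal profile around site centers
#'
#' Averages the track across site centers at each offset in
#' `[-flank, +flank]` (step = the track's bin width). The site center is the
#' floor midpoint `floor((start + end)/2)`; sites whose flanked window leaves
#' the chromosome are dropped (not zero-padded, which would deflate the
#' means) and counted in `n_dropped`.
#'
#' @param track a [signal_track()].
#' @param sites a non-empty `interval_set`.
#' @param flank half-width of the window in bp (default 2000).
#' @return An `aggregate_profile`: list with `class_label`, `offsets`,
#'   `mean_signal`, `n_sites`, `n_dropped`.
#' @export
aggregate_profile <- function(track, sites, flank = 2000) {
  .assert(nrow(sites) > 0, "aggregate_profile: empty site set")
  .assert(flank > 0, "aggregate_profile: flank must be > 0")
  bw <- track$bin_width
  offsets <- seq(-flank, flank, by = bw)
  acc <- numeric(length(offsets))
  n_used <- 0L; n_dropped <- 0L
  for (ch in unique(sites$chrom)) {
    .assert(ch %in% names(track$values),
            "aggregate_profile: chromosome '%s' absent from track", ch)
    v <- track$values[[ch]]
    sub <- sites[sites$chrom == ch, ]
    centers <- floor((sub$start + sub$end) / 2)
    for (ctr in centers) {
      bins <- (ctr + offsets) %/% bw + 1
      if (any(bins < 1) || any(bins > length(v))) {
        n_dropped <- n_dropped + 1L
        next
      }
      acc <- acc + v[bins]
      n_used <- n_used + 1L
    }
  }
  .assert(n_used > 0, "aggregate_profile: all sites clipped at chromosome edges")
  structure(list(class_label = set_label(sites), offsets = offsets,
                 mean_signal = acc / n_used, n_sites = n_used,
                 n_dropped = n_dropped),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("<aggregate_profile '%s'> %d sites (%d dropped), peak mean %.3f at offset %+d bp\n",
              x$class_label, x$n_sites, x$n_dropped, max(x$mean_signal),
              x$offsets[which.max(x$mean_signal)]))
  invisible(x)
}

#' @export
plot.aggregate_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$mean_signal, type = "l",
                 xlab = "offset from site center (bp)", ylab = "mean signal",
                 main = x$class_label, ...)
  invisible(x)
}

#' Fraction of sites overlapping a peak set
#'
#' The site-class openness summary: the proportion of `sites` members with
#' at least one base pair inside a called peak.
#'
#' @param sites a non-empty `interval_set`.
#' @param peaks an `interval_set` of called peaks.
#' @return A fraction in [0, 1].
#' @export
fraction_in_peaks <- function(sites, peaks) {
  .assert(nrow(sites) > 0, "fraction_in_peaks: empty site set")
  nrow(intersect_members(sites, peaks)) / nrow(sites)
}
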