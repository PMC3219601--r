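#' Position weight matrices in TRANSFAC format
#'
#' `parse_transfac()` reads a single TRANSFAC matrix record (position lines
#' `NN  countA countC countG countT [consensus]`) into a `pwm` object;
#' `write_transfac()` is the inverse. A `pwm` carries the raw count matrix, a
#' background base distribution and a pseudocount; scoring uses
#' pseudocount-smoothed log2-odds (see [score_window()]).
#'
#' @param path path to a TRANSFAC-format file (first record is read).
#' @param text alternatively, the record as a character vector of lines.
#' @param background base probabilities over (A,C,G,T); default uniform.
#' @param pseudocount added to every count cell before frequencies; default 1.
#' @return A `pwm`: list with `id`, `counts` (L x 4 matrix), `background`,
#'   `pseudocount`.
#' @export
parse_transfac <- function(path = NULL, text = NULL,
                           background = rep(0.25, 4), pseudocount = 1) {
  .assert(xor(is.null(path), is.null(text)),
          "parse_transfac: give exactly one of path/text")
  if (!is.null(path)) text <- readLines(path)
  id <- NA_character_
  idl <- grep("^(ID|AC|NA)\\s+", text, value = TRUE)
  if (length(idl)) id <- sub("^\\S+\\s+", "", idl[1])
  pos <- grep("^[0-9]+\\s", text, value = TRUE)
  .assert(length(pos) >= 1, "parse_transfac: no position lines found")
  rows <- lapply(pos, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    .assert(length(f) >= 5, "parse_transfac: position line with < 4 counts: '%s'", l)
    v <- suppressWarnings(as.numeric(f[2:5]))
    .assert(!anyNA(v), "parse_transfac: non-numeric count in line '%s'", l)
    .assert(all(v >= 0), "parse_transfac: negative count in line '%s'", l)
    v
  })
  counts <- do.call(rbind, rows)
  colnames(counts) <- c("A", "C", "G", "T")
  new_pwm(id = id, counts = counts, background = background,
          pseudocount = pseudocount)
}

#' @rdname parse_transfac
#' @param pwm a `pwm` object.
#' @export
write_transfac <- function(pwm, path) {
  bases <- c("A", "C", "G", "T")
  cons <- paste(bases[apply(pwm$counts, 1, which.max)], collapse = "")
  lines <- c(sprintf("ID  %s", pwm$id),
             "P0      A      C      G      T")
  for (i in seq_len(nrow(pwm$counts))) {
    lines <- c(lines, sprintf("%02d  %5g  %5g  %5g  %5g  %s", i,
                              pwm$counts[i, 1], pwm$counts[i, 2],
                              pwm$counts[i, 3], pwm$counts[i, 4],
                              substr(cons, i, i)))
  }
  writeLines(c(lines, "XX", "//"), path)
  invisible(path)
}

#' @rdname parse_transfac
#' @param id matrix identifier.
#' @param counts L x 4 nonnegative count matrix over (A,C,G,T).
#' @export
new_pwm <- function(id, counts, background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  .assert(ncol(counts) == 4 && nrow(counts) >= 1, "pwm: counts must be L x 4")
  .assert(all(counts >= 0), "pwm: negative counts")
  .assert(pseudocount > 0, "pwm: pseudocount must be > 0")
  .assert(abs(sum(background) - 1) < 1e-8 && all(background > 0),
          "pwm: background must be a positive probability vector")
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(id = id, counts = counts,
                 background = as.numeric(background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s'> length %d, consensus %s\n", x$id, nrow(x$counts),
              pwm_consensus(x)))
  invisible(x)
}

#' @rdname parse_transfac
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$counts)[apply(pwm$counts, 1, which.max)], collapse = "")
}

#' @rdname parse_transfac
#' @export
pwm_length <- function(pwm) nrow(pwm$counts)

# L x 5 log2-odds score matrix in bits; column 5 is N (neutral, 0).
.pwm_score_matrix <- function(pwm) {
  p <- (pwm$counts + pwm$pseudocount) /
    (rowSums(pwm$counts) + 4 * pwm$pseudocount)
  s <- log2(sweep(p, 2, pwm$background, "/"))
  cbind(s, N = 0)
}

#' Reverse-complement a PWM
#'
#' Row order reversed and A/T, C/G columns swapped, so scoring a window with
#' the reverse-complemented PWM equals scoring the window's reverse
#' complement with the original.
#' @param pwm a `pwm`.
#' @return A `pwm`.
#' @export
reverse_complement_pwm <- function(pwm) {
  rc <- pwm$counts[rev(seq_len(nrow(pwm$counts))), c("T", "G", "C", "A"),
                   drop = FALSE]
  colnames(rc) <- c("A", "C", "G", "T")
  new_pwm(id = pwm$id, counts = rc,
          background = pwm$background[c(4, 3, 2, 1)],
          pseudocount = pwm$pseudocount)
}

.encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  code <- rep.int(5L, length(v))
  code[v == 65L] <- 1L  # A
  code[v == 67L] <- 2L  # C
  code[v == 71L] <- 3L  # G
  code[v == 84L] <- 4L  # T
  code
}

#' Score a single window against a PWM
#'
#' Log2-odds in bits: `sum over positions of log2(p_pos(base)/bg(base))`
#' with `p` from pseudocount-smoothed frequencies. `N` bases contribute 0,
#' so masked sequence neither creates nor destroys hits.
#'
#' @param window a DNA string of exactly the PWM's length (A/C/G/T/N).
#' @param pwm a `pwm`.
#' @return The score in bits.
#' @export
score_window <- function(window, pwm) {
  L <- pwm_length(pwm)
  .assert(nchar(window) == L, "score_window: window length %d != PWM length %d",
          nchar(window), L)
  S <- .pwm_score_matrix(pwm)
  code <- .encode_dna(window)
  sum(S[cbind(seq_len(L), code)])
}

# All window scores of a sequence on the given PWM (one strand).
.scan_scores <- function(code, S) {
  L <- nrow(S)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  tot <- numeric(nw)
  for (j in seq_len(L)) {
    tot <- tot + S[j, code[j:(j + nw - 1L)]]
  }
  tot
}

#' Best motif score in a sequence
#'
#' Maximum window log2-odds over all windows, on both strands by default
#' (the reverse strand is scored via the reverse-complemented PWM).
#'
#' @param seq a DNA string.
#' @param pwm a `pwm`.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return Best score in bits (`-Inf` if the sequence is shorter than the PWM).
#' @export
best_hit_score <- function(seq, pwm, both_strands = TRUE) {
  code <- .encode_dna(seq)
  s <- .scan_scores(code, .pwm_score_matrix(pwm))
  if (both_strands) {
    s <- c(s, .scan_scores(code, .pwm_score_matrix(reverse_complement_pwm(pwm))))
  }
  if (!length(s)) -Inf else max(s)
}

#' Matrix-adaptive score threshold from the exact null score distribution
#'
#' Computes, by dynamic programming over positions (scores discretized to
#' `1/scale` bits), the exact distribution of the window score under the
#' background model, and returns the smallest threshold whose tail
#' probability P(score >= t) does not exceed `p`. This makes the default
#' screening threshold reproducible and adaptive to the matrix.
#'
#' @param pwm a `pwm`.
#' @param p target per-window match probability (default 1e-4).
#' @param scale score discretization, bins per bit (default 1000).
#' @return Threshold in bits.
#' @export
pwm_threshold <- function(pwm, p = 1e-4, scale = 1000) {
  .assert(p > 0 && p <= 1, "pwm_threshold: p must be in (0, 1]")
  S <- round(.pwm_score_matrix(pwm)[, 1:4, drop = FALSE] * scale)
  bg <- pwm$background
  # v[k] = P(partial score == k - 1 + cur_off)
  v <- 1; cur_off <- 0
  for (i in seq_len(nrow(S))) {
    smin <- min(S[i, ])
    newlen <- length(v) + (max(S[i, ]) - smin)
    nv <- numeric(newlen)
    for (b in 1:4) {
      sh <- S[i, b] - smin
      nv[(1 + sh):(length(v) + sh)] <- nv[(1 + sh):(length(v) + sh)] + bg[b] * v
    }
    v <- nv
    cur_off <- cur_off + smin
  }
  tail_p <- rev(cumsum(rev(v)))
  k <- which(tail_p <= p)
  if (!length(k)) {
    # even the best score is more probable than p: threshold just above max
    return((cur_off + length(v)) / scale)
  }
  (cur_off + min(k) - 1) / scale
}

#' Screen a cistrome for a motif
#'
#' For every peak, extracts its sequence from the genome and asks whether any
#' window on either strand scores at least `threshold`; reports the fraction
#' of peaks with a hit. When `threshold` is `NULL` it is derived from the
#' matrix via [pwm_threshold()] at per-window probability 1e-4.
#'
#' @param peaks an `interval_set`.
#' @param genome a named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param pwm a `pwm`.
#' @param threshold score threshold in bits, or `NULL` for the default.
#' @param both_strands scan both strands (default TRUE).
#' @return A `motif_screen`: list with `n_peaks`, `n_with_hit`, `fraction`,
#'   `threshold`, `scanned_both_strands`, `label`, and per-peak `best_scores`.
#' @export
screen_cistrome <- function(peaks, genome, pwm, threshold = NULL,
                            both_strands = TRUE) {
  genome <- .genome_chars(genome)
  if (is.null(threshold)) threshold <- pwm_threshold(pwm)
  .assert(is.finite(threshold) || is.infinite(threshold),
          "screen_cistrome: threshold must be numeric")
  Sf <- .pwm_score_matrix(pwm)
  Sr <- .pwm_score_matrix(reverse_complement_pwm(pwm))
  best <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    .assert(ch %in% names(genome),
            "screen_cistrome: peak %d on unknown chromosome '%s'", i, ch)
    .assert(peaks$end[i] <= nchar(genome[[ch]]),
            "screen_cistrome: peak %d (%s:%g-%g) outside genome bounds",
            i, ch, peaks$start[i], peaks$end[i])
    code <- .encode_dna(substr(genome[[ch]], peaks$start[i] + 1, peaks$end[i]))
    s <- .scan_scores(code, Sf)
    if (both_strands) s <- c(s, .scan_scores(code, Sr))
    best[i] <- if (length(s)) max(s) else -Inf
  }
  n_hit <- sum(best >= threshold)
  structure(list(n_peaks = nrow(peaks), n_with_hit = n_hit,
                 fraction = if (nrow(peaks)) n_hit / nrow(peaks) else NA_real_,
                 threshold = threshold, scanned_both_strands = both_strands,
                 label = set_label(peaks), best_scores = best),
            class = "motif_screen")
}

#' @export
print.motif_screen <- function(x, ...) {
  cat(sprintf("<motif_screen '%s'> %d/%d peaks with hit (%.1f%%) at threshold %.3f bits%s\n",
              x$label, x$n_with_hit, x$n_peaks, 100 * x$fraction, x$threshold,
              if (x$scanned_both_strands) ", both strands" else ""))
  invisible(x)
}

.genome_chars <- function(genome) {
  if (inherits(genome, "DNAStringSet") || inherits(genome, "XStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    .assert(is.character(genome) && !is.null(names(genome)),
            "genome must be a named character vector or DNAStringSet")
    genome
  }
}

#' Compare two motif-screen fractions
#'
#' Two-sided Fisher exact test on the 2x2 table
#' (with hit / without) x (cistrome A / cistrome B).
#'
#' @param a,b `motif_screen` results.
#' @return List with `p_value`, `odds_ratio` (ad/bc, Haldane-corrected if a
#'   cell is zero) and the `table`.
#' @export
compare_screen_fractions <- function(a, b) {
  .assert(a$n_peaks > 0 && b$n_peaks > 0,
          "compare_screen_fractions: empty cistrome")
  tab <- matrix(c(a$n_with_hit, a$n_peaks - a$n_with_hit,
                  b$n_with_hit, b$n_peaks - b$n_with_hit), nrow = 2,
                dimnames = list(c("hit", "no_hit"), c("A", "B")))
  p <- stats::fisher.test(tab)$p.value
  or <- .odds_ratio(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  list(p_value = p, odds_ratio = or$or, or_corrected = or$corrected, table = tab)
}

#' Read a multi-record FASTA file as named chromosome sequences
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
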