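#' Genomic interval sets
#'
#' An `interval_set` is the package's currency for cistromes and peak lists: a
#' data frame of genomic intervals in BED convention (0-based, half-open
#' `[start, end)`), carrying a `label` such as `"ERa"`, `"FoxA1"` or `"PBX1"`.
#' Two intervals overlap iff they lie on the same chromosome and share at
#' least one base pair, i.e. `max(starts) < min(ends)`. Strand is ignored
#' throughout: cistromes are unstranded.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; 0-based inclusive start, exclusive end.
#' @param name optional character labels per interval.
#' @param score optional numeric scores per interval.
#' @param label a single string naming the set.
#' @return An object of class `interval_set`: a data frame with columns
#'   `chrom`, `start`, `end` and optionally `name`, `score`.
#' @examples
#' iv <- interval_set(c("chr1", "chr1"), c(0, 200), c(100, 300), label = "toy")
#' length_bp(iv)
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         label = "") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  .validate_intervals(df)
  structure(df, class = c("interval_set", "data.frame"), label = label)
}

.validate_intervals <- function(df, where = "interval set") {
  bad <- which(!(df$end > df$start) | df$start < 0 | !nzchar(df$chrom) |
                 is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (need end > start >= 0, non-empty chrom)",
                 where, bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set '%s'> %d intervals, %s bp on %d chromosome(s)\n",
              set_label(x), nrow(x), format(length_bp(x), big.mark = ","),
              length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
set_label <- function(x) attr(x, "label") %||% ""

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total base pairs covered by a set (after merging overlaps)
#' @param x an `interval_set`.
#' @return Integer-valued number of distinct base positions covered.
#' @export
length_bp <- function(x) {
  m <- .merge_intervals(x)
  sum(m$end - m$start)
}

#' Read and write BED files
#'
#' `read_bed()` parses a BED3+ file (tab- or space-separated) into an
#' [interval_set()], preserving the 0-based half-open coordinates verbatim.
#' `track` and `browser` lines and `#` comments are skipped. Malformed lines
#' (non-integer coordinates, `end <= start`) raise an error naming the line
#' number. `write_bed()` is the inverse.
#'
#' @param path file path.
#' @param label set label; defaults to the file name without extension.
#' @return `read_bed()`: an `interval_set`.
#' @export
read_bed <- function(path, label = NULL) {
  .assert(file.exists(path), "read_bed: no such file: %s", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(interval_set(character(), numeric(), numeric(), label = label))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  n <- lengths(fields)
  if (any(n < 3)) {
    stop(sprintf("read_bed: line %d has fewer than 3 fields", idx[which(n < 3)[1]]),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("read_bed: malformed interval on line %d of %s", idx[bad[1]], path),
         call. = FALSE)
  }
  name <- ifelse(n >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  score <- suppressWarnings(as.numeric(
    ifelse(n >= 5, vapply(fields, function(f) f[min(5, length(f))], ""), NA)))
  out <- interval_set(chrom, start, end, label = label)
  if (any(n >= 4)) out$name <- as.character(name)
  if (any(n >= 5)) out$score <- score
  out
}

#' @rdname read_bed
#' @param x an `interval_set` to write.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  df <- df[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genome domain: chromosome lengths
#'
#' The resampling domain for [gsc_test()] and the coordinate bound for the
#' synthetic generators: a named vector of chromosome lengths in bp.
#'
#' @param lengths named numeric vector, chromosome -> length (bp).
#' @return An object of class `genome_domain`.
#' @export
genome_domain <- function(lengths) {
  .assert(length(lengths) > 0 && !is.null(names(lengths)) &&
            all(nzchar(names(lengths))), "genome_domain: lengths must be named")
  .assert(all(lengths > 0), "genome_domain: lengths must be positive")
  structure(as.numeric(lengths), names = names(lengths), class = "genome_domain")
}

#' @rdname genome_domain
#' @param path a two-column `chrom<TAB>length` file.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  genome_domain(stats::setNames(df$length, df$chrom))
}

#' @export
print.genome_domain <- function(x, ...) {
  cat(sprintf("<genome_domain> %d chromosome(s), %s bp total\n",
              length(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

.check_in_domain <- function(x, domain, what = "interval set") {
  miss <- setdiff(unique(x$chrom), names(domain))
  .assert(length(miss) == 0, "%s uses chromosome '%s' absent from domain",
          what, if (length(miss)) miss[1] else "")
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, ]
    .assert(all(sub$end <= domain[[ch]]),
            "%s: interval beyond end of %s", what, ch)
  }
  invisible(TRUE)
}

#' Canonicalize an interval set
#'
#' Sorts by (chrom, start, end) and collapses exact duplicate members.
#' Member-level operations ([intersect_members()], [subtract_members()],
#' [venn_partition()]) act on canonicalized members; base-pair computations
#' additionally merge overlapping/book-ended intervals internally.
#'
#' @param x an `interval_set`.
#' @return A canonicalized `interval_set`.
#' @export
canonicalize <- function(x) {
  df <- as.data.frame(x)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"), label = set_label(x))
}

# Merge overlapping/book-ended intervals; returns plain data.frame.
.merge_intervals <- function(x) {
  df <- as.data.frame(x)[, c("chrom", "start", "end")]
  if (!nrow(df)) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- lapply(split(df, df$chrom), function(d) {
    s <- d$start; e <- d$end
    # book-ended (end == next start) intervals merge too
    newgrp <- c(TRUE, s[-1] > cummax(e[-length(e)]))
    grp <- cumsum(newgrp)
    data.frame(chrom = d$chrom[1],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise interval overlap
#'
#' The one-base-pair rule: two intervals overlap iff they are on the same
#' chromosome and `max(starts) < min(ends)`. Vectorized over rows; abutting
#' half-open intervals share no base and do not overlap.
#'
#' @param a,b `interval_set`s of equal row count (or one of them 1-row).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

# For each member of a: does it overlap >=1 member of b?  Uses IRanges.
.overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  if (!nrow(a) || !nrow(b)) return(hit)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, ]
    qa <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    qb <- IRanges::IRanges(start = bb$start + 1L, end = bb$end)
    hit[ia] <- IRanges::overlapsAny(qa, qb)
  }
  hit
}

#' Member-level set operations on interval sets
#'
#' `intersect_members(a, b)` returns the members of `a` (whole, untruncated)
#' that overlap at least one member of `b`; `subtract_members(a, b)` returns
#' those that overlap none. Together they partition `a`. Member-level (not
#' base-pair truncating) semantics are the default because the operations
#' define *sets of binding sites*, e.g. the FoxA1-independent ERa sites;
#' `mode = "bp"` of `subtract_members()` gives truncating subtraction.
#'
#' @param a,b `interval_set`s (canonicalized; see [canonicalize()]).
#' @param mode `"member"` (default) removes whole overlapping members;
#'   `"bp"` removes covered base pairs, possibly truncating/splitting.
#' @return An `interval_set`.
#' @export
intersect_members <- function(a, b) {
  keep <- .overlaps_any(a, b)
  out <- as.data.frame(a)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interval_set", "data.frame"), label = set_label(a))
}

#' @rdname intersect_members
#' @export
subtract_members <- function(a, b, mode = c("member", "bp")) {
  mode <- match.arg(mode)
  if (mode == "member") {
    keep <- !.overlaps_any(a, b)
    out <- as.data.frame(a)[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(structure(out, class = c("interval_set", "data.frame"),
                     label = set_label(a)))
  }
  # bp mode: remove covered bases from the merged coverage of a
  ma <- .merge_intervals(a)
  mb <- .merge_intervals(b)
  res <- list()
  for (ch in unique(ma$chrom)) {
    da <- ma[ma$chrom == ch, ]
    db <- mb[mb$chrom == ch, ]
    ra <- IRanges::IRanges(start = da$start + 1L, end = da$end)
    if (nrow(db)) {
      rb <- IRanges::IRanges(start = db$start + 1L, end = db$end)
      ra <- IRanges::setdiff(ra, rb)
    }
    if (length(ra)) {
      res[[ch]] <- data.frame(chrom = ch, start = IRanges::start(ra) - 1,
                              end = IRanges::end(ra))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(out) <- NULL
  structure(out, class = c("interval_set", "data.frame"), label = set_label(a))
}

# Base positions covered by both coverages; starts/ends are merged and sorted
# per chromosome. Event-sweep, pure base R so the resampling loop stays cheap.
.bp_intersect <- function(sa, ea, sb, eb) {
  if (!length(sa) || !length(sb)) return(0)
  pos <- c(sa, ea, sb, eb)
  delta <- c(rep(1, length(sa)), rep(-1, length(ea)),
             rep(1, length(sb)), rep(-1, length(eb)))
  o <- order(pos, -delta)  # starts before ends at the same position
  pos <- pos[o]
  cov <- cumsum(delta[o])
  n <- length(pos)
  sum((pos[-1] - pos[-n])[cov[-n] == 2])
}

#' Base-pair overlap between two interval sets
#'
#' Number of base positions covered by both sets (each merged first), the
#' `basepair_overlap_marginal` statistic used by [gsc_test()].
#'
#' @param a,b `interval_set`s.
#' @return A single number of shared base pairs.
#' @export
basepair_overlap <- function(a, b) {
  ma <- .merge_intervals(a)
  mb <- .merge_intervals(b)
  total <- 0
  for (ch in intersect(unique(ma$chrom), unique(mb$chrom))) {
    da <- ma[ma$chrom == ch, ]
    db <- mb[mb$chrom == ch, ]
    total <- total + .bp_intersect(da$start, da$end, db$start, db$end)
  }
  total
}
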