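#' Expression study container
#'
#' A genes x samples matrix of log2 intensities with a detection-flag matrix
#' and a 2x2 design: silencing arm (`siCTRL`/`siPBX1`) x treatment
#' (`O` vehicle / `E2` estrogen).
#'
#' @param mat numeric genes x samples matrix of log2 intensities; rownames
#'   are gene ids, colnames sample ids.
#' @param design data frame with columns `sample`, `sirna`, `treatment`
#'   matching the matrix columns.
#' @param detected logical matrix of the same shape (default: all detected).
#' @param normalized has median-reference normalization been applied?
#' @return An `expression_study`.
#' @export
expression_study <- function(mat, design, detected = NULL, normalized = FALSE) {
  mat <- as.matrix(mat)
  .assert(!is.null(colnames(mat)) && (nrow(mat) == 0 || !is.null(rownames(mat))),
          "expression_study: matrix needs row and column names")
  .assert(all(c("sample", "sirna", "treatment") %in% names(design)),
          "expression_study: design needs sample/sirna/treatment columns")
  .assert(identical(sort(colnames(mat)), sort(as.character(design$sample))),
          "expression_study: design samples must match matrix columns")
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  }
  .assert(identical(dim(detected), dim(mat)),
          "expression_study: detection flags must match matrix shape")
  .assert(all(is.finite(mat[detected])),
          "expression_study: non-finite intensity at a detected spot")
  structure(list(matrix = mat, detected = detected, design = design,
                 normalized = normalized),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cells <- table(x$design$sirna, x$design$treatment)
  cat(sprintf("<expression_study> %d genes x %d samples%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) ", median-normalized" else ""))
  print(cells)
  invisible(x)
}

.cell_samples <- function(study, sirna, treatment) {
  which(study$design$sirna == sirna & study$design$treatment == treatment)
}

#' Median-reference normalization
#'
#' The reference array is the per-gene median across arrays. For each array,
#' the median (over its detected genes) of (array - reference) is subtracted,
#' so that afterwards the median gene-by-gene difference between every array
#' and the reference is exactly zero. The reference used is stored in
#' `attr(, "reference")` of the returned study.
#'
#' @param study an [expression_study()] with at least 3 arrays.
#' @return The normalized `expression_study`.
#' @export
median_reference_normalize <- function(study) {
  mat <- study$matrix
  .assert(ncol(mat) >= 3, "median_reference_normalize: need >= 3 arrays")
  .assert(all(colSums(study$detected) > 0),
          "median_reference_normalize: an array has no detected genes")
  ref <- apply(mat, 1, stats::median)
  shifts <- vapply(seq_len(ncol(mat)), function(j) {
    d <- (mat[, j] - ref)[study$detected[, j]]
    stats::median(d)
  }, 0)
  mat <- sweep(mat, 2, shifts, "-")
  out <- expression_study(mat, study$design, study$detected, normalized = TRUE)
  attr(out, "reference") <- ref
  attr(out, "shifts") <- shifts
  out
}

#' Remove genes detected in too few samples
#'
#' @param study an [expression_study()].
#' @param min_detected_samples genes detected in fewer samples are dropped;
#'   the default 1 removes only never-detected spots.
#' @return A filtered `expression_study`.
#' @export
filter_detected <- function(study, min_detected_samples = 1) {
  keep <- rowSums(study$detected) >= min_detected_samples
  expression_study(study$matrix[keep, , drop = FALSE], study$design,
                   study$detected[keep, , drop = FALSE], study$normalized)
}

# Vectorized per-gene two-sample t-test. Pooled (equal-variance) by default:
# under the equal-variance Gaussian model its level is exact, which the
# calibration properties require at n = 3 per class (Welch is conservative
# there); var_equal = FALSE gives Welch.
.row_ttest <- function(xa, xb, var_equal = TRUE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  d <- mb - ma
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(d))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate: zero variance in both classes
  degen <- se == 0
  p[degen & d == 0] <- 1           # identical values: not responsive
  p[degen & d != 0] <- 0           # exact separation with no noise
  list(p = p, delta = d, t = t)
}

#' Per-gene two-class t-test
#'
#' Computes a per-gene two-sample t-test between two design cells on
#' normalized log intensities and returns the genes significant at `alpha`
#' with their direction (sign of the mean difference, cell2 - cell1). The
#' test is pooled-variance by default (exact level under equal-variance
#' Gaussian noise; `var_equal = FALSE` switches to Welch). No multiple
#' testing correction is applied by default, mirroring the raw p < 0.01
#' convention of the assay this reproduces; `adjust = "BH"` applies
#' Benjamini-Hochberg before thresholding.
#'
#' @param study a normalized [expression_study()].
#' @param contrast list of two design cells, each `c(sirna, treatment)`;
#'   default vehicle vs estrogen in the control arm.
#' @param alpha significance level on the (possibly adjusted) p (default 0.01).
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) t-test.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `de_result` data frame: `gene`, `delta` (log2 difference,
#'   cell2 - cell1), `p`, `significant`, `direction` (`up`/`down`).
#' @export
two_class_ttest <- function(study,
                            contrast = list(c("siCTRL", "O"), c("siCTRL", "E2")),
                            alpha = 0.01, var_equal = TRUE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  i1 <- .cell_samples(study, contrast[[1]][1], contrast[[1]][2])
  i2 <- .cell_samples(study, contrast[[2]][1], contrast[[2]][2])
  .assert(length(i1) >= 2 && length(i2) >= 2,
          "two_class_ttest: need >= 2 samples per class")
  r <- .row_ttest(study$matrix[, i1, drop = FALSE],
                  study$matrix[, i2, drop = FALSE], var_equal = var_equal)
  p_use <- if (adjust == "BH") stats::p.adjust(r$p, "BH") else r$p
  out <- data.frame(gene = rownames(study$matrix), delta = r$delta, p = r$p,
                    significant = p_use < alpha,
                    direction = ifelse(r$delta > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"), alpha = alpha,
            contrast = contrast)
}

#' Per-gene four-class ANOVA
#'
#' One-way ANOVA per gene across the four design cells
#' (sirna x treatment); genes with p < `alpha` are flagged.
#'
#' @inheritParams two_class_ttest
#' @return A `de_result` data frame with `gene`, `F`, `p`, `significant`.
#' @export
four_class_anova <- function(study, alpha = 0.01) {
  cells <- expand.grid(sirna = c("siCTRL", "siPBX1"), treatment = c("O", "E2"),
                       stringsAsFactors = FALSE)
  groups <- lapply(seq_len(nrow(cells)),
                   function(i) .cell_samples(study, cells$sirna[i], cells$treatment[i]))
  .assert(all(lengths(groups) >= 2), "four_class_anova: all 4 cells need >= 2 samples")
  k <- length(groups)
  n <- sum(lengths(groups))
  mat <- study$matrix
  gm <- rowMeans(mat[, unlist(groups), drop = FALSE])
  ssb <- 0; ssw <- 0
  for (g in groups) {
    xg <- mat[, g, drop = FALSE]
    mg <- rowMeans(xg)
    ssb <- ssb + length(g) * (mg - gm)^2
    ssw <- ssw + rowSums((xg - mg)^2)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw == 0
  p[degen & ssb == 0] <- 1  # constant gene
  p[degen & ssb > 0] <- 0
  out <- data.frame(gene = rownames(mat), F = Fstat, p = p,
                    significant = p < alpha, stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"), alpha = alpha)
}

#' Estrogen-responsive genes and their knockdown-dependent subset
#'
#' Combines the vehicle-vs-estrogen tests from the control and knockdown
#' arms into the responsive gene set and its knockdown-dependent subset.
#' "Responsive" means significant in the control arm (up-regulated only by
#' default, matching the notion of estrogen-*induced* targets;
#' `direction = "both"` keeps both signs). A responsive gene is called
#' *dependent* by one of two criteria:
#' \describe{
#'   \item{`"attenuation"` (default)}{its estrogen effect in the knockdown
#'     arm is less than `atten_frac` (default 50%) of the control-arm effect
#'     (signed ratio, so sign flips count as attenuated). This directly
#'     measures loss of the response and is unbiased when per-arm power is
#'     below 1.}
#'   \item{`"significance"`}{it is no longer significant at `alpha` in the
#'     knockdown arm. Simpler, but upward-biased at small n: any responsive
#'     gene the knockdown arm merely fails to re-detect is miscalled
#'     dependent.}
#' }
#' Both criteria's fractions are reported in the result for comparison.
#'
#' @param de_ctrl,de_kd `de_result`s of [two_class_ttest()] for the control
#'   and knockdown arms (same study, same contrast direction).
#' @param method dependence criterion, `"attenuation"` or `"significance"`.
#' @param direction `"up"` (estrogen-induced, default) or `"both"`.
#' @param atten_frac attenuation cutoff on the effect ratio (default 0.5).
#' @return A `responsive_genes`: list with `responsive_all`, `directions`,
#'   `responsive_kd`, `dependent`, `dependent_fraction`, `method`,
#'   `fraction_by_method`, `flag`.
#' @export
dependent_genes <- function(de_ctrl, de_kd,
                            method = c("attenuation", "significance"),
                            direction = c("up", "both"), atten_frac = 0.5) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  .assert(identical(de_ctrl$gene, de_kd$gene),
          "dependent_genes: the two results cover different genes")
  sel <- de_ctrl$significant
  if (direction == "up") sel <- sel & de_ctrl$direction == "up"
  responsive <- de_ctrl$gene[sel]
  att <- (de_kd$delta / de_ctrl$delta < atten_frac)[sel]
  lost <- (!de_kd$significant)[sel]
  dep <- switch(method, attenuation = att, significance = lost)
  frac <- function(v) if (length(v)) mean(v) else NA_real_
  structure(list(
    responsive_all = responsive,
    directions = stats::setNames(de_ctrl$direction[sel], responsive),
    responsive_kd = de_kd$gene[de_kd$significant],
    dependent = responsive[dep],
    dependent_fraction = frac(dep),
    method = method, direction = direction,
    fraction_by_method = c(attenuation = frac(att), significance = frac(lost)),
    flag = if (!length(responsive)) "no_responsive_genes" else "ok"),
    class = "responsive_genes")
}

#' @export
print.responsive_genes <- function(x, ...) {
  if (x$flag != "ok") {
    cat("<responsive_genes> no responsive genes; fraction undefined\n")
    return(invisible(x))
  }
  cat(sprintf("<responsive_genes> %d responsive (%s), %d dependent (%.1f%% by %s; %.1f%% by %s)\n",
              length(x$responsive_all), x$direction, length(x$dependent),
              100 * x$fraction_by_method[["attenuation"]], "attenuation",
              100 * x$fraction_by_method[["significance"]], "significance loss"))
  invisible(x)
}

#' Read/write the expression-study text interchange format
#'
#' The matrix is a TSV of genes x samples with a `gene` first column; the
#' design a TSV with `sample`, `sirna`, `treatment`; detection flags an
#' optional TSV of 0/1 in the matrix layout.
#'
#' @param matrix_path,design_path,detected_path file paths.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, design_path,
                                  detected_path = NULL) {
  m <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(m[, -1, drop = FALSE]); rownames(mat) <- m[[1]]
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  det <- NULL
  if (!is.null(detected_path)) {
    d <- utils::read.table(detected_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
    det <- as.matrix(d[, -1, drop = FALSE]) > 0
    rownames(det) <- d[[1]]
  }
  expression_study(mat, design, det)
}

#' @rdname read_expression_study
#' @param study an [expression_study()].
#' @param dir output directory; files `expression.tsv`, `design.tsv`,
#'   `detected.tsv` are written there.
#' @export
write_expression_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(mat, path) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(study$matrix, file.path(dir, "expression.tsv"))
  w(study$detected * 1L, file.path(dir, "detected.tsv"))
  utils::write.table(study$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
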