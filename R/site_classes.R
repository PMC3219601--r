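#' Three-way Venn partition of cistromes
#'
#' Assigns every member of each of three cistromes to one of the 7 exclusive
#' classes defined by which of the three factors' sets it overlaps (the
#' one-base-pair rule). Because peak overlap is not transitive, class
#' membership is determined per *reference* factor from its own members:
#' counts for the same nominal class may differ slightly between reference
#' factors, and summaries quote a stated reference (default: the first set).
#'
#' @param sets a named list of exactly three `interval_set`s (canonicalized);
#'   names are the factor labels, e.g. `list(ERa = ..., FoxA1 = ..., PBX1 = ...)`.
#' @return A `venn_partition`: list with
#'   \describe{
#'     \item{factors}{the three factor names, in input order;}
#'     \item{assignment}{per factor, a character vector giving each member's
#'       class label (labels are `+`-joined subsets in input order);}
#'     \item{members}{per factor, the canonicalized `interval_set`;}
#'     \item{reference_counts}{per factor, its member count;}
#'     \item{class_labels}{the 7 labels in canonical order.}
#'   }
#' @examples
#' a <- interval_set("chr1", 0, 100, label = "A")
#' vp <- venn_partition(list(A = a, B = a, C = a))
#' venn_counts(vp, reference = "A")
#' @export
venn_partition <- function(sets) {
  .assert(is.list(sets) && length(sets) == 3 && !is.null(names(sets)) &&
            all(nzchar(names(sets))) && !anyDuplicated(names(sets)),
          "venn_partition: need a named list of exactly 3 interval sets")
  fac <- names(sets)
  sets <- lapply(sets, canonicalize)
  labels <- venn_class_labels(fac)
  assignment <- list()
  for (f in fac) {
    others <- setdiff(fac, f)
    x <- sets[[f]]
    inother <- vapply(others, function(g) .overlaps_any(x, sets[[g]]),
                      logical(nrow(x)))
    if (nrow(x) == 1) inother <- matrix(inother, nrow = 1)
    lab <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      memb <- c(f, others[inother[i, ]])
      lab[i] <- paste(fac[fac %in% memb], collapse = "+")
    }
    assignment[[f]] <- lab
  }
  structure(list(factors = fac, assignment = assignment, members = sets,
                 reference_counts = vapply(sets, nrow, 0L),
                 class_labels = labels),
            class = "venn_partition")
}

#' Canonical order of the 7 Venn class labels
#' @param factors character vector of the three factor names, in input order.
#' @return Character vector of 7 labels: singles, pairs, triple.
#' @export
venn_class_labels <- function(factors) {
  .assert(length(factors) == 3, "venn_class_labels: need 3 factor names")
  pairs <- utils::combn(factors, 2, paste, collapse = "+")
  c(factors, pairs, paste(factors, collapse = "+"))
}

#' Class counts quoted from a reference factor
#'
#' @param x a `venn_partition`.
#' @param reference which factor's members anchor the counts (default first).
#' @return Named integer vector over the classes that contain the reference
#'   factor; they partition its member set, so the counts sum to its size.
#' @export
venn_counts <- function(x, reference = x$factors[1]) {
  .assert(reference %in% x$factors, "venn_counts: unknown reference '%s'", reference)
  lab <- x$assignment[[reference]]
  classes <- x$class_labels[vapply(strsplit(x$class_labels, "\\+"),
                                   function(s) reference %in% s, TRUE)]
  out <- vapply(classes, function(cl) sum(lab == cl), 0L)
  stats::setNames(out, classes)
}

#' Member intervals of one Venn class
#'
#' @param x a `venn_partition`.
#' @param class a class label (see `x$class_labels`).
#' @param reference anchoring factor; default the first factor named in the
#'   class (its own members represent the class).
#' @return An `interval_set` of the reference factor's members in that class.
#' @export
venn_class_sites <- function(x, class,
                             reference = strsplit(class, "\\+")[[1]][1]) {
  .assert(class %in% x$class_labels, "venn_class_sites: unknown class '%s'", class)
  .assert(reference %in% strsplit(class, "\\+")[[1]],
          "venn_class_sites: reference '%s' not part of class '%s'",
          reference, class)
  m <- x$members[[reference]]
  out <- as.data.frame(m)[x$assignment[[reference]] == class, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interval_set", "data.frame"), label = class)
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> factors: %s\n", paste(x$factors, collapse = ", ")))
  print(summary(x))
  invisible(x)
}

#' @export
summary.venn_partition <- function(object, ...) {
  tab <- matrix(NA_integer_, length(object$class_labels), 3,
                dimnames = list(object$class_labels, object$factors))
  for (f in object$factors) {
    cnt <- venn_counts(object, f)
    tab[names(cnt), f] <- cnt
  }
  as.data.frame(tab)
}

#' Write one BED file per Venn class
#' @param x a `venn_partition`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_venn_beds <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in x$class_labels) {
    sites <- venn_class_sites(x, cl)
    p <- file.path(dir, paste0(gsub("\\+", "_", cl), ".bed"))
    write_bed(sites, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
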