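#' Gene annotation (TSS table)
#'
#' A gene annotation is a data frame with columns `gene_id`, `chrom`, `tss`
#' (0-based bp position) and `strand` (`+`/`-`). The TSS window used for
#' site-to-gene assignment is symmetric and strand-independent.
#'
#' @param gene_id,chrom,tss,strand vectors of equal length.
#' @return A validated data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = "+") {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = as.numeric(tss),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  .assert(!anyDuplicated(df$gene_id), "gene_annotation: duplicated gene_id")
  .assert(all(df$tss >= 0), "gene_annotation: tss must be >= 0")
  .assert(all(df$strand %in% c("+", "-")), "gene_annotation: strand must be +/-")
  structure(df, class = c("gene_annotation", "data.frame"))
}

#' @rdname gene_annotation
#' @param path a 4-column `gene_id  chrom  tss  strand` table, or a BED6 file
#'   (TSS taken as `start` for `+`, `end - 1` for `-`, name as gene_id).
#' @param format `"tss"` (default) or `"bed6"`.
#' @export
read_gene_annotation <- function(path, format = c("tss", "bed6")) {
  format <- match.arg(format)
  if (format == "tss") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(gene_annotation(df$gene_id, df$chrom, df$tss, df$strand))
  }
  bed <- read_bed(path)
  .assert(!is.null(bed$name), "read_gene_annotation: BED6 needs a name column")
  strand <- attr(bed, "strand") %||% rep("+", nrow(bed))
  gene_annotation(bed$name, bed$chrom,
                  ifelse(strand == "-", bed$end - 1, bed$start), strand)
}

#' Genes with a binding site within a TSS window
#'
#' A gene qualifies iff at least one site interval overlaps (one-base-pair
#' rule) the half-open window `[tss - window, tss + window)`, clipped at 0.
#' The window is symmetric and strand-independent; the default +/-20 kb is
#' the conventional distance for linking distal binding events to genes.
#'
#' @param sites an `interval_set`.
#' @param genes a [gene_annotation()].
#' @param window half-width in bp (default 20000).
#' @return Character vector of qualifying `gene_id`s.
#' @export
genes_with_site <- function(sites, genes, window = 20000) {
  .assert(window > 0, "genes_with_site: window must be > 0")
  if (!nrow(sites) || !nrow(genes)) return(character(0))
  win <- interval_set(genes$chrom, pmax(0, genes$tss - window),
                      genes$tss + window)
  genes$gene_id[.overlaps_any(win, sites)]
}

#' Enrichment of responsive genes near a binding-site class
#'
#' The radar statistic: the proportion of responsive genes with at least one
#' site of the class within the TSS window, divided by the same proportion in
#' the null gene list, with a two-sided Fisher exact p on the underlying 2x2
#' table. A ratio of proportions (not raw counts) is used so the statistic is
#' comparable across lists of different size and hovers around 1 under no
#' association; `raw_counts = TRUE` gives the literal count ratio.
#'
#' @param class_sites an `interval_set` (one Venn class's sites).
#' @param responsive,null_genes disjoint character vectors of gene ids.
#' @param genes a [gene_annotation()] covering both lists.
#' @param window TSS half-window in bp.
#' @param raw_counts report the unnormalized count ratio instead.
#' @return An `enrichment_ratio`: one-row data frame with counts, `ratio`,
#'   `p_value` and a `flag` (`"ok"`, `"infinite"`, or `"empty_class"`).
#' @export
enrichment_ratio <- function(class_sites, responsive, null_genes, genes,
                             window = 20000, raw_counts = FALSE) {
  .assert(length(intersect(responsive, null_genes)) == 0,
          "enrichment_ratio: responsive and null lists overlap")
  .assert(length(responsive) > 0 && length(null_genes) > 0,
          "enrichment_ratio: empty gene list")
  if (!nrow(class_sites)) {
    return(structure(data.frame(n_resp_with = NA, n_resp = length(responsive),
                                n_null_with = NA, n_null = length(null_genes),
                                ratio = NA_real_, p_value = NA_real_,
                                flag = "empty_class"),
                     class = c("enrichment_ratio", "data.frame")))
  }
  gsub <- genes[genes$gene_id %in% c(responsive, null_genes), , drop = FALSE]
  with_site <- genes_with_site(class_sites, gsub, window)
  a <- sum(responsive %in% with_site); n1 <- length(responsive)
  b <- sum(null_genes %in% with_site); n2 <- length(null_genes)
  ratio <- if (raw_counts) {
    if (b == 0) Inf else a / b
  } else {
    if (b == 0) Inf else (a / n1) / (b / n2)
  }
  p <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value
  structure(data.frame(n_resp_with = a, n_resp = n1, n_null_with = b,
                       n_null = n2, ratio = ratio, p_value = p,
                       flag = if (is.infinite(ratio)) "infinite" else "ok"),
            class = c("enrichment_ratio", "data.frame"))
}

#' Radar table: enrichment per Venn class per responsive-gene set
#'
#' One [enrichment_ratio()] row per (class, responsive set), classes in the
#' canonical Venn label order. Each class is evaluated independently, so a
#' gene near sites of two classes counts toward both. Class sites are
#' anchored to the stated reference factor when it belongs to the class, and
#' to the first factor of the class label otherwise.
#'
#' @param partition a [venn_partition()].
#' @param responsive_sets named list of responsive gene-id vectors (e.g.
#'   `list(all = ..., dependent = ...)`).
#' @param null_genes character vector of null-list gene ids.
#' @param genes a [gene_annotation()].
#' @param window TSS half-window in bp.
#' @param reference preferred anchoring factor for shared classes.
#' @return A data frame of class `radar_table` with columns `class`, `set`
#'   and the `enrichment_ratio` fields.
#' @export
radar_table <- function(partition, responsive_sets, null_genes, genes,
                        window = 20000, reference = partition$factors[1]) {
  rows <- list()
  for (cl in partition$class_labels) {
    members <- strsplit(cl, "\\+")[[1]]
    anchor <- if (reference %in% members) reference else members[1]
    sites <- venn_class_sites(partition, cl, anchor)
    for (nm in names(responsive_sets)) {
      er <- enrichment_ratio(sites, responsive_sets[[nm]], null_genes,
                             genes, window)
      rows[[length(rows) + 1L]] <- cbind(data.frame(class = cl, set = nm),
                                         as.data.frame(er))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), set = character())
  rownames(out) <- NULL
  structure(out, class = c("radar_table", "data.frame"))
}
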