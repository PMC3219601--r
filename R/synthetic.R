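#' Synthetic study design
#'
#' Parameters for the synthetic-data generators, which emit every input the
#' pipeline consumes with planted ground truth: a random genome, three
#' cistromes with a designed Venn structure, motif occurrences planted per
#' site class, an expression study with a planted responsive set and
#' knockdown-dependent fraction, a class-scaled accessibility track, and an
#' outcome cohort with expression-linked event probabilities.
#'
#' Defaults are the emulated study's conditions: 200 bp peaks, a
#' three-cistrome Venn in which about half of the ERa sites are shared with
#' PBX1, motif presence at 85% of PBX1-class sites, a 2x2 expression design
#' with 3 replicates per cell, estrogen effect 2.0 log2 units against noise
#' SD 0.5, 71% of responsive genes knockdown-dependent, accessibility
#' amplitudes ordered shared > PBX1-unique > FoxA1-unique, and an outcome
#' cohort whose top-decile expressers carry a 0.5 vs 0.1 yearly event
#' probability.
#'
#' @param seed root seed; every generator derives its own stream from it.
#' @param chrom_lengths named vector of synthetic chromosome lengths (bp).
#' @param gc genome GC content.
#' @param peak_width binding-site width in bp.
#' @param venn_counts named vector over the 7 class labels of
#'   `ERa`/`FoxA1`/`PBX1`: loci planted per class.
#' @param motif_plant_prob per-class probability that a site carries the
#'   motif consensus; named like `venn_counts`.
#' @param n_genes,n_responsive genes overall / estrogen-responsive among them.
#' @param n_samples_per_cell replicates per design cell.
#' @param effect_size,noise_sd,baseline_mean,baseline_sd expression model
#'   parameters (log2 scale).
#' @param dependent_fraction fraction of responsive genes whose estrogen
#'   effect is abolished under knockdown.
#' @param link_prob probability that a responsive gene's TSS is placed near
#'   a site of its linkage classes (the explicit class-to-gene linkage that
#'   makes TSS enrichment testable).
#' @param resp_link_classes,dep_link_classes linkage classes for responsive
#'   (non-dependent) and dependent genes.
#' @param bin_width,track_baseline accessibility track resolution and
#'   baseline mean.
#' @param openness_amplitudes per-class accessibility bump heights.
#' @param cohort_n,event_prob_high,event_prob_low,high_fraction outcome
#'   cohort size, per-year event probabilities, and the expression fraction
#'   defining the high-risk group.
#' @return A `synthetic_design` (list).
#' @export
synthetic_design <- function(
    seed = 1,
    chrom_lengths = c(chrS1 = 12e6, chrS2 = 9e6, chrS3 = 7e6),
    gc = 0.41,
    peak_width = 200,
    venn_counts = c("ERa" = 120, "FoxA1" = 200, "PBX1" = 250,
                    "ERa+FoxA1" = 150, "ERa+PBX1" = 120, "FoxA1+PBX1" = 80,
                    "ERa+FoxA1+PBX1" = 160),
    motif_plant_prob = NULL,
    n_genes = 2000, n_responsive = 200, n_samples_per_cell = 3,
    effect_size = 2.0, noise_sd = 0.5, baseline_mean = 8, baseline_sd = 1,
    dependent_fraction = 0.71,
    link_prob = 0.6,
    resp_link_classes = c("ERa", "ERa+FoxA1", "ERa+PBX1", "ERa+FoxA1+PBX1"),
    dep_link_classes = c("PBX1", "ERa+PBX1"),
    bin_width = 10, track_baseline = 0.5,
    openness_amplitudes = c("ERa" = 0.5, "FoxA1" = 1, "PBX1" = 2,
                            "ERa+FoxA1" = 1, "ERa+PBX1" = 2, "FoxA1+PBX1" = 3,
                            "ERa+FoxA1+PBX1" = 3),
    cohort_n = 300, event_prob_high = 0.5, event_prob_low = 0.1,
    high_fraction = 0.10) {
  labels <- venn_class_labels(c("ERa", "FoxA1", "PBX1"))
  .assert(all(names(venn_counts) %in% labels) && all(venn_counts >= 0),
          "synthetic_design: venn_counts must be named by the 7 class labels")
  if (is.null(motif_plant_prob)) {
    motif_plant_prob <- stats::setNames(
      ifelse(grepl("PBX1", labels), 0.85, 0.15), labels)
  }
  .assert(all(motif_plant_prob >= 0 & motif_plant_prob <= 1),
          "synthetic_design: motif_plant_prob outside [0, 1]")
  .assert(dependent_fraction >= 0 && dependent_fraction <= 1 &&
            event_prob_high >= 0 && event_prob_high <= 1 &&
            event_prob_low >= 0 && event_prob_low <= 1,
          "synthetic_design: probabilities must lie in [0, 1]")
  .assert(n_responsive <= n_genes, "synthetic_design: n_responsive > n_genes")
  design <- list(seed = seed, chrom_lengths = chrom_lengths, gc = gc,
                 peak_width = peak_width, venn_counts = venn_counts,
                 motif_plant_prob = motif_plant_prob,
                 n_genes = n_genes, n_responsive = n_responsive,
                 n_samples_per_cell = n_samples_per_cell,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dependent_fraction = dependent_fraction,
                 link_prob = link_prob,
                 resp_link_classes = resp_link_classes,
                 dep_link_classes = dep_link_classes,
                 bin_width = bin_width, track_baseline = track_baseline,
                 openness_amplitudes = openness_amplitudes,
                 cohort_n = cohort_n, event_prob_high = event_prob_high,
                 event_prob_low = event_prob_low,
                 high_fraction = high_fraction)
  structure(design, class = "synthetic_design")
}

#' The bundled synthetic PBX1-like PWM
#'
#' A TALE-homeodomain-style matrix with consensus TGATTGAT, shipped at
#' `inst/extdata/pbx1_like_synthetic.transfac`. It is a synthetic stand-in
#' constructed for this package (the commercial TRANSFAC matrix is not
#' redistributable), adequate for screening and planting because only its
#' consensus and information content matter to the synthetic study.
#'
#' @return A `pwm`.
#' @export
pbx1_like_pwm <- function() {
  parse_transfac(system.file("extdata", "pbx1_like_synthetic.transfac",
                             package = "cistrometry", mustWork = TRUE))
}

#' Generate a random genome
#'
#' I.i.d. bases at the design's GC content, one sequence per chromosome;
#' deterministic under the design seed.
#'
#' @param design a [synthetic_design()].
#' @return List with `genome` (named character vector) and `domain`
#'   (a [genome_domain()]).
#' @export
gen_genome <- function(design) {
  .assert(all(design$chrom_lengths >= 10000), "gen_genome: chromosomes must be >= 10 kb")
  set.seed(.stage_seed(design$seed, 1))
  probs <- c(A = (1 - design$gc) / 2, C = design$gc / 2,
             G = design$gc / 2, T = (1 - design$gc) / 2)
  codes <- utf8ToInt("ACGT")
  genome <- vapply(design$chrom_lengths, function(L) {
    intToUtf8(codes[sample.int(4L, L, replace = TRUE, prob = probs)])
  }, "")
  list(genome = genome, domain = genome_domain(design$chrom_lengths))
}

#' Generate three cistromes with a designed Venn structure
#'
#' Places `venn_counts[class]` non-overlapping loci of `peak_width` bp per
#' class (uniformly across chromosomes, rejection-sampled so no two loci
#' share a base); the members of a multi-factor class are the *same*
#' interval in every member factor, so [venn_partition()] must recover the
#' designed counts exactly.
#'
#' @param design a [synthetic_design()].
#' @return List with `sets` (named list of three `interval_set`s) and
#'   `truth` (data frame `locus`, `chrom`, `start`, `end`, `class`).
#' @export
gen_cistromes <- function(design) {
  set.seed(.stage_seed(design$seed, 2))
  w <- design$peak_width
  lens <- design$chrom_lengths
  total <- sum(design$venn_counts)
  .assert(total * w * 4 < sum(lens),
          "gen_cistromes: domain too small for %d loci of %d bp", total, w)
  taken <- lapply(lens, function(L) matrix(numeric(0), ncol = 2))
  chrom <- character(total); start <- numeric(total)
  placed <- 0; tries <- 0
  while (placed < total) {
    tries <- tries + 1
    .assert(tries < 200 * total, "gen_cistromes: rejection sampling failed; domain too crowded")
    ch <- sample(names(lens), 1, prob = lens)
    s <- floor(stats::runif(1, 0, lens[[ch]] - w))
    tk <- taken[[ch]]
    if (nrow(tk) && any(pmax(tk[, 1], s) < pmin(tk[, 2], s + w))) next
    placed <- placed + 1
    taken[[ch]] <- rbind(tk, c(s, s + w))
    chrom[placed] <- ch; start[placed] <- s
  }
  classes <- rep(names(design$venn_counts), design$venn_counts)
  truth <- data.frame(locus = sprintf("locus%05d", seq_len(total)),
                      chrom = chrom, start = start, end = start + w,
                      class = classes, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  truth$locus <- sprintf("locus%05d", seq_len(total))  # stable after sort
  rownames(truth) <- NULL
  sets <- lapply(c("ERa", "FoxA1", "PBX1"), function(f) {
    sel <- grepl(f, truth$class)
    interval_set(truth$chrom[sel], truth$start[sel], truth$end[sel],
                 name = truth$locus[sel], label = f)
  })
  list(sets = stats::setNames(sets, c("ERa", "FoxA1", "PBX1")), truth = truth)
}

#' Plant motif occurrences into a genome
#'
#' Writes the PWM consensus (forward or reverse complement, random strand)
#' at a uniform offset inside each selected site; selection is Bernoulli
#' with the design's per-class probability. Consensus (not PWM-sampled)
#' planting makes every planted site an unambiguous hit.
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth the `truth` table from [gen_cistromes()].
#' @param pwm a `pwm` (default [pbx1_like_pwm()]).
#' @param probs named per-class planting probabilities (default from the
#'   design is passed explicitly).
#' @param seed integer seed.
#' @return List with `genome` (modified) and `truth` (with a `planted`
#'   logical column).
#' @export
plant_motifs <- function(genome, truth, pwm = pbx1_like_pwm(),
                         probs, seed = 1) {
  set.seed(seed)
  L <- pwm_length(pwm)
  w <- unique(truth$end - truth$start)
  .assert(all(L < w), "plant_motifs: motif length must be below peak width")
  cons <- pwm_consensus(pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  planted <- stats::runif(nrow(truth)) < probs[truth$class]
  for (i in which(planted)) {
    off <- floor(stats::runif(1, 0, truth$end[i] - truth$start[i] - L + 1))
    ins <- if (stats::runif(1) < 0.5) cons else rc
    p0 <- truth$start[i] + off + 1  # 1-based substring start
    substr(genome[[truth$chrom[i]]], p0, p0 + L - 1) <- ins
  }
  truth$planted <- planted
  list(genome = genome, truth = truth)
}

#' Generate gene annotation with class-linked TSS placement
#'
#' Genes are named `g00001...`; the first `n_responsive` are the planted
#' responsive set, of which the first `round(dependent_fraction *
#' n_responsive)` are the planted dependent subset (the same convention
#' [gen_expression()] uses, so the two generators agree). With probability
#' `link_prob` a responsive gene's TSS is placed within a quarter window of
#' a site of its linkage classes (dependent genes near `dep_link_classes`,
#' the rest near `resp_link_classes`); all other TSSs are uniform.
#'
#' @param design a [synthetic_design()].
#' @param truth the `truth` table from [gen_cistromes()].
#' @param window the TSS window the analysis will use (default 20000).
#' @return List with `genes` (a [gene_annotation()]) and `truth`
#'   (list `responsive`, `dependent`).
#' @export
gen_gene_annotation <- function(design, truth, window = 20000) {
  set.seed(.stage_seed(design$seed, 4))
  n <- design$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  n_resp <- design$n_responsive
  n_dep <- round(design$dependent_fraction * n_resp)
  responsive <- ids[seq_len(n_resp)]
  dependent <- ids[seq_len(n_dep)]
  lens <- design$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  tss <- floor(stats::runif(n, 0, lens[chrom]))
  centers <- floor((truth$start + truth$end) / 2)
  place_near <- function(classes) {
    cand <- which(truth$class %in% classes)
    i <- cand[sample.int(length(cand), 1)]
    jitter <- round(stats::runif(1, -window / 4, window / 4))
    pos <- min(max(0, centers[i] + jitter), lens[[truth$chrom[i]]] - 1)
    c(truth$chrom[i], pos)
  }
  for (g in seq_len(n_resp)) {
    if (stats::runif(1) < design$link_prob) {
      cls <- if (ids[g] %in% dependent) design$dep_link_classes else
        design$resp_link_classes
      near <- place_near(cls)
      chrom[g] <- near[1]; tss[g] <- as.numeric(near[2])
    }
  }
  list(genes = gene_annotation(ids, chrom, tss,
                               strand = rep(c("+", "-"), length.out = n)),
       truth = list(responsive = responsive, dependent = dependent))
}

#' Generate a layout with exact planted TSS-enrichment rates
#'
#' A calibrated alternative to the linkage of [gen_gene_annotation()]:
#' responsive genes receive a class site within the window with probability
#' `rate_resp`, null genes with probability `rate_null`, so the planted
#' enrichment ratio is exactly `rate_resp / rate_null`. Site-carrying genes
#' get one dedicated site at a uniform offset within the window.
#'
#' @param n_resp,n_null list sizes.
#' @param rate_resp,rate_null with-site probabilities.
#' @param domain a [genome_domain()].
#' @param window TSS half-window (bp).
#' @param peak_width site width (bp).
#' @param seed integer seed.
#' @return List with `genes`, `sites` (an `interval_set`), `responsive`,
#'   `null_genes`.
#' @export
gen_enrichment_layout <- function(n_resp, n_null, rate_resp, rate_null,
                                  domain, window = 20000, peak_width = 200,
                                  seed = 1) {
  set.seed(seed)
  n <- n_resp + n_null
  ids <- sprintf("g%05d", seq_len(n))
  responsive <- ids[seq_len(n_resp)]
  null_genes <- ids[seq.int(n_resp + 1, n)]
  lens <- as.numeric(domain)
  chrom <- sample(names(domain), n, replace = TRUE, prob = lens)
  tss <- floor(stats::runif(n, window, lens[match(chrom, names(domain))] - window))
  has_site <- stats::runif(n) < c(rep(rate_resp, n_resp), rep(rate_null, n_null))
  idx <- which(has_site)
  off <- floor(stats::runif(length(idx), -window, window - peak_width))
  sites <- interval_set(chrom[idx], pmax(0, tss[idx] + off),
                        pmax(0, tss[idx] + off) + peak_width,
                        label = "planted")
  list(genes = gene_annotation(ids, chrom, tss), sites = canonicalize(sites),
       responsive = responsive, null_genes = null_genes,
       truth_has_site = has_site)
}

#' Generate the expression study with planted responsive/dependent genes
#'
#' Per-gene baseline `Normal(baseline_mean, baseline_sd)`; responsive genes
#' gain `effect_size` under estrogen in the control arm; the planted
#' dependent subset loses the gain entirely in the knockdown arm; i.i.d.
#' Gaussian noise with `noise_sd` on every measurement. Gene ids follow the
#' same convention as [gen_gene_annotation()].
#'
#' @param design a [synthetic_design()].
#' @return List with `study` (an [expression_study()]) and `truth`
#'   (list `responsive`, `dependent`).
#' @export
gen_expression <- function(design) {
  set.seed(.stage_seed(design$seed, 5))
  n <- design$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  n_resp <- design$n_responsive
  n_dep <- round(design$dependent_fraction * n_resp)
  resp <- seq_len(n_resp)
  dep <- seq_len(n_dep)
  nd <- setdiff(resp, dep)
  m <- design$n_samples_per_cell
  cells <- expand.grid(sirna = c("siCTRL", "siPBX1"),
                       treatment = c("O", "E2"), stringsAsFactors = FALSE)
  base <- stats::rnorm(n, design$baseline_mean, design$baseline_sd)
  cols <- list(); samples <- character(0)
  sirna <- character(0); treatment <- character(0)
  for (i in seq_len(nrow(cells))) {
    mu <- base
    if (cells$treatment[i] == "E2") {
      if (cells$sirna[i] == "siCTRL") {
        mu[resp] <- mu[resp] + design$effect_size
      } else {
        mu[nd] <- mu[nd] + design$effect_size  # dependent genes lose the effect
      }
    }
    for (r in seq_len(m)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(n, mu, design$noise_sd)
      samples <- c(samples, sprintf("%s_%s_r%d", cells$sirna[i],
                                    cells$treatment[i], r))
      sirna <- c(sirna, cells$sirna[i])
      treatment <- c(treatment, cells$treatment[i])
    }
  }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(ids, samples)
  study <- expression_study(mat, data.frame(sample = samples, sirna = sirna,
                                            treatment = treatment,
                                            stringsAsFactors = FALSE))
  list(study = study,
       truth = list(responsive = ids[resp], dependent = ids[dep]))
}

#' Generate an accessibility track scaled by site class
#'
#' Gamma-distributed baseline noise (mean `track_baseline`) plus a Gaussian
#' bump at every planted site center, with SD half the peak width and height
#' `openness_amplitudes[class]`.
#'
#' @param design a [synthetic_design()].
#' @param truth the `truth` table from [gen_cistromes()].
#' @param domain a [genome_domain()].
#' @return A [signal_track()].
#' @export
gen_track <- function(design, truth, domain) {
  set.seed(.stage_seed(design$seed, 6))
  bw <- design$bin_width
  sigma <- design$peak_width / 2
  vals <- lapply(names(domain), function(ch) {
    nb <- ceiling(domain[[ch]] / bw)
    v <- stats::rgamma(nb, shape = 4, rate = 4 / design$track_baseline)
    sub <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      centers <- floor((sub$start + sub$end) / 2)
      amps <- design$openness_amplitudes[sub$class]
      half <- ceiling(3 * sigma / bw)
      for (i in seq_len(nrow(sub))) {
        cbin <- centers[i] %/% bw + 1
        bins <- max(1, cbin - half):min(nb, cbin + half)
        d <- (bins - 0.5) * bw - centers[i]
        v[bins] <- v[bins] + amps[i] * exp(-d^2 / (2 * sigma^2))
      }
    }
    v
  })
  signal_track(stats::setNames(vals, names(domain)), bw, domain)
}

#' Generate an outcome cohort with expression-linked events
#'
#' Expression is standard normal; the top `high_fraction` of expressers get
#' per-year event probability `event_prob_high`, the rest
#' `event_prob_low`. Each sample draws an exponential event time with rate
#' `-log(1 - p)` (so the cumulative event probability by year y is
#' `1 - (1-p)^y`), from which the fixed-year statuses and, censored at the
#' last follow-up, the Kaplan-Meier columns `time`/`event` both derive —
#' keeping the binary statuses and the curve mutually consistent.
#'
#' @param design a [synthetic_design()].
#' @param years follow-up years (default `c(1, 3, 5)`).
#' @return A [survival_cohort()] carrying a `truth_high` attribute with the
#'   high-risk sample ids.
#' @export
gen_cohort <- function(design, years = c(1, 3, 5)) {
  set.seed(.stage_seed(design$seed, 7))
  n <- design$cohort_n
  ids <- sprintf("s%04d", seq_len(n))
  expr <- stats::rnorm(n)
  k <- floor(n * design$high_fraction)
  hi <- rank(-expr, ties.method = "first") <= k
  p <- ifelse(hi, design$event_prob_high, design$event_prob_low)
  lambda <- -log(1 - pmin(p, 1 - 1e-12))
  tmax <- max(years)
  t_event <- ifelse(lambda > 0, stats::rexp(n, pmax(lambda, 1e-12)), Inf)
  df <- data.frame(id = ids, expression = expr, stringsAsFactors = FALSE)
  for (y in years) {
    df[[paste0("status_y", y)]] <- ifelse(t_event <= y, "event", "event-free")
  }
  df$time <- pmin(t_event, tmax)
  df$event <- as.integer(t_event <= tmax)
  out <- survival_cohort(df, years)
  attr(out, "truth_high") <- ids[hi]
  out
}
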