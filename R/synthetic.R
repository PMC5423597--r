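# Synthetic ccRCC-like cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# G1/G3-graded cohort in which whole cytoband loci are recurrently lost or
# gained with grade-dependent carrier probabilities, plus sporadic
# single-gene noise, and survival whose hazard grows with the G3-related
# alteration burden. Default carrier probabilities are anchored to printed
# archetype frequencies of the kind observed in real ccRCC cohorts (see the
# methods vignette); they are the stated world, not tuning knobs.

#' Specify one planted locus
#'
#' @param cytoband band label, e.g. `"3p22.1"`; the chromosome is parsed from
#'   its prefix.
#' @param n_genes number of genes laid down in the band.
#' @param state `"loss"`, `"gain"`, or `"mixed"` (loss in G1 carriers, gain
#'   in G3 carriers).
#' @param p_g1,p_g3 per-sample carrier probability in each grade.
#' @param class planted truth label recorded for every gene of the locus:
#'   one of `"g1_loss"`, `"g3_loss"`, `"g3_gain"`, `"mixed"`, `"common"`,
#'   `"neutral"`.
#' @param span fraction of the locus's genes altered per carrier, as one
#'   contiguous run with a random offset (1 = the whole band).
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(cytoband, n_genes, state, p_g1, p_g3, class,
                       span = 1) {
  stopifnot(state %in% c("loss", "gain", "mixed"),
            p_g1 >= 0, p_g1 <= 1, p_g3 >= 0, p_g3 <= 1,
            span > 0, span <= 1, n_genes >= 1)
  structure(list(cytoband = cytoband, n_genes = as.integer(n_genes),
                 state = state, p_g1 = p_g1, p_g3 = p_g3,
                 class = class, span = span), class = "locus_spec")
}

#' Cohort design for the synthetic generator
#'
#' The default design mirrors a 46-sample cohort (26 G1, 20 G3) with six
#' archetypal loci: a grade-neutral common 3p loss, a G1-favouring 3p loss,
#' a neutral mid-frequency 5q gain, a G3-favouring gain, a G3-favouring loss
#' and a mixed-type band lost in G1 but gained in G3 carriers.
#'
#' @param n_g1,n_g3 samples per grade.
#' @param loci list of [locus_spec()] objects (at least one).
#' @param noise_rate per (sample, gene) probability of a spurious
#'   single-gene alteration of random sign.
#' @param base_rate baseline tumour-death hazard (per month) of a sample
#'   with zero G3-related burden.
#' @param log_hr_per_gene increment of the log tumour-death hazard per
#'   G3-related altered gene (G3 losses + G3 gains).
#' @param background_rate grade-independent other-cause death hazard.
#' @param censor_window months; administrative censoring drawn uniformly.
#' @param seed integer RNG seed.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_g1 = 26, n_g3 = 20, loci = default_loci(),
                          noise_rate = 0.01,
                          base_rate = 0.002, log_hr_per_gene = 0.04,
                          background_rate = 0.001,
                          censor_window = c(36, 120), seed = 1L) {
  if (length(loci) == 0) stop_data("design needs at least one locus")
  stopifnot(n_g1 >= 1, n_g3 >= 1, noise_rate >= 0, noise_rate <= 1)
  structure(list(n_g1 = as.integer(n_g1), n_g3 = as.integer(n_g3),
                 loci = loci, noise_rate = noise_rate,
                 base_rate = base_rate, log_hr_per_gene = log_hr_per_gene,
                 background_rate = background_rate,
                 censor_window = censor_window, seed = as.integer(seed)),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_loci <- function() {
  list(
    locus_spec("3p21.31", 40, "loss", 0.82, 0.82, "common"),
    locus_spec("3p22.1",  30, "loss", 0.81, 0.20, "g1_loss"),
    locus_spec("5q31.1",  20, "gain", 0.50, 0.50, "neutral"),
    locus_spec("7q22.1",  25, "gain", 0.02, 0.70, "g3_gain"),
    locus_spec("14q24.3", 15, "loss", 0.02, 0.50, "g3_loss"),
    locus_spec("4p16.3",  16, "mixed", 0.45, 0.45, "mixed")
  )
}

GENE_WIDTH <- 60000
GENE_PERIOD <- 100000
LOCUS_GAP <- 1000000
MIN_SEG <- 120000   # noise/single-gene segments padded to pass the filters

parse_band_chrom <- function(cytoband) {
  sub("^((?:[0-9]{1,2}|X|Y)).*$", "\\1", cytoband)
}

#' Generate a synthetic cohort
#'
#' Lays the designed loci down on their chromosomes (genes of 60 kbp on a
#' 100 kbp grid), draws per-grade carriers per locus, emits each carrier's
#' contiguous gene run as one called segment (so that segment-to-gene
#' annotation is genuinely exercised), adds single-gene noise segments, and
#' draws survival from an exponential cause-specific model whose tumour-death
#' log hazard is linear in the sample's planted G3-related burden.
#'
#' @param design a [cohort_design()].
#' @return list with elements `segments` (internal half-open coordinates, as
#'   returned by [read_segments()]), `gene_model` (with cytobands),
#'   `cytobands`, `clinical`, and `truth` (`symbol`, `cytoband`, `class`).
#' @seealso [write_cohort()] to materialise the file dialects,
#'   [cohort_matrix()] for the annotate-and-build shortcut.
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  samples <- c(sprintf("G1_%03d", seq_len(design$n_g1)),
               sprintf("G3_%03d", seq_len(design$n_g3)))
  grades <- rep(c("G1", "G3"), c(design$n_g1, design$n_g3))

  # gene model + cytoband table
  gene_rows <- list(); band_rows <- list()
  chrom_offset <- new.env(parent = emptyenv())
  for (li in seq_along(design$loci)) {
    lc <- design$loci[[li]]
    ch <- parse_band_chrom(lc$cytoband)
    off <- get0(ch, chrom_offset, ifnotfound = 1000000)
    starts <- off + (seq_len(lc$n_genes) - 1) * GENE_PERIOD
    gene_rows[[li]] <- data.frame(
      symbol = sprintf("%s_%03d", gsub("[^0-9A-Za-z]", "_", lc$cytoband),
                       seq_len(lc$n_genes)),
      chrom = ch, start_bp = starts, end_bp = starts + GENE_WIDTH,
      cytoband = lc$cytoband, locus = li, stringsAsFactors = FALSE)
    band_rows[[li]] <- data.frame(
      chrom = ch, start_bp = off - LOCUS_GAP / 2,
      end_bp = off + lc$n_genes * GENE_PERIOD + LOCUS_GAP / 2 - 1,
      cytoband = lc$cytoband, stringsAsFactors = FALSE)
    assign(ch, off + lc$n_genes * GENE_PERIOD + LOCUS_GAP, chrom_offset)
  }
  gene_model <- do.call(rbind, gene_rows)
  cytobands <- do.call(rbind, band_rows)

  # carrier draws -> segments
  seg <- list(); k <- 0
  burden <- setNames(integer(length(samples)), samples)
  for (li in seq_along(design$loci)) {
    lc <- design$loci[[li]]
    gl <- gene_model[gene_model$locus == li, , drop = FALSE]
    p <- ifelse(grades == "G1", lc$p_g1, lc$p_g3)
    carrier <- runif(length(samples)) < p
    n_run <- max(1L, round(lc$span * lc$n_genes))
    for (si in which(carrier)) {
      first <- if (n_run >= lc$n_genes) 1L else
        sample.int(lc$n_genes - n_run + 1L, 1L)
      run <- gl[first:(first + n_run - 1L), , drop = FALSE]
      st <- switch(lc$state, mixed = if (grades[si] == "G1") "loss" else "gain",
                   lc$state)
      k <- k + 1
      seg[[k]] <- segment_over(run, samples[si], st)
      if (lc$class %in% c("g3_gain", "g3_loss") ||
          (lc$class == "mixed" && st == "gain"))
        burden[si] <- burden[si] + n_run
    }
  }
  # sporadic single-gene noise of random sign
  noise <- which(matrix(runif(length(samples) * nrow(gene_model)),
                        length(samples)) < design$noise_rate, arr.ind = TRUE)
  if (nrow(noise) > 0) {
    for (r in seq_len(nrow(noise))) {
      k <- k + 1
      seg[[k]] <- segment_over(gene_model[noise[r, 2], , drop = FALSE],
                               samples[noise[r, 1]],
                               if (runif(1) < 0.5) "loss" else "gain")
    }
  }
  segments <- if (k > 0) do.call(rbind, seg) else empty_segments()
  rownames(segments) <- NULL

  # cause-specific exponential survival
  rate_tumour <- design$base_rate * exp(design$log_hr_per_gene * burden)
  t_tumour <- rexp(length(samples), rate_tumour)
  t_other <- rexp(length(samples), design$background_rate)
  t_cens <- runif(length(samples), design$censor_window[1],
                  design$censor_window[2])
  time <- pmin(t_tumour, t_other, t_cens)
  cause <- ifelse(time == t_tumour, "DOTD",
                  ifelse(time == t_other, "DBOR", "alive"))
  clinical <- data.frame(sample_id = samples, grade = grades,
                         surv_time = round(time, 2),
                         event = cause != "alive", death_cause = cause,
                         g3_burden = as.integer(burden),
                         stringsAsFactors = FALSE)

  truth <- gene_model[, c("symbol", "cytoband")]
  truth$class <- vapply(gene_model$locus,
                        function(li) design$loci[[li]]$class, "")
  list(segments = segments,
       gene_model = gene_model[, c("symbol", "chrom", "start_bp", "end_bp",
                                   "cytoband")],
       cytobands = cytobands, clinical = clinical, truth = truth,
       design = design)
}

# one called segment covering a contiguous gene run, padded so that
# single-gene events still pass the 5-marker / 100-kbp segment filters;
# marker density ~ 1 per 2 kbp
segment_over <- function(genes, sample_id, state) {
  s <- min(genes$start_bp); e <- max(genes$end_bp)
  pad <- max(0, MIN_SEG - (e - s)) / 2
  s <- max(0, s - pad); e <- e + pad
  data.frame(sample_id = sample_id, chrom = genes$chrom[1],
             start_bp = s, end_bp = e, state = state,
             n_markers = floor((e - s) / 2000), length_bp = e - s,
             stringsAsFactors = FALSE)
}

#' Materialise a synthetic cohort as the pipeline's file dialects
#'
#' Writes `segments.seg` (1-based inclusive coordinates), `genes.bed`,
#' `cytobands.txt` (UCSC layout), `clinical.tsv` and `truth.tsv` under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(segments = file.path(dir, "segments.seg"),
         genes = file.path(dir, "genes.bed"),
         cytobands = file.path(dir, "cytobands.txt"),
         clinical = file.path(dir, "clinical.tsv"),
         truth = file.path(dir, "truth.tsv"))
  seg <- cohort$segments
  out <- data.frame(Sample = seg$sample_id, Chromosome = seg$chrom,
                    Start = seg$start_bp + 1, End = seg$end_bp,
                    State = seg$state, NumMarkers = seg$n_markers)
  write.table(out, p["segments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gm <- cohort$gene_model
  write.table(data.frame(gm$chrom, gm$start_bp, gm$end_bp, gm$symbol,
                         gm$cytoband),
              p["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cb <- cohort$cytobands
  write.table(data.frame(paste0("chr", cb$chrom), cb$start_bp, cb$end_bp,
                         sub("^[0-9XY]+", "", cb$cytoband), "gneg"),
              p["cytobands"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cohort$clinical, p["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth, p["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(p)
}

#' Annotate-and-build shortcut for a synthetic cohort
#'
#' @param cohort result of [generate_cohort()].
#' @param conflict_policy passed to [build_cna_matrix()].
#' @return a [cna_matrix()].
#' @export
cohort_matrix <- function(cohort, conflict_policy = "zero") {
  triples <- annotate_segments_to_genes(cohort$segments, cohort$gene_model)
  build_cna_matrix(triples, cohort$clinical$sample_id,
                   cohort$gene_model$symbol,
                   conflict_policy = conflict_policy)
}

#' Deterministic worked-example cohort
#'
#' A 46-sample (26 G1 / 20 G3) matrix containing one gene per canonical
#' grade-contingency pattern, named `pat_<G1 carriers>_<G3 carriers>`:
#' three strong G1-loss patterns (21/4, 20/4, 21/5), a VHL-like 14/1 loss,
#' a BRAF-like 0/3 gain, an MLH1-like 22/9 loss and a neutral 13/10 filler.
#' The first `a` G1 samples and the first `c` G3 samples carry each pattern.
#'
#' @return list with `matrix` (a [cna_matrix()]) and `clinical`.
#' @export
worked_example_cohort <- function() {
  samples <- c(sprintf("G1_%02d", 1:26), sprintf("G3_%02d", 1:20))
  grades <- rep(c("G1", "G3"), c(26, 20))
  pats <- list(pat_21_4 = c(21, 4, -1L), pat_20_4 = c(20, 4, -1L),
               pat_21_5 = c(21, 5, -1L), pat_14_1 = c(14, 1, -1L),
               pat_0_3 = c(0, 3, 1L), pat_22_9 = c(22, 9, -1L),
               pat_13_10 = c(13, 10, -1L))
  vals <- matrix(0L, 46, length(pats),
                 dimnames = list(samples, names(pats)))
  for (j in seq_along(pats)) {
    a <- pats[[j]][1]; cc <- pats[[j]][2]; v <- pats[[j]][3]
    if (a > 0) vals[seq_len(a), j] <- v
    if (cc > 0) vals[26 + seq_len(cc), j] <- v
  }
  # deterministic survival: a third of the G3 samples die of tumour disease
  time <- c(60 + seq_len(26), ifelse(seq_len(20) <= 7, 10 + 4 * seq_len(20),
                                     48 + seq_len(20)))
  cause <- c(rep("alive", 26), ifelse(seq_len(20) <= 7, "DOTD", "alive"))
  clinical <- data.frame(sample_id = samples, grade = grades,
                         surv_time = time, event = cause != "alive",
                         death_cause = cause, stringsAsFactors = FALSE)
  list(matrix = cna_matrix(vals), clinical = clinical)
}

#' Simulate two survival groups with a planted hazard ratio
#'
#' Exponential event times with rates `base_rate` (group 0) and
#' `base_rate * hazard_ratio` (group 1), uniform administrative censoring.
#' Supports calibration checks of the Cox/logrank stage.
#'
#' @param n0,n1 group sizes.
#' @param hazard_ratio planted hazard ratio of group 1 vs group 0.
#' @param base_rate events per month in group 0.
#' @param censor_window `c(lo, hi)` months.
#' @param seed RNG seed.
#' @return clinical-style `data.frame` with a logical `group1` column.
#' @export
simulate_two_group_survival <- function(n0, n1, hazard_ratio,
                                        base_rate = 0.01,
                                        censor_window = c(24, 120),
                                        seed = 1L) {
  set.seed(seed)
  n <- n0 + n1
  g1 <- rep(c(FALSE, TRUE), c(n0, n1))
  t_ev <- rexp(n, base_rate * ifelse(g1, hazard_ratio, 1))
  t_c <- runif(n, censor_window[1], censor_window[2])
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             grade = ifelse(g1, "G3", "G1"),
             surv_time = pmin(t_ev, t_c), event = t_ev <= t_c,
             death_cause = ifelse(t_ev <= t_c, "DOTD", "alive"),
             group1 = g1, stringsAsFactors = FALSE)
}

#' Random pathway membership table over a gene model
#'
#' Draws overlapping pathways from the synthetic gene universe so the
#' pathway-projection stage can be exercised without shipping a real
#' membership database. Clearly synthetic: identifiers are `SPW01`, ...
#'
#' @param gene_model gene model `data.frame`.
#' @param n_pathways number of pathways.
#' @param mean_size mean genes per pathway.
#' @param seed RNG seed.
#' @return `data.frame` with `pathway_id`, `pathway_name`, `gene`.
#' @export
synthetic_pathways <- function(gene_model, n_pathways = 8, mean_size = 15,
                               seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pathways), function(i) {
    sz <- max(2, stats::rpois(1, mean_size))
    data.frame(pathway_id = sprintf("SPW%02d", i),
               pathway_name = sprintf("synthetic pathway %02d", i),
               gene = sample(gene_model$symbol, min(sz, nrow(gene_model))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
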