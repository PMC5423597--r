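# Fixture builders shared across test files.

# a cna_matrix from a plain integer matrix (auto dimnames)
mk_matrix <- function(v, samples = NULL, genes = NULL) {
  samples <- samples %||% rownames(v) %||% sprintf("S%02d", seq_len(nrow(v)))
  genes <- genes %||% colnames(v) %||% sprintf("g%02d", seq_len(ncol(v)))
  dimnames(v) <- list(samples, genes)
  cna_matrix(v)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal clinical table for a matrix
mk_clinical <- function(samples, grades, surv_time = NULL, event = NULL,
                        cause = NULL) {
  cl <- data.frame(sample_id = samples, grade = grades,
                   stringsAsFactors = FALSE)
  if (!is.null(surv_time)) {
    cl$surv_time <- surv_time
    cl$event <- event %||% rep(FALSE, length(samples))
    cl$death_cause <- cause %||% ifelse(cl$event, "DOTD", "alive")
  }
  cl
}

# write a segmentation file in the external 1-based dialect
write_seg_file <- function(df, path = tempfile(fileext = ".seg")) {
  out <- data.frame(Sample = df$sample_id, Chromosome = df$chrom,
                    Start = df$start_bp + 1, End = df$end_bp,
                    State = df$state, NumMarkers = df$n_markers)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random segments + genes on a couple of chromosomes, for overlap checks
random_interval_fixture <- function(seed, n_seg = 25, n_genes = 10) {
  set.seed(seed)
  genes <- data.frame(
    symbol = sprintf("G%02d", seq_len(n_genes)),
    chrom = sample(c("1", "2"), n_genes, replace = TRUE),
    start_bp = sample.int(5e6, n_genes), stringsAsFactors = FALSE)
  genes$end_bp <- genes$start_bp + sample(c(2e4, 5e4, 2e5), n_genes,
                                          replace = TRUE)
  segments <- data.frame(
    sample_id = sample(c("A", "B", "C"), n_seg, replace = TRUE),
    chrom = sample(c("1", "2"), n_seg, replace = TRUE),
    start_bp = sample.int(5e6, n_seg), stringsAsFactors = FALSE)
  segments$end_bp <- segments$start_bp + sample(c(1e5, 5e5, 1e6), n_seg,
                                                replace = TRUE)
  segments$state <- sample(c("loss", "gain"), n_seg, replace = TRUE)
  segments$n_markers <- 50
  segments$length_bp <- segments$end_bp - segments$start_bp
  list(segments = segments, genes = genes)
}

# small fast cohort design for repeated-seed simulations
small_design <- function(seed, loci = NULL, n_g1 = 26, n_g3 = 20,
                         noise_rate = 0.01) {
  cohort_design(n_g1 = n_g1, n_g3 = n_g3,
                loci = loci %||% default_loci(),
                noise_rate = noise_rate, seed = seed)
}
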