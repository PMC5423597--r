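# Weighted matrices, correlation, UPGMA clustering, patient groups A-F/Z.

#' Recurrence-weighted CNA matrix
#'
#' Replaces the ternary coding by cohort-recurrence weights: an entry of -1
#' becomes minus the number of samples that lose that gene, +1 becomes plus
#' the number of samples that gain it, 0 stays 0. Signs are preserved, so a
#' recurrent alteration contributes more to sample-sample correlations than
#' a private one.
#'
#' @param matrix a [cna_matrix()].
#' @return numeric matrix of the same shape and dimnames.
#' @export
weight_matrix <- function(matrix) {
  v <- matrix$values
  n_loss <- colSums(v == -1L)
  n_gain <- colSums(v == 1L)
  w <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  w[v == -1L] <- -n_loss[col(v)[v == -1L]]
  w[v == 1L] <- n_gain[col(v)[v == 1L]]
  w
}

#' Per-sample cytoband alteration counts
#'
#' Samples x cytobands matrix counting each sample's altered genes of one
#' state per band — the feature matrix behind tumour-by-cytoband
#' correlation heatmaps.
#'
#' @param matrix a [cna_matrix()].
#' @param genes gene model with `cytoband`.
#' @param state `"loss"`, `"gain"` or `"any"`.
#' @return numeric matrix, rows = samples, cols = cytobands.
#' @export
cytoband_count_matrix <- function(matrix, genes,
                                  state = c("loss", "gain", "any")) {
  state <- match.arg(state)
  v <- matrix$values
  genes <- genes[genes$symbol %in% colnames(v), , drop = FALSE]
  ind <- switch(state, loss = v == -1L, gain = v == 1L, any = v != 0L)
  bands <- unique(genes$cytoband)
  out <- vapply(bands, function(b)
    rowSums(ind[, genes$symbol[genes$cytoband == b], drop = FALSE]),
    numeric(nrow(v)))
  if (nrow(v) == 1) out <- matrix(out, 1, dimnames = list(rownames(v), bands))
  out
}

#' Pearson correlation matrix over rows
#'
#' Plain Pearson correlation between the rows of a numeric matrix (samples,
#' cytobands, ...). Zero-variance rows get correlation 0 against every
#' other row and 1 with themselves, so all-neutral samples stay in the
#' heatmap without NaN.
#'
#' @param x numeric matrix (>= 2 rows); rows are the entities correlated.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2)
    stop_data("need at least two rows to correlate")
  r <- suppressWarnings(cor(t(x), method = "pearson"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Average-linkage Euclidean clustering
#'
#' Agglomerative UPGMA (average linkage) on Euclidean distances between the
#' rows of `m`. Following the convention of clustering the correlation
#' matrix itself, pass a [correlation_matrix()] result to cluster samples by
#' the similarity of their correlation profiles; any feature matrix works
#' too. Deterministic for a given input.
#'
#' @param m numeric matrix with finite entries.
#' @return an [stats::hclust] object (merge list, heights, leaf order).
#' @export
cluster_average_euclidean <- function(m) {
  if (any(!is.finite(m))) stop_data("non-finite entries in clustering input")
  hclust(dist(m, method = "euclidean"), method = "average")
}

#' Rule-based patient group assignment (A-F, Z)
#'
#' Counts each sample's alteration burden in four categories over a
#' labelled discriminative gene set: losses/gains of `+G1` genes and
#' losses/gains of `+G3` genes. A category is "present" when its burden
#' reaches its threshold (default 3 genes). Groups follow the composite
#' logic of CNA-defined patient groups:
#'
#' * `A` — G1 losses only;
#' * `B` — G3 losses only;
#' * `C` — G3 gains only;
#' * `D` — G1 and G3 losses (no G3 gains);
#' * `E` — G1 losses and G3 gains (no G3 losses);
#' * `F` — G3 losses and G3 gains together (G1 burden allowed);
#' * `Z` — no category present (unstratifiable by this gene set).
#'
#' G1 gains are tallied but do not enter the decision rule.
#'
#' @param matrix a [cna_matrix()].
#' @param gene_set a `gene_set_result` whose labels include `+G1`/`+G3`
#'   (e.g. [derive_hro201()]).
#' @param thresholds named integer vector with entries `G1_loss`,
#'   `G1_gain`, `G3_loss`, `G3_gain`.
#' @return `data.frame`: `sample_id`, `group`, and the four burden counts.
#' @export
assign_patient_groups <- function(matrix, gene_set,
                                  thresholds = c(G1_loss = 3L, G1_gain = 3L,
                                                 G3_loss = 3L,
                                                 G3_gain = 3L)) {
  need <- c("G1_loss", "G1_gain", "G3_loss", "G3_gain")
  miss <- setdiff(need, names(thresholds))
  if (length(miss) > 0)
    stop_data("missing burden threshold(s): ", paste(miss, collapse = ", "))
  mem <- gene_set$members
  v <- matrix$values
  g1_genes <- intersect(mem$symbol[mem$label == "+G1"], colnames(v))
  g3_genes <- intersect(mem$symbol[mem$label == "+G3"], colnames(v))
  burden <- function(genes, s)
    if (length(genes) == 0) integer(nrow(v)) else
      rowSums(v[, genes, drop = FALSE] == s)
  b <- data.frame(G1_loss = burden(g1_genes, -1L),
                  G1_gain = burden(g1_genes, 1L),
                  G3_loss = burden(g3_genes, -1L),
                  G3_gain = burden(g3_genes, 1L))
  pres <- sweep(as.matrix(b), 2, thresholds[colnames(b)], `>=`)
  g1l <- pres[, "G1_loss"]; g3l <- pres[, "G3_loss"]; g3g <- pres[, "G3_gain"]
  group <- ifelse(g3l & g3g, "F",
           ifelse(g1l & g3l, "D",
           ifelse(g1l & g3g, "E",
           ifelse(g3l, "B",
           ifelse(g3g, "C",
           ifelse(g1l, "A", "Z"))))))
  data.frame(sample_id = rownames(v), group = group, b,
             row.names = NULL, stringsAsFactors = FALSE)
}
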