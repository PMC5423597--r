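# Cytoband-level aggregation of gene CNAs and grade testing (Figs 2-5 data).
#
# The 2x2 unit at band level is the gene-sample event: for a band with G
# genes, a grade with n samples offers G*n "slots", of which the events of
# one state (loss or gain) fill a subset. Pooling events across a band's
# genes is what gives cytobands far smaller p-values than any single gene
# can reach in a ~46-sample cohort. The construction is a documented
# reconstruction; see the methods vignette.

#' Summarise CNAs per cytoband
#'
#' @param matrix a [cna_matrix()].
#' @param genes gene model with a `cytoband` column ([assign_cytobands()]).
#' @param clinical clinical table.
#' @return `data.frame`, one row per cytoband containing at least one
#'   modelled gene: gene-class counts, number of affected tumours,
#'   per-(grade, state) gene-sample event counts, and Fisher p-values for
#'   the loss and gain event tables (`p_loss`, `p_gain`).
#' @export
summarize_cytobands <- function(matrix, genes, clinical) {
  check_clinical(clinical)
  if (is.null(genes$cytoband) || anyNA(genes$cytoband))
    stop_data("gene(s) without cytoband: ",
              paste(genes$symbol[is.na(genes$cytoband)], collapse = ", "))
  v <- matrix$values
  genes <- genes[genes$symbol %in% colnames(v), , drop = FALSE]
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  n_g1 <- sum(grade == "G1"); n_g3 <- sum(grade == "G3")
  prof <- profile_genes(matrix, clinical)
  prof <- prof[match(genes$symbol, prof$symbol), ]
  bands <- unique(genes$cytoband)
  rows <- lapply(bands, function(b) {
    sym <- genes$symbol[genes$cytoband == b]
    vb <- v[, sym, drop = FALSE]
    pb <- prof[genes$cytoband == b, ]
    ev <- function(g, s) sum(vb[grade == g, , drop = FALSE] == s)
    ng <- length(sym)
    data.frame(cytoband = b, n_genes_total = ng,
               n_loss_only = sum(pb$cna_class == "loss_only"),
               n_gain_only = sum(pb$cna_class == "gain_only"),
               n_mixed = sum(pb$cna_class == "mixed"),
               n_tumours_affected = sum(rowSums(vb != 0L) > 0),
               loss_g1 = ev("G1", -1L), loss_g3 = ev("G3", -1L),
               gain_g1 = ev("G1", 1L), gain_g3 = ev("G3", 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_loss <- mapply(function(e1, e3, ng)
    fisher_cytoband_p(e1, e3, ng, n_g1, n_g3),
    out$loss_g1, out$loss_g3, out$n_genes_total)
  out$p_gain <- mapply(function(e1, e3, ng)
    fisher_cytoband_p(e1, e3, ng, n_g1, n_g3),
    out$gain_g1, out$gain_g3, out$n_genes_total)
  rownames(out) <- NULL
  out
}

fisher_cytoband_p <- function(events_g1, events_g3, n_genes, n_g1, n_g3) {
  slots_g1 <- n_genes * n_g1; slots_g3 <- n_genes * n_g3
  if (slots_g1 == 0 || slots_g3 == 0) stop_data("cytoband with zero slots")
  fisher_p(events_g1, slots_g1 - events_g1,
           events_g3, slots_g3 - events_g3)
}

#' Fisher test for one cytoband summary row
#'
#' Tests whether the band's gene-sample events of the given state are
#' distributed across G1 and G3 slots in proportion to the grade sizes.
#'
#' @param summary one row of [summarize_cytobands()] output.
#' @param state `"loss"` or `"gain"`.
#' @param n_g1,n_g3 number of G1 and G3 samples in the cohort.
#' @return two-sided p-value.
#' @export
fisher_cytoband <- function(summary, state = c("loss", "gain"),
                            n_g1, n_g3) {
  state <- match.arg(state)
  e1 <- summary[[paste0(state, "_g1")]]
  e3 <- summary[[paste0(state, "_g3")]]
  fisher_cytoband_p(e1, e3, summary$n_genes_total, n_g1, n_g3)
}

#' Select grade-discriminative cytobands
#'
#' Bands whose smaller of `p_loss`/`p_gain` falls below `threshold`, sorted
#' ascending by that minimum.
#'
#' @param summaries output of [summarize_cytobands()].
#' @param threshold p-value cut, e.g. `1e-14` for the most extreme bands.
#' @return subset of `summaries` with an extra `p_min` column.
#' @export
select_discriminative_cytobands <- function(summaries, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  p_min <- pmin(summaries$p_loss, summaries$p_gain)
  keep <- which(p_min < threshold)
  out <- summaries[keep[order(p_min[keep])], , drop = FALSE]
  out$p_min <- sort(p_min[keep])
  rownames(out) <- NULL
  out
}

#' Ordered per-gene alteration profile of one cytoband
#'
#' The plottable bar-chart data behind band figures: genes in genomic
#' order with per-grade loss and gain carrier counts, restricted to an
#' optional sample subset.
#'
#' @param matrix a [cna_matrix()].
#' @param genes gene model with `cytoband`.
#' @param cytoband band label.
#' @param clinical clinical table.
#' @param samples optional character vector restricting the counts.
#' @return `data.frame`: `symbol`, `start_bp`, `n_loss_g1`, `n_loss_g3`,
#'   `n_gain_g1`, `n_gain_g3`.
#' @export
cytoband_profile <- function(matrix, genes, cytoband, clinical,
                             samples = NULL) {
  gl <- genes[genes$cytoband == cytoband & !is.na(genes$cytoband), ,
              drop = FALSE]
  if (nrow(gl) == 0) stop_data("unknown cytoband: ", cytoband)
  gl <- gl[order(gl$start_bp), , drop = FALSE]
  v <- matrix$values[, gl$symbol, drop = FALSE]
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(v))
    if (length(miss) > 0)
      stop_data("unknown sample(s): ", paste(miss, collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  cnt <- function(g, s) colSums(v[grade %in% g, , drop = FALSE] == s)
  data.frame(symbol = gl$symbol, start_bp = gl$start_bp,
             n_loss_g1 = cnt("G1", -1L), n_loss_g3 = cnt("G3", -1L),
             n_gain_g1 = cnt("G1", 1L), n_gain_g3 = cnt("G3", 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
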