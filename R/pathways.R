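# Projection of gene-level CNAs onto pathway membership tables (WB III).

#' Rank pathways by CNA burden
#'
#' For each pathway, counts member genes, member genes altered in at least
#' one sample, and gene-sample alteration events per (grade, state). Ranked
#' by altered-gene count, ties broken by pathway id. Member genes absent
#' from the matrix count as unaltered.
#'
#' @param matrix a [cna_matrix()].
#' @param clinical clinical table.
#' @param pathways membership table ([read_pathways()]).
#' @param n_top number of top altered genes reported per pathway.
#' @return `data.frame` with one row per pathway: `pathway_id`,
#'   `pathway_name`, `n_member_genes`, `n_member_in_matrix`,
#'   `n_altered_genes`, event counts `loss_g1`, `loss_g3`, `gain_g1`,
#'   `gain_g3`, and `top_genes` (comma-separated `symbol(count)`).
#' @export
pathway_burden <- function(matrix, clinical, pathways, n_top = 3L) {
  check_clinical(clinical)
  v <- matrix$values
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    sub <- pathways[pathways$pathway_id == pid, ]
    members <- unique(sub$gene)
    present <- intersect(members, colnames(v))
    vp <- v[, present, drop = FALSE]
    n_alt_per_gene <- colSums(vp != 0L)
    altered <- present[n_alt_per_gene > 0]
    top <- head(altered[order(-n_alt_per_gene[altered], altered)], n_top)
    ev <- function(g, s) sum(vp[grade == g, , drop = FALSE] == s)
    data.frame(pathway_id = pid, pathway_name = sub$pathway_name[1],
               n_member_genes = length(members),
               n_member_in_matrix = length(present),
               n_altered_genes = length(altered),
               loss_g1 = ev("G1", -1L), loss_g3 = ev("G3", -1L),
               gain_g1 = ev("G1", 1L), gain_g3 = ev("G3", 1L),
               top_genes = paste(sprintf("%s(%d)", top,
                                         n_alt_per_gene[top]),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_altered_genes, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Colour/shape coding of one pathway's genes
#'
#' Reproduces the pathway-map legend semantics: the colour reflects the
#' pooled alteration states of the gene over the chosen samples (`loss`,
#' `gain`, `both`, `none`) and the shape reflects which grade dominates its
#' carriers — `G1-diamond` when strictly more G1 than G3 carriers,
#' `G3-circle` for the converse, `equal-rectangle` for non-zero ties, and
#' `none-rectangle` for unaltered genes.
#'
#' @inheritParams pathway_burden
#' @param pathway_id pathway to decompose.
#' @param samples optional sample subset (e.g. one tumour).
#' @return `data.frame`: `symbol`, `colour`, `shape`, `g1_carriers`,
#'   `g3_carriers`.
#' @export
gene_pathway_shapes <- function(matrix, clinical, pathways, pathway_id,
                                samples = NULL) {
  sub <- pathways[pathways$pathway_id == pathway_id, ]
  if (nrow(sub) == 0) stop_data("unknown pathway: ", pathway_id)
  v <- matrix$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  members <- sort(unique(sub$gene))
  rows <- lapply(members, function(g) {
    col_v <- if (g %in% colnames(v)) v[, g] else integer(nrow(v))
    has_loss <- any(col_v == -1L); has_gain <- any(col_v == 1L)
    colour <- if (has_loss && has_gain) "both"
      else if (has_loss) "loss" else if (has_gain) "gain" else "none"
    g1 <- sum(col_v != 0L & grade == "G1")
    g3 <- sum(col_v != 0L & grade == "G3")
    shape <- if (g1 + g3 == 0) "none-rectangle"
      else if (g1 > g3) "G1-diamond"
      else if (g3 > g1) "G3-circle" else "equal-rectangle"
    data.frame(symbol = g, colour = colour, shape = shape,
               g1_carriers = g1, g3_carriers = g3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pathway membership multiplicity per gene
#'
#' @param pathways membership table.
#' @param genes optional gene universe; genes absent from the table get 0.
#' @return named integer vector of pathway counts per gene.
#' @export
genes_to_pathway_counts <- function(pathways, genes = NULL) {
  uniq <- unique(pathways[, c("pathway_id", "gene")])
  counts <- table(uniq$gene)
  universe <- genes %||% names(counts)
  out <- setNames(integer(length(universe)), universe)
  hit <- intersect(universe, names(counts))
  out[hit] <- as.integer(counts[hit])
  out
}
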