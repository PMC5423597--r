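# Bespoke gene-set derivation: carrier-ratio (HRO201-style), recurrence
# (TP20-style), shared signatures (HRO286-style), and set intersections.

#' Carrier-ratio statistic per gene
#'
#' For each altered gene, `R = (g1 - g3) / (g1 + g3)` where `g1`/`g3` are
#' the numbers of G1/G3 carriers (any alteration by default). `R` spans
#' `[-1, 1]`: +1 = G1-exclusive, -1 = G3-exclusive. Genes with no carrier in
#' either grade are excluded (R undefined).
#'
#' @inheritParams stratify_all_genes
#' @return `data.frame`: `symbol`, `g1_carriers`, `g3_carriers`, `R`.
#' @export
ratio_stats <- function(matrix, clinical,
                        mode = c("any_alteration", "loss_only",
                                 "gain_only")) {
  mode <- match.arg(mode)
  check_clinical(clinical)
  v <- matrix$values
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  cm <- carrier_matrix(v, mode)
  g1 <- colSums(cm[grade == "G1", , drop = FALSE])
  g3 <- colSums(cm[grade == "G3", , drop = FALSE])
  keep <- g1 + g3 > 0
  data.frame(symbol = colnames(v)[keep], g1_carriers = g1[keep],
             g3_carriers = g3[keep],
             R = (g1[keep] - g3[keep]) / (g1[keep] + g3[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

new_gene_set <- function(name, members) {
  structure(list(name = name, members = members), class = "gene_set_result")
}

#' @export
print.gene_set_result <- function(x, ...) {
  cat("Gene set", x$name, "-", nrow(x$members), "genes\n")
  print(table(x$members$label))
  invisible(x)
}

#' Derive a grade-discriminative gene set from the carrier ratio
#'
#' Implements the two-constraint selection behind the 201-gene
#' discriminative set: the `+G3` subset collects genes altered in at least
#' `min_g3` G3 patients with ratio `R <= r_g3`, the `+G1` subset genes
#' altered in at least `min_g1` G1 patients with `R >= r_g1`. Both
#' boundaries are closed ("or less" / "or more"). Since `r_g1 > r_g3` the
#' subsets are disjoint by construction. Carrier counts pool losses and
#' gains by default.
#'
#' @inheritParams stratify_all_genes
#' @param min_g3 minimum G3 carriers for the `+G3` subset.
#' @param r_g3 upper `R` bound (inclusive) for `+G3`.
#' @param min_g1 minimum G1 carriers for the `+G1` subset.
#' @param r_g1 lower `R` bound (inclusive) for `+G1`.
#' @param name label attached to the result.
#' @return a `gene_set_result`: `name` plus `members`
#'   (`symbol`, `label` in `{"+G1", "+G3"}`, `R`, carrier counts).
#' @export
derive_hro201 <- function(matrix, clinical, min_g3 = 4L, r_g3 = -2 / 3,
                          min_g1 = 5L, r_g1 = 2 / 5,
                          mode = "any_alteration", name = "HRO201") {
  rs <- ratio_stats(matrix, clinical, mode)
  eps <- 1e-12
  plus_g3 <- rs$g3_carriers >= min_g3 & rs$R <= r_g3 + eps
  plus_g1 <- rs$g1_carriers >= min_g1 & rs$R >= r_g1 - eps
  members <- rbind(rs[plus_g1, , drop = FALSE], rs[plus_g3, , drop = FALSE])
  members$label <- rep(c("+G1", "+G3"), c(sum(plus_g1), sum(plus_g3)))
  members <- members[order(members$label, members$symbol),
                     c("symbol", "label", "R", "g1_carriers", "g3_carriers")]
  rownames(members) <- NULL
  new_gene_set(name, members)
}

#' Recurrently altered genes (TP20-style)
#'
#' Genes altered (loss or gain) in at least `min_tumours` samples,
#' partitioned by CNA class into loss-only, gain-only and mixed-type lists.
#'
#' @param matrix a [cna_matrix()].
#' @param min_tumours recurrence threshold (inclusive), default 20.
#' @return list of character vectors `loss_only`, `gain_only`, `mixed`.
#' @export
derive_tp20 <- function(matrix, min_tumours = 20L) {
  stopifnot(min_tumours >= 1)
  v <- matrix$values
  n_loss <- colSums(v == -1L); n_gain <- colSums(v == 1L)
  qual <- (n_loss + n_gain) >= min_tumours
  list(loss_only = colnames(v)[qual & n_loss > 0 & n_gain == 0],
       gain_only = colnames(v)[qual & n_gain > 0 & n_loss == 0],
       mixed = colnames(v)[qual & n_loss > 0 & n_gain > 0])
}

#' Shared-signature gene set from anchor samples (HRO286-style)
#'
#' Genes whose grade-stratification p-value falls below `p_threshold` and
#' whose matrix value is identical and non-zero across every anchor sample.
#' Members are labelled by the shared state.
#'
#' @inheritParams stratify_all_genes
#' @param anchor_samples character vector of matrix samples (non-empty);
#'   typically a tight cluster found by [cluster_average_euclidean()].
#' @param p_threshold Fisher p cut applied before the shared-state scan.
#' @param name label attached to the result.
#' @return a `gene_set_result` with labels `"loss"`/`"gain"`.
#' @export
derive_shared_signature <- function(matrix, clinical, anchor_samples,
                                    p_threshold = 0.1,
                                    name = "shared_signature") {
  if (length(anchor_samples) == 0) stop_data("empty anchor set")
  miss <- setdiff(anchor_samples, rownames(matrix$values))
  if (length(miss) > 0)
    stop_data("unknown anchor sample(s): ", paste(miss, collapse = ", "))
  strat <- stratify_all_genes(matrix, clinical)$results
  candidates <- strat$symbol[strat$p_value < p_threshold]
  va <- matrix$values[anchor_samples, candidates, drop = FALSE]
  shared <- apply(va, 2, function(col)
    if (col[1] != 0L && all(col == col[1])) col[1] else 0L)
  keep <- shared != 0L
  members <- data.frame(symbol = candidates[keep],
                        label = ifelse(shared[keep] == -1L, "loss", "gain"),
                        stringsAsFactors = FALSE)
  members <- members[order(members$symbol), , drop = FALSE]
  rownames(members) <- NULL
  new_gene_set(name, members)
}

#' Pairwise intersection sizes of gene sets
#'
#' @param sets named list (length >= 2) of `gene_set_result` objects or
#'   plain character vectors.
#' @return symmetric integer matrix; the diagonal holds set sizes.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2) stop_data("need at least two gene sets")
  syms <- lapply(sets, function(s)
    if (inherits(s, "gene_set_result")) unique(s$members$symbol)
    else unique(as.character(s)))
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  out <- matrix(0L, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets))
    for (j in seq_along(sets))
      out[i, j] <- length(intersect(syms[[i]], syms[[j]]))
  out
}

#' Write a gene set as a two-column TSV
#'
#' @param set a `gene_set_result`.
#' @param path output file.
#' @export
write_gene_set <- function(set, path) {
  write.table(set$members[, c("symbol", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
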