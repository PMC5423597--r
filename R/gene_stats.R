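# Per-gene summaries and Fisher exact grade stratification (WB I core).

#' Two-sided Fisher exact test for a 2x2 grade contingency table
#'
#' The table counts carriers and non-carriers of an alteration among G1 and
#' G3 samples. The two-sided p-value follows the minimum-likelihood
#' convention: all tables with the observed margins whose point
#' hypergeometric probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7) contribute. The odds ratio is the
#' unconditional cross-product `ad/bc`, `Inf` when `bc == 0`.
#'
#' @param a,b G1 carriers and non-carriers.
#' @param c,d G3 carriers and non-carriers.
#' @return list with `p_value`, `odds_ratio` and the `contingency` counts.
#' @export
#' @examples
#' fisher_gene(14, 12, 1, 19)$p_value  # ~ 4.44e-4
fisher_gene <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_data("contingency counts must be non-negative integers")
  if (a + b == 0 || c + d == 0)
    stop_data("both grade margins must be positive")
  list(p_value = fisher_p(a, b, c, d),
       odds_ratio = if (b * c == 0) {
         if (a * d == 0) NaN else Inf
       } else (a * d) / (b * c),
       contingency = counts)
}

# minimum-likelihood two-sided p by direct hypergeometric enumeration
fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Summarise every gene of a CNA matrix
#'
#' One row per gene: loss/gain/alteration counts, per-grade carrier counts
#' (any alteration), and the CNA class — `loss_only`, `gain_only`, `mixed`
#' (lost in some samples and gained in others) or `unaltered`. Conflicted
#' (sample, gene) pairs are excluded from all tallies by construction (their
#' matrix entry is 0 under the default conflict policy).
#'
#' @param matrix a [cna_matrix()].
#' @param clinical clinical table covering every matrix sample.
#' @return `data.frame` with columns `symbol`, `n_loss`, `n_gain`,
#'   `n_altered`, `g1_carriers`, `g2_carriers`, `g3_carriers`,
#'   `g4_carriers`, `cna_class`.
#' @export
profile_genes <- function(matrix, clinical) {
  v <- matrix$values
  check_clinical(clinical)
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  if (anyNA(grade))
    stop_data("sample(s) without clinical record: ",
              paste(rownames(v)[is.na(grade)], collapse = ", "))
  n_loss <- colSums(v == -1L)
  n_gain <- colSums(v == 1L)
  alt <- v != 0L
  carriers <- function(g) if (any(grade == g))
    colSums(alt[grade == g, , drop = FALSE]) else integer(ncol(v))
  cls <- ifelse(n_loss > 0 & n_gain > 0, "mixed",
         ifelse(n_loss > 0, "loss_only",
         ifelse(n_gain > 0, "gain_only", "unaltered")))
  data.frame(symbol = colnames(v), n_loss = n_loss, n_gain = n_gain,
             n_altered = n_loss + n_gain,
             g1_carriers = carriers("G1"), g2_carriers = carriers("G2"),
             g3_carriers = carriers("G3"), g4_carriers = carriers("G4"),
             cna_class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Ratio of gene losses to gene gains within one grade
#'
#' Total `-1` entries divided by total `+1` entries over the grade's
#' samples. With zero gains the ratio is undefined: `NA` is returned with a
#' warning rather than `Inf`.
#'
#' @param matrix a [cna_matrix()].
#' @param clinical clinical table.
#' @param grade grade label, e.g. `"G1"`.
#' @return a single number (or `NA` if undefined).
#' @export
loss_gain_ratio <- function(matrix, clinical, grade) {
  check_clinical(clinical)
  ids <- clinical$sample_id[clinical$grade == grade]
  ids <- intersect(ids, rownames(matrix$values))
  if (length(ids) == 0) stop_data("no samples of grade ", grade)
  v <- matrix$values[ids, , drop = FALSE]
  losses <- sum(v == -1L); gains <- sum(v == 1L)
  if (gains == 0) {
    warning("no gains among grade ", grade, " samples; ratio undefined")
    return(NA_real_)
  }
  losses / gains
}

# carrier indicator per mode, restricted to given sample rows
carrier_matrix <- function(v, mode) {
  switch(mode,
         any_alteration = v != 0L,
         loss_only = v == -1L,
         gain_only = v == 1L,
         stop_data("unknown carrier mode: ", mode))
}

#' Fisher-stratify all altered genes by Fuhrman grade
#'
#' For every gene altered in at least one sample, builds the 2x2 table of
#' carriers vs non-carriers among G1 and G3 samples (G2/G4 samples are
#' excluded from the test but untouched elsewhere) and applies
#' [fisher_gene()]. Convenience subsets at p < 0.1, 0.01 and 0.001 are
#' attached.
#'
#' @param matrix a [cna_matrix()].
#' @param clinical clinical table; must contain G1 and G3 samples.
#' @param mode carrier definition: `"any_alteration"` (default),
#'   `"loss_only"` or `"gain_only"`.
#' @param bh add a Benjamini-Hochberg adjusted column `p_adj` (off by
#'   default; the headline analysis uses raw p-values and threshold
#'   subsets).
#' @return list with `results` (`data.frame`: `symbol`, `g1_carriers`,
#'   `g3_carriers`, `a`..`d`, `p_value`, `odds_ratio`) sorted by p, and
#'   `subsets`, a list of symbol vectors named `"0.1"`, `"0.01"`, `"0.001"`.
#' @export
stratify_all_genes <- function(matrix, clinical,
                               mode = c("any_alteration", "loss_only",
                                        "gain_only"),
                               bh = FALSE) {
  mode <- match.arg(mode)
  check_clinical(clinical)
  v <- matrix$values
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  if (anyNA(grade)) stop_data("matrix sample(s) missing from clinical table")
  n_g1 <- sum(grade == "G1"); n_g3 <- sum(grade == "G3")
  if (n_g1 == 0 || n_g3 == 0)
    stop_data("need both G1 and G3 samples for grade stratification")
  altered <- colSums(v != 0L) >= 1
  if (!any(altered))
    return(list(results = data.frame(symbol = character(), g1_carriers =
                  integer(), g3_carriers = integer(), a = integer(),
                  b = integer(), c = integer(), d = integer(),
                  p_value = numeric(), odds_ratio = numeric()),
                subsets = list(`0.1` = character(), `0.01` = character(),
                               `0.001` = character())))
  cm <- carrier_matrix(v[, altered, drop = FALSE], mode)
  a <- colSums(cm[grade == "G1", , drop = FALSE])
  cc <- colSums(cm[grade == "G3", , drop = FALSE])
  res <- data.frame(symbol = colnames(v)[altered],
                    g1_carriers = a, g3_carriers = cc,
                    a = a, b = n_g1 - a, c = cc, d = n_g3 - cc,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$p_value <- mapply(fisher_p, res$a, res$b, res$c, res$d)
  res$odds_ratio <- ifelse(res$b * res$c == 0,
                           ifelse(res$a * res$d == 0, NaN, Inf),
                           (res$a * res$d) / (res$b * res$c))
  if (bh) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  subsets <- lapply(c(0.1, 0.01, 0.001),
                    function(t) res$symbol[res$p_value < t])
  names(subsets) <- c("0.1", "0.01", "0.001")
  list(results = res, subsets = subsets)
}

#' Grade-exclusive gene lists
#'
#' Genes altered in at least one G1 sample and in no G3 sample, and the
#' symmetric G3-exclusive list. The two sets are disjoint by construction.
#'
#' @inheritParams stratify_all_genes
#' @return list with character vectors `g1_exclusive`, `g3_exclusive`.
#' @export
exclusive_gene_lists <- function(matrix, clinical) {
  check_clinical(clinical)
  v <- matrix$values
  grade <- clinical$grade[match(rownames(v), clinical$sample_id)]
  alt <- v != 0L
  in_g1 <- colSums(alt[grade == "G1", , drop = FALSE]) > 0
  in_g3 <- colSums(alt[grade == "G3", , drop = FALSE]) > 0
  list(g1_exclusive = colnames(v)[in_g1 & !in_g3],
       g3_exclusive = colnames(v)[in_g3 & !in_g1])
}
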