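# The central object: a ternary patient x gene CNA matrix.

#' Construct a CNA matrix object
#'
#' Thin S3 wrapper around an integer matrix with samples in rows, genes in
#' columns and entries in `{-1, 0, +1}` (loss / neutral / gain), plus the
#' record of (sample, gene) pairs where a loss and a gain segment both
#' overlapped the gene ("conflicts") and how they were resolved.
#'
#' @param values integer matrix, rows = samples, cols = genes, entries in
#'   -1/0/1; dimnames required.
#' @param conflicts `data.frame` with columns `sample_id`, `symbol` (may have
#'   zero rows).
#' @return an object of class `cna_matrix`.
#' @export
cna_matrix <- function(values,
                       conflicts = data.frame(sample_id = character(),
                                              symbol = character())) {
  stopifnot(is.matrix(values),
            nrow(values) == 0 || !is.null(rownames(values)),
            ncol(values) == 0 || !is.null(colnames(values)))
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (length(values) > 0 && !all(values %in% c(-1L, 0L, 1L)))
    stop_data("CNA matrix entries must be -1, 0 or 1")
  storage.mode(values) <- "integer"
  structure(list(values = values,
                 conflicts = conflicts[, c("sample_id", "symbol"),
                                       drop = FALSE]),
            class = "cna_matrix")
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat("CNA matrix:", nrow(x$values), "samples x", ncol(x$values), "genes\n")
  cat("  losses:", sum(x$values == -1L),
      " gains:", sum(x$values == 1L),
      " conflicts:", nrow(x$conflicts), "\n")
  invisible(x)
}

#' @export
dim.cna_matrix <- function(x) dim(x$values)

#' @export
`==.cna_matrix` <- function(e1, e2) {
  identical(e1$values, e2$values) &&
    identical(conflict_key(e1), conflict_key(e2))
}

conflict_key <- function(m) {
  sort(paste(m$conflicts$sample_id, m$conflicts$symbol, sep = "\r"))
}

#' Annotate segments to genes by interval overlap
#'
#' A gene is hit by a segment iff their half-open intervals overlap by at
#' least 1 bp; no minimum fractional overlap is applied. Each
#' (sample, gene, state) combination is emitted at most once, however many
#' same-state segments of that sample cover the gene.
#'
#' @param segments segment `data.frame` ([read_segments()]).
#' @param genes gene model `data.frame` ([read_gene_model()]).
#' @return `data.frame` with columns `sample_id`, `symbol`, `state`.
#' @export
annotate_segments_to_genes <- function(segments, genes) {
  validate_gene_model(genes)
  if (nrow(segments) == 0)
    return(data.frame(sample_id = character(), symbol = character(),
                      state = character(), stringsAsFactors = FALSE))
  # internal half-open [s, e) -> 1-based closed [s+1, e] for IRanges
  seg_gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start_bp + 1,
                              end = segments$end_bp))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start_bp + 1,
                              end = genes$end_bp))
  hits <- GenomicRanges::findOverlaps(seg_gr, gene_gr)
  out <- data.frame(
    sample_id = segments$sample_id[S4Vectors::queryHits(hits)],
    symbol = genes$symbol[S4Vectors::subjectHits(hits)],
    state = segments$state[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  unique(out)
}

#' Build the ternary CNA matrix from (sample, gene, state) triples
#'
#' When both a loss and a gain hit the same (sample, gene) cell the pair is
#' recorded in the matrix's `conflicts` and resolved by `conflict_policy`:
#' `"zero"` (default) sets the entry to 0 so the pair is excluded from all
#' per-gene tallies downstream, `"loss"`/`"gain"` force that state.
#'
#' @param triples `data.frame` from [annotate_segments_to_genes()].
#' @param samples character vector giving the full, ordered sample list
#'   (samples without any call get an all-zero row).
#' @param genes character vector of gene symbols (column order).
#' @param conflict_policy one of `"zero"`, `"loss"`, `"gain"`.
#' @return a [cna_matrix()].
#' @export
build_cna_matrix <- function(triples, samples, genes,
                             conflict_policy = c("zero", "loss", "gain")) {
  conflict_policy <- match.arg(conflict_policy)
  samples <- as.character(samples)
  genes <- as.character(genes)
  if (anyDuplicated(samples) || anyDuplicated(genes))
    stop_data("duplicated sample or gene identifiers")
  vals <- matrix(0L, nrow = length(samples), ncol = length(genes),
                 dimnames = list(samples, genes))
  conflicts <- data.frame(sample_id = character(), symbol = character(),
                          stringsAsFactors = FALSE)
  if (nrow(triples) > 0) {
    bad_s <- !triples$sample_id %in% samples
    bad_g <- !triples$symbol %in% genes
    if (any(bad_s))
      stop_data("triple references unknown sample(s): ",
                paste(unique(triples$sample_id[bad_s]), collapse = ", "))
    if (any(bad_g))
      stop_data("triple references unknown gene(s): ",
                paste(unique(triples$symbol[bad_g]), collapse = ", "))
    triples <- unique(triples[, c("sample_id", "symbol", "state")])
    key <- paste(triples$sample_id, triples$symbol, sep = "\r")
    dup <- key[duplicated(key)]           # same cell, both states
    is_conf <- key %in% dup
    if (any(is_conf)) {
      cf <- unique(triples[is_conf, c("sample_id", "symbol")])
      conflicts <- cf[order(cf$sample_id, cf$symbol), , drop = FALSE]
      rownames(conflicts) <- NULL
    }
    plain <- triples[!is_conf, , drop = FALSE]
    idx <- cbind(match(plain$sample_id, samples), match(plain$symbol, genes))
    vals[idx] <- ifelse(plain$state == "loss", -1L, 1L)
    if (conflict_policy != "zero" && nrow(conflicts) > 0) {
      cidx <- cbind(match(conflicts$sample_id, samples),
                    match(conflicts$symbol, genes))
      vals[cidx] <- if (conflict_policy == "loss") -1L else 1L
    }
  }
  cna_matrix(vals, conflicts)
}

#' Write / read a CNA matrix as TSV
#'
#' Layout: optional `#conflict<TAB>sample<TAB>gene` header lines, then a
#' header row (`sample_id` followed by gene symbols) and one row per sample
#' with entries in -1/0/1. `read_matrix(write_matrix(m))` is the identity,
#' conflict annotations included.
#'
#' @param m a [cna_matrix()].
#' @param path output/input file.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` a
#'   [cna_matrix()].
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "cna_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(m$conflicts) > 0)
    writeLines(paste("#conflict", m$conflicts$sample_id, m$conflicts$symbol,
                     sep = "\t"), con)
  writeLines(paste(c("sample_id", colnames(m$values)), collapse = "\t"), con)
  if (nrow(m$values) > 0) {
    body <- apply(m$values, 1, paste, collapse = "\t")
    writeLines(paste(rownames(m$values), body,
                     sep = if (ncol(m$values) > 0) "\t" else ""), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  is_conf <- startsWith(lines, "#conflict\t")
  conflicts <- data.frame(sample_id = character(), symbol = character(),
                          stringsAsFactors = FALSE)
  if (any(is_conf)) {
    parts <- strsplit(lines[is_conf], "\t", fixed = TRUE)
    conflicts <- data.frame(sample_id = vapply(parts, `[`, "", 2),
                            symbol = vapply(parts, `[`, "", 3),
                            stringsAsFactors = FALSE)
  }
  lines <- lines[!is_conf]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  genes <- header[-1]
  body <- lines[-1]
  vals <- matrix(0L, nrow = length(body), ncol = length(genes))
  samples <- character(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    samples[i] <- parts[1]
    if (length(genes) > 0) {
      v <- suppressWarnings(as.integer(parts[-1]))
      bad <- which(is.na(v) | !v %in% c(-1L, 0L, 1L))
      if (length(bad) > 0)
        stop_data("invalid matrix entry at sample ", parts[1],
                  ", gene ", genes[bad[1]])
      vals[i, ] <- v
    }
  }
  dimnames(vals) <- list(samples, genes)
  cna_matrix(vals, conflicts)
}
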