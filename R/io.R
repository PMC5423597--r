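# Readers and writers for the pipeline's external file dialects.
#
# External coordinates follow the genome-browser convention (1-based,
# inclusive); everything internal is 0-based half-open, so
# length_bp == end_bp - start_bp and two features abut iff end == start.

#' Read a copy-number segmentation file
#'
#' Reads a tab-delimited SEG-like table with one called copy-number segment
#' per row and applies the segment-level quality filters: a minimum number of
#' supporting markers and a minimum genomic segment size. Defaults mirror the
#' array-processing settings the pipeline assumes upstream (5 markers,
#' 100 kbp).
#'
#' The file must carry a header naming (case-insensitively, synonyms allowed)
#' the sample, chromosome, start, end, marker-count and either a categorical
#' state column (`loss`/`gain`) or a mean copy-number column (`Mean`), which
#' is converted to a state by `mean < 2 - delta` = loss, `mean > 2 + delta` =
#' gain. Rows whose state is neither loss nor gain after conversion are
#' skipped and counted in a message.
#'
#' @param path path to the segmentation file.
#' @param min_markers minimum markers per segment (inclusive).
#' @param min_length_bp minimum segment length in bp (inclusive).
#' @param delta half-width of the copy-neutral band around 2 used when only a
#'   mean copy-number column is present.
#' @return a `data.frame` of segments with columns `sample_id`, `chrom`,
#'   `start_bp`, `end_bp` (0-based half-open), `state` (`"loss"`/`"gain"`),
#'   `n_markers`, `length_bp`.
#' @export
#' @examples
#' seg <- system.file("extdata", "example_segments.seg", package = "cnastrat")
#' read_segments(seg)
read_segments <- function(path, min_markers = 5L, min_length_bp = 100000L,
                          delta = 0.5) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) {
    warning("empty segmentation file: ", path)
    return(empty_segments())
  }
  col <- function(synonyms, required = TRUE) {
    hit <- which(tolower(names(raw)) %in% synonyms)
    if (length(hit) == 0) {
      if (required)
        stop_data("segmentation file lacks a column named one of: ",
                  paste(synonyms, collapse = ", "))
      return(NULL)
    }
    raw[[hit[1]]]
  }
  sample_id <- as.character(col(c("sample", "sample_id", "id")))
  chrom <- normalize_chrom(col(c("chromosome", "chrom", "chr")))
  start1 <- suppressWarnings(as.numeric(col(c("start", "start_bp", "loc.start"))))
  end1 <- suppressWarnings(as.numeric(col(c("end", "end_bp", "loc.end"))))
  n_markers <- suppressWarnings(as.numeric(col(c("nummarkers", "n_markers",
                                                "num.mark", "markers"))))
  state_raw <- col(c("state", "call", "type"), required = FALSE)
  mean_raw <- col(c("mean", "seg.mean", "cn", "copynumber"), required = FALSE)
  if (is.null(state_raw) && is.null(mean_raw))
    stop_data("segmentation file needs a State or a Mean copy-number column")

  bad_row <- which(is.na(start1) | is.na(end1) | is.na(n_markers) |
                     end1 < start1)
  if (length(bad_row) > 0)
    stop_data("malformed segment row(s) at line(s) ",
              paste(bad_row + 1L, collapse = ", "),
              " (header is line 1)")
  unknown <- !chrom %in% ACCEPTED_CHROMS & !chrom %in% c("M", "MT")
  if (any(unknown))
    stop_data("unknown chromosome name(s): ",
              paste(unique(chrom[unknown]), collapse = ", "),
              "; accepted: ", paste(ACCEPTED_CHROMS, collapse = ", "))

  if (!is.null(state_raw)) {
    st <- tolower(as.character(state_raw))
    st[st %in% c("loss", "del", "deletion", "-1")] <- "loss"
    st[st %in% c("gain", "amp", "amplification", "1", "+1")] <- "gain"
  } else {
    m <- suppressWarnings(as.numeric(mean_raw))
    st <- rep(NA_character_, length(m))
    st[!is.na(m) & m < 2 - delta] <- "loss"
    st[!is.na(m) & m > 2 + delta] <- "gain"
  }

  seg <- data.frame(sample_id = sample_id, chrom = chrom,
                    start_bp = start1 - 1, end_bp = end1,
                    state = st, n_markers = n_markers,
                    stringsAsFactors = FALSE)
  seg$length_bp <- seg$end_bp - seg$start_bp

  drop_mito <- seg$chrom %in% c("M", "MT")
  if (any(drop_mito)) seg <- seg[!drop_mito, , drop = FALSE]
  n_uncalled <- sum(!seg$state %in% c("loss", "gain"))
  if (n_uncalled > 0) {
    message(n_uncalled, " segment(s) neither loss nor gain; skipped")
    seg <- seg[seg$state %in% c("loss", "gain"), , drop = FALSE]
  }
  keep <- seg$n_markers >= min_markers & seg$length_bp >= min_length_bp
  seg <- seg[keep, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = numeric(), end_bp = numeric(),
             state = character(), n_markers = numeric(),
             length_bp = numeric(), stringsAsFactors = FALSE)
}

#' Read a BED-style gene model
#'
#' Expects at least 4 tab-separated columns: chromosome, start (0-based),
#' end, gene symbol. Symbols must be unique. A fifth `cytoband` column is
#' honoured if present; otherwise use [assign_cytobands()].
#'
#' @param path BED file path.
#' @return `data.frame` with `symbol`, `chrom`, `start_bp`, `end_bp` and,
#'   when available, `cytoband`.
#' @export
read_gene_model <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4) stop_data("gene model needs >= 4 BED columns")
  genes <- data.frame(symbol = as.character(raw[[4]]),
                      chrom = normalize_chrom(raw[[1]]),
                      start_bp = as.numeric(raw[[2]]),
                      end_bp = as.numeric(raw[[3]]),
                      stringsAsFactors = FALSE)
  if (ncol(raw) >= 5 && !all(is.na(raw[[5]])) && is.character(raw[[5]]))
    genes$cytoband <- as.character(raw[[5]])
  validate_gene_model(genes)
}

validate_gene_model <- function(genes) {
  if (nrow(genes) == 0) stop_data("empty gene model")
  if (anyDuplicated(genes$symbol))
    stop_data("duplicated gene symbol(s): ",
              paste(unique(genes$symbol[duplicated(genes$symbol)]),
                    collapse = ", "))
  if (any(genes$end_bp <= genes$start_bp))
    stop_data("gene model contains end <= start")
  genes
}

#' Read a UCSC cytoBand table
#'
#' Five tab-separated columns without header: chrom, start, end, band name
#' (e.g. `p21.31`), Giemsa stain. Band labels are returned joined with the
#' chromosome (`3p21.31`).
#'
#' @param path cytoBand.txt path.
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `cytoband`.
#' @export
read_cytobands <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop_data("cytoband table needs >= 4 columns")
  chrom <- normalize_chrom(raw[[1]])
  data.frame(chrom = chrom,
             start_bp = as.numeric(raw[[2]]),
             end_bp = as.numeric(raw[[3]]),
             cytoband = paste0(chrom, as.character(raw[[4]])),
             stringsAsFactors = FALSE)
}

#' Assign each gene to a cytoband by its midpoint
#'
#' Membership by gene midpoint avoids double-counting genes that span a band
#' boundary.
#'
#' @param genes gene model `data.frame` ([read_gene_model()]).
#' @param cytobands cytoband table ([read_cytobands()]).
#' @return the gene model with a `cytoband` column added/replaced.
#' @export
assign_cytobands <- function(genes, cytobands) {
  mid <- floor((genes$start_bp + genes$end_bp) / 2)
  band <- rep(NA_character_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ci <- which(cytobands$chrom == ch)
    if (length(ci) == 0) next
    hit <- findInterval(mid[gi], cytobands$start_bp[ci])
    ok <- hit >= 1 & mid[gi] < cytobands$end_bp[ci][pmax(hit, 1)]
    band[gi[ok]] <- cytobands$cytoband[ci][hit[ok]]
  }
  if (anyNA(band))
    stop_data("gene(s) outside every cytoband: ",
              paste(genes$symbol[is.na(band)], collapse = ", "))
  genes$cytoband <- band
  genes
}

#' Read a clinical annotation table
#'
#' Tab-delimited with header: `sample_id`, `grade` (G1-G4), `surv_time`
#' (months), `event` (0/1 or TRUE/FALSE), `death_cause` (`DOTD` death of
#' tumour disease, `DBOR` death because of other reasons, `alive`).
#'
#' @param path TSV path.
#' @return validated clinical `data.frame`.
#' @export
read_clinical <- function(path) {
  cl <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  check_clinical(cl)
  if (!is.null(cl$surv_time) && any(cl$surv_time < 0, na.rm = TRUE))
    stop_data("negative survival time")
  if (!is.null(cl$event)) {
    cl$event <- as.logical(cl$event)
    if (!is.null(cl$death_cause)) {
      bad <- cl$event & !cl$death_cause %in% c("DOTD", "DBOR")
      if (any(bad))
        stop_data("event without a DOTD/DBOR death cause for sample(s): ",
                  paste(cl$sample_id[bad], collapse = ", "))
    }
  }
  cl
}

#' Read a gene-to-pathway membership table
#'
#' Tab-delimited with header; columns `pathway_id`, `pathway_name`
#' (optional), `gene`. A gene may appear under many pathways.
#'
#' @param path TSV path.
#' @return `data.frame` with `pathway_id`, `pathway_name`, `gene`.
#' @export
read_pathways <- function(path) {
  pw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "gene") %in% names(pw)))
    stop_data("pathway table needs columns pathway_id and gene")
  if (is.null(pw$pathway_name)) pw$pathway_name <- pw$pathway_id
  pw[, c("pathway_id", "pathway_name", "gene")]
}
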