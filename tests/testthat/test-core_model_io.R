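# Readers, segment filters, segment->gene annotation, matrix round-trip.

test_that("read_segments applies the marker and length filters inclusively", {
  seg <- data.frame(
    sample_id = "S1", chrom = "3",
    start_bp = c(0, 0, 0, 0), end_bp = c(2e5, 2e5, 99999, 100000),
    state = "loss", n_markers = c(4, 5, 50, 50))
  path <- write_seg_file(seg)
  got <- read_segments(path)
  # n_markers = 4 dropped; length 99,999 dropped; boundaries 5 and 100 kbp kept
  expect_equal(nrow(got), 2)
  expect_equal(got$length_bp, c(2e5, 1e5))
  expect_equal(got$start_bp, c(0, 0))   # 1-based 1 -> 0-based 0
  expect_equal(got$end_bp[2], 100000)
})

test_that("read_segments handles empty files, bad rows, bad chromosomes", {
  p <- tempfile()
  writeLines("Sample\tChromosome\tStart\tEnd\tState\tNumMarkers", p)
  expect_warning(got <- read_segments(p), "empty")
  expect_equal(nrow(got), 0)

  writeLines(c("Sample\tChromosome\tStart\tEnd\tState\tNumMarkers",
               "S1\t3\t1\t200000\tloss\t50",
               "S1\t3\tnot_a_number\t200000\tloss\t50"), p)
  expect_error(read_segments(p), "line.*3")

  writeLines(c("Sample\tChromosome\tStart\tEnd\tState\tNumMarkers",
               "S1\tchr99\t1\t200000\tloss\t50"), p)
  expect_error(read_segments(p), "accepted")
})

test_that("numeric mean columns convert to states with a neutral band", {
  p <- tempfile()
  writeLines(c("Sample\tChromosome\tStart\tEnd\tMean\tNumMarkers",
               "S1\t1\t1\t200000\t1.2\t50",    # loss
               "S1\t1\t1\t200000\t2.9\t50",    # gain
               "S1\t1\t1\t200000\t2.1\t50"),   # neutral -> skipped
             p)
  expect_message(got <- read_segments(p), "1 segment")
  expect_equal(got$state, c("loss", "gain"))
})

test_that("raising either filter never increases surviving segments", {
  fx <- random_interval_fixture(11)
  path <- write_seg_file(fx$segments)
  base <- nrow(read_segments(path, min_markers = 5, min_length_bp = 1e5))
  for (mm in c(10, 50, 60)) {
    expect_lte(nrow(read_segments(path, min_markers = mm,
                                  min_length_bp = 1e5)), base)
  }
  for (ml in c(2e5, 5e5, 1e6)) {
    expect_lte(nrow(read_segments(path, min_markers = 5,
                                  min_length_bp = ml)), base)
  }
})

test_that("annotation respects half-open boundaries and deduplicates", {
  genes <- data.frame(symbol = c("A", "B", "C"), chrom = "1",
                      start_bp = c(199, 200, 400),
                      end_bp = c(300, 300, 500))
  seg <- data.frame(sample_id = "S1", chrom = "1", start_bp = 100,
                    end_bp = 200, state = "loss", n_markers = 10,
                    length_bp = 100)
  hits <- annotate_segments_to_genes(seg, genes)
  expect_equal(hits$symbol, "A")   # [100,200) vs [199,300) hits, [200,300) no

  # one segment spanning 3 genes -> 3 triples
  wide <- seg; wide$end_bp <- 1000
  expect_equal(nrow(annotate_segments_to_genes(wide, genes)), 3)

  # two same-state overlapping segments of one sample -> one triple
  two <- rbind(seg, transform(seg, start_bp = 150, end_bp = 260))
  hits2 <- annotate_segments_to_genes(two, genes)
  expect_equal(nrow(hits2[hits2$symbol == "A", ]), 1)
})

test_that("annotation agrees with the brute-force overlap oracle", {
  for (seed in c(1, 2, 3)) {
    fx <- random_interval_fixture(seed)
    got <- annotate_segments_to_genes(fx$segments, fx$genes)
    want <- oracle_overlap(fx$segments, fx$genes)
    key <- function(d) sort(paste(d$sample_id, d$symbol, d$state))
    expect_equal(key(got), key(want))
    # conservation: deduplicated triple count matches the oracle's
    expect_equal(nrow(got), nrow(want))
  }
})

test_that("build_cna_matrix codes states and resolves conflicts", {
  samples <- c("S1", "S2"); genes <- c("A", "B")
  empty <- build_cna_matrix(data.frame(sample_id = character(),
                                       symbol = character(),
                                       state = character()),
                            samples, genes)
  expect_true(all(empty$values == 0L))

  one <- build_cna_matrix(data.frame(sample_id = "S1", symbol = "A",
                                     state = "loss"), samples, genes)
  expect_equal(sum(one$values == -1L), 1)
  expect_equal(one$values["S1", "A"], -1L)

  conf_triples <- data.frame(sample_id = c("S1", "S1"),
                             symbol = c("A", "A"),
                             state = c("loss", "gain"))
  conf <- build_cna_matrix(conf_triples, samples, genes)
  expect_equal(nrow(conf$conflicts), 1)
  expect_equal(conf$values["S1", "A"], 0L)
  forced <- build_cna_matrix(conf_triples, samples, genes,
                             conflict_policy = "gain")
  expect_equal(forced$values["S1", "A"], 1L)

  expect_error(build_cna_matrix(data.frame(sample_id = "S9", symbol = "A",
                                           state = "loss"),
                                samples, genes), "unknown sample")
})

test_that("matrix TSV round-trip is the identity, conflicts included", {
  co <- generate_cohort(small_design(5))
  m <- cohort_matrix(co)
  # plant a conflict to exercise the annotation round-trip
  m$conflicts <- data.frame(sample_id = rownames(m$values)[1],
                            symbol = colnames(m$values)[1])
  m$values[1, 1] <- 0L
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_true(m == back)
  expect_identical(back$values, m$values)

  # invalid entry rejected, naming the cell
  bad_path <- tempfile()
  writeLines(c("sample_id\tA\tB", "S1\t0\t2"), bad_path)
  expect_error(read_matrix(bad_path), "invalid matrix entry.*gene B")

  # empty gene list round-trips to an empty matrix
  m0 <- mk_matrix(matrix(0L, 2, 0), genes = character(0))
  p0 <- tempfile()
  write_matrix(m0, p0)
  expect_equal(dim(read_matrix(p0)), c(2, 0))
})

test_that("extdata example files parse and assemble into a matrix", {
  seg <- read_segments(system.file("extdata", "example_segments.seg",
                                   package = "cnastrat"))
  genes <- read_gene_model(system.file("extdata", "example_genes.bed",
                                       package = "cnastrat"))
  bands <- read_cytobands(system.file("extdata", "example_cytobands.txt",
                                      package = "cnastrat"))
  clinical <- read_clinical(system.file("extdata", "example_clinical.tsv",
                                        package = "cnastrat"))
  genes <- assign_cytobands(genes, bands)
  expect_equal(genes$cytoband[genes$symbol == "GENE_A"], "3p21.31")
  m <- build_cna_matrix(annotate_segments_to_genes(seg, genes),
                        clinical$sample_id, genes$symbol)
  expect_equal(m$values["S1", "GENE_A"], -1L)
  expect_equal(m$values["S1", "GENE_B"], -1L)
  expect_equal(m$values["S2", "GENE_B"], 0L)   # segment ends before gene B
  expect_equal(m$values["S3", "GENE_D"], 1L)
})
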