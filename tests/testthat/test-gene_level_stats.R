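# Per-gene profiles, loss/gain ratios, Fisher stratification.

test_that("profile_genes classifies and counts consistently", {
  v <- cbind(lossy = c(-1L, -1L, 0L, 0L), mixed = c(-1L, 1L, 0L, 0L),
             gainy = c(0L, 0L, 1L, 0L), silent = c(0L, 0L, 0L, 0L))
  m <- mk_matrix(v)
  cl <- mk_clinical(rownames(m$values), c("G1", "G1", "G3", "G3"))
  prof <- profile_genes(m, cl)
  expect_equal(prof$cna_class,
               c("loss_only", "mixed", "gain_only", "unaltered"))
  expect_equal(prof$n_loss[prof$symbol == "lossy"], 2)
  expect_equal(prof$g1_carriers, c(2, 2, 0, 0))
  expect_equal(prof$g3_carriers, c(0, 0, 1, 0))
  # conservation: per-gene tallies sum to matrix-wide entry counts
  expect_equal(sum(prof$n_loss), sum(v == -1L))
  expect_equal(sum(prof$n_gain), sum(v == 1L))

  expect_error(profile_genes(m, cl[-1, ]), "without clinical record")
})

test_that("conservation holds on a full synthetic cohort", {
  co <- generate_cohort(small_design(3))
  m <- cohort_matrix(co)
  prof <- profile_genes(m, co$clinical)
  expect_equal(sum(prof$n_loss), sum(m$values == -1L))
  expect_equal(sum(prof$n_gain), sum(m$values == 1L))
  expect_equal(sum(prof$n_altered), sum(m$values != 0L))
})

test_that("loss_gain_ratio reproduces the printed-style ratios", {
  # 10 losses vs 8 gains among G1 -> 1.25; 29 vs 50 among G3 -> 0.58
  v <- matrix(0L, 4, 79)
  v[1, 1:10] <- -1L; v[2, 11:18] <- 1L
  v[3, 1:29] <- -1L; v[4, 21:70] <- 1L
  m <- mk_matrix(v)
  cl <- mk_clinical(rownames(m$values), c("G1", "G1", "G3", "G3"))
  expect_equal(loss_gain_ratio(m, cl, "G1"), 1.25)
  expect_equal(loss_gain_ratio(m, cl, "G3"), 0.58)

  zero <- mk_matrix(matrix(0L, 2, 3))
  clz <- mk_clinical(rownames(zero$values), c("G1", "G1"))
  expect_warning(r <- loss_gain_ratio(zero, clz, "G1"), "undefined")
  expect_true(is.na(r))
})

test_that("fisher_gene reproduces the published worked examples", {
  # VHL-like loss pattern 14/26 G1 vs 1/20 G3
  expect_equal(fisher_gene(14, 12, 1, 19)$p_value, 0.0004437,
               tolerance = 1e-3)
  # BRAF-like gain 0/26 vs 3/20; two-sided == one-sided == 1140/15180
  expect_equal(fisher_gene(0, 26, 3, 17)$p_value, 1140 / 15180,
               tolerance = 1e-12)
  # balanced tables are null
  expect_equal(fisher_gene(13, 13, 10, 10)$p_value, 1)
  expect_equal(fisher_gene(14, 12, 1, 19)$odds_ratio, 14 * 19 / 12)
  expect_equal(fisher_gene(1, 0, 1, 1)$odds_ratio, Inf)
  expect_error(fisher_gene(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_gene(0, 0, 3, 4), "margins")
})

test_that("fisher_gene matches brute-force enumeration and is symmetric", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    cc <- cuts[3] - cuts[2]; d <- n - cuts[3]
    if (a + b == 0 || cc + d == 0) next
    p <- fisher_gene(a, b, cc, d)$p_value
    expect_equal(p, oracle_fisher(a, b, cc, d), tolerance = 1e-10)
    expect_equal(p, fisher_gene(cc, d, a, b)$p_value, tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("stratify_all_genes tests altered genes against G1 vs G3", {
  we <- worked_example_cohort()
  st <- stratify_all_genes(we$matrix, we$clinical)
  expect_equal(nrow(st$results), 7)
  # the strongest planted pattern sits in the p<0.001 subset
  expect_true("pat_21_4" %in% st$subsets[["0.001"]])
  p214 <- st$results$p_value[st$results$symbol == "pat_21_4"]
  expect_equal(p214, 6.7e-5, tolerance = 0.005)
  expect_false("pat_13_10" %in% st$subsets[["0.1"]])
  # loss_only mode ignores the gain-pattern gene
  st_loss <- stratify_all_genes(we$matrix, we$clinical, mode = "loss_only")
  expect_equal(st_loss$results$g3_carriers[
    st_loss$results$symbol == "pat_0_3"], 0)

  empty <- mk_matrix(matrix(0L, 4, 0), genes = character(0))
  cl <- mk_clinical(rownames(empty$values), c("G1", "G1", "G3", "G3"))
  expect_equal(nrow(stratify_all_genes(empty, cl)$results), 0)

  g1_only <- mk_clinical(c("S01", "S02"), c("G1", "G1"))
  m2 <- mk_matrix(matrix(c(-1L, 0L), 2, 1), samples = c("S01", "S02"))
  expect_error(stratify_all_genes(m2, g1_only), "G1 and G3")
})

test_that("G2/G4 samples are excluded from the grade test", {
  v <- rbind(matrix(-1L, 3, 1), matrix(0L, 3, 1))
  m <- mk_matrix(v)
  cl <- mk_clinical(rownames(m$values), c("G1", "G2", "G4", "G3", "G3", "G2"))
  st <- stratify_all_genes(m, cl)
  # only 1 G1 carrier and 0/2 G3 carriers enter the table
  expect_equal(st$results[1, c("a", "b", "c", "d")],
               data.frame(a = 1, b = 0, c = 0, d = 2),
               ignore_attr = TRUE)
})

test_that("neutral loci produce near-uniform small-p rates (type I)", {
  # one grade-neutral locus; fraction of per-gene p < 0.1 over 100 seeds
  # should sit within 3 SD of the nominal 0.1 (Fisher is conservative, so
  # the lower bound uses the discreteness-corrected attainable rate)
  loci <- list(locus_spec("5q31.1", 10, "gain", 0.5, 0.5, "neutral"))
  hits <- 0; total <- 0
  for (seed in 1:100) {
    co <- generate_cohort(small_design(seed, loci = loci, noise_rate = 0))
    st <- stratify_all_genes(cohort_matrix(co), co$clinical)
    hits <- hits + length(st$subsets[["0.1"]])
    total <- total + nrow(st$results)
  }
  frac <- hits / total
  sd3 <- 3 * sqrt(0.1 * 0.9 / 100)   # locus-correlated: ~100 independent draws
  expect_lt(frac, 0.1 + sd3)
})

test_that("exclusive gene lists are correct and disjoint", {
  v <- cbind(g1x = c(-1L, 0L, 0L, 0L), both = c(-1L, 0L, -1L, 0L),
             g3x = c(0L, 0L, 1L, 0L))
  m <- mk_matrix(v)
  cl <- mk_clinical(rownames(m$values), c("G1", "G1", "G3", "G3"))
  ex <- exclusive_gene_lists(m, cl)
  expect_equal(ex$g1_exclusive, "g1x")
  expect_equal(ex$g3_exclusive, "g3x")
  expect_length(intersect(ex$g1_exclusive, ex$g3_exclusive), 0)
})
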