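# Weighted matrices, correlation, clustering, A-F/Z group assignment.

test_that("weight_matrix replaces signs by signed recurrence counts", {
  v <- cbind(g1 = c(-1L, -1L, -1L, 1L, 1L, 0L),
             g2 = c(0L, 0L, 0L, 0L, 0L, 0L))
  m <- mk_matrix(v)
  w <- weight_matrix(m)
  expect_equal(unname(w[, "g1"]), c(-3, -3, -3, 2, 2, 0))
  expect_true(all(w[, "g2"] == 0))
  # brute-force per-column check on synthetic data
  co <- generate_cohort(small_design(14))
  mc <- cohort_matrix(co)
  wc <- weight_matrix(mc)
  for (g in sample(colnames(mc$values), 10)) {
    nl <- sum(mc$values[, g] == -1L); ng <- sum(mc$values[, g] == 1L)
    expect_equal(unname(wc[, g]),
                 unname(ifelse(mc$values[, g] == -1L, -nl,
                               ifelse(mc$values[, g] == 1L, ng, 0))))
  }
  # sign preservation
  expect_true(all(sign(wc) == sign(mc$values)))
})

test_that("correlation matrices are Pearson with zero-variance fallback", {
  set.seed(31)
  x <- matrix(rnorm(10 * 20), 10)
  r <- correlation_matrix(x)
  expect_equal(dim(r), c(10, 10))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 10))
  for (i in 1:4) for (j in 6:9)
    expect_equal(r[i, j], oracle_pearson(x[i, ], x[j, ]), tolerance = 1e-12)

  # duplicated row correlates at exactly 1
  xd <- rbind(x, x[1, ])
  expect_equal(correlation_matrix(xd)[1, 11], 1)

  # orthogonal equal-size loss patterns anticorrelate
  a <- c(1, 1, 1, 0, 0, 0); b <- c(0, 0, 0, 1, 1, 1)
  expect_lt(correlation_matrix(rbind(a, b))["a", "b"], 0)

  # zero-variance rows: 0 off-diagonal, 1 on the diagonal, no NaN
  xz <- rbind(flat = rep(2, 20), x)
  rz <- correlation_matrix(xz)
  expect_equal(unname(rz["flat", 2]), 0)
  expect_equal(unname(rz["flat", "flat"]), 1)
  expect_false(anyNA(rz))

  expect_error(correlation_matrix(x[1, , drop = FALSE]), "two rows")
})

test_that("clustering is UPGMA on Euclidean distance", {
  # two identical rows merge first at height 0
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  hc <- cluster_average_euclidean(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  # colinear 3-point configuration: heights 1 and mean(3, 2) = 2.5
  m3 <- cbind(c(0, 1, 3), 0)
  hc3 <- cluster_average_euclidean(m3)
  expect_equal(hc3$height, c(1, 2.5))
  # agrees with the naive UPGMA oracle on random 8-row instances
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 5), 8)
    expect_equal(sort(cluster_average_euclidean(x)$height),
                 oracle_upgma_heights(x), tolerance = 1e-10)
  }
  expect_error(cluster_average_euclidean(matrix(c(1, NA), 1)), "non-finite")
})

test_that("group rule maps burden combinations to A-F/Z", {
  genes <- c(paste0("u", 1:4), paste0("w", 1:4))
  set <- structure(list(name = "toy", members = data.frame(
    symbol = genes, label = rep(c("+G1", "+G3"), each = 4),
    stringsAsFactors = FALSE)), class = "gene_set_result")
  v <- matrix(0L, 8, 8, dimnames = list(sprintf("S%d", 1:8), genes))
  v[1, 1:3] <- -1L                              # A: G1 losses only
  v[2, 5:7] <- -1L                              # B: G3 losses only
  v[3, 5:7] <- 1L                               # C: G3 gains only
  v[4, 1:3] <- -1L; v[4, 5:7] <- -1L            # D
  v[5, 1:3] <- -1L; v[5, 5:7] <- 1L             # E
  v[6, 1:3] <- -1L; v[6, 5:7] <- -1L; v[6, 8] <- 1L  # F needs 3 G3 gains
  v[6, 5:6] <- -1L
  # make sample 6 carry 3 G3 losses AND 3 G3 gains via separate genes
  v[6, 5:8] <- c(-1L, -1L, -1L, 1L)
  v[7, 1:2] <- -1L                              # below threshold -> Z
  groups <- assign_patient_groups(mk_matrix(v), set)
  expect_equal(groups$group[1:5], c("A", "B", "C", "D", "E"))
  expect_equal(groups$group[7:8], c("Z", "Z"))
  expect_equal(groups$G1_loss[1], 3)
  expect_error(assign_patient_groups(mk_matrix(v), set,
                                     thresholds = c(G1_loss = 3)),
               "missing burden threshold")
})

test_that("F captures joint G3 losses and gains", {
  genes <- paste0("w", 1:6)
  set <- structure(list(name = "toy", members = data.frame(
    symbol = genes, label = "+G3", stringsAsFactors = FALSE)),
    class = "gene_set_result")
  v <- matrix(0L, 1, 6, dimnames = list("S1", genes))
  v[1, 1:3] <- -1L; v[1, 4:6] <- 1L
  expect_equal(assign_patient_groups(mk_matrix(v), set)$group, "F")
})

test_that("group assignment is invariant under row/column permutation", {
  co <- generate_cohort(small_design(15))
  m <- cohort_matrix(co)
  set <- derive_hro201(m, co$clinical)
  g0 <- assign_patient_groups(m, set)
  set.seed(1)
  perm_s <- sample(nrow(m$values)); perm_g <- sample(ncol(m$values))
  mp <- cna_matrix(m$values[perm_s, perm_g])
  gp <- assign_patient_groups(mp, set)
  expect_equal(gp$group[match(g0$sample_id, gp$sample_id)], g0$group)
})

test_that("uniform carrier counts make weighting a global rescale", {
  # every gene lost in exactly 3 and gained in exactly 3 samples
  v <- matrix(0L, 8, 6)
  for (j in 1:6) {
    v[setdiff(1:4, ((j - 1) %% 4) + 1), j] <- -1L
    v[setdiff(5:8, 4 + ((j - 1) %% 4) + 1), j] <- 1L
  }
  m <- mk_matrix(v)
  expect_true(all(colSums(v == -1L) == 3) && all(colSums(v == 1L) == 3))
  r_raw <- correlation_matrix(m$values)
  r_w <- correlation_matrix(weight_matrix(m))
  expect_equal(r_w, r_raw, tolerance = 1e-12)
})

test_that("samples-by-cytoband counting feeds the heatmap pipeline", {
  co <- generate_cohort(small_design(16))
  m <- cohort_matrix(co)
  cm <- cytoband_count_matrix(m, co$gene_model, "gain")
  expect_equal(nrow(cm), nrow(m$values))
  band <- "7q22.1"
  sym <- co$gene_model$symbol[co$gene_model$cytoband == band]
  expect_equal(unname(cm[, band]),
               unname(rowSums(m$values[, sym, drop = FALSE] == 1L)))
  r <- correlation_matrix(cm)
  hc <- cluster_average_euclidean(r)
  expect_equal(length(hc$order), nrow(m$values))
})
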