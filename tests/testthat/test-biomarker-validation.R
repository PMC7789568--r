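test_that("pca_fit centers, separates constructed groups, stores centroids", {
  # two identical samples per group with distinct group means
  x <- cbind(c1 = c(10, 0, 5), c2 = c(10, 0, 5),
             k1 = c(0, 10, 5), k2 = c(0, 10, 5))
  rownames(x) <- c("d1", "d2", "d3")
  g <- c("case", "case", "control", "control")
  m <- pca_fit(x, g)
  # PC1 separates the groups; within-group projected variance is 0
  expect_gt(abs(m$centroids["case", 1] - m$centroids["control", 1]), 1)
  expect_equal(unname(m$scores["c1", ]), unname(m$scores["c2", ]))
  # centroids are the means of projected training samples, by definition
  expect_equal(unname(m$centroids["case", ]),
               unname(colMeans(m$scores[g == "case", ])))
  # training projections are centered per component
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(m$rotation), diag(2), ignore_attr = TRUE)
  expect_error(pca_fit(x[1, , drop = FALSE], g), "2 DMRs")
})

test_that("pca_fit recovers a planted rank-2 subspace", {
  set.seed(71)
  n_dmr <- 40
  basis <- qr.Q(qr(matrix(rnorm(n_dmr * 2), ncol = 2)))
  scores <- matrix(rnorm(2 * 12, sd = c(5, 2)), nrow = 2)
  x <- basis %*% scores + rnorm(n_dmr)     # constant per-DMR offsets
  rownames(x) <- sprintf("d%d", 1:n_dmr)
  colnames(x) <- sprintf("s%d", 1:12)
  m <- pca_fit(x, rep(c("case", "control"), each = 6))
  # principal angles between span(rotation) and span(basis) ~ 0
  sv <- svd(crossprod(m$rotation, basis))$d
  expect_lt(max(abs(sv - 1)), 1e-8)
})

test_that("classify_samples predicts the nearest centroid with a tie rule", {
  x <- cbind(c1 = c(10, 0), c2 = c(12, 2),
             k1 = c(0, 10), k2 = c(2, 12))
  rownames(x) <- c("d1", "d2")
  g <- c("case", "case", "control", "control")
  m <- pca_fit(x, g)
  # the case-mean preimage classifies as case
  pred <- classify_samples(m, rowMeans(x[, 1:2]))
  expect_identical(pred$predicted, "case")
  # midpoint of the two group means projects onto the centroid midpoint
  mid <- rowMeans(cbind(rowMeans(x[, 1:2]), rowMeans(x[, 3:4])))
  expect_identical(classify_samples(m, mid)$predicted, "unclassified")
  expect_error(classify_samples(m, c(1, 2, 3)), "length")
})

test_that("remove_outlier_dmrs flags only values alien to both groups", {
  set.seed(73)
  n_dmr <- 1000
  # large training groups so the estimated 3-SD bands carry ~ the nominal
  # normal tail (small n inflates the tail and would not meet the 1% bound)
  train <- matrix(rnorm(n_dmr * 80, mean = 50, sd = 5), nrow = n_dmr,
                  dimnames = list(sprintf("d%d", 1:n_dmr), NULL))
  g <- rep(c("case", "control"), each = 40)
  blinded <- matrix(rnorm(n_dmr * 2, mean = 50, sd = 5), nrow = n_dmr,
                    dimnames = list(rownames(train), NULL))
  r <- remove_outlier_dmrs(train, blinded, g)
  expect_lte(r$removed, 0.01 * n_dmr)   # null blinded data: <= 1% removed

  # a clean world where only the constructed spike is alien to both groups:
  # blinded values sit exactly at the training row means except one
  train2 <- train[1:12, ]
  g2 <- g
  clean <- cbind(rowMeans(train2), rowMeans(train2))
  rownames(clean) <- rownames(train2)
  spiked <- clean
  spiked["d7", 2] <- 5000                # 100x spike
  r2 <- remove_outlier_dmrs(train2, spiked, g2)
  expect_identical(r2$outlier_dmrs, "d7")
  # idempotent on the surviving set
  r3 <- remove_outlier_dmrs(train2[r2$keep, ], spiked[r2$keep, ], g2)
  expect_identical(r3$removed, 0L)
  expect_identical(r3$keep, r2$keep)
})

test_that("permutation_test is deterministic and uses the add-one rule", {
  s <- make_sim(n_windows = 150, seed = 81, n_planted_dmrs = 5)
  p1 <- permutation_test(s$counts, s$grid, n_permutations = 1, seed = 5)
  p2 <- permutation_test(s$counts, s$grid, n_permutations = 1, seed = 5)
  expect_identical(p1$null_counts, p2$null_counts)
  expect_gt(p1$p_value, 0)
  expect_error(permutation_test(s$counts, s$grid, n_permutations = 0),
               "n_permutations")
})

test_that("permutation empirical p is calibrated (scaled-down null check)", {
  # tiny null worlds: 6v6, 100 windows, 19 permutations, reject at 0.05
  rejections <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    s <- make_sim(n_windows = 100, seed = 9000 + i, n_case = 6,
                  n_control = 6, effect_fold = 1, n_planted_dmrs = 0,
                  base_mean_depth = 10)
    pn <- permutation_test(s$counts, s$grid, n_permutations = 19,
                           p_threshold = 1e-3, seed = 100 + i)
    if (pn$p_value <= 0.05) rejections <- rejections + 1
  }
  expect_lte(abs(rejections - 0.05 * n_rep),
             3 * sqrt(n_rep * 0.05 * 0.95) + 1e-9)
})

test_that("cross_validate scores strong signal perfectly, never leaks", {
  s <- make_sim(n_windows = 400, seed = 83, effect_fold = 4,
                base_mean_depth = 50, n_planted_dmrs = 20)
  cv <- cross_validate(s$counts, s$grid)
  expect_equal(cv$accuracy, 1.0)
  expect_identical(nrow(cv$folds), 26L)

  # corrupting a held-out sample's counts cannot change that fold's DMRs
  cc <- s$counts$counts
  cc[, "case_3"] <- as.integer(cc[, "case_3"] * 50)
  cv2 <- cross_validate(count_matrix(cc, s$counts$samples[, c("sample_id",
                                                              "group")]),
                        s$grid)
  expect_identical(cv$folds$n_dmrs[cv$folds$sample_id == "case_3"],
                   cv2$folds$n_dmrs[cv2$folds$sample_id == "case_3"])

  # a duplicate of a training sample is classified as its group
  dup <- cbind(s$counts$counts,
               dup_1 = s$counts$counts[, "control_2"])
  smp <- rbind(s$counts$samples[, c("sample_id", "group")],
               data.frame(sample_id = "dup_1", group = "control"))
  cvd <- cross_validate(count_matrix(dup, smp), s$grid)
  expect_identical(
    cvd$folds$predicted[cvd$folds$sample_id == "dup_1"], "control")

  expect_error(cross_validate(make_sim(n_windows = 50, n_case = 2,
                                       n_control = 2)$counts,
                              tile_genome(c(chr1 = 5e4), 1000)),
               ">= 3")
})

test_that("cross_validate sits at chance on null data", {
  correct <- 0
  total <- 0
  for (i in 1:3) {
    s <- make_sim(n_windows = 300, seed = 500 + i, effect_fold = 1,
                  n_planted_dmrs = 0)
    cv <- cross_validate(s$counts, s$grid, p_threshold = 0.01)
    correct <- correct + sum(cv$folds$predicted == cv$folds$truth)
    total <- total + nrow(cv$folds)
  }
  expect_gt(correct / total, 0.25)
  expect_lt(correct / total, 0.75)
})

test_that("blinded_workflow classifies, logs provenance, is deterministic", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 4e5, seed = 85,
                    effect_fold = 3, n_planted_dmrs = 15)
  sim <- (function(cfg) {
    grid <- tile_genome(c(chr1 = cfg$chrom_length), cfg$window_size)
    planted <- plant_dmrs(grid, cfg)
    baseline <- simulate_window_baseline(grid, cfg)
    counts <- simulate_counts(grid, cfg, planted, baseline = baseline)
    bc <- cfg; bc$n_case <- 3; bc$n_control <- 3; bc$seed <- 860L
    class(bc) <- "sim_config"
    blind <- simulate_counts(grid, bc, planted, baseline = baseline)
    truth <- blind$samples$group
    colnames(blind$counts) <- sprintf("b%d", 1:6)
    blind <- count_matrix(blind$counts,
                          data.frame(sample_id = colnames(blind$counts),
                                     group = "blinded"))
    list(grid = grid, counts = counts, blind = blind, truth = truth)
  })(cfg)
  cls <- blinded_workflow(sim$counts, sim$blind, sim$grid)
  expect_identical(cls$predicted, sim$truth)
  expect_gte(attr(cls, "n_dmrs"), attr(cls, "n_dmrs_after_outlier_removal"))
  cls2 <- blinded_workflow(sim$counts, sim$blind, sim$grid)
  expect_identical(as.data.frame(cls), as.data.frame(cls2))

  # empty blinded set -> empty result
  empty <- count_matrix(sim$counts$counts[, integer(0), drop = FALSE],
                        data.frame(sample_id = character(),
                                   group = character()))
  expect_identical(nrow(blinded_workflow(sim$counts, empty, sim$grid)), 0L)
})

test_that("classification accuracy is monotone in the planted effect", {
  acc <- vapply(c(1, 2, 3), function(fold) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 6e5, seed = 87,
                      effect_fold = fold,
                      n_planted_dmrs = if (fold == 1) 0 else 20)
    grid <- tile_genome(c(chr1 = cfg$chrom_length), cfg$window_size)
    planted <- plant_dmrs(grid, cfg)
    counts <- simulate_counts(grid, cfg, planted)
    cv <- cross_validate(counts, grid, p_threshold = 0.01)
    cv$accuracy
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
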