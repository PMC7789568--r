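# fabricate an aligned results table from a significance mask
mask_results <- function(grid, sig, lfc = NULL) {
  p <- ifelse(sig, 1e-8, 0.5)
  if (is.null(lfc)) lfc <- rep(1, nrow(grid))
  data.frame(window = grid$window, s1 = 10, s2 = 10, lfc = lfc,
             p_value = p, q_value = p, flag = "ok",
             stringsAsFactors = FALSE)
}

test_that("call_dmrs merges adjacent significant windows", {
  grid <- tile_genome(c(chr1 = 12000), 1000)
  expect_identical(nrow(call_dmrs(mask_results(grid, rep(FALSE, 12)),
                                  grid)), 0L)

  sig <- rep(FALSE, 12)
  sig[c(5, 6, 9)] <- TRUE
  d <- call_dmrs(mask_results(grid, sig), grid)
  expect_identical(d$n_windows, c(2L, 1L))
  expect_equal(d$start, c(4000, 8000))
  expect_equal(d$stop, c(6000, 9000))
  expect_equal(d$length_kb, c(2, 1))

  # runs never merge across chromosomes
  g2 <- tile_genome(c(a = 3000, b = 3000), 1000)
  sig2 <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  d2 <- call_dmrs(mask_results(g2, sig2), g2)
  expect_identical(nrow(d2), 2L)
  expect_identical(d2$chrom, c("a", "b"))

  expect_error(call_dmrs(mask_results(grid, sig)[1:5, ], grid), "aligned")
})

test_that("call_dmrs equals the run-length-encoding oracle on random masks", {
  set.seed(41)
  grid <- tile_genome(c(chr1 = 40000, chr2 = 25000), 1000)
  n1 <- 40L
  for (i in 1:200) {
    sig <- runif(65) < 0.25
    d <- call_dmrs(mask_results(grid, sig), grid)
    o1 <- oracle_rle_runs(sig[1:40])
    o2 <- oracle_rle_runs(sig[41:65])
    expect_identical(nrow(d), nrow(o1) + nrow(o2))
    expect_identical(d$first_window, c(o1$first, o2$first + n1))
    expect_identical(d$n_windows, as.integer(c(o1$n, o2$n)))
  }
})

test_that("maxLFC comes from the minimum-p window, ties to larger |lfc|", {
  grid <- tile_genome(c(chr1 = 3000), 1000)
  res <- mask_results(grid, c(TRUE, TRUE, TRUE), lfc = c(0.5, -2, 1))
  res$p_value <- c(1e-8, 1e-10, 1e-8)
  d <- call_dmrs(res, grid)
  expect_equal(d$maxLFC, -2)
  expect_identical(d$direction, "decrease")
  # tie on min p: the larger |lfc| wins
  res$p_value <- c(1e-10, 1e-10, 1e-8)
  expect_equal(call_dmrs(res, grid)$maxLFC, -2)
})

test_that("threshold_table counts are monotone in threshold tightness", {
  grid <- tile_genome(c(chr1 = 50000), 1000)
  res <- mask_results(grid, rep(FALSE, 50))
  # random p on alternating windows: runs cannot split, so DMR-count
  # monotonicity is guaranteed (a tightened threshold CAN split one
  # multi-window run into two DMRs, so the general claim is only about
  # significant-window counts; see the methods vignette)
  set.seed(47)
  res$p_value <- rep(1, 50)
  res$p_value[seq(1, 50, by = 2)] <- 10^runif(25, -9, 0)
  tt <- threshold_table(res, grid)
  expect_identical(tt$table$threshold, c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7))
  expect_true(all(diff(tt$table$n_dmrs) <= 0))
  expect_true(all(diff(tt$table$n_multiple_window) <= 0))
  # window-level monotonicity always holds, whatever the p landscape
  res$p_value <- 10^runif(50, -9, 0)
  n_sig <- vapply(tt$table$threshold,
                  function(th) sum(res$p_value < th), numeric(1))
  expect_true(all(diff(n_sig) <= 0))

  res$p_value <- rep(1, 50)
  tt0 <- threshold_table(res, grid)
  expect_true(all(tt0$table$n_dmrs == 0))
  expect_error(threshold_table(res, grid, thresholds = numeric(0)),
               "empty")
})

test_that("dmr_features computes CpG density bins from sequence", {
  grid <- tile_genome(c(c1 = 2000), 1000)
  # 20 CGs in the first kb, none in the second
  seq1 <- paste0(strrep("CGAAA", 20), strrep("A", 900),
                 strrep("T", 1000))
  res <- mask_results(grid, c(TRUE, TRUE), lfc = c(1, -1))
  res$p_value <- c(1e-8, 1e-9)
  d <- call_dmrs(res, grid)          # one 2-window DMR
  d1 <- dmr_features(d, c(c1 = seq1))
  expect_identical(d1$cpg_count, 20L)
  expect_equal(d1$cpg_density, 1)    # 20 per 2000 bp = 1 per 100 bp
  expect_identical(d1$cpg_density_bin, 1L)

  # density rounds half-up into bins, clamped to 1..10
  grid1 <- tile_genome(c(c1 = 1000), 1000)
  res1 <- mask_results(grid1, TRUE)
  dd <- call_dmrs(res1, grid1)
  rich <- paste0(strrep("CG", 100), strrep("A", 800))   # 10 per 100bp
  expect_identical(dmr_features(dd, c(c1 = rich))$cpg_density_bin, 10L)
  desert <- paste0("ACGT", strrep("A", 996))            # 0.1 per 100bp
  expect_identical(dmr_features(dd, c(c1 = desert))$cpg_density_bin, 1L)
  expect_error(dmr_features(dd, c(other = "A")), "missing sequence")
})

test_that("associate_genes applies strand-aware promoter bands", {
  grid <- tile_genome(c(chr1 = 100000), 1000)
  res <- mask_results(grid, c(rep(FALSE, 9), TRUE, rep(FALSE, 90)))
  d <- call_dmrs(res, grid)          # DMR at [9000,10000)
  genes <- data.frame(
    gene_id = c("inside", "prox_plus", "far", "minus_prox"),
    chrom = "chr1",
    start = c(9500, 10500, 50000, 2000),
    stop = c(20000, 12000, 60000, 8500),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  a <- associate_genes(d, genes)
  a <- a[order(a$gene_id), ]
  expect_identical(a$gene_id, c("inside", "minus_prox", "prox_plus"))
  expect_identical(a$category[a$gene_id == "inside"], "overlap")
  # DMR ends 500 bp before the + gene start -> proximal_1k
  expect_identical(a$category[a$gene_id == "prox_plus"], "proximal_1k")
  expect_equal(a$distance[a$gene_id == "prox_plus"], 501)
  # minus-strand gene with TSS at stop: DMR is upstream, gap 501
  expect_identical(a$category[a$gene_id == "minus_prox"], "proximal_1k")

  # no gene in range -> intergenic
  lonely <- call_dmrs(mask_results(grid, c(TRUE, rep(FALSE, 99))), grid)
  ai <- associate_genes(lonely, genes[genes$gene_id == "far", ])
  expect_identical(ai$category, "intergenic")
  expect_true(is.na(ai$gene_id))

  expect_error(associate_genes(d, transform(genes, strand = "?")),
               "strand")
})

test_that("associate_genes matches the all-pairs brute-force oracle", {
  set.seed(53)
  grid <- tile_genome(c(chr1 = 200000), 1000)
  for (rep_i in 1:25) {
    sig <- runif(200) < 0.05
    if (!any(sig)) next
    d <- call_dmrs(mask_results(grid, sig), grid)
    gs <- sort(sample.int(190000, 8))
    genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                        start = gs, stop = gs + sample(500:8000, 8, TRUE),
                        strand = sample(c("+", "-"), 8, TRUE),
                        stringsAsFactors = FALSE)
    a <- associate_genes(d, genes)
    for (i in seq_len(nrow(d))) {
      expected <- list()
      for (k in 1:8) {
        o <- oracle_gene_category(d$start[i], d$stop[i], genes$start[k],
                                  genes$stop[k], genes$strand[k])
        if (!is.null(o)) expected[[genes$gene_id[k]]] <- o
      }
      got <- a[a$dmr_id == d$dmr_id[i], ]
      if (length(expected) == 0) {
        expect_identical(got$category, "intergenic")
      } else {
        expect_setequal(got$gene_id, names(expected))
        for (g in got$gene_id) {
          expect_identical(got$category[got$gene_id == g],
                           expected[[g]]$category)
          expect_equal(got$distance[got$gene_id == g],
                       expected[[g]]$distance)
        }
      }
    }
  }
})

test_that("gene_set_overlap is the hypergeometric tail", {
  r0 <- gene_set_overlap(c("a", "b"), c("c", "d"), universe = 50)
  expect_identical(r0$overlap, 0L)
  expect_equal(r0$p_value, 1)

  rs <- gene_set_overlap(c("a", "b"), c("a", "b", "c"), universe = 50)
  expect_equal(rs$percent_overlap, 100 * 2 / 3)

  sub <- gene_set_overlap(c("a", "b"), letters[1:10], universe = 50)
  expect_identical(sub$overlap, 2L)

  # enumeration oracle on small universes
  set.seed(61)
  for (i in 1:30) {
    u <- sample(10:50, 1)
    pool <- sprintf("g%d", seq_len(u))
    gs <- sample(pool, sample(2:min(15, u), 1))
    dg <- sample(pool, sample(2:min(15, u), 1))
    r <- gene_set_overlap(dg, gs, u)
    expect_equal(r$p_value,
                 oracle_hyper_tail(r$overlap, length(gs), u, length(dg)),
                 tolerance = 1e-12)
  }
  expect_error(gene_set_overlap(letters[1:9], letters[1:5], universe = 6),
               "universe")
})
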