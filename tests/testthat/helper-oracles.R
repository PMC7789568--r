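# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route from the implementation it checks.

# Conditional exact test by direct enumeration of NB split probabilities,
# conditioning numerically on the total via dnbinom (any common p cancels).
oracle_exact_test <- function(s1, s2, n1, n2, r, p0 = 0.3) {
  s <- s1 + s2
  if (s == 0) return(1.0)
  a <- 0:s
  pa <- stats::dnbinom(a, size = n1 * r, prob = p0) *
    stats::dnbinom(s - a, size = n2 * r, prob = p0)
  pa <- pa / sum(pa)
  sum(pa[pa <= pa[s1 + 1] * (1 + 1e-12)])
}

# Conditional log-likelihood for two samples by enumerating all splits.
oracle_cll2 <- function(y, r, p0 = 0.4) {
  stopifnot(length(y) == 2)
  s <- sum(y)
  num <- stats::dnbinom(y[1], size = r, prob = p0) *
    stats::dnbinom(y[2], size = r, prob = p0)
  a <- 0:s
  den <- sum(stats::dnbinom(a, size = r, prob = p0) *
               stats::dnbinom(s - a, size = r, prob = p0))
  log(num / den)
}

# Naive character-scan CpG counter.
oracle_cpg_scan <- function(seq, start0, stop0) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- 0L
  i <- start0 + 1
  while (i <= stop0 - 1) {
    if (chars[i] == "C" && chars[i + 1] == "G") n <- n + 1L
    i <- i + 1
  }
  n
}

# Run-length-encoding DMR merge oracle on a significance mask (one chrom).
oracle_rle_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values],
             n = r$lengths[r$values])
}

# Brute-force DMR-gene category oracle; independently structured rule.
oracle_gene_category <- function(dstart, dstop, gstart, gstop, strand,
                                 max_dist = 10000) {
  overlaps <- !(dstop <= gstart || gstop <= dstart)
  if (overlaps) return(list(category = "overlap", distance = 0))
  if (strand == "+") {
    before_tss <- dstop <= gstart
    gap1 <- if (before_tss) gstart - dstop + 1 else dstart - gstop + 1
  } else {
    before_tss <- dstart >= gstop
    gap1 <- if (before_tss) dstart - gstop + 1 else gstart - dstop + 1
  }
  if (gap1 > max_dist) return(NULL)
  if (!before_tss) return(list(category = "downstream_10k", distance = gap1))
  cat <- if (gap1 <= 1000) "proximal_1k" else
    if (gap1 <= 5000) "proximal_5k" else "distal_10k"
  list(category = cat, distance = gap1)
}

# Hypergeometric upper tail via explicit choose() arithmetic.
oracle_hyper_tail <- function(overlap, m, universe, k) {
  xs <- max(0, m + k - universe):min(m, k)
  pmf <- choose(m, xs) * choose(universe - m, k - xs) / choose(universe, k)
  sum(pmf[xs >= overlap])
}

# Small simulated count matrix on a bare grid (no genome needed). Unless
# given, the planted-DMR count is scaled to the grid so packing stays
# feasible on tiny test genomes.
make_sim <- function(n_windows = 500, seed = 1, ...) {
  extra <- list(...)
  if (!"n_planted_dmrs" %in% names(extra)) {
    extra$n_planted_dmrs <- max(1L, n_windows %/% 40L)
  }
  cfg <- do.call(sim_config, c(list(n_chromosomes = 1,
                                    chrom_length = n_windows * 1000,
                                    seed = seed), extra))
  grid <- tile_genome(c(chr1 = cfg$chrom_length), cfg$window_size)
  planted <- plant_dmrs(grid, cfg)
  counts <- simulate_counts(grid, cfg, planted)
  list(cfg = cfg, grid = grid, planted = planted, counts = counts)
}
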