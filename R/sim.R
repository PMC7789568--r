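#' Simulation configuration
#'
#' Parameters of the synthetic MeDIP-seq world: a small genome tiled into
#' 1-kb windows, 13 case vs 13 control samples, negative-binomial (NB)
#' window counts with lognormal library-size variation, and a minority of
#' planted differentially methylated regions (DMRs), 62% of which decrease
#' methylation in cases.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome, bases.
#' @param window_size Window width, bases.
#' @param n_case,n_control Group sizes (13 vs 13 by default, matching the
#'   cohort design the generator emulates).
#' @param base_mean_depth Expected reads per window for an average sample
#'   at a baseline window (default 30; desk-scale depth giving high power
#'   at the default 2.5-fold planted effect).
#' @param baseline_cv Lognormal coefficient of variation of the per-window
#'   baseline mean `b(w)` (default 0.5; windows differ in MeDIP
#'   enrichability, so a flat baseline would be unrealistic and would make
#'   the low-count filter vacuous).
#' @param libsize_cv Lognormal CV of per-sample library-size factors
#'   (default 0.2).
#' @param dispersion NB dispersion `phi >= 0` (`var = mu + phi mu^2`);
#'   `phi = 0` gives Poisson counts.
#' @param n_planted_dmrs Number of planted DMRs.
#' @param planted_width_windows Named numeric vector of probabilities over
#'   widths in windows (names "1","2",...). Default heavily favors
#'   single-window DMRs, the dominant observed DMR length.
#' @param effect_fold Multiplicative effect (`>= 1`) applied to case means
#'   in planted windows, up or down.
#' @param frac_decrease Fraction of planted DMRs whose case methylation
#'   decreases (default 0.62, the observed decrease fraction).
#' @param background_cpg_rate Expected CpG dinucleotides per 100 bp of
#'   simulated sequence (default 2: a "CpG desert" context).
#' @param seed Integer seed; every simulation operation derives its own
#'   stream from it, so identical configs give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 1e6,
                       window_size = 1000, n_case = 13, n_control = 13,
                       base_mean_depth = 30, baseline_cv = 0.5,
                       libsize_cv = 0.2, dispersion = 0.1,
                       n_planted_dmrs = 50,
                       planted_width_windows = c("1" = 0.90, "2" = 0.08,
                                                 "3" = 0.02),
                       effect_fold = 2.5, frac_decrease = 0.62,
                       background_cpg_rate = 2, seed = 1L) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              window_size = window_size, n_case = n_case,
              n_control = n_control, base_mean_depth = base_mean_depth,
              baseline_cv = baseline_cv, libsize_cv = libsize_cv,
              dispersion = dispersion, n_planted_dmrs = n_planted_dmrs,
              planted_width_windows = planted_width_windows,
              effect_fold = effect_fold, frac_decrease = frac_decrease,
              background_cpg_rate = background_cpg_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (n_chromosomes < 1 || chrom_length <= 0 || window_size <= 0)
      stop("configuration error: genome dimensions must be positive")
    if (chrom_length < window_size)
      stop("configuration error: chrom_length < window_size")
    if (n_case < 0 || n_control < 0 || n_planted_dmrs < 0 ||
        base_mean_depth < 0)
      stop("configuration error: counts must be non-negative")
    if (dispersion < 0)
      stop("configuration error: dispersion must be >= 0")
    if (effect_fold < 1)
      stop("configuration error: effect_fold must be >= 1")
    if (frac_decrease < 0 || frac_decrease > 1)
      stop("configuration error: frac_decrease must be in [0,1]")
    if (background_cpg_rate < 0)
      stop("configuration error: background_cpg_rate must be >= 0")
    if (any(planted_width_windows < 0) || sum(planted_width_windows) <= 0)
      stop("configuration error: invalid width distribution")
  })
  cfg$planted_width_windows <-
    cfg$planted_width_windows / sum(cfg$planted_width_windows)
  class(cfg) <- "sim_config"
  cfg
}

# Derived, independent RNG streams per operation (all < 2^31).
sim_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

sim_chrom_names <- function(config) {
  paste0("chr", seq_len(config$n_chromosomes))
}

#' Simulate genome sequences
#'
#' Builds each chromosome from a renewal stream of tokens: with probability
#' `q = rate / (1 - rate)` (where `rate = background_cpg_rate / 100`) the
#' next token is a "CG" dinucleotide, otherwise a single base drawn
#' uniformly from A/C/G/T. Accidental C-followed-by-G adjacencies between
#' single-base tokens are rewritten away, so the only CG dinucleotides are
#' the injected tokens and the expected CG count is exactly
#' `chrom_length * rate`.
#'
#' @param config A [sim_config()].
#' @return Named character vector of uppercase A/C/G/T sequences.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chrom_length
  rate <- config$background_cpg_rate / 100
  if (rate >= 0.5) stop("configuration error: background_cpg_rate too high")
  q <- rate / (1 - rate)
  set.seed(sim_seed(config, 1L))
  alphabet <- c("A", "C", "G", "T")     # integer codes 1..4
  out <- list()
  for (ch in sim_chrom_names(config)) {
    # L tokens always cover >= L bases (each token is 1 or 2 bases)
    is_cg <- stats::runif(L) < q
    starts <- cumsum(c(1L, 1L + is_cg))[seq_len(L)]
    code <- integer(starts[L] + 1L)
    code[starts[is_cg]] <- 2L           # C
    code[starts[is_cg] + 1L] <- 3L      # G
    code[starts[!is_cg]] <- sample.int(4L, sum(!is_cg), replace = TRUE)
    code <- code[seq_len(L)]
    code[code == 0L] <- 1L              # truncated trailing CG token
    injected <- starts[is_cg]           # injected C positions (1-based)
    injected <- injected[injected <= L - 1L]
    if (L >= 2) {
      acc <- which(code[-L] == 2L & code[-1] == 3L)
      if (length(injected) > 0) acc <- setdiff(acc, injected)
      while (length(acc) > 0) {
        code[acc + 1L] <- c(1L, 2L, 4L)[sample.int(3L, length(acc),
                                                   replace = TRUE)]
        # only a rewritten position can start a new C-G pair
        cand <- acc[acc <= L - 2L] + 1L
        acc <- cand[code[cand] == 2L & code[cand + 1L] == 3L]
      }
    }
    out[[ch]] <- paste(alphabet[code], collapse = "")
  }
  unlist(out)
}

#' Plant ground-truth DMRs on a window grid
#'
#' Places `n_planted_dmrs` mutually non-adjacent runs of windows (so merging
#' significant windows downstream recovers exactly the planted regions),
#' with widths drawn from `planted_width_windows` and direction `decrease`
#' with probability `frac_decrease`.
#'
#' @param grid A [tile_genome()] grid.
#' @param config A [sim_config()].
#' @return A data.frame (class `planted_dmrs`) with one row per planted DMR:
#'   `chrom`, `first_window`, `last_window` (grid row indices), `width`,
#'   `direction`, `fold`.
#' @export
plant_dmrs <- function(grid, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_planted_dmrs
  widths <- as.integer(names(config$planted_width_windows))
  set.seed(sim_seed(config, 2L))
  empty <- data.frame(chrom = character(), first_window = integer(),
                      last_window = integer(), width = integer(),
                      direction = character(), fold = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("planted_dmrs", "data.frame")
  if (n == 0) return(empty)
  if (n * (max(widths) + 1) > nrow(grid) / 2) {
    stop("infeasible packing: n_planted_dmrs x max width too large for grid")
  }
  occupied <- rep(FALSE, nrow(grid))      # planted windows + 1-window buffer
  rows <- vector("list", n)
  tries <- 0L
  placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("infeasible packing: could not place non-adjacent DMR runs")
    }
    w <- sample(widths, 1, prob = config$planted_width_windows)
    i <- sample.int(nrow(grid) - w + 1L, 1)
    span <- i:(i + w - 1L)
    if (length(unique(grid$chrom[span])) != 1L) next
    guard <- max(1L, i - 1L):min(nrow(grid), i + w)
    if (any(occupied[guard])) next
    occupied[guard] <- TRUE
    placed <- placed + 1L
    rows[[placed]] <- data.frame(chrom = grid$chrom[i], first_window = i,
                                 last_window = i + w - 1L, width = w,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$first_window), , drop = FALSE]
  out$direction <- ifelse(stats::runif(n) < config$frac_decrease,
                          "decrease", "increase")
  out$fold <- config$effect_fold
  rownames(out) <- NULL
  class(out) <- c("planted_dmrs", "data.frame")
  out
}

#' Simulate a negative-binomial count matrix
#'
#' Counts `Y(w, j) ~ NB(mu(w, j), phi)` with
#' `mu(w, j) = b(w) * f(j) * e(w, j)`, where `b(w)` is a lognormal
#' per-window baseline with mean `base_mean_depth` and CV `baseline_cv`,
#' `f(j)` a lognormal library-size factor with mean 1 and CV `libsize_cv`,
#' and `e(w, j)` equals `effect_fold` (or its reciprocal, per the planted
#' direction) when sample `j` is a case and window `w` is planted, else 1.
#' Recorded library sizes are the realized column sums.
#'
#' @param grid A window grid.
#' @param config A [sim_config()].
#' @param planted Output of [plant_dmrs()] on the same grid.
#' @param baseline Optional per-window baseline means `b(w)`; pass the same
#'   vector when simulating several batches (e.g. training and blinded
#'   samples) of one assay — the baseline is a property of the windows, not
#'   of the batch. Default: drawn from the config
#'   (see [simulate_window_baseline()]).
#' @return A [count_matrix()] with samples `case_1..n`, `control_1..n`.
#' @export
simulate_counts <- function(grid, config, planted = NULL, baseline = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) stop("configuration error: negative dispersion")
  nw <- nrow(grid)
  n1 <- config$n_case
  n2 <- config$n_control
  if (is.null(baseline)) baseline <- simulate_window_baseline(grid, config)
  if (length(baseline) != nw) stop("baseline must have one value per window")
  b <- baseline
  set.seed(sim_seed(config, 3L))
  f <- rlnorm_mean_cv(n1 + n2, 1, config$libsize_cv)
  eff <- matrix(1, nrow = nw, ncol = n1 + n2)
  if (!is.null(planted) && nrow(planted) > 0) {
    if (max(planted$last_window) > nw) {
      stop("planted DMRs refer to windows outside the grid")
    }
    for (k in seq_len(nrow(planted))) {
      span <- planted$first_window[k]:planted$last_window[k]
      fk <- if (planted$direction[k] == "decrease") 1 / planted$fold[k]
            else planted$fold[k]
      eff[span, seq_len(n1)] <- fk
    }
  }
  mu <- (b * eff) * rep(f, each = nw)
  y <- if (config$dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts <- matrix(as.integer(y), nrow = nw,
                   dimnames = list(grid$window,
                                   c(sprintf("case_%d", seq_len(n1)),
                                     sprintf("control_%d", seq_len(n2)))))
  samples <- data.frame(sample_id = colnames(counts),
                        group = rep(c("case", "control"), c(n1, n2)),
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

#' Draw the per-window baseline means of the count model
#'
#' Lognormal `b(w)` with mean `base_mean_depth` and CV `baseline_cv`,
#' deterministic for a fixed config seed. Exposed so that several simulated
#' batches can share one baseline.
#'
#' @param grid A window grid.
#' @param config A [sim_config()].
#' @return Numeric vector, one expected depth per window.
#' @export
simulate_window_baseline <- function(grid, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, 6L))
  rlnorm_mean_cv(nrow(grid), config$base_mean_depth, config$baseline_cv)
}

# lognormal with given mean and coefficient of variation; cv = 0 degenerates
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate read intervals realizing a count matrix
#'
#' Emits, for each (window, sample), exactly `count` intervals of length
#' `read_length` whose midpoints lie inside the window, so that
#' [count_reads()] on the output reproduces the input matrix exactly.
#' Reads near chromosome ends are shifted or shortened so coordinates stay
#' within the chromosome without moving the midpoint out of its window.
#'
#' @param counts A `count_matrix`.
#' @param grid The grid the counts refer to.
#' @param read_length Read length in bases; must not exceed the window size.
#' @param seed Integer seed.
#' @return Data.frame with `chrom`, `start`, `stop`, `sample_id`.
#' @export
simulate_reads <- function(counts, grid, read_length = 100, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  ws <- grid_window_size(grid)
  if (read_length > ws) stop("read_length > window_size")
  if (read_length < 1) stop("read_length must be positive")
  set.seed(seed)
  chrom_len <- tapply(grid$stop, grid$chrom, max)
  half <- floor(read_length / 2)
  pieces <- list()
  for (j in seq_len(ncol(counts$counts))) {
    cj <- counts$counts[, j]
    idx <- rep(which(cj > 0), cj[cj > 0])
    if (length(idx) == 0) next
    wstart <- grid$start[idx]
    wstop <- grid$stop[idx]
    L <- as.numeric(chrom_len[grid$chrom[idx]])
    lo <- pmax(wstart, half)
    hi <- pmin(wstop - 1, L - read_length + half)
    bad <- hi < lo                        # window too close to a chrom end
    hi[bad] <- lo[bad]                    # placeholder; overwritten below
    mid <- lo + floor(stats::runif(length(idx)) * (hi - lo + 1))
    start <- mid - half
    stop_ <- start + read_length
    # anchor the read at the window start, clipped to the chromosome; the
    # clipped read's midpoint still falls inside its window
    start[bad] <- wstart[bad]
    stop_[bad] <- pmin(wstart[bad] + read_length, L[bad])
    pieces[[length(pieces) + 1]] <-
      data.frame(chrom = grid$chrom[idx], start = start, stop = stop_,
                 sample_id = colnames(counts$counts)[j],
                 stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: genome, grid (with CpG counts), planted DMRs and
#' count matrix from one configuration. Optionally also simulates blinded
#' samples drawn from the case/control generators.
#'
#' @param config A [sim_config()].
#' @param n_blinded_case,n_blinded_control Numbers of extra blinded samples
#'   generated from the case / control models (default 0).
#' @return List with `config`, `genome`, `grid`, `planted`, `counts`, and —
#'   when blinded samples were requested — `blinded_counts` plus
#'   `blinded_truth` (their generating group).
#' @export
simulate_dataset <- function(config = sim_config(), n_blinded_case = 0,
                             n_blinded_control = 0) {
  genome <- simulate_genome(config)
  grid <- tile_genome(vapply(genome, nchar, numeric(1)),
                      config$window_size)
  grid <- add_cpg_counts(grid, genome)
  planted <- plant_dmrs(grid, config)
  baseline <- simulate_window_baseline(grid, config)
  counts <- simulate_counts(grid, config, planted, baseline = baseline)
  out <- list(config = config, genome = genome, grid = grid,
              planted = planted, counts = counts)
  if (n_blinded_case + n_blinded_control > 0) {
    bc <- config
    bc$n_case <- n_blinded_case
    bc$n_control <- n_blinded_control
    bc$seed <- sim_seed(config, 7L) %% 2147483647L
    class(bc) <- "sim_config"
    bcounts <- simulate_counts(grid, bc, planted, baseline = baseline)
    truth <- bcounts$samples$group
    colnames(bcounts$counts) <- sprintf("blinded_%d",
                                        seq_len(ncol(bcounts$counts)))
    samples <- data.frame(sample_id = colnames(bcounts$counts),
                          group = "blinded", stringsAsFactors = FALSE)
    out$blinded_counts <- count_matrix(bcounts$counts, samples)
    out$blinded_truth <- stats::setNames(truth, samples$sample_id)
  }
  out
}
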