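#' Tile chromosomes into fixed-size windows
#'
#' Tiles each chromosome into contiguous, non-overlapping windows of
#' `window_size` bases using 0-based half-open coordinates (BED convention).
#' A trailing partial window is retained with its true length; its true
#' length (not `window_size`) is used wherever a window length matters,
#' e.g. in [rpkm()].
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param window_size Window width in bases (default 1000, the 1-kb windows
#'   used throughout the pipeline).
#' @return A `window_grid`: a data.frame with columns `chrom`, `start`,
#'   `stop` and `window` (the label `"chrom:start-stop"`), ordered by
#'   chromosome (input order) then start, with attribute `window_size`.
#' @examples
#' g <- tile_genome(c(chr1 = 5400), 1000)
#' nrow(g)            # 6 windows, last one [5000,5400)
#' @export
tile_genome <- function(chrom_lengths, window_size = 1000) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector of chromosome lengths")
  }
  if (any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (length(window_size) != 1L || window_size <= 0) {
    stop("window_size must be a single positive number")
  }
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               stop = pmin(starts + window_size, L),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid$window <- window_label(grid$chrom, grid$start, grid$stop)
  rownames(grid) <- NULL
  attr(grid, "window_size") <- window_size
  class(grid) <- c("window_grid", "data.frame")
  grid
}

window_label <- function(chrom, start, stop) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(stop))
}

grid_window_size <- function(grid) {
  ws <- attr(grid, "window_size")
  if (is.null(ws)) stop("grid has no window_size attribute")
  ws
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %d bp over %d chromosome(s)\n",
              nrow(x), as.integer(grid_window_size(x)),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Count aligned-read intervals per window per sample
#'
#' Each read is assigned to exactly one window: the window containing its
#' midpoint `floor((start + stop) / 2)`. Reads on chromosomes absent from
#' the grid, or whose midpoint falls beyond the tiled length, are counted
#' as skipped and reported via the `skipped` attribute; assigned + skipped
#' always equals the input total per sample.
#'
#' @param reads A data.frame of read intervals with columns `chrom`,
#'   `start`, `stop` (0-based half-open) and `sample_id`.
#' @param grid A [tile_genome()] window grid.
#' @param samples Optional sample sheet (data.frame with `sample_id`,
#'   `group`); defaults to the samples present in `reads`, group "blinded".
#' @return A `count_matrix`: list with `counts` (integer matrix, windows x
#'   samples, rownames = window labels) and `samples` (data.frame with
#'   `sample_id`, `group`, `library_size` = column sum of counted reads).
#' @export
count_reads <- function(reads, grid, samples = NULL) {
  needed <- c("chrom", "start", "stop", "sample_id")
  if (!all(needed %in% names(reads))) {
    stop("reads must have columns chrom, start, stop, sample_id")
  }
  bad <- which(reads$stop <= reads$start)
  if (length(bad) > 0) {
    stop(sprintf("malformed interval (stop <= start) at read record %d",
                 bad[1]))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = unique(as.character(reads$sample_id)),
                          group = "blinded", stringsAsFactors = FALSE)
  }
  ws <- grid_window_size(grid)
  chroms <- unique(grid$chrom)
  # windows per chromosome and offset of each chromosome's first grid row
  nwin <- vapply(chroms, function(ch) sum(grid$chrom == ch), integer(1))
  offset <- stats::setNames(cumsum(c(0L, nwin[-length(nwin)])), chroms)

  mid <- floor((reads$start + reads$stop) / 2)
  known <- as.character(reads$chrom) %in% chroms
  widx <- rep(NA_integer_, nrow(reads))
  if (any(known)) {
    ch <- as.character(reads$chrom)[known]
    within <- mid[known] %/% ws + 1L
    ok <- within <= nwin[ch] & mid[known] >= 0
    widx[known][ok] <- offset[ch][ok] + within[ok]
  }
  sample_ids <- as.character(samples$sample_id)
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(sample_ids),
                   dimnames = list(grid$window, sample_ids))
  keep <- !is.na(widx) & as.character(reads$sample_id) %in% sample_ids
  if (any(keep)) {
    tab <- table(factor(widx[keep], levels = seq_len(nrow(grid))),
                 factor(as.character(reads$sample_id)[keep],
                        levels = sample_ids))
    counts <- matrix(as.integer(tab), nrow = nrow(grid),
                     dimnames = list(grid$window, sample_ids))
  }
  skipped <- table(factor(as.character(reads$sample_id)[!keep |
                                                          is.na(widx)],
                          levels = sample_ids))
  out <- count_matrix(counts, samples)
  attr(out, "skipped") <- stats::setNames(as.integer(skipped), sample_ids)
  out
}

#' Construct a count matrix container
#'
#' @param counts Integer matrix, windows in rows (rownames = window labels),
#'   samples in columns.
#' @param samples Data.frame with `sample_id` and `group` (one of `"case"`,
#'   `"control"`, `"blinded"`). Library sizes are recorded as the realized
#'   column sums.
#' @return A `count_matrix` (list with elements `counts`, `samples`).
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("samples must have columns sample_id and group")
  }
  if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
  if (!all(samples$group %in% c("case", "control", "blinded"))) {
    stop("group must be one of case, control, blinded")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    stop("every counts column must appear in the sample sheet")
  }
  samples$library_size <- as.numeric(colSums(counts))
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d windows x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm(w, j) = count(w, j) / ((len(w)/1000) * (N(j)/1e6))` with `N(j)` the
#' sample's library size and `len(w)` the true window length (trailing
#' partial windows use their real length).
#'
#' @param counts A `count_matrix`.
#' @param grid The window grid the counts were made on.
#' @return Numeric matrix of the same shape as `counts$counts`.
#' @export
rpkm <- function(counts, grid) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!identical(rownames(counts$counts), grid$window)) {
    stop("counts rows are not aligned to the grid")
  }
  N <- counts$samples$library_size
  if (any(N <= 0)) {
    stop(sprintf("zero library size for sample %s",
                 counts$samples$sample_id[which(N <= 0)[1]]))
  }
  len_kb <- (grid$stop - grid$start) / 1000
  sweep(counts$counts / len_kb, 2, N / 1e6, "/")
}

#' Count CpG dinucleotides in an interval
#'
#' Number of `"CG"` dinucleotides (case-insensitive) lying fully inside the
#' 0-based half-open interval. `"CG"` is its own reverse complement, so a
#' single-strand count covers both strands.
#'
#' @param sequence A character string or `Biostrings::DNAString`.
#' @param interval Length-2 numeric `c(start, stop)`, 0-based half-open;
#'   default the whole sequence.
#' @return Integer count.
#' @export
cpg_count <- function(sequence, interval = NULL) {
  if (inherits(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  L <- nchar(sequence)
  if (is.null(interval)) interval <- c(0, L)
  if (interval[1] < 0 || interval[2] > L || interval[1] >= interval[2]) {
    stop("interval out of sequence bounds")
  }
  sub <- substr(sequence, interval[1] + 1, interval[2])
  as.integer(Biostrings::countPattern(
    "CG", Biostrings::DNAString(toupper(sub))))
}

#' Attach per-window CpG counts to a grid
#'
#' Counts `"CG"` dinucleotides fully inside each window. A CpG straddling a
#' window boundary belongs to no window.
#'
#' @param grid A window grid.
#' @param genome Named list/`DNAStringSet` of chromosome sequences covering
#'   the grid's chromosomes.
#' @return The grid with an added integer `cpg` column.
#' @export
add_cpg_counts <- function(grid, genome) {
  ws <- grid_window_size(grid)
  cls <- class(grid)
  grid <- as.data.frame(grid)
  grid$cpg <- 0L
  for (ch in unique(grid$chrom)) {
    if (!ch %in% names(genome)) stop(sprintf("missing sequence for %s", ch))
    seq <- genome[[ch]]
    if (!inherits(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(as.character(seq)))
    rows <- which(grid$chrom == ch)
    m <- Biostrings::matchPattern("CG", seq)
    s0 <- Biostrings::start(m) - 1L          # 0-based CpG start
    if (length(s0) > 0) {
      idx <- s0 %/% ws + 1L                  # window ordinal within chrom
      wstop <- grid$stop[rows][idx]
      keep <- (s0 + 2) <= wstop              # fully inside its window
      tab <- tabulate(idx[keep], nbins = length(rows))
      grid$cpg[rows] <- as.integer(tab)
    }
  }
  attr(grid, "window_size") <- ws
  class(grid) <- cls
  grid
}
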