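#' Write / read a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read reads as 6-column BED
#'
#' BED6 with the sample id in the name field (score 0, strand "."),
#' multiplexing all samples into one file.
#'
#' @param reads Data.frame with `chrom`, `start`, `stop`, `sample_id`.
#' @param path File path.
#' @export
write_reads_bed <- function(reads, path) {
  bed <- data.frame(reads$chrom, as.integer(reads$start),
                    as.integer(reads$stop), reads$sample_id, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least 3 columns")
  data.frame(chrom = bed[[1]], start = bed[[2]], stop = bed[[3]],
             sample_id = if (ncol(bed) >= 4) bed[[4]] else "sample_1",
             stringsAsFactors = FALSE)
}

#' Write / read a window count matrix as TSV
#'
#' Rows are windows labeled `"chrom:start-stop"`, columns are sample ids.
#' Reading requires a sample sheet to restore group labels.
#'
#' @param counts A [count_matrix()].
#' @param path File path.
#' @param samples Sample sheet data.frame (`sample_id`, `group`) for
#'   `read_counts_tsv`.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  d <- data.frame(window = rownames(counts$counts), counts$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, samples) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$window
  count_matrix(m, samples)
}

#' Write / read the sample sheet
#'
#' @param samples Data.frame with `sample_id` and `group`.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d))) {
    stop("sample sheet must have columns sample_id and group")
  }
  d
}

#' Reconstruct a window grid from count-matrix window labels
#'
#' Parses `"chrom:start-stop"` labels back into a grid (window size taken
#' from the first full window). Used by the CLI `test` entry point, which
#' consumes a counts TSV without the genome.
#'
#' @param labels Character vector of window labels in grid order.
#' @return A `window_grid`.
#' @export
grid_from_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop(sprintf("malformed window label: %s",
                             labels[which(bad)[1]]))
  grid <- data.frame(chrom = vapply(m, `[`, "", 2),
                     start = as.numeric(vapply(m, `[`, "", 3)),
                     stop = as.numeric(vapply(m, `[`, "", 4)),
                     window = labels, stringsAsFactors = FALSE)
  attr(grid, "window_size") <- max(grid$stop - grid$start)
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Write DMRs as BED6 and as a feature table
#'
#' @param dmrs A `dmr_set`.
#' @param path File path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  stopifnot(inherits(dmrs, "dmr_set"))
  bed <- data.frame(dmrs$chrom, as.integer(dmrs$start),
                    as.integer(dmrs$stop), dmrs$dmr_id, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
write_dmr_table <- function(dmrs, path) {
  utils::write.table(as.data.frame(dmrs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from BED6
#'
#' Name field = gene id; strand required.
#'
#' @param path BED6 file path.
#' @return Data.frame `gene_id`, `chrom`, `start`, `stop`, `strand`.
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("gene annotation must be BED6 (strand required)")
  data.frame(gene_id = bed[[4]], chrom = bed[[1]], start = bed[[2]],
             stop = bed[[3]], strand = bed[[6]], stringsAsFactors = FALSE)
}

#' Write the per-window test results as TSV
#'
#' @param results A [test_all()] result.
#' @param grid The window grid (for coordinates).
#' @param path File path.
#' @export
write_results_tsv <- function(results, grid, path) {
  d <- data.frame(chrom = grid$chrom, start = as.integer(grid$start),
                  stop = as.integer(grid$stop),
                  as.data.frame(results)[, c("s1", "s2", "lfc", "p_value",
                                             "q_value", "flag")],
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
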