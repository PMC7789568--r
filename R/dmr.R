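#' Call DMRs by merging adjacent significant windows
#'
#' Windows with `p < p_threshold` are marked significant; maximal runs of
#' consecutive significant windows on the same chromosome become one DMR
#' whose interval is the union of its member windows (no flank extension).
#' `maxLFC` is the fold change of the minimum-p member window (ties broken
#' toward the larger `|lfc|`), and direction is its sign.
#'
#' @param results A [test_all()] result aligned to `grid`.
#' @param grid The window grid the results were computed on.
#' @param p_threshold Significance threshold on the raw p-value (default
#'   1e-5, the working threshold of the pipeline).
#' @return A `dmr_set` data.frame: `dmr_id`, `chrom`, `start`, `stop`,
#'   `n_windows`, `min_p`, `all_q_below_05`, `maxLFC`, `direction`,
#'   `length_kb`, plus `first_window`/`last_window` grid row indices.
#' @export
call_dmrs <- function(results, grid, p_threshold = 1e-5) {
  if (nrow(results) != nrow(grid) ||
      !identical(results$window, grid$window)) {
    stop("results are not aligned to the grid")
  }
  sig <- which(results$p_value < p_threshold)
  empty <- data.frame(dmr_id = character(), chrom = character(),
                      start = numeric(), stop = numeric(),
                      n_windows = integer(), min_p = numeric(),
                      all_q_below_05 = logical(), maxLFC = numeric(),
                      direction = character(), length_kb = numeric(),
                      first_window = integer(), last_window = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("dmr_set", "data.frame")
  attr(empty, "p_threshold") <- p_threshold
  if (length(sig) == 0) return(empty)
  # break runs at non-consecutive grid indices or chromosome changes
  new_run <- c(TRUE, diff(sig) != 1 |
                 grid$chrom[sig[-1]] != grid$chrom[sig[-length(sig)]])
  run_id <- cumsum(new_run)
  rows <- lapply(split(sig, run_id), function(span) {
    r <- results[span, , drop = FALSE]
    best <- which(r$p_value == min(r$p_value))
    if (length(best) > 1) best <- best[which.max(abs(r$lfc[best]))]
    data.frame(chrom = grid$chrom[span[1]],
               start = grid$start[span[1]],
               stop = grid$stop[span[length(span)]],
               n_windows = length(span),
               min_p = min(r$p_value),
               all_q_below_05 = all(r$q_value < 0.05),
               maxLFC = r$lfc[best],
               direction = if (r$lfc[best] < 0) "decrease" else "increase",
               first_window = span[1],
               last_window = span[length(span)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$length_kb <- (out$stop - out$start) / 1000
  out <- cbind(dmr_id = sprintf("DMR%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  attr(out, "p_threshold") <- p_threshold
  out
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set: %d DMRs at p < %g (%d multi-window)\n",
              nrow(x), attr(x, "p_threshold"),
              sum(x$n_windows >= 2)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' DMR counts across p-value thresholds
#'
#' Repeats [call_dmrs()] at each threshold and reports the all-window and
#' multiple-window DMR counts, plus the histogram of DMRs by number of
#' significant windows at the working threshold. The significant-window
#' count is always monotone non-increasing as the threshold tightens; the
#' DMR count almost always is, but can tick up when tightening splits one
#' multi-window run into two regions (interior window losing significance).
#'
#' @param results,grid As for [call_dmrs()].
#' @param thresholds Vector of thresholds (default `1e-3` .. `1e-7`).
#' @param working Working threshold for the per-size histogram.
#' @return List with `table` (data.frame `threshold`, `n_dmrs`,
#'   `n_multiple_window`) and `window_histogram` (named vector).
#' @export
threshold_table <- function(results, grid,
                            thresholds = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                            working = 1e-5) {
  if (length(thresholds) == 0) stop("empty threshold list")
  thresholds <- sort(thresholds, decreasing = TRUE)
  tab <- do.call(rbind, lapply(thresholds, function(th) {
    d <- call_dmrs(results, grid, th)
    data.frame(threshold = th, n_dmrs = nrow(d),
               n_multiple_window = sum(d$n_windows >= 2))
  }))
  dw <- call_dmrs(results, grid, working)
  hist <- if (nrow(dw) == 0) integer(0) else table(dw$n_windows)
  list(table = tab, window_histogram = hist, working = working)
}

#' Attach sequence-derived features to DMRs
#'
#' Adds CpG count, CpG density (per 100 bp) and the clamped 1..10+ density
#' bin used for the density histogram; densities below 0.5 fall in bin 1
#' (there is no zero bin), densities of 10 or more in bin 10.
#'
#' @param dmrs A [call_dmrs()] result.
#' @param genome Named sequences covering the DMR intervals.
#' @return The `dmr_set` with added `cpg_count`, `cpg_density`,
#'   `cpg_density_bin` columns.
#' @export
dmr_features <- function(dmrs, genome) {
  stopifnot(inherits(dmrs, "dmr_set"))
  if (nrow(dmrs) == 0) {
    dmrs$cpg_count <- integer(0)
    dmrs$cpg_density <- numeric(0)
    dmrs$cpg_density_bin <- integer(0)
    return(dmrs)
  }
  cpg <- integer(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    ch <- dmrs$chrom[i]
    if (!ch %in% names(genome)) {
      stop(sprintf("missing sequence for %s", ch))
    }
    cpg[i] <- cpg_count(genome[[ch]], c(dmrs$start[i], dmrs$stop[i]))
  }
  dens <- 100 * cpg / (dmrs$stop - dmrs$start)
  dmrs$cpg_count <- cpg
  dmrs$cpg_density <- dens
  dmrs$cpg_density_bin <- pmin(pmax(as.integer(floor(dens + 0.5)), 1L), 10L)
  dmrs
}

#' Associate genes within a distance of each DMR
#'
#' For every (DMR, gene) pair within `max_dist`: `"overlap"` when the
#' intervals intersect; otherwise, when the DMR lies upstream of the gene's
#' TSS (strand-aware), the 1-based end-to-TSS gap assigns `"proximal_1k"`
#' (1-1000 bp), `"proximal_5k"` (1001-5000) or `"distal_10k"` (5001-10000);
#' non-upstream neighbours within range are `"downstream_10k"`. DMRs with
#' no gene in range get a single `"intergenic"` row.
#'
#' @param dmrs A `dmr_set`.
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `stop`,
#'   `strand` (`"+"`/`"-"`), 0-based half-open.
#' @param max_dist Maximum 1-based gap, default 10000.
#' @return Data.frame with one row per association: `dmr_id`, `gene_id`,
#'   `category`, `distance` (1-based gap; 0 for overlap, NA for
#'   intergenic).
#' @export
associate_genes <- function(dmrs, genes, max_dist = 10000) {
  stopifnot(inherits(dmrs, "dmr_set"))
  needed <- c("gene_id", "chrom", "start", "stop", "strand")
  if (!all(needed %in% names(genes))) {
    stop("genes must have columns gene_id, chrom, start, stop, strand")
  }
  if (any(genes$start >= genes$stop)) stop("gene start must be < stop")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("unknown strand for gene %s", genes$gene_id[which(bad)[1]]))
  }
  out <- vector("list", nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    rows <- NULL
    for (k in seq_len(nrow(g))) {
      cat_dist <- classify_dmr_gene(dmrs$start[i], dmrs$stop[i],
                                    g$start[k], g$stop[k], g$strand[k],
                                    max_dist)
      if (!is.null(cat_dist)) {
        rows <- rbind(rows, data.frame(dmr_id = dmrs$dmr_id[i],
                                       gene_id = g$gene_id[k],
                                       category = cat_dist$category,
                                       distance = cat_dist$distance,
                                       stringsAsFactors = FALSE))
      }
    }
    if (is.null(rows)) {
      rows <- data.frame(dmr_id = dmrs$dmr_id[i], gene_id = NA_character_,
                         category = "intergenic", distance = NA_real_,
                         stringsAsFactors = FALSE)
    }
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(dmr_id = character(), gene_id = character(),
                      category = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# category + distance for one DMR/gene pair, or NULL when out of range
classify_dmr_gene <- function(dstart, dstop, gstart, gstop, strand,
                              max_dist) {
  if (dstart < gstop && gstart < dstop) {
    return(list(category = "overlap", distance = 0))
  }
  upstream_gap <- if (strand == "+") gstart - dstop else dstart - gstop
  if (upstream_gap >= 0) {
    d <- upstream_gap + 1              # 1-based end-to-TSS gap
    if (d > max_dist) return(NULL)
    cat <- if (d <= 1000) "proximal_1k"
           else if (d <= 5000) "proximal_5k"
           else "distal_10k"
    return(list(category = cat, distance = d))
  }
  gap <- max(dstart - gstop, gstart - dstop) + 1
  if (gap > max_dist) return(NULL)
  list(category = "downstream_10k", distance = gap)
}

#' Hypergeometric gene-set overlap test
#'
#' Tests whether the DMR-associated genes over-represent a user-supplied
#' gene set, against a declared gene universe:
#' `P[X >= overlap]` for `X ~ Hypergeometric(set size, universe - set size,
#' |dmr genes|)`.
#'
#' @param dmr_genes Character vector of DMR-associated gene ids.
#' @param gene_set Character vector; the set to test.
#' @param universe Size of the declared gene universe both sets are drawn
#'   from.
#' @return List: `overlap`, `percent_overlap` (of the gene set), `p_value`.
#' @export
gene_set_overlap <- function(dmr_genes, gene_set, universe) {
  dmr_genes <- unique(dmr_genes[!is.na(dmr_genes)])
  gene_set <- unique(gene_set)
  m <- length(gene_set)
  k <- length(dmr_genes)
  if (m > universe || k > universe) {
    stop("universe mismatch: a set is larger than the declared universe")
  }
  ov <- length(intersect(dmr_genes, gene_set))
  if (ov > min(m, k)) stop("impossible overlap; universe mismatch")
  p <- stats::phyper(ov - 1, m, universe - m, k, lower.tail = FALSE)
  list(overlap = ov,
       percent_overlap = if (m == 0) NA_real_ else 100 * ov / m,
       p_value = min(max(p, 0), 1))
}
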