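#' Fit a 2-component PCA model on DMR RPKM
#'
#' Centers each DMR (row) by its training mean — no unit-variance scaling —
#' and extracts the first two right-singular vectors of the centered
#' samples-by-DMRs matrix. Group centroids are the per-group means of the
#' projected labeled training samples.
#'
#' @param x Numeric matrix of RPKM, DMRs in rows, samples in columns.
#' @param groups Group label per column (`"case"` / `"control"`).
#' @return A `pca_model`: `dmr_ids`, `center` (per-DMR means), `rotation`
#'   (DMRs x 2, orthonormal), `explained` (variance fractions),
#'   `centroids` (2 x 2, rows case/control), `scores` (training
#'   projections).
#' @export
pca_fit <- function(x, groups) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 DMRs for a 2-component model")
  if (length(groups) != ncol(x)) stop("groups must label every column")
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    stop("need >= 2 labeled samples per group")
  }
  center <- rowMeans(x)
  xc <- t(x - center)                    # samples x DMRs, column-centered
  sv <- svd(xc, nu = 0, nv = 2)
  rotation <- sv$v
  rownames(rotation) <- rownames(x)
  colnames(rotation) <- c("PC1", "PC2")
  scores <- xc %*% rotation
  rownames(scores) <- colnames(x)
  ev <- sv$d^2
  centroids <- rbind(case = colMeans(scores[groups == "case", , drop = FALSE]),
                     control = colMeans(scores[groups == "control", ,
                                               drop = FALSE]))
  structure(list(dmr_ids = rownames(x), center = center,
                 rotation = rotation,
                 explained = ev[1:2] / sum(ev),
                 centroids = centroids, scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d DMRs, PC1/PC2 explain %.1f%% / %.1f%%\n",
              length(x$dmr_ids), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Nearest-centroid classification in PCA space
#'
#' Centers new samples with the model's per-DMR means, projects onto the
#' two stored components, and predicts the group with the nearer centroid
#' (Euclidean); an exact tie gives `"unclassified"`.
#'
#' @param model A [pca_fit()] model.
#' @param x Numeric vector (one sample, aligned to the model's DMR list) or
#'   matrix (DMRs x samples).
#' @return Data.frame with `sample_id`, `predicted`, `d_case`, `d_control`,
#'   `PC1`, `PC2`.
#' @export
classify_samples <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (is.vector(x)) x <- matrix(x, ncol = 1,
                                dimnames = list(names(x), "sample"))
  if (nrow(x) != length(model$dmr_ids)) {
    stop("sample vector length does not match the model's DMR list")
  }
  scores <- t(x - model$center) %*% model$rotation
  d1 <- sqrt(rowSums(sweep(scores, 2, model$centroids["case", ])^2))
  d2 <- sqrt(rowSums(sweep(scores, 2, model$centroids["control", ])^2))
  pred <- ifelse(d1 < d2, "case", ifelse(d2 < d1, "control", "unclassified"))
  data.frame(sample_id = colnames(x) %||% sprintf("S%d", seq_len(ncol(x))),
             predicted = pred, d_case = d1, d_control = d2,
             PC1 = scores[, 1], PC2 = scores[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove batch-outlier DMRs before blinded classification
#'
#' Drops any DMR for which some blinded sample's RPKM lies outside the
#' training `mean +/- k * SD` band of **both** groups simultaneously —
#' i.e. the blinded value is consistent with neither training group, the
#' signature of a batch artifact rather than a group difference.
#'
#' @param train Training RPKM matrix (DMRs x labeled samples).
#' @param blinded Blinded RPKM matrix (same DMR rows).
#' @param groups Group labels for the training columns.
#' @param k Band width in SDs (default 3).
#' @return List: `keep` (surviving DMR row names), `removed` (count),
#'   `outlier_dmrs` (names removed).
#' @export
remove_outlier_dmrs <- function(train, blinded, groups, k = 3) {
  if (nrow(train) != nrow(blinded)) stop("matrices must share DMR rows")
  stats_for <- function(g) {
    m <- train[, groups == g, drop = FALSE]
    list(mean = rowMeans(m), sd = apply(m, 1, stats::sd))
  }
  ca <- stats_for("case")
  co <- stats_for("control")
  out_case <- abs(blinded - ca$mean) > k * ca$sd
  out_ctrl <- abs(blinded - co$mean) > k * co$sd
  is_out <- apply(out_case & out_ctrl, 1, any)
  if (all(is_out)) {
    stop("all DMRs flagged as outliers; raise k or revisit the blinded data")
  }
  list(keep = rownames(train)[!is_out], removed = sum(is_out),
       outlier_dmrs = rownames(train)[is_out])
}

#' Label-permutation null for the DMR count
#'
#' Shuffles group labels uniformly among the labeled samples (preserving
#' the group sizes), reruns the full test + DMR-calling pipeline for each
#' permutation, and compares the observed DMR count with the permutation
#' distribution. Empirical p uses the add-one rule
#' `(1 + #(perm >= observed)) / (n + 1)`, so it is never 0. A permutation
#' that reproduces the original labeling is allowed and counted.
#'
#' @param counts A [count_matrix()].
#' @param grid The window grid.
#' @param n_permutations Number of label permutations (default 100).
#' @param p_threshold Working DMR threshold.
#' @param seed Integer seed; fixed seed gives identical null counts.
#' @return A `permutation_null`: `observed`, `null_counts`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(counts, grid, n_permutations = 100,
                             p_threshold = 1e-5, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  observed <- nrow(call_dmrs(test_all(counts), grid, p_threshold))
  labeled <- which(counts$samples$group %in% c("case", "control"))
  labels <- counts$samples$group[labeled]
  set.seed(seed)
  null_counts <- integer(n_permutations)
  for (i in seq_len(n_permutations)) {
    perm <- counts
    perm$samples$group[labeled] <- sample(labels)
    null_counts[i] <- nrow(call_dmrs(test_all(perm), grid, p_threshold))
  }
  p <- (1 + sum(null_counts >= observed)) / (n_permutations + 1)
  structure(list(observed = observed, null_counts = null_counts,
                 p_value = p, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation null: observed %d DMRs vs null max %d over %d perms; p = %.4g\n",
    x$observed, max(x$null_counts), x$n_permutations, x$p_value))
  invisible(x)
}

# RPKM aggregated over each DMR's member windows (counts summed, true
# union length used); rows named by dmr_id
dmr_rpkm <- function(counts, grid, dmrs) {
  stopifnot(inherits(counts, "count_matrix"), inherits(dmrs, "dmr_set"))
  if (!identical(rownames(counts$counts), grid$window)) {
    stop("counts rows are not aligned to the grid")
  }
  N <- counts$samples$library_size
  if (any(N <= 0)) {
    stop(sprintf("zero library size for sample %s",
                 counts$samples$sample_id[which(N <= 0)[1]]))
  }
  m <- matrix(0, nrow = nrow(dmrs), ncol = ncol(counts$counts),
              dimnames = list(dmrs$dmr_id, colnames(counts$counts)))
  for (i in seq_len(nrow(dmrs))) {
    span <- dmrs$first_window[i]:dmrs$last_window[i]
    m[i, ] <- colSums(counts$counts[span, , drop = FALSE])
  }
  len_kb <- (dmrs$stop - dmrs$start) / 1000
  sweep(m / len_kb, 2, N / 1e6, "/")
}

#' Leave-one-out cross-validation of the DMR biomarker
#'
#' For each labeled sample in turn: hold it out, re-derive DMRs from the
#' remaining samples only, fit the PCA nearest-centroid model on the
#' training RPKM and classify the held-out sample. The held-out sample
#' never influences DMR selection. When a fold yields fewer than 2 DMRs at
#' the threshold, the two smallest-p tested windows stand in as
#' single-window regions so the fold can still be scored (documented
#' fallback; relevant only for weak signal).
#'
#' @param counts A [count_matrix()].
#' @param grid The window grid.
#' @param p_threshold Working DMR threshold.
#' @return A `cv_result`: `folds` (data.frame `sample_id`, `truth`,
#'   `predicted`, `n_dmrs`), `accuracy`, `scheme`.
#' @export
cross_validate <- function(counts, grid, p_threshold = 1e-5) {
  stopifnot(inherits(counts, "count_matrix"))
  labeled <- which(counts$samples$group %in% c("case", "control"))
  if (sum(counts$samples$group == "case") < 3 ||
      sum(counts$samples$group == "control") < 3) {
    stop("need >= 3 samples per group for leave-one-out")
  }
  folds <- vector("list", length(labeled))
  for (f in seq_along(labeled)) {
    j <- labeled[f]
    keep_cols <- setdiff(seq_len(ncol(counts$counts)), j)
    keep_cols <- intersect(keep_cols, labeled)
    train <- count_matrix(counts$counts[, keep_cols, drop = FALSE],
                          counts$samples[keep_cols, c("sample_id", "group")])
    g <- train$samples$group
    if (sum(g == "case") < 2 || sum(g == "control") < 2) {
      warning(sprintf("fold %s skipped: < 2 samples per group",
                      counts$samples$sample_id[j]))
      next
    }
    res <- test_all(train)
    dmrs <- call_dmrs(res, grid, p_threshold)
    if (nrow(dmrs) < 2) dmrs <- top_window_dmrs(res, grid, 2)
    train_rpkm <- dmr_rpkm(train, grid, dmrs)
    held <- count_matrix(counts$counts[, j, drop = FALSE],
                         data.frame(sample_id = counts$samples$sample_id[j],
                                    group = "blinded"))
    held_rpkm <- dmr_rpkm(held, grid, dmrs)
    model <- pca_fit(train_rpkm, g)
    pred <- classify_samples(model, held_rpkm)
    folds[[f]] <- data.frame(sample_id = counts$samples$sample_id[j],
                             truth = counts$samples$group[j],
                             predicted = pred$predicted,
                             n_dmrs = nrow(dmrs),
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  acc <- mean(folds$predicted == folds$truth)
  structure(list(folds = folds, accuracy = acc, scheme = "leave-one-out"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: accuracy %.3f over %d folds\n",
              x$scheme, x$accuracy, nrow(x$folds)))
  invisible(x)
}

# smallest-p tested windows as single-window stand-in regions
top_window_dmrs <- function(results, grid, n) {
  ok <- which(results$flag == "ok")
  top <- ok[order(results$p_value[ok])][seq_len(min(n, length(ok)))]
  out <- data.frame(dmr_id = sprintf("W%d", seq_along(top)),
                    chrom = grid$chrom[top], start = grid$start[top],
                    stop = grid$stop[top], n_windows = 1L,
                    min_p = results$p_value[top],
                    all_q_below_05 = results$q_value[top] < 0.05,
                    maxLFC = results$lfc[top],
                    direction = ifelse(results$lfc[top] < 0, "decrease",
                                       "increase"),
                    length_kb = (grid$stop[top] - grid$start[top]) / 1000,
                    first_window = top, last_window = top,
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_set", "data.frame")
  attr(out, "p_threshold") <- NA_real_
  out
}

#' Blinded-sample classification workflow
#'
#' The full validation path for blinded samples: derive DMRs from the
#' training samples only, compute DMR RPKM for training and blinded
#' samples, remove batch-outlier DMRs, fit the PCA nearest-centroid model,
#' and classify each blinded sample. Provenance (DMR counts before/after
#' outlier removal) is attached to the result.
#'
#' @param train_counts Labeled [count_matrix()].
#' @param blinded_counts Blinded [count_matrix()] on the same grid.
#' @param grid The shared window grid.
#' @param p_threshold Working DMR threshold.
#' @param outlier_sd Band width for [remove_outlier_dmrs()].
#' @return A `classification_result` data.frame (one row per blinded
#'   sample: `sample_id`, `predicted`, `d_case`, `d_control`) with
#'   attributes `n_dmrs`, `n_dmrs_after_outlier_removal`,
#'   `dmrs_removed_as_outliers`.
#' @export
blinded_workflow <- function(train_counts, blinded_counts, grid,
                             p_threshold = 1e-5, outlier_sd = 3) {
  stopifnot(inherits(train_counts, "count_matrix"),
            inherits(blinded_counts, "count_matrix"))
  if (!identical(rownames(train_counts$counts),
                 rownames(blinded_counts$counts))) {
    stop("grid mismatch between training and blinded counts")
  }
  res <- test_all(train_counts)
  dmrs <- call_dmrs(res, grid, p_threshold)
  if (nrow(dmrs) < 2) {
    stop("fewer than 2 DMRs from training data; cannot fit the classifier")
  }
  empty <- data.frame(sample_id = character(), predicted = character(),
                      d_case = numeric(), d_control = numeric(),
                      stringsAsFactors = FALSE)
  if (ncol(blinded_counts$counts) == 0) {
    class(empty) <- c("classification_result", "data.frame")
    attr(empty, "n_dmrs") <- nrow(dmrs)
    attr(empty, "n_dmrs_after_outlier_removal") <- nrow(dmrs)
    attr(empty, "dmrs_removed_as_outliers") <- 0L
    return(empty)
  }
  groups <- train_counts$samples$group
  train_rpkm <- dmr_rpkm(train_counts, grid, dmrs)
  blinded_rpkm <- dmr_rpkm(blinded_counts, grid, dmrs)
  surv <- remove_outlier_dmrs(train_rpkm, blinded_rpkm, groups,
                              k = outlier_sd)
  if (length(surv$keep) < 2) {
    stop("fewer than 2 DMRs survive outlier removal; raise outlier_sd")
  }
  model <- pca_fit(train_rpkm[surv$keep, , drop = FALSE], groups)
  pred <- classify_samples(model, blinded_rpkm[surv$keep, , drop = FALSE])
  out <- pred[, c("sample_id", "predicted", "d_case", "d_control")]
  class(out) <- c("classification_result", "data.frame")
  attr(out, "n_dmrs") <- nrow(dmrs)
  attr(out, "n_dmrs_after_outlier_removal") <- length(surv$keep)
  attr(out, "dmrs_removed_as_outliers") <- surv$removed
  out
}
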