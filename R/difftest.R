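#' Adjust counts to a common library size
#'
#' Scales each sample's counts to the geometric mean library size
#' `N* = exp(mean(log N(j)))` with half-up rounding:
#' `y'(w, j) = floor(y(w, j) * N*/N(j) + 0.5)`. The conditional exact test
#' assumes equal means across samples within a group; this deterministic
#' rescaling is the equalization step that makes that assumption hold
#' approximately.
#'
#' @param counts A [count_matrix()].
#' @param common_libsize Optional target library size overriding the
#'   geometric mean (mainly for testing the rounding rule on exact ratios).
#' @return List with `adjusted` (integer matrix) and `common_libsize` (N*).
#' @export
adjust_to_common_libsize <- function(counts, common_libsize = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- counts$samples$library_size
  if (any(N <= 0)) {
    stop(sprintf("zero library size for sample %s",
                 counts$samples$sample_id[which(N <= 0)[1]]))
  }
  nstar <- if (is.null(common_libsize)) exp(mean(log(N)))
           else common_libsize
  adj <- sweep(counts$counts, 2, nstar / N, "*")
  adj <- matrix(as.integer(floor(adj + 0.5)), nrow = nrow(counts$counts),
                dimnames = dimnames(counts$counts))
  list(adjusted = adj, common_libsize = nstar)
}

#' Conditional negative-binomial log-likelihood
#'
#' Log-probability of observing counts `y` conditional on their sum, for n
#' i.i.d. NB(r, p) variables with equal means: the p parameter cancels, so
#' the conditional likelihood depends only on `r = 1/phi` and is the basis
#' of the common-dispersion estimator.
#'
#' @param y Integer vector of counts from one group at one window.
#' @param r NB size parameter, `r = 1/phi > 0`.
#' @return The conditional log-likelihood (0 when `sum(y) == 0`).
#' @export
conditional_loglik <- function(y, r) {
  if (r <= 0) stop("r must be positive")
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  n <- length(y)
  s <- sum(y)
  sum(lgamma(y + r)) - n * lgamma(r) - sum(lgamma(y + 1)) +
    lgamma(n * r) + lgamma(s + 1) - lgamma(s + n * r)
}

# Vectorized over windows: y is a windows x samples matrix of one group.
cll_matrix <- function(y, r) {
  n <- ncol(y)
  s <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) - rowSums(lgamma(y + 1)) +
    lgamma(n * r) + lgamma(s + 1) - lgamma(s + n * r)
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the summed conditional log-likelihood over case and control
#' groups across all windows passing the low-count filter, by
#' golden-section search on `log(phi)` over `[1e-6, 10]` (tolerance 1e-6).
#'
#' @param adjusted Integer matrix of library-size-adjusted counts
#'   (windows x samples).
#' @param groups Character vector of group labels per column (`"case"` /
#'   `"control"`).
#' @param min_mean Low-count filter: windows with mean adjusted count below
#'   this are excluded from estimation (default 1).
#' @return A `dispersion_fit` list: `phi`, `r`, `windows_used`, `loglik`,
#'   `at_boundary` (logical, with a warning when TRUE).
#' @export
estimate_common_dispersion <- function(adjusted, groups, min_mean = 1.0) {
  stopifnot(is.matrix(adjusted))
  if (length(groups) != ncol(adjusted)) {
    stop("groups must label every column of adjusted")
  }
  g1 <- adjusted[, groups == "case", drop = FALSE]
  g2 <- adjusted[, groups == "control", drop = FALSE]
  if (ncol(g1) < 2 || ncol(g2) < 2) stop("need >= 2 samples per group")
  keep <- rowMeans(adjusted[, groups %in% c("case", "control"),
                            drop = FALSE]) >= min_mean
  if (!any(keep)) stop("no windows pass the low-count filter")
  g1 <- g1[keep, , drop = FALSE]
  g2 <- g2[keep, , drop = FALSE]
  obj <- function(logphi) {
    r <- 1 / exp(logphi)
    sum(cll_matrix(g1, r)) + sum(cll_matrix(g2, r))
  }
  lo <- log(1e-6)
  hi <- log(10)
  opt <- golden_section_max(obj, lo, hi, tol = 1e-6)
  at_boundary <- (opt$x - lo) < 1e-3 || (hi - opt$x) < 1e-3
  if (at_boundary) {
    warning("dispersion estimate at search boundary; treat phi as a limit")
  }
  phi <- exp(opt$x)
  structure(list(phi = phi, r = 1 / phi, windows_used = sum(keep),
                 loglik = opt$value, at_boundary = at_boundary),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf(
    "common NB dispersion: phi = %.4g (r = %.4g), %d windows, logL = %.2f%s\n",
    x$phi, x$r, x$windows_used, x$loglik,
    if (x$at_boundary) " [boundary]" else ""))
  invisible(x)
}

golden_section_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

# log conditional probabilities of all splits a = 0..s of the total s
# between group sums S1 ~ NB(n1 r, pi) and S2 ~ NB(n2 r, pi)
exact_test_logprobs <- function(s, n1, n2, r) {
  a <- 0:s
  lgamma(a + n1 * r) - lgamma(a + 1) - lgamma(n1 * r) +
    lgamma(s - a + n2 * r) - lgamma(s - a + 1) - lgamma(n2 * r) +
    lgamma((n1 + n2) * r) + lgamma(s + 1) - lgamma(s + (n1 + n2) * r)
}

#' Conditional negative-binomial exact test for one window
#'
#' With group sums `S1 ~ NB(n1 r, pi)` and `S2 ~ NB(n2 r, pi)` independent,
#' conditions on the total `s = s1 + s2` and sums the probabilities of all
#' splits no more probable than the observed one (with a `1 + 1e-12`
#' relative tolerance for floating-point ties) — the "doubling-free"
#' two-sided exact-test convention.
#'
#' @param s1,s2 Observed group sums of adjusted counts (non-negative
#'   integers).
#' @param n1,n2 Number of samples per group.
#' @param r NB size `1/phi`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
exact_test_window <- function(s1, s2, n1, n2, r) {
  if (s1 < 0 || s2 < 0) stop("negative sums")
  if (n1 < 1 || n2 < 1) stop("need at least one sample per group")
  if (r <= 0) stop("r must be positive")
  s <- s1 + s2
  if (s == 0) return(1.0)
  lp <- exact_test_logprobs(s, n1, n2, r)
  lobs <- lp[s1 + 1]
  p <- sum(exp(lp[lp <= lobs + log1p(1e-12)]))
  min(max(p, 0), 1)
}

#' Log2 fold change of group mean counts
#'
#' `log2((s1/n1 + prior) / (s2/n2 + prior))`; positive when the case mean
#' exceeds the control mean (i.e. increased methylation in cases).
#'
#' @param s1,s2 Group sums of adjusted counts.
#' @param n1,n2 Group sizes.
#' @param prior Prior count stabilizing small means (default 0.125).
#' @return Finite log2 fold change.
#' @export
log_fold_change <- function(s1, s2, n1, n2, prior = 0.125) {
  log2((s1 / n1 + prior) / (s2 / n2 + prior))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j: p(j) >= p(i)} (m * p(j) / rank(j))`, clamped to at most
#' 1; monotone step-up FDR adjustment.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Per-window differential test across a count matrix
#'
#' The full testing pipeline: library-size equalization, low-count filter,
#' common-dispersion estimation (unless overridden), conditional NB exact
#' test on the per-window group sums, log2 fold change, and BH adjustment
#' over all tested windows. Filtered windows are retained with the sentinel
#' `p = q = 1` and flag `"low_count"`. Blinded samples are ignored.
#'
#' @param counts A [count_matrix()] containing both groups.
#' @param min_mean Low-count filter threshold on the mean adjusted count.
#' @param prior Prior count for the fold change.
#' @param dispersion Optional fixed dispersion `phi` overriding estimation.
#' @return A `window_test_result` data.frame with columns `window`, `s1`,
#'   `s2`, `lfc`, `p_value`, `q_value`, `flag`, and attributes `dispersion`
#'   (the [estimate_common_dispersion()] fit or the override) and
#'   `common_libsize`.
#' @export
test_all <- function(counts, min_mean = 1.0, prior = 0.125,
                     dispersion = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- counts$samples$group
  labeled <- groups %in% c("case", "control")
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 2 || n2 < 2) stop("both groups must have >= 2 samples")
  adj <- adjust_to_common_libsize(counts)
  y <- adj$adjusted[, labeled, drop = FALSE]
  g <- groups[labeled]
  keep <- rowMeans(y) >= min_mean
  if (!any(keep)) stop("no windows pass the low-count filter")
  fit <- if (is.null(dispersion)) {
    estimate_common_dispersion(adj$adjusted[, labeled, drop = FALSE], g,
                               min_mean = min_mean)
  } else {
    if (dispersion < 0) stop("dispersion must be >= 0")
    structure(list(phi = dispersion, r = 1 / max(dispersion, 1e-12),
                   windows_used = sum(keep), loglik = NA_real_,
                   at_boundary = FALSE, override = TRUE),
              class = "dispersion_fit")
  }
  s1 <- rowSums(y[, g == "case", drop = FALSE])
  s2 <- rowSums(y[, g == "control", drop = FALSE])
  p <- rep(1.0, nrow(y))
  for (w in which(keep)) {
    p[w] <- exact_test_window(s1[w], s2[w], n1, n2, fit$r)
  }
  q <- rep(1.0, nrow(y))
  q[keep] <- bh_adjust(p[keep])
  res <- data.frame(window = rownames(counts$counts),
                    s1 = s1, s2 = s2,
                    lfc = log_fold_change(s1, s2, n1, n2, prior),
                    p_value = p, q_value = q,
                    flag = ifelse(keep, "ok", "low_count"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dispersion") <- fit
  attr(res, "common_libsize") <- adj$common_libsize
  class(res) <- c("window_test_result", "data.frame")
  res
}
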