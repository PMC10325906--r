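# ChIP-signal quantification around TSSs and temporal classification:
# CPM and region-length normalization, coefficient-of-variation filtering,
# log2/z-score transforms, and a from-scratch fuzzy c-means implementation
# with the minimum-centroid-distance (Dmin) cluster-number diagnostic.

#' Tag a matrix as a signal matrix at a processing stage
#'
#' @param m numeric matrix (regions/genes x samples or bins).
#' @param stage one of `raw`, `cpm`, `length_cpm`, `log2`, `zscore`.
#' @export
signal_matrix <- function(m, stage = c("raw", "cpm", "length_cpm", "log2",
                                       "zscore")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(m), is.numeric(m))
  structure(m, stage = stage)
}

signal_stage <- function(m) attr(m, "stage") %||% "raw"

#' Counts-per-million normalization
#'
#' Scales each sample (column) so its total equals one million:
#' `value * 1e6 / colsum`.
#'
#' @param m raw count matrix.
#' @return CPM-scaled matrix (stage `cpm`).
#' @export
cpm_normalize <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[which(totals <= 0)[1]] %||% which(totals <= 0)[1]
    stop("sample '", bad, "' has zero total count; cannot CPM-normalize")
  }
  signal_matrix(sweep(unclass(m), 2, totals, "/") * 1e6, stage = "cpm")
}

#' Per-kilobase length normalization
#'
#' Divides each row by its merged-region length in kilobases
#' (`value / (length/1000)`), so genes whose multiple TSS windows merged
#' into longer regions are comparable with single-TSS genes.
#'
#' @param m CPM matrix with row names.
#' @param lengths named vector of total region length per row, in bases.
#' @return length-normalized matrix (stage `length_cpm`).
#' @export
length_normalize <- function(m, lengths) {
  if (is.null(rownames(m))) stop("signal matrix needs row names")
  len <- lengths[rownames(m)]
  if (any(is.na(len))) {
    stop("missing region length for row '",
         rownames(m)[which(is.na(len))[1]], "'")
  }
  if (any(len <= 0)) stop("region lengths must be positive")
  signal_matrix(unclass(m) / (as.numeric(len) / 1000), stage = "length_cpm")
}

#' Coefficient-of-variation filter
#'
#' Drops low-variability rows before clustering: a row is retained when
#' `sd/mean >= cv_min` on the linear (pre-log) scale. Rows with mean zero
#' are removed. The default threshold 0.2 removes genes whose signal barely
#' moves across timepoints.
#'
#' @param m signal matrix on a linear scale.
#' @param cv_min minimum coefficient of variation (default 0.2).
#' @return the retained rows, stage preserved.
#' @export
cv_filter <- function(m, cv_min = 0.2) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  keep <- mu > 0 & (s / mu) >= cv_min
  signal_matrix(unclass(m)[keep, , drop = FALSE], stage = signal_stage(m))
}

#' Log2 transform and row-wise z-scores
#'
#' `x -> log2(x + pseudocount)` followed by per-row standardization
#' `(x - rowmean) / rowsd`. Rows with zero variance after the log transform
#' carry no temporal shape and are dropped with a warning.
#'
#' @param m non-negative signal matrix.
#' @param pseudocount added before the log (default 1).
#' @return z-scored matrix (stage `zscore`); every row has mean 0, sd 1.
#' @export
log2_zscore <- function(m, pseudocount = 1) {
  if (any(m < 0)) stop("log2/z-score transform expects non-negative values")
  lg <- log2(unclass(m) + pseudocount)
  s <- apply(lg, 1, sd)
  zero_var <- s == 0 | !is.finite(s)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance row(s) dropped before z-scoring")
    lg <- lg[!zero_var, , drop = FALSE]
    s <- s[!zero_var]
  }
  z <- (lg - rowMeans(lg)) / s
  signal_matrix(z, stage = "zscore")
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimization of the fuzzy c-means objective
#' `J = sum_ik u_ik^m d(x_i, v_k)^2` with Euclidean distance and
#' fuzzifier `m > 1`: centroids `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`,
#' memberships `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`. A point that
#' coincides with one or more centroids gets its membership split equally
#' among them. Initialization draws a random membership matrix from the
#' seeded RNG and normalizes its rows; iteration stops when the largest
#' membership change falls below `tol` or after `max_iter` sweeps.
#'
#' Alternating optimization only guarantees a local minimum; with
#' `nstart > 1` the fit is repeated from `nstart` seeded initializations
#' (seeds `seed, seed + 1, ...`) and the run with the lowest final
#' objective is returned, the usual guard against poor local optima.
#'
#' @param x numeric matrix, observations in rows.
#' @param c number of clusters (`1 <= c <= nrow(x)`).
#' @param m fuzzifier, > 1 (default 2).
#' @param seed RNG seed for the random-membership initialization.
#' @param tol convergence tolerance on `max |delta u|` (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param nstart number of seeded restarts; best-objective run wins.
#' @return A `cluster_model` list: `c`, `m`, `centroids` (c x p),
#'   `membership` (n x c, rows sum to 1), `objective_trace`, `converged`,
#'   `iterations`, `dmin` (minimum pairwise centroid distance), `seed`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, seed = 1L, tol = 1e-6,
                         max_iter = 300L, nstart = 1L) {
  if (nstart > 1) {
    fits <- lapply(seq_len(nstart) - 1L, function(r) {
      fuzzy_cmeans(x, c, m = m, seed = seed + r, tol = tol,
                   max_iter = max_iter, nstart = 1L)
    })
    obj <- vapply(fits, function(f) f$objective_trace[f$iterations],
                  numeric(1))
    return(fits[[which.min(obj)]])
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("fuzzy c-means requires finite inputs")
  n <- nrow(x)
  if (c < 1) stop("cluster count must be >= 1")
  if (c > n) stop("cluster count c = ", c, " exceeds number of rows (", n, ")")
  if (m <= 1) stop("fuzzifier m must be > 1")
  set.seed(as.integer(seed))
  u <- matrix(runif(n * c), nrow = n, ncol = c)
  u <- u / rowSums(u)
  exp_u <- 2 / (m - 1)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  centroids <- NULL
  xsq <- rowSums(x^2)
  repeat {
    iter <- iter + 1L
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    # squared Euclidean distances n x c, clamped at zero for roundoff
    d2 <- pmax(outer(xsq, rowSums(centroids^2), "+") - 2 * x %*% t(centroids),
               0)
    zero <- d2 < .Machine$double.eps
    u_new <- matrix(0, n, c)
    any_zero <- rowSums(zero) > 0
    if (any(any_zero)) {
      zr <- which(any_zero)
      u_new[zr, ] <- zero[zr, , drop = FALSE] /
        rowSums(zero[zr, , drop = FALSE])
    }
    if (any(!any_zero)) {
      i <- which(!any_zero)
      w <- d2[i, , drop = FALSE]^(-1 / (m - 1))  # d^(-2/(m-1))
      u_new[i, ] <- w / rowSums(w)
    }
    trace <- c(trace, sum(u_new^m * d2))
    shift <- max(abs(u_new - u))
    u <- u_new
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  rownames(u) <- rownames(x)
  colnames(centroids) <- colnames(x)
  structure(list(c = as.integer(c), m = m, centroids = centroids,
                 membership = u, objective_trace = trace,
                 converged = converged, iterations = iter,
                 dmin = dmin(centroids), seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "fuzzy c-means: %d clusters, m = %.2f, %d rows, %s in %d iterations, Dmin = %.4f\n",
    x$c, x$m, nrow(x$membership),
    if (x$converged) "converged" else "not converged", x$iterations, x$dmin))
  invisible(x)
}

#' Minimum pairwise centroid distance
#'
#' @param centroids a centroid matrix (clusters in rows) or a
#'   `cluster_model`.
#' @return the smallest Euclidean distance between any two centroids;
#'   `Inf` for a single cluster.
#' @export
dmin <- function(centroids) {
  if (inherits(centroids, "cluster_model")) centroids <- centroids$centroids
  if (nrow(centroids) < 2) return(Inf)
  min(dist(centroids))
}

#' Dmin diagnostic curve over a range of cluster counts
#'
#' Fits fuzzy c-means at each candidate `c` several times with seeds
#' derived from `seed` and reports the mean minimum centroid distance.
#' The curve informs the cluster-count choice (a sharp decay of Dmin marks
#' the point where extra clusters start splitting real groups); the final
#' `c` remains an explicit user decision.
#'
#' @param x data matrix as in [fuzzy_cmeans()].
#' @param c_range integer vector of candidate cluster counts (all >= 2).
#' @param m fuzzifier.
#' @param repeats fits per candidate (default 3).
#' @param seed base seed; fit `r` of candidate `c` uses
#'   `seed + 97 * c + r`.
#' @return data frame with columns `c` and `dmin` (mean across repeats).
#' @export
dmin_curve <- function(x, c_range, m = 2, repeats = 3L, seed = 1L) {
  stopifnot(all(c_range >= 2), all(c_range <= nrow(x)))
  rows <- lapply(c_range, function(cc) {
    vals <- vapply(seq_len(repeats), function(r) {
      fuzzy_cmeans(x, c = cc, m = m, seed = seed + 97L * cc + r)$dmin
    }, numeric(1))
    data.frame(c = cc, dmin = mean(vals))
  })
  do.call(rbind, rows)
}

#' Hard cluster assignment
#'
#' Assigns each row to its maximum-membership cluster; ties break toward
#' the lowest cluster index, deterministically.
#'
#' @param model a fitted `cluster_model`.
#' @return named integer vector of cluster labels in `1..c`.
#' @export
hard_assign <- function(model) {
  u <- model$membership
  setNames(max.col(u, ties.method = "first"), rownames(u))
}
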