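# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops over every pair, straight from definitions.

# loop over every CpG x window pair; hit = region with >= min_sites CpGs
# whose delta < -drop_gt
brute_screen <- function(windows, deltas, drop_gt = 50, min_sites = 3) {
  counts <- list()
  for (r in unique(windows$name)) counts[[r]] <- character(0)
  for (i in seq_len(nrow(deltas))) {
    if (!(deltas$delta[i] < -drop_gt)) next
    for (w in seq_len(nrow(windows))) {
      if (deltas$chrom[i] == windows$chrom[w] &&
          deltas$pos[i] >= windows$start[w] &&
          deltas$pos[i] < windows$end[w]) {
        counts[[windows$name[w]]] <-
          union(counts[[windows$name[w]]],
                paste(deltas$chrom[i], deltas$pos[i]))
      }
    }
  }
  n <- vapply(counts, length, integer(1))
  sort(names(n)[n >= min_sites])
}

# O(n^2) pairwise union: repeatedly fuse any two overlapping (or, if asked,
# book-ended) intervals until fixed point
brute_merge <- function(df, merge_book_ended = TRUE) {
  ivs <- lapply(seq_len(nrow(df)),
                function(i) list(chrom = df$chrom[i], start = df$start[i],
                                 end = df$end[i]))
  repeat {
    fused <- FALSE
    for (i in seq_along(ivs)) {
      for (j in seq_along(ivs)) {
        if (i >= j) next
        a <- ivs[[i]]; b <- ivs[[j]]
        if (a$chrom != b$chrom) next
        touch <- if (merge_book_ended) {
          a$start <= b$end && b$start <= a$end
        } else {
          a$start < b$end && b$start < a$end
        }
        if (touch) {
          ivs[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                           end = max(a$end, b$end))
          ivs <- ivs[-j]
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  out <- do.call(rbind, lapply(ivs, function(v) {
    data.frame(chrom = v$chrom, start = v$start, end = v$end,
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}

# all-pairs overlap test for bedtools intersect -v semantics
brute_diffspec <- function(peaks, baseline) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ov <- FALSE
    for (j in seq_len(nrow(baseline))) {
      if (peaks$chrom[i] == baseline$chrom[j] &&
          peaks$start[i] < baseline$end[j] &&
          baseline$start[j] < peaks$end[i]) { ov <- TRUE; break }
    }
    keep[i] <- !ov
  }
  peaks[keep, , drop = FALSE]
}

# naive per-element fuzzy c-means, explicit loops over i, k, j
naive_fcm <- function(x, c, m = 2, seed = 1, tol = 1e-6, max_iter = 300) {
  n <- nrow(x); p <- ncol(x)
  set.seed(as.integer(seed))
  u <- matrix(runif(n * c), n, c)
  for (i in 1:n) u[i, ] <- u[i, ] / sum(u[i, ])
  for (iter in 1:max_iter) {
    v <- matrix(0, c, p)
    for (k in 1:c) {
      num <- rep(0, p); den <- 0
      for (i in 1:n) {
        num <- num + u[i, k]^m * x[i, ]
        den <- den + u[i, k]^m
      }
      v[k, ] <- num / den
    }
    u_new <- matrix(0, n, c)
    for (i in 1:n) {
      d <- rep(0, c)
      for (k in 1:c) d[k] <- sqrt(sum((x[i, ] - v[k, ])^2))
      if (any(d^2 < .Machine$double.eps)) {
        z <- d^2 < .Machine$double.eps
        u_new[i, z] <- 1 / sum(z)
      } else {
        for (k in 1:c) {
          u_new[i, k] <- 1 / sum((d[k] / d)^(2 / (m - 1)))
        }
      }
    }
    shift <- max(abs(u_new - u))
    u <- u_new
    if (shift < tol) break
  }
  list(membership = u, centroids = v)
}

# per-anchor loop-and-average over track bins
naive_profile <- function(track, anchors, flank, skip_zero = FALSE) {
  bs <- track$bin_size
  nb <- 2 * flank / bs
  acc <- NULL
  for (i in seq_len(nrow(anchors))) {
    ctr <- (anchors$start[i] + anchors$end[i]) %/% 2
    v <- track$values[[anchors$chrom[i]]]
    vals <- rep(NA_real_, nb)
    ok <- TRUE
    for (j in 1:nb) {
      pos <- ctr - flank + (j - 0.5) * bs
      idx <- floor(pos / bs) + 1
      if (idx < 1 || idx > length(v)) { ok <- FALSE; break }
      vals[j] <- v[idx]
    }
    if (!ok) next
    if (skip_zero && all(vals == 0)) next
    acc <- rbind(acc, vals)
  }
  colMeans(acc)
}

# pooled-bin regrouping of CpG deltas around anchors
naive_meth_profile <- function(deltas, anchors, flank, bin_size) {
  nb <- 2 * flank / bin_size
  pools <- vector("list", nb)
  for (i in seq_len(nrow(anchors))) {
    ctr <- (anchors$start[i] + anchors$end[i]) %/% 2
    for (s in seq_len(nrow(deltas))) {
      if (deltas$chrom[s] != anchors$chrom[i]) next
      off <- deltas$pos[s] - ctr
      if (off >= -flank && off < flank) {
        b <- (off + flank) %/% bin_size + 1
        pools[[b]] <- c(pools[[b]], deltas$delta[s])
      }
    }
  }
  vapply(pools, function(p) if (length(p) == 0) NA_real_ else mean(p),
         numeric(1))
}

# Pearson correlation straight from the sum formula
pearson_sums <- function(a, b) {
  n <- length(a)
  (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
}

brute_dmin <- function(centroids) {
  best <- Inf
  for (i in seq_len(nrow(centroids))) {
    for (j in seq_len(nrow(centroids))) {
      if (i < j) {
        best <- min(best, sqrt(sum((centroids[i, ] - centroids[j, ])^2)))
      }
    }
  }
  best
}
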