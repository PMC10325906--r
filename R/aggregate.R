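# DMR-anchored aggregation: binned genome-wide signal tracks, Day-0
# subtraction of CPM-normalized ChIP signal, and average profiles of
# signal or methylation change around anchor (DMR) centers.

#' Construct a binned signal track
#'
#' A binned track stores one value per fixed-width genome bin: bin `k`
#' (1-based) of a chromosome covers `[(k-1)*bin_size, k*bin_size)`.
#'
#' @param values named list, chromosome -> numeric vector of per-bin values.
#' @param bin_size bin width in bases.
#' @param norm normalization tag: `raw`, `cpm` or `delta`.
#' @export
binned_track <- function(values, bin_size, norm = c("raw", "cpm", "delta")) {
  norm <- match.arg(norm)
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  if (!all(vapply(values, is.numeric, logical(1)))) {
    stop("binned track values must be numeric vectors")
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 norm = norm),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned track (%s), bin size %d bp, %d chromosome(s), %d bins\n",
              x$norm, x$bin_size, length(x$values),
              sum(lengths(x$values))))
  invisible(x)
}

#' CPM-normalize a binned track
#'
#' Scales all bins so the track total equals one million, making tracks
#' from libraries of different depth comparable before subtraction.
#'
#' @param track a raw [binned_track()].
#' @export
cpm_normalize_track <- function(track) {
  total <- sum(vapply(track$values, sum, numeric(1)))
  if (total <= 0) stop("track total is zero; cannot CPM-normalize")
  binned_track(lapply(track$values, function(v) v * 1e6 / total),
               bin_size = track$bin_size, norm = "cpm")
}

#' Read a binned bedGraph track
#'
#' Expects 4-column bedGraph records aligned to a fixed binning
#' (`start = (k-1)*bin_size`, `end = start + bin_size`); bins absent from
#' the file are zero. Chromosome extents come from `chrom_sizes`.
#'
#' @param path bedGraph path.
#' @param bin_size bin width the file was written at.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param norm normalization tag to attach.
#' @export
read_binned_bedgraph <- function(path, bin_size, chrom_sizes,
                                 norm = c("raw", "cpm", "delta")) {
  norm <- match.arg(norm)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^track|^#|^\\s*$", lines)]
  vals <- lapply(chrom_sizes, function(len) numeric(ceiling(len / bin_size)))
  names(vals) <- names(chrom_sizes)
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4)) stop("malformed bedGraph line in ", path)
    chrom <- vapply(fields, `[`, "", 1)
    start <- as.integer(vapply(fields, `[`, "", 2))
    end <- as.integer(vapply(fields, `[`, "", 3))
    val <- as.numeric(vapply(fields, `[`, "", 4))
    if (any(is.na(start) | is.na(end) | is.na(val))) {
      stop("malformed bedGraph record in ", path)
    }
    if (any(start %% bin_size != 0 | end - start != bin_size)) {
      stop("bedGraph records in ", path, " are not aligned to ", bin_size,
           "-bp bins")
    }
    if (!all(chrom %in% names(vals))) {
      stop("unknown chromosome in ", path, ": ",
           setdiff(chrom, names(vals))[1])
    }
    for (ch in unique(chrom)) {
      i <- chrom == ch
      vals[[ch]][start[i] %/% bin_size + 1L] <- val[i]
    }
  }
  binned_track(vals, bin_size = bin_size, norm = norm)
}

#' Write a binned track as bedGraph
#'
#' Zero bins are omitted, keeping files sparse; values print to six
#' decimals.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @export
write_binned_bedgraph <- function(track, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    writeLines(sprintf("%s\t%d\t%d\t%.6f", ch, (nz - 1L) * bs, nz * bs,
                       v[nz]), con, sep = "\n")
  }
  invisible(path)
}

#' Per-bin signal change between two CPM tracks
#'
#' `value_t - value_0` in every bin (the Day-0 subtraction of normalized
#' ChIP signal). Both tracks must share the binning and chromosome set and
#' be CPM-normalized.
#'
#' @param track_t later-timepoint [binned_track()], `cpm`.
#' @param track_0 reference-timepoint [binned_track()], `cpm`.
#' @return a `delta` [binned_track()].
#' @export
signal_change <- function(track_t, track_0) {
  if (track_t$bin_size != track_0$bin_size) {
    stop("bin sizes differ (", track_t$bin_size, " vs ", track_0$bin_size, ")")
  }
  if (!identical(sort(names(track_t$values)), sort(names(track_0$values))) ||
      !identical(lengths(track_t$values)[sort(names(track_t$values))],
                 lengths(track_0$values)[sort(names(track_0$values))])) {
    stop("tracks cover different chromosomes or extents")
  }
  if (track_t$norm != "cpm" || track_0$norm != "cpm") {
    stop("signal_change expects CPM-normalized tracks")
  }
  out <- lapply(names(track_t$values), function(ch) {
    track_t$values[[ch]] - track_0$values[[ch]]
  })
  names(out) <- names(track_t$values)
  binned_track(out, bin_size = track_t$bin_size, norm = "delta")
}

anchor_centers <- function(anchors) (anchors$start + anchors$end) %/% 2L

#' Average signal profile around anchor centers
#'
#' For each anchor the window `[c - flank, c + flank)` around its center
#' `c = floor((start + end)/2)` is sampled in `2*flank/bin_size` offset
#' bins (each offset bin reads the track bin containing its center), and
#' the per-offset mean across anchors is returned. Anchors whose window
#' extends past a chromosome end are skipped and counted; with
#' `skip_zero_anchors`, anchors sampling all-zero signal are excluded from
#' the average as well.
#'
#' @param track a [binned_track()].
#' @param anchors [genomic_intervals()] (e.g. DMRs).
#' @param flank half-window in bases (default 3000); must be a multiple of
#'   the track's bin size.
#' @param skip_zero_anchors drop anchors with all-zero sampled signal?
#' @return A `profile_curve` data frame: `offset` (bin-center offset from
#'   the anchor center, bases), `value` (mean across anchors used), `n`
#'   (anchors contributing); attributes `n_anchors_used`,
#'   `n_anchors_skipped`.
#' @export
profile_around_anchors <- function(track, anchors, flank = 3000L,
                                   skip_zero_anchors = FALSE) {
  bs <- track$bin_size
  if (nrow(anchors) == 0) stop("no anchors supplied")
  if (flank %% bs != 0) stop("flank must be divisible by the bin size")
  nb <- 2L * flank %/% bs
  offsets <- -flank + (seq_len(nb) - 0.5) * bs
  rows <- matrix(NA_real_, nrow = nrow(anchors), ncol = nb)
  skipped <- 0L
  ctr <- anchor_centers(anchors)
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) { skipped <- skipped + 1L; next }
    pos <- ctr[i] + offsets  # offset-bin centers in genome coordinates
    idx <- floor(pos / bs) + 1L
    if (idx[1] < 1 || idx[nb] > length(v)) { skipped <- skipped + 1L; next }
    rows[i, ] <- v[idx]
  }
  used <- !is.na(rows[, 1])
  if (skip_zero_anchors) {
    allzero <- used & apply(rows, 1, function(r) all(r == 0))
    skipped <- skipped + sum(allzero)
    used <- used & !allzero
  }
  if (!any(used)) stop("no usable anchors after skipping")
  curve <- colMeans(rows[used, , drop = FALSE])
  structure(data.frame(offset = offsets, value = curve, n = sum(used)),
            n_anchors_used = sum(used), n_anchors_skipped = skipped,
            class = c("profile_curve", "data.frame"))
}

#' Methylation-change profile around anchor centers
#'
#' CpG deltas within `[c - flank, c + flank)` of any anchor center are
#' pooled into offset bins (`offset = pos - c`) and averaged per bin.
#' CpGs are sparse, so bins holding no CpG are reported as `NA`
#' (missing), never zero.
#'
#' @param deltas a `delta_track` from [methylation_delta()].
#' @param anchors [genomic_intervals()] (e.g. DMRs).
#' @param flank half-window in bases (default 3000).
#' @param bin_size offset-bin width in bases (default 10).
#' @return A `profile_curve` data frame: `offset`, `value` (mean delta,
#'   `NA` where empty), `n` (CpGs pooled into the bin).
#' @export
methylation_profile <- function(deltas, anchors, flank = 3000L,
                                bin_size = 10L) {
  if (nrow(anchors) == 0) stop("no anchors supplied")
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  nb <- 2L * flank %/% bin_size
  offsets <- -flank + (seq_len(nb) - 0.5) * bin_size
  sums <- numeric(nb)
  counts <- integer(nb)
  ctr <- anchor_centers(anchors)
  for (i in seq_len(nrow(anchors))) {
    sel <- deltas$chrom == anchors$chrom[i] &
      deltas$pos >= ctr[i] - flank & deltas$pos < ctr[i] + flank
    if (!any(sel)) next
    off <- deltas$pos[sel] - ctr[i]
    bin <- (off + flank) %/% bin_size + 1L
    for (j in seq_along(bin)) {
      sums[bin[j]] <- sums[bin[j]] + deltas$delta[sel][j]
      counts[bin[j]] <- counts[bin[j]] + 1L
    }
  }
  if (all(counts == 0)) {
    warning("no CpG within ", flank, " bp of any anchor center")
  }
  value <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(data.frame(offset = offsets, value = value, n = counts),
            n_anchors_used = nrow(anchors), n_anchors_skipped = 0L,
            class = c("profile_curve", "data.frame"))
}
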