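# The CpG demethylation screen: coverage filtering, per-CpG change between
# two timepoints under joint coverage filtering, per-region qualification
# ("three or more CpGs losing more than 50 percentage points"), and the
# cross-condition contrast that defines the iron-dependent set.

#' Filter CpG sites by read depth
#'
#' Retains sites whose coverage lies in the closed interval
#' `[min_cov, max_cov]`; sites with depth below `min_cov` or above `max_cov`
#' are omitted. Defaults follow the screen's rule of dropping CpGs with
#' fewer than 5 or more than 1000 reads. Tracks without coverage
#' (the `level4` bedGraph dialect) are rejected.
#'
#' @param track a [methylome_track()] carrying coverage.
#' @param min_cov,max_cov closed depth bounds (defaults 5 and 1000).
#' @return the filtered [methylome_track()].
#' @export
coverage_filter <- function(track, min_cov = 5L, max_cov = 1000L) {
  stopifnot(inherits(track, "methylome_track"))
  if (!"coverage" %in% names(track) || any(is.na(track$coverage))) {
    i <- if ("coverage" %in% names(track)) which(is.na(track$coverage))[1] else 1L
    where <- if (nrow(track) > 0) paste0(track$chrom[i], ":", track$pos[i]) else ""
    stop("track '", track_label(track),
         "' has sites without defined coverage (", where,
         "); coverage-based screens need the counts6 dialect")
  }
  keep <- track$coverage >= min_cov & track$coverage <= max_cov
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = track_label(track),
            class = c("methylome_track", "data.frame"))
}

#' Per-CpG methylation change between two timepoints
#'
#' Applies the coverage filter to both tracks, intersects the surviving
#' sites, and computes `delta = meth_later - meth_base` in percentage
#' points. Only CpGs passing the depth filter in *both* timepoints enter
#' the delta track, so every change is measured on adequately covered data.
#'
#' @param base track at the reference timepoint (e.g. Day 0).
#' @param later track at the later timepoint (e.g. Day 8).
#' @param min_cov,max_cov closed depth bounds applied to both tracks.
#' @return A `delta_track` data frame with columns `chrom`, `pos`,
#'   `meth_base`, `meth_later`, `delta`.
#' @export
methylation_delta <- function(base, later, min_cov = 5L, max_cov = 1000L) {
  b <- coverage_filter(base, min_cov, max_cov)
  l <- coverage_filter(later, min_cov, max_cov)
  kb <- paste(b$chrom, b$pos)
  kl <- paste(l$chrom, l$pos)
  common <- intersect(kb, kl)
  if (length(common) == 0) {
    warning("no CpG passes the coverage filter in both '",
            track_label(base), "' and '", track_label(later), "'")
  }
  bi <- b[match(common, kb), , drop = FALSE]
  li <- l[match(common, kl), , drop = FALSE]
  df <- data.frame(chrom = bi$chrom, pos = bi$pos, meth_base = bi$meth,
                   meth_later = li$meth, delta = li$meth - bi$meth,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$pos, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, base_label = track_label(base),
            later_label = track_label(later),
            class = c("delta_track", "data.frame"))
}

#' Screen windows for demethylated regions
#'
#' A CpG qualifies when it lies inside any window of a region and its
#' methylation dropped by strictly more than `drop_gt` percentage points
#' (`delta < -drop_gt`; a drop of exactly `drop_gt` never qualifies). A
#' region is a hit when it holds at least `min_sites` qualifying CpGs,
#' pooled across all its windows (a gene's multiple TSS windows count as
#' one region). CpGs inside the windows of several regions count for each.
#'
#' The drop is read in absolute percentage points (the change is a plain
#' subtraction of levels); `relative = TRUE` switches to the
#' relative-reduction reading, where a CpG qualifies when it lost more
#' than `drop_gt` percent *of its starting level*
#' (`delta < -drop_gt/100 * meth_base`). `per_window = TRUE` screens each
#' window as its own region instead of pooling a gene's windows.
#'
#' @param windows [genomic_intervals()] whose `name` column is the region
#'   (gene or enhancer) id.
#' @param deltas a `delta_track` from [methylation_delta()].
#' @param drop_gt minimum drop in percentage points (or percent of the
#'   baseline level when `relative`), exclusive (default 50).
#' @param min_sites minimum number of qualifying CpGs (default 3).
#' @param relative interpret `drop_gt` relative to the baseline level?
#' @param per_window screen windows individually instead of pooled by id?
#' @return A `screen_hits` data frame: `region_id`, `n_qualifying`, and a
#'   list-column `sites` of qualifying (chrom, pos, delta) records.
#' @export
screen_windows <- function(windows, deltas, drop_gt = 50, min_sites = 3L,
                           relative = FALSE, per_window = FALSE) {
  if (!"name" %in% names(windows)) {
    stop("screen windows must carry the source region id in 'name'")
  }
  if (per_window && nrow(windows) > 0) {
    windows$name <- sprintf("%s#%d", windows$name,
                            stats::ave(seq_len(nrow(windows)), windows$name,
                                       FUN = seq_along))
  }
  hits_empty <- structure(
    data.frame(region_id = character(), n_qualifying = integer(),
               stringsAsFactors = FALSE),
    sites = list(), params = list(drop_gt = drop_gt, min_sites = min_sites,
                                  relative = relative),
    class = c("screen_hits", "data.frame"))
  if (nrow(windows) == 0 || nrow(deltas) == 0) return(hits_empty)
  threshold <- if (relative) -drop_gt / 100 * deltas$meth_base
  else rep(-drop_gt, nrow(deltas))
  qual <- deltas[deltas$delta < threshold, , drop = FALSE]
  if (nrow(qual) == 0) return(hits_empty)
  pairs <- list()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    qi <- which(qual$chrom == ch)
    if (length(qi) == 0) next
    ov <- IRanges::findOverlaps(
      as_iranges0(qual$pos[qi], qual$pos[qi] + 1L),
      as_iranges0(windows$start[wi], windows$end[wi]))
    if (length(ov) == 0) next
    pairs[[ch]] <- data.frame(
      region_id = windows$name[wi[S4Vectors::subjectHits(ov)]],
      chrom = ch, pos = qual$pos[qi[S4Vectors::queryHits(ov)]],
      delta = qual$delta[qi[S4Vectors::queryHits(ov)]],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) return(hits_empty)
  tab <- do.call(rbind, pairs)
  # one CpG can sit in several windows of the same region (e.g. overlapping
  # TSS windows); it counts once per region
  tab <- tab[!duplicated(tab[c("region_id", "chrom", "pos")]), , drop = FALSE]
  counts <- table(tab$region_id)
  keep_ids <- names(counts)[counts >= min_sites]
  keep_ids <- keep_ids[order(keep_ids, method = "radix")]
  if (length(keep_ids) == 0) return(hits_empty)
  sites <- lapply(keep_ids, function(id) {
    s <- tab[tab$region_id == id, c("chrom", "pos", "delta"), drop = FALSE]
    s[order(s$chrom, s$pos, method = "radix"), , drop = FALSE]
  })
  names(sites) <- keep_ids
  structure(
    data.frame(region_id = keep_ids,
               n_qualifying = as.integer(counts[keep_ids]),
               stringsAsFactors = FALSE),
    sites = sites, params = list(drop_gt = drop_gt, min_sites = min_sites,
                                 relative = relative),
    class = c("screen_hits", "data.frame"))
}

#' Contrast screen hits between two conditions
#'
#' Partitions the union of hit region ids into condition-specific and shared
#' sets (the Venn-diagram construction). With A the untreated and B the
#' iron-chelated condition, `only_a` is the iron-dependent demethylated set.
#'
#' @param hits_a,hits_b `screen_hits` from [screen_windows()], computed with
#'   identical parameters and annotation.
#' @param label_a,label_b condition labels.
#' @return A `screen_contrast` list with `only_a`, `only_b`, `shared`,
#'   `labels`.
#' @export
condition_contrast <- function(hits_a, hits_b, label_a = "A", label_b = "B") {
  pa <- attr(hits_a, "params")
  pb <- attr(hits_b, "params")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    stop("screen hits were computed with different parameters; ",
         "contrast requires identical screens")
  }
  a <- hits_a$region_id
  b <- hits_b$region_id
  structure(list(only_a = sort(setdiff(a, b)), only_b = sort(setdiff(b, a)),
                 shared = sort(intersect(a, b)),
                 labels = c(label_a, label_b)),
            class = "screen_contrast")
}

#' @export
print.screen_contrast <- function(x, ...) {
  cat(sprintf("screen contrast %s vs %s: %d only-%s, %d only-%s, %d shared\n",
              x$labels[1], x$labels[2], length(x$only_a), x$labels[1],
              length(x$only_b), x$labels[2], length(x$shared)))
  invisible(x)
}
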