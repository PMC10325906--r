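# Interval algebra for the window constructions used throughout the
# pipeline: strand-aware TSS-upstream promoter windows, bedtools-style peak
# merging and subtraction, peak-center enhancer windows, and merged TSS +/-
# 5 kb regions for ChIP-signal quantification. Overlap machinery is
# delegated to IRanges; the public surface stays 0-based half-open.

# 0-based half-open [start, end) -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

clip_windows <- function(df, chrom_sizes = NULL) {
  df$start <- pmax(df$start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[df$chrom])
    df$end <- ifelse(is.na(lim), df$end, pmin(df$end, lim))
  }
  df[df$start < df$end, , drop = FALSE]
}

#' Strand-aware upstream promoter windows
#'
#' For every TSS of every gene, returns the window of `size` bases
#' immediately upstream of the TSS, excluding the TSS base itself: on the
#' plus strand `[t - size, t)`, on the minus strand `[t + 1, t + 1 + size)`.
#' Windows are clipped to chromosome bounds; a window that falls entirely
#' outside the chromosome yields no interval for that TSS.
#'
#' @param genes a [gene_table()].
#' @param size window size in bases (default 1000, i.e. 1 kb upstream).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return [genomic_intervals()] labelled with the source gene id.
#' @export
upstream_windows <- function(genes, size = 1000L, chrom_sizes = NULL) {
  stopifnot(size >= 1)
  size <- as.integer(size)
  n_tss <- lengths(genes$tss)
  gene_id <- rep(genes$gene_id, n_tss)
  chrom <- rep(genes$chrom, n_tss)
  strand <- rep(genes$strand, n_tss)
  tss <- unlist(genes$tss, use.names = FALSE)
  if (length(tss) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  start <- ifelse(strand == "+", tss - size, tss + 1L)
  end <- ifelse(strand == "+", tss, tss + 1L + size)
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), strand = strand, name = gene_id,
                   stringsAsFactors = FALSE)
  df <- clip_windows(df, chrom_sizes)
  genomic_intervals(df$chrom, df$start, df$end, strand = df$strand,
                    name = df$name)
}

#' Merge overlapping intervals
#'
#' bedtools-merge semantics: intervals overlapping by at least 1 bp are
#' always merged; book-ended intervals (`[a,b)` and `[b,c)`) are merged only
#' when `merge_book_ended` is set (the default, mirroring `bedtools merge`
#' at distance 0). The result is sorted and pairwise disjoint.
#'
#' @param intervals a [genomic_intervals()] data frame.
#' @param merge_book_ended merge abutting intervals too?
#' @return merged [genomic_intervals()].
#' @export
merge_intervals <- function(intervals, merge_book_ended = TRUE) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end", "strand")])
  gap <- if (merge_book_ended) 1L else 0L
  parts <- split(seq_len(nrow(intervals)), intervals$chrom)
  out <- lapply(names(parts), function(ch) {
    i <- parts[[ch]]
    r <- IRanges::reduce(as_iranges0(intervals$start[i], intervals$end[i]),
                         min.gapwidth = gap)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  genomic_intervals(df$chrom, df$start, df$end)
}

#' Fixed-flank windows around interval centers
#'
#' The putative-enhancer construction: for each peak the window of
#' `flank` bases on either side of the peak center
#' (`c = floor((start + end) / 2)`), i.e. `[c - flank, c + flank)`, clipped
#' to chromosome bounds. Peak names are carried through; unnamed peaks get
#' `peak_<i>` labels so every enhancer window has a source id.
#'
#' @param intervals a [genomic_intervals()] data frame of peaks.
#' @param flank half-width in bases (default 500).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return [genomic_intervals()] of enhancer windows.
#' @export
center_windows <- function(intervals, flank = 500L, chrom_sizes = NULL) {
  flank <- as.integer(flank)
  if (nrow(intervals) == 0) return(intervals)
  ctr <- (intervals$start + intervals$end) %/% 2L
  nm <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("peak_%d", seq_len(nrow(intervals)))
  df <- data.frame(chrom = intervals$chrom, start = ctr - flank,
                   end = ctr + flank, name = nm, stringsAsFactors = FALSE)
  df <- clip_windows(df, chrom_sizes)
  genomic_intervals(df$chrom, df$start, df$end, name = df$name)
}

#' Differentiation-specific peaks (overlap subtraction)
#'
#' `bedtools intersect -v` semantics: retains exactly the peaks that share
#' zero bases with every pre-induction (baseline) peak; an overlap of 1 bp
#' or more removes a peak, book-ended contact does not.
#'
#' @param peaks candidate peaks ([genomic_intervals()]).
#' @param preinduction_peaks peaks already present before induction.
#' @return the subset of `peaks` with no baseline overlap.
#' @export
differentiation_specific <- function(peaks, preinduction_peaks) {
  if (nrow(peaks) == 0 || nrow(preinduction_peaks) == 0) return(peaks)
  drop <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    qi <- which(peaks$chrom == ch)
    si <- which(preinduction_peaks$chrom == ch)
    if (length(si) == 0) next
    hits <- IRanges::overlapsAny(
      as_iranges0(peaks$start[qi], peaks$end[qi]),
      as_iranges0(preinduction_peaks$start[si], preinduction_peaks$end[si]))
    drop[qi] <- hits
  }
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS +/- flank regions for ChIP-signal quantification
#'
#' One strand-independent window `[t - flank, t + flank)` per TSS of each
#' gene. With `merge = TRUE` (gene-level mode) overlapping windows of the
#' same gene are merged and the total merged length recorded for length
#' normalization; windows of different genes are never merged. With
#' `merge = FALSE` every TSS keeps its own window even when overlapping
#' (per-TSS mode).
#'
#' @param genes a [gene_table()].
#' @param flank half-width in bases (default 5000).
#' @param merge merge overlapping windows within each gene?
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return list with `windows` ([genomic_intervals()] named by gene) and
#'   `lengths` (named integer vector of total window length per gene, bases).
#' @export
tss_regions <- function(genes, flank = 5000L, merge = TRUE,
                        chrom_sizes = NULL) {
  stopifnot(flank >= 1)
  flank <- as.integer(flank)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[[i]]
    df <- data.frame(chrom = genes$chrom[i], start = tss - flank,
                     end = tss + flank, name = genes$gene_id[i],
                     stringsAsFactors = FALSE)
    df <- clip_windows(df, chrom_sizes)
    if (nrow(df) == 0) return(df)
    if (merge && nrow(df) > 1) {
      r <- IRanges::reduce(as_iranges0(df$start, df$end), min.gapwidth = 1L)
      df <- data.frame(chrom = genes$chrom[i], start = IRanges::start(r) - 1L,
                       end = IRanges::end(r), name = genes$gene_id[i],
                       stringsAsFactors = FALSE)
    }
    df
  })
  df <- do.call(rbind, rows)
  win <- genomic_intervals(df$chrom, df$start, df$end, name = df$name)
  len <- tapply(win$end - win$start, win$name, sum)
  lengths <- setNames(as.integer(len), names(len))
  # keep annotation order for downstream row alignment
  lengths <- lengths[intersect(genes$gene_id, names(lengths))]
  list(windows = win, lengths = lengths)
}
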