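# Small in-code fixture builders shared across test files.

make_track <- function(chrom, pos, meth, coverage = NULL, label = "t") {
  if (is.null(coverage)) {
    methylome_track(data.frame(chrom = chrom, pos = pos, meth = meth),
                    label = label)
  } else {
    n_meth <- as.integer(round(coverage * meth / 100))
    methylome_track(
      data.frame(chrom = chrom, pos = pos, meth = 100 * n_meth / coverage,
                 n_meth = n_meth, n_unmeth = coverage - n_meth),
      label = label)
  }
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 1000,
                             max_width = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(max_width, n, replace = TRUE),
                    name = sprintf("iv%03d", seq_len(n)))
}

# delta track built directly, bypassing coverage filtering
make_deltas <- function(chrom, pos, delta) {
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       meth_base = 80, meth_later = 80 + delta,
                       delta = delta, stringsAsFactors = FALSE),
            base_label = "b", later_label = "l",
            class = c("delta_track", "data.frame"))
}

random_binned_track <- function(chrom_sizes, bin_size = 10, norm = "cpm") {
  vals <- lapply(chrom_sizes, function(l) {
    runif(ceiling(l / bin_size), 0, 10)
  })
  binned_track(vals, bin_size, norm = norm)
}
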