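# Closed-form assay quantifications: HTRF demethylase activity (DF%),
# lysosomal flux and degradation deltas from normalized band intensities,
# ChIP percent-input, bisulfite-clone methylation summaries, and pixel
# colocalization by Pearson correlation.

#' HTRF demethylase activity (DF%)
#'
#' Time-resolved FRET readout of an enzymatic demethylation reaction:
#' `DF% = ((665/620 of enzyme(+)) / (665/620 of enzyme(-)) - 1) * 100`,
#' comparing the acceptor/donor fluorescence ratio with and without enzyme.
#'
#' @param plus,minus lists or named vectors with elements `f665` and `f620`
#'   (fluorescence at 665 nm and 620 nm; 620 nm reading must be positive).
#' @return DF% as a single number (0 when ratios are equal).
#' @export
htrf_df_percent <- function(plus, minus) {
  ratio <- function(w, which) {
    f665 <- w[["f665"]]; f620 <- w[["f620"]]
    if (is.null(f665) || is.null(f620)) {
      stop("well readings need f665 and f620 components")
    }
    if (f620 <= 0) stop(which, " reading has non-positive 620 nm signal")
    f665 / f620
  }
  r_minus <- ratio(minus, "enzyme(-)")
  if (r_minus <= 0) stop("enzyme(-) ratio must be positive")
  (ratio(plus, "enzyme(+)") / r_minus - 1) * 100
}

check_norm_tags <- function(a, b) {
  ta <- attr(a, "norm"); tb <- attr(b, "norm")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb)) {
    stop("mixed normalization tags ('", ta, "' vs '", tb,
         "'); both levels must be normalized the same way")
  }
}

#' Lysosomal flux from inhibitor/vehicle levels
#'
#' Flux of a protein through the lysosome, measured as the level under
#' lysosomal inhibition (bafilomycin A1) minus the level under vehicle:
#' accumulation upon inhibition reflects ongoing degradation. Negative
#' fluxes are biologically interpretable as assay noise and are flagged,
#' not clipped.
#'
#' @param level_inhibited,level_vehicle normalized levels (same
#'   normalization; attach a `norm` attribute to assert it).
#' @return `inhibited - vehicle`, with attribute `negative` when < 0.
#' @export
lysosomal_flux <- function(level_inhibited, level_vehicle) {
  check_norm_tags(level_inhibited, level_vehicle)
  flux <- as.numeric(level_inhibited) - as.numeric(level_vehicle)
  if (any(flux < 0)) {
    message("negative lysosomal flux value(s) observed (assay noise)")
  }
  structure(flux, negative = any(flux < 0))
}

#' Level change after a treatment
#'
#' `level_post - level_pre`: e.g. the ferritin change 3 h after iron
#' chelation relative to the pre-treatment level (negative values indicate
#' degradation).
#'
#' @param level_post,level_pre normalized levels (same normalization).
#' @export
treatment_delta <- function(level_post, level_pre) {
  check_norm_tags(level_post, level_pre)
  as.numeric(level_post) - as.numeric(level_pre)
}

#' ChIP enrichment as percent of input
#'
#' `100 * ip / (input / input_fraction)`: the input signal is scaled up by
#' the fraction of chromatin it represents before expressing the IP signal
#' as a percentage. The dilution fraction must be supplied explicitly.
#'
#' @param ip_signal IP qPCR signal (>= 0).
#' @param input_signal input-control signal (> 0).
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return percent of input.
#' @export
percent_input <- function(ip_signal, input_signal, input_fraction) {
  if (missing(input_fraction)) {
    stop("input_fraction must be given explicitly (e.g. 0.01 for a 1% input)")
  }
  if (any(input_signal <= 0)) stop("input signal must be positive")
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must lie in (0, 1]")
  }
  100 * ip_signal / (input_signal / input_fraction)
}

#' Bisulfite-clone methylation summary
#'
#' Summarizes a clones-by-CpG matrix of methylation calls (the
#' closed/open-circle "lollipop" data): per-CpG percent methylation across
#' clones and the overall percent across all calls. For a complete matrix
#' the overall percent equals the mean of the per-CpG percents.
#'
#' @param calls logical or 0/1 matrix, clones in rows, CpG positions in
#'   columns (TRUE/1 = methylated).
#' @return list with `per_cpg` (named percent vector) and `overall`.
#' @export
clone_methylation_summary <- function(calls) {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1 || ncol(calls) < 1) {
    stop("clone matrix needs at least one clone and one CpG")
  }
  if (is.logical(calls)) calls <- calls * 1
  if (any(is.na(calls)) || !all(calls %in% c(0, 1))) {
    stop("clone matrix must contain only methylated/unmethylated calls")
  }
  per_cpg <- 100 * colMeans(calls)
  if (is.null(names(per_cpg))) {
    names(per_cpg) <- sprintf("CpG_%d", seq_len(ncol(calls)))
  }
  list(per_cpg = per_cpg, overall = 100 * mean(calls))
}

#' Pearson colocalization of two channels within a mask
#'
#' Pearson correlation between the pixel intensities of two channels,
#' restricted to a region mask (e.g. the cytoplasm of a single cell).
#' Requires at least two masked pixels and non-constant signal in both
#' channels.
#'
#' @param intensities_a,intensities_b numeric vectors/arrays of equal
#'   length.
#' @param mask logical selector of the same length (default: all pixels).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(intensities_a, intensities_b,
                                   mask = NULL) {
  a <- as.numeric(intensities_a)
  b <- as.numeric(intensities_b)
  if (length(a) != length(b)) stop("channels have different lengths")
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  mask <- as.logical(mask)
  if (length(mask) != length(a)) stop("mask length does not match channels")
  a <- a[mask]; b <- b[mask]
  if (length(a) < 2) stop("need at least 2 masked pixels")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("constant channel within mask; correlation undefined")
  }
  cor(a, b)
}
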