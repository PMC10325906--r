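# Seeded synthetic-data generator. Emulates the study design the pipeline
# was built for -- 3T3-L1 adipocyte differentiation with (DFO+) or without
# (DFO-) iron chelation -- producing every input the pipeline consumes,
# with planted ground truth: multi-condition multi-timepoint CpG
# methylomes with promoter demethylation planted in one condition only,
# peak sets with pre-induction and induced-only peaks, per-gene ChIP count
# tables following seven temporal prototypes, binned ChIP tracks with
# DMR-localized signal loss, and a truth manifest.

#' Simulation configuration
#'
#' Defaults describe the emulated study: two 1-Mb chromosomes carrying 200
#' genes (20% with two TSSs), merged-replicate WGBS depth around 30x with
#' a few deliberately under-/over-covered sites to exercise the depth
#' filter, high baseline promoter methylation (Beta(8,2), mean 80%),
#' Gaussian level noise of 3 percentage points, and 20 genes planted with
#' a 60-point promoter methylation drop at Day 8 in the untreated (DFO-)
#' condition only. ChIP counts follow 7 temporal prototypes across
#' (Day 0, Day 2 DFO-, Day 2 DFO+) with log2-scale noise 0.4 (about 0.2 on
#' the z-scale); binned Day-2 DFO- tracks carry exponential-decay signal
#' loss of depth 4 and length scale 400 bp at 40 DMR anchors.
#'
#' @param ... overrides for any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chroms = 2L, chrom_length = 1000000L,
    n_genes = 200L, frac_multi_tss = 0.2,
    promoter_cpg_spacing = 60L, background_cpg_spacing = 150L,
    coverage_mean = 30, coverage_size = 8,
    frac_low_cov = 0.05, frac_high_cov = 0.01,
    baseline_beta = c(8, 2), noise_sd = 3,
    n_planted = 20L, effect = 60, upstream_size = 1000L,
    n_baseline_peaks = 60L, n_induced_peaks = 40L,
    peak_width = c(200L, 800L),
    chip_amplitude = 2, chip_noise_sd = 0.4, chip_base_log2 = c(6, 10),
    n_chip_prototypes = 7L, tss_flank = 5000L,
    n_dmrs = 40L, dmr_width = c(600L, 1400L),
    dmr_depth = 4, dmr_scale = 400, chip_bin_size = 10L,
    track_base_mean = 5, track_base_sd = 0.5, track_noise_sd = 0.2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chroms),
           sprintf("chr%d", seq_len(config$n_chroms)))
}

#' Generate the gene annotation
#'
#' Places genes on evenly spaced slots across the chromosomes (jittered
#' TSSs, alternating coverage of both strands); the configured fraction of
#' genes receives a second TSS 1.5 kb downstream of the first. Output is
#' deterministic for a fixed config.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a [gene_table()]) and `chrom_sizes`.
#' @export
make_annotation <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  sizes <- sim_chrom_sizes(config)
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  slot <- config$chrom_length %/% per_chrom
  # slot must hold the +/-2 kb TSS jitter, the 1 kb upstream window and a
  # possible second TSS 1.5 kb downstream without neighbouring windows
  # ever overlapping
  if (slot < 8000) stop("genes do not fit: need at least 8 kb per gene slot")
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  chrom <- names(sizes)[(seq_len(config$n_genes) - 1L) %/% per_chrom + 1L]
  slot_i <- (seq_len(config$n_genes) - 1L) %% per_chrom
  tss1 <- slot_i * slot + slot %/% 2L +
    as.integer(round(runif(config$n_genes, -2000, 2000)))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  multi <- runif(config$n_genes) < config$frac_multi_tss
  tss <- lapply(seq_len(config$n_genes), function(i) {
    if (multi[i]) c(tss1[i], tss1[i] + 1500L) else tss1[i]
  })
  list(genes = gene_table(ids, chrom, strand, tss), chrom_sizes = sizes)
}

sim_cpg_positions <- function(config, annotation) {
  promoters <- upstream_windows(annotation$genes, size = config$upstream_size,
                                chrom_sizes = annotation$chrom_sizes)
  out <- list()
  for (ch in names(annotation$chrom_sizes)) {
    len <- annotation$chrom_sizes[[ch]]
    n_bg <- ceiling(len / config$background_cpg_spacing)
    gaps <- ceiling(rexp(n_bg, rate = 1 / config$background_cpg_spacing)) + 1L
    bg <- cumsum(gaps)
    bg <- bg[bg < len - 1L]
    pr <- promoters[promoters$chrom == ch, , drop = FALSE]
    dense <- unlist(lapply(seq_len(nrow(pr)), function(i) {
      seq(pr$start[i] + 5L, pr$end[i] - 1L, by = config$promoter_cpg_spacing)
    }), use.names = FALSE)
    out[[ch]] <- sort(unique(c(bg, as.integer(dense))))
  }
  out
}

#' Simulate the WGBS methylomes
#'
#' Emits one per-CpG track per (condition, timepoint) combination over a
#' shared CpG map: DFO- and DFO+ at Day 0 and Day 8. Every site draws a
#' baseline methylation level from the high-methylation Beta, adds
#' Gaussian level noise per track, and the planted genes' upstream-window
#' CpGs drop by the configured effect at Day 8 in the DFO- condition only.
#' Read depth is negative-binomial with deliberate below-5 and above-1000
#' outliers (outside planted windows), and methylated-read counts are
#' binomially sampled given level and depth, so reported levels carry
#' realistic sampling granularity.
#'
#' @param config a [sim_config()].
#' @param annotation output of [make_annotation()].
#' @return list with `tracks` (named list of [methylome_track()]) and
#'   `truth` (planted gene ids, affected condition/timepoint, windows).
#' @export
simulate_methylomes <- function(config = sim_config(),
                                annotation = make_annotation(config)) {
  set.seed(config$seed + 2L)
  genes <- annotation$genes
  planted <- sort(sample(genes$gene_id, config$n_planted))
  pos_by_chrom <- sim_cpg_positions(config, annotation)
  chrom <- rep(names(pos_by_chrom), lengths(pos_by_chrom))
  pos <- unlist(pos_by_chrom, use.names = FALSE)
  n <- length(pos)
  baseline <- rbeta(n, config$baseline_beta[1], config$baseline_beta[2]) * 100
  windows <- upstream_windows(genes[genes$gene_id %in% planted, , drop = FALSE],
                              size = config$upstream_size,
                              chrom_sizes = annotation$chrom_sizes)
  in_planted <- logical(n)
  for (i in seq_len(nrow(windows))) {
    in_planted <- in_planted | (chrom == windows$chrom[i] &
                                  pos >= windows$start[i] &
                                  pos < windows$end[i])
  }
  combos <- expand.grid(cond = c("DFOminus", "DFOplus"),
                        day = c("Day0", "Day8"), stringsAsFactors = FALSE)
  tracks <- list()
  for (k in seq_len(nrow(combos))) {
    cond <- combos$cond[k]; day <- combos$day[k]
    level <- baseline + rnorm(n, 0, config$noise_sd)
    if (cond == "DFOminus" && day == "Day8") {
      level[in_planted] <- level[in_planted] - config$effect
    }
    level <- pmin(pmax(level, 0), 100)
    coverage <- rnbinom(n, mu = config$coverage_mean,
                        size = config$coverage_size)
    # deliberate depth-filter casualties, kept out of planted windows
    u <- runif(n)
    low <- u < config$frac_low_cov & !in_planted
    high <- u >= config$frac_low_cov &
      u < config$frac_low_cov + config$frac_high_cov & !in_planted
    coverage[low] <- sample(0:4, sum(low), replace = TRUE)
    coverage[high] <- 1001L + sample(0:200, sum(high), replace = TRUE)
    coverage <- pmax(coverage, 1L)
    n_meth <- rbinom(n, coverage, level / 100)
    label <- paste0(day, "-", cond)
    tracks[[label]] <- methylome_track(
      data.frame(chrom = chrom, pos = pos,
                 meth = 100 * n_meth / coverage, n_meth = n_meth,
                 n_unmeth = coverage - n_meth, stringsAsFactors = FALSE),
      label = label)
  }
  list(tracks = tracks,
       truth = list(planted_genes = planted, affected_condition = "DFOminus",
                    affected_timepoint = "Day8", effect = config$effect,
                    planted_windows = windows))
}

#' Simulate peak sets per timepoint
#'
#' Baseline peaks are present from Day 0 onward; induced-only peaks appear
#' from Day 2. Peaks are placed on disjoint slots (>= 1 kb apart) so that
#' merging never fuses distinct peaks and the differentiation-specific
#' subtraction recovers exactly the induced set.
#'
#' @param config a [sim_config()].
#' @return list with `peaks` (named list of [genomic_intervals()] per
#'   timepoint: Day0, Day2, Day4) and `truth` (the induced-only peaks).
#' @export
simulate_peaks <- function(config = sim_config()) {
  set.seed(config$seed + 3L)
  sizes <- sim_chrom_sizes(config)
  n_total <- config$n_baseline_peaks + config$n_induced_peaks
  per_chrom <- ceiling(n_total / config$n_chroms)
  slot <- config$chrom_length %/% per_chrom
  if (slot < max(config$peak_width) + 2000L) {
    stop("peaks do not fit without risking overlap")
  }
  chrom <- names(sizes)[(seq_len(n_total) - 1L) %/% per_chrom + 1L]
  slot_i <- (seq_len(n_total) - 1L) %% per_chrom
  width <- as.integer(round(runif(n_total, config$peak_width[1],
                                  config$peak_width[2])))
  start <- slot_i * slot + 1000L +
    as.integer(round(runif(n_total, 0, slot - max(config$peak_width) - 2000L)))
  induced <- sample(c(rep(FALSE, config$n_baseline_peaks),
                      rep(TRUE, config$n_induced_peaks)))
  name <- ifelse(induced, sprintf("induced_%03d", cumsum(induced)),
                 sprintf("baseline_%03d", cumsum(!induced)))
  all_peaks <- genomic_intervals(chrom, start, start + width, name = name)
  induced_names <- name[induced]
  is_ind <- all_peaks$name %in% induced_names
  peaks <- list(Day0 = all_peaks[!is_ind, , drop = FALSE],
                Day2 = all_peaks,
                Day4 = all_peaks)
  peaks <- lapply(peaks, function(p) { rownames(p) <- NULL; p })
  list(peaks = peaks,
       truth = list(induced_peaks = all_peaks[is_ind, , drop = FALSE]))
}

chip_prototypes <- function(k = 7L) {
  # k points on the circle of row-z-scored 3-vectors (mean 0, sd 1):
  # sqrt(2) * (cos(theta) e1 + sin(theta) e2) with an orthonormal basis of
  # the mean-zero plane; distinct angles give distinct temporal shapes
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  proto <- sqrt(2) * (outer(cos(theta), e1) + outer(sin(theta), e2))
  colnames(proto) <- c("Day0", "Day2_DFOminus", "Day2_DFOplus")
  rownames(proto) <- sprintf("prototype_%d", seq_len(k))
  proto
}

#' Simulate ChIP-seq inputs
#'
#' Two artifacts: (1) a per-gene count table over three conditions
#' (Day 0, Day 2 DFO-, Day 2 DFO+) in duplicate, where every gene follows
#' one of seven temporal prototypes on the log2 scale with multiplicative
#' noise and counts scale with the gene's merged TSS-region length; and
#' (2) binned genome-wide signal tracks for Day 0 and Day 2 DFO- in which
#' exponential-decay signal loss is written around DMR anchors in the
#' Day 2 DFO- track only.
#'
#' @param config a [sim_config()].
#' @param annotation output of [make_annotation()].
#' @return list with `counts` (genes x 6 matrix), `lengths` (merged TSS
#'   region length per gene), `tracks` (raw [binned_track()]s `Day0`,
#'   `Day2_DFOminus`), `dmrs` ([genomic_intervals()]), and `truth`
#'   (per-gene prototype labels, prototype matrix, DMR effect).
#' @export
simulate_chip <- function(config = sim_config(),
                          annotation = make_annotation(config)) {
  set.seed(config$seed + 4L)
  genes <- annotation$genes
  n <- nrow(genes)
  proto <- chip_prototypes(config$n_chip_prototypes)
  labels <- setNames(rep(seq_len(config$n_chip_prototypes), length.out = n),
                     genes$gene_id)
  regions <- tss_regions(genes, flank = config$tss_flank, merge = TRUE,
                         chrom_sizes = annotation$chrom_sizes)
  len <- regions$lengths[genes$gene_id]
  base <- runif(n, config$chip_base_log2[1], config$chip_base_log2[2])
  samples <- c("Day0", "Day2_DFOminus", "Day2_DFOplus")
  counts <- matrix(0L, nrow = n, ncol = 6,
                   dimnames = list(genes$gene_id,
                                   paste0(rep(samples, each = 2),
                                          "_rep", 1:2)))
  for (j in seq_along(samples)) {
    for (r in 1:2) {
      lg <- base + config$chip_amplitude * proto[labels, j] +
        rnorm(n, 0, config$chip_noise_sd)
      counts[, 2 * (j - 1) + r] <- as.integer(round((len / 1000) * 2^lg))
    }
  }
  # DMR anchors on dedicated slots, clear of chromosome ends
  sizes <- annotation$chrom_sizes
  per_chrom <- ceiling(config$n_dmrs / config$n_chroms)
  slot <- (config$chrom_length - 20000L) %/% per_chrom
  dm_chrom <- names(sizes)[(seq_len(config$n_dmrs) - 1L) %/% per_chrom + 1L]
  dm_slot <- (seq_len(config$n_dmrs) - 1L) %% per_chrom
  dm_width <- as.integer(round(runif(config$n_dmrs, config$dmr_width[1],
                                     config$dmr_width[2])))
  dm_center <- 10000L + dm_slot * slot + slot %/% 2L
  dmrs <- genomic_intervals(dm_chrom, dm_center - dm_width %/% 2L,
                            dm_center - dm_width %/% 2L + dm_width,
                            name = sprintf("dmr_%03d", seq_len(config$n_dmrs)))
  bs <- config$chip_bin_size
  mk_base <- function() {
    lapply(sizes, function(l) {
      nb <- ceiling(l / bs)
      rgamma(nb, shape = (config$track_base_mean / config$track_base_sd)^2,
             rate = config$track_base_mean / config$track_base_sd^2)
    })
  }
  shared <- mk_base()
  noise <- function(v) pmax(v + rnorm(length(v), 0, config$track_noise_sd), 0)
  day0 <- lapply(shared, noise)
  day2 <- shared
  ctr <- anchor_centers(dmrs)
  for (i in seq_len(config$n_dmrs)) {
    ch <- dmrs$chrom[i]
    v <- day2[[ch]]
    bins <- seq(max(1, (ctr[i] - 3 * config$dmr_scale * 4) %/% bs),
                min(length(v), (ctr[i] + 3 * config$dmr_scale * 4) %/% bs))
    centers <- (bins - 0.5) * bs
    v[bins] <- v[bins] -
      config$dmr_depth * exp(-abs(centers - ctr[i]) / config$dmr_scale)
    day2[[ch]] <- v
  }
  day2 <- lapply(day2, noise)
  tracks <- list(Day0 = binned_track(day0, bs, norm = "raw"),
                 Day2_DFOminus = binned_track(day2, bs, norm = "raw"))
  list(counts = signal_matrix(counts, stage = "raw"),
       lengths = regions$lengths, tracks = tracks, dmrs = dmrs,
       truth = list(cluster_labels = labels, prototypes = proto,
                    dmr_depth = config$dmr_depth,
                    dmr_scale = config$dmr_scale))
}

#' Write a complete synthetic dataset to disk
#'
#' Runs all generators and writes the directory layout the pipeline
#' expects: annotation and chromosome sizes, four methylome bedGraphs,
#' three peak BED files, the ChIP count table, two binned ChIP bedGraphs,
#' the DMR BED, and `truth.json` with the planted ground truth. A fixed
#' config (including its seed) yields a byte-identical file tree.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) list with `paths` of all written files and `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- make_annotation(config)
  meth <- simulate_methylomes(config, ann)
  pk <- simulate_peaks(config)
  chip <- simulate_chip(config, ann)
  p <- list()
  p$genes <- file.path(out_dir, "genes.tsv")
  write_genes(ann$genes, p$genes)
  p$chrom_sizes <- file.path(out_dir, "chrom_sizes.tsv")
  writeLines(sprintf("%s\t%d", names(ann$chrom_sizes), ann$chrom_sizes),
             con <- file(p$chrom_sizes, "wb")); close(con)
  for (label in names(meth$tracks)) {
    f <- file.path(out_dir, sprintf("methylome_%s.bedgraph", label))
    write_methylome_bedgraph(meth$tracks[[label]], f)
    p[[paste0("methylome_", label)]] <- f
  }
  for (tp in names(pk$peaks)) {
    f <- file.path(out_dir, sprintf("peaks_%s.bed", tp))
    write_intervals_bed(pk$peaks[[tp]], f)
    p[[paste0("peaks_", tp)]] <- f
  }
  p$chip_counts <- file.path(out_dir, "chip_counts.tsv")
  write_count_table(chip$counts, p$chip_counts, id_col = "gene_id")
  for (tr in names(chip$tracks)) {
    f <- file.path(out_dir, sprintf("chip_%s.bedgraph", tr))
    write_binned_bedgraph(chip$tracks[[tr]], f)
    p[[paste0("chip_", tr)]] <- f
  }
  p$dmrs <- file.path(out_dir, "dmrs.bed")
  write_intervals_bed(chip$dmrs, p$dmrs)
  truth <- list(
    planted_genes = meth$truth$planted_genes,
    affected_condition = meth$truth$affected_condition,
    affected_timepoint = meth$truth$affected_timepoint,
    effect = meth$truth$effect,
    induced_peaks = chip_truth_peaks(pk$truth$induced_peaks),
    cluster_labels = as.list(chip$truth$cluster_labels),
    n_dmrs = nrow(chip$dmrs))
  p$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, p$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = p, truth = truth, config = config))
}

chip_truth_peaks <- function(peaks) {
  lapply(seq_len(nrow(peaks)), function(i) {
    list(chrom = peaks$chrom[i], start = peaks$start[i], end = peaks$end[i],
         name = peaks$name[i])
  })
}
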