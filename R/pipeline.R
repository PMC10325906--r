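# End-to-end pipeline: chains the promoter/enhancer demethylation screens,
# the condition contrast, temporal ChIP clustering, and DMR-anchored
# aggregation over a directory of inputs, writing per-stage TSVs, a
# machine-readable summary and the resolved configuration.

#' Default pipeline configuration
#'
#' Numeric knobs default to the analysis parameters the pipeline is built
#' around: coverage bounds 5-1000, methylation drop > 50 points at >= 3
#' CpGs, 1 kb upstream promoter windows, +/-500 bp enhancer windows,
#' TSS +/-5 kb ChIP regions, +/-3 kb DMR aggregation at 10-bp bins,
#' 7 clusters with fuzzifier 2.
#'
#' @param ... overrides for any default field.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_cov = 5L, max_cov = 1000L, drop = 50, min_cpgs = 3L,
              upstream = 1000L, enhancer_flank = 500L, tss_flank = 5000L,
              aggregate_flank = 3000L, bin = 10L,
              clusters = 7L, fuzzifier = 2, cv_min = 0.2, seed = 1L,
              nstart = 5L, dmin_scan = integer(0))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline_config field(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) format(col, trim = TRUE,
                                           scientific = FALSE, digits = 12)
               else as.character(col)
             }), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

hits_table <- function(hits) {
  sites <- attr(hits, "sites")
  data.frame(
    region_id = hits$region_id, n_qualifying = hits$n_qualifying,
    qualifying = vapply(hits$region_id, function(id) {
      s <- sites[[id]]
      paste(sprintf("%s:%d:%.1f", s$chrom, s$pos, s$delta), collapse = ",")
    }, character(1)), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Expects the layout written by [simulate_dataset()] (or equivalently
#' named real inputs): `genes.tsv`, `chrom_sizes.tsv`, four
#' `methylome_<Day>-<condition>.bedgraph` tracks, `peaks_Day*.bed`,
#' `chip_counts.tsv`, `chip_Day0.bedgraph` / `chip_Day2_DFOminus.bedgraph`,
#' and `dmrs.bed`. Stages: (1) promoter screen per condition and the
#' DFO- vs DFO+ contrast; (2) enhancer construction (merge, center
#' windows, Day-0 subtraction) and the enhancer screen; (3) ChIP
#' normalization and fuzzy c-means clustering of mean replicate CPM;
#' (4) DMR-anchored aggregation of ChIP signal change and methylation
#' change. Outputs per-stage TSVs, `summary.json`, and the resolved
#' config (`config_used.yaml`) into `out_dir`. Identical inputs and
#' config yield identical outputs.
#'
#' @param data_dir input directory.
#' @param out_dir output directory (created; write-once per run).
#' @param config a [pipeline_config()] list or a path to a YAML file of
#'   overrides.
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(data_dir, out_dir, config = pipeline_config()) {
  if (is.character(config) && length(config) == 1) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  need <- function(f) {
    path <- file.path(data_dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    path
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  genes <- read_genes(need("genes.tsv"))
  chrom_sizes <- read_chrom_sizes(need("chrom_sizes.tsv"))
  say("annotation: %d genes, %d chromosomes", nrow(genes),
      length(chrom_sizes))

  # --- stage 1: promoter demethylation screens and contrast -------------
  tracks <- lapply(c(base_minus = "methylome_Day0-DFOminus.bedgraph",
                     later_minus = "methylome_Day8-DFOminus.bedgraph",
                     base_plus = "methylome_Day0-DFOplus.bedgraph",
                     later_plus = "methylome_Day8-DFOplus.bedgraph"),
                   function(f) read_methylome_bedgraph(need(f)))
  promoters <- upstream_windows(genes, size = config$upstream,
                                chrom_sizes = chrom_sizes)
  screen_one <- function(base, later, label) {
    say("%s: %d/%d CpGs read", label, nrow(base), nrow(later))
    deltas <- methylation_delta(base, later, config$min_cov, config$max_cov)
    say("%s: %d CpGs pass coverage in both timepoints", label, nrow(deltas))
    hits <- screen_windows(promoters, deltas, drop_gt = config$drop,
                           min_sites = config$min_cpgs)
    say("%s: %d hit regions (>= %d CpGs dropping > %g points)", label,
        nrow(hits), config$min_cpgs, config$drop)
    list(deltas = deltas, hits = hits)
  }
  scr_minus <- screen_one(tracks$base_minus, tracks$later_minus, "DFO-")
  scr_plus <- screen_one(tracks$base_plus, tracks$later_plus, "DFO+")
  contrast <- condition_contrast(scr_minus$hits, scr_plus$hits,
                                 "DFO-", "DFO+")
  write_tsv(hits_table(scr_minus$hits),
            file.path(out_dir, "tss_hits_DFOminus.tsv"))
  write_tsv(hits_table(scr_plus$hits),
            file.path(out_dir, "tss_hits_DFOplus.tsv"))
  contrast_df <- data.frame(
    region_id = c(contrast$only_a, contrast$shared, contrast$only_b),
    set = c(rep("DFO-_only", length(contrast$only_a)),
            rep("shared", length(contrast$shared)),
            rep("DFO+_only", length(contrast$only_b))),
    stringsAsFactors = FALSE)
  write_tsv(contrast_df, file.path(out_dir, "tss_contrast.tsv"))

  # --- stage 2: enhancer construction and screen ------------------------
  peak_files <- list.files(data_dir, pattern = "^peaks_.*\\.bed$",
                           full.names = TRUE)
  if (length(peak_files) == 0) stop("missing input file: peaks_*.bed")
  peak_sets <- lapply(sort(peak_files), read_intervals_bed)
  names(peak_sets) <- sub("^peaks_(.*)\\.bed$", "\\1",
                          basename(sort(peak_files)))
  merged <- merge_intervals(do.call(rbind, lapply(peak_sets, function(p) {
    p[, c("chrom", "start", "end", "strand")]
  })))
  say("peaks: %d merged across %d timepoints", nrow(merged),
      length(peak_sets))
  merged$name <- sprintf("peak_%05d", seq_len(nrow(merged)))
  enhancers_all <- center_windows(merged, flank = config$enhancer_flank,
                                  chrom_sizes = chrom_sizes)
  diffspec <- differentiation_specific(merged, peak_sets[["Day0"]])
  enhancers_diff <- center_windows(diffspec, flank = config$enhancer_flank,
                                   chrom_sizes = chrom_sizes)
  say("enhancers: %d all, %d differentiation-specific", nrow(enhancers_all),
      nrow(enhancers_diff))
  enh_hits <- screen_windows(enhancers_diff, scr_minus$deltas,
                             drop_gt = config$drop,
                             min_sites = config$min_cpgs)
  write_intervals_bed(enhancers_all, file.path(out_dir, "enhancers_all.bed"))
  write_intervals_bed(enhancers_diff,
                      file.path(out_dir, "enhancers_diffspec.bed"))
  write_tsv(hits_table(enh_hits), file.path(out_dir, "enhancer_hits.tsv"))

  # --- stage 3: ChIP clustering -----------------------------------------
  counts <- read_count_table(need("chip_counts.tsv"))
  cpm <- cpm_normalize(counts)
  samples <- unique(sub("_rep[0-9]+$", "", colnames(cpm)))
  mean_cpm <- vapply(samples, function(s) {
    rowMeans(unclass(cpm)[, sub("_rep[0-9]+$", "", colnames(cpm)) == s,
                          drop = FALSE])
  }, numeric(nrow(cpm)))
  regions <- tss_regions(genes, flank = config$tss_flank, merge = TRUE,
                         chrom_sizes = chrom_sizes)
  lmat <- length_normalize(signal_matrix(mean_cpm, "cpm"), regions$lengths)
  filt <- cv_filter(lmat, cv_min = config$cv_min)
  say("clustering: %d/%d genes pass CV >= %g", nrow(filt), nrow(lmat),
      config$cv_min)
  z <- log2_zscore(filt)
  model <- fuzzy_cmeans(z, c = config$clusters, m = config$fuzzifier,
                        seed = config$seed, nstart = config$nstart)
  labels <- hard_assign(model)
  say("clustering: %d clusters, Dmin = %.4f, %s", model$c, model$dmin,
      if (model$converged) "converged" else "iteration cap reached")
  write_count_table(model$membership,
                    file.path(out_dir, "cluster_membership.tsv"),
                    id_col = "gene_id")
  write_count_table(model$centroids,
                    file.path(out_dir, "cluster_centroids.tsv"),
                    id_col = "cluster")
  write_tsv(data.frame(gene_id = names(labels), cluster = unname(labels)),
            file.path(out_dir, "cluster_labels.tsv"))
  if (length(config$dmin_scan) > 0) {
    write_tsv(dmin_curve(z, config$dmin_scan, m = config$fuzzifier,
                         seed = config$seed),
              file.path(out_dir, "dmin_curve.tsv"))
  }

  # --- stage 4: DMR-anchored aggregation --------------------------------
  dmrs <- read_intervals_bed(need("dmrs.bed"))
  t0 <- cpm_normalize_track(read_binned_bedgraph(
    need("chip_Day0.bedgraph"), config$bin, chrom_sizes))
  t2 <- cpm_normalize_track(read_binned_bedgraph(
    need("chip_Day2_DFOminus.bedgraph"), config$bin, chrom_sizes))
  delta_track <- signal_change(t2, t0)
  chip_profile <- profile_around_anchors(delta_track, dmrs,
                                         flank = config$aggregate_flank)
  meth_profile <- methylation_profile(scr_minus$deltas, dmrs,
                                      flank = config$aggregate_flank,
                                      bin_size = config$bin)
  write_tsv(as.data.frame(chip_profile),
            file.path(out_dir, "dmr_chip_profile.tsv"))
  write_tsv(as.data.frame(meth_profile),
            file.path(out_dir, "dmr_methylation_profile.tsv"))
  say("aggregation: %d DMR anchors, ChIP profile minimum %.3f at offset %d",
      nrow(dmrs), min(chip_profile$value),
      as.integer(chip_profile$offset[which.min(chip_profile$value)]))

  summary <- list(
    n_genes = nrow(genes),
    tss_hits = list(`DFO-` = nrow(scr_minus$hits),
                    `DFO+` = nrow(scr_plus$hits)),
    contrast = list(`DFO-_only` = length(contrast$only_a),
                    `DFO+_only` = length(contrast$only_b),
                    shared = length(contrast$shared)),
    merged_peaks = nrow(merged),
    enhancers_all = nrow(enhancers_all),
    enhancers_diffspec = nrow(enhancers_diff),
    enhancer_hits = nrow(enh_hits),
    clustered_genes = nrow(z),
    cluster_sizes = as.list(table(factor(labels,
                                         levels = seq_len(model$c)))),
    dmin = model$dmin,
    chip_profile_min_offset =
      as.integer(chip_profile$offset[which.min(chip_profile$value)]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  resolved <- config
  yaml::write_yaml(resolved, file.path(out_dir, "config_used.yaml"))
  writeLines(log_lines, con <- file(file.path(out_dir, "pipeline.log"),
                                    "wb")); close(con)
  invisible(summary)
}
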