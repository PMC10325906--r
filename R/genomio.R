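#' @importFrom stats rnorm runif rbinom rnbinom rbeta rexp rgamma sd cor dist setNames
#' @importFrom utils read.table write.table head
NULL

# All coordinates in this package are 0-based half-open (BED/bedGraph
# convention). A single CpG at position p occupies [p, p + 1).

#' Construct a per-CpG methylome track
#'
#' A methylome track is a data frame of CpG sites, one row per cytosine,
#' sorted by (chromosome, position) with no duplicate positions. Methylation
#' is expressed in percent; coverage, when defined, is the total read depth
#' (`n_meth + n_unmeth` when counts are present).
#'
#' @param sites data frame with columns `chrom`, `pos`, `meth` and optionally
#'   `n_meth`, `n_unmeth` (both or neither).
#' @param label condition/timepoint identifier, e.g. `"Day8-DFO"`.
#' @return A `methylome_track` data frame with a `coverage` column when
#'   counts are present.
#' @export
methylome_track <- function(sites, label = "track") {
  stopifnot(is.data.frame(sites))
  needed <- c("chrom", "pos", "meth")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0) {
    stop("methylome track is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$meth <- as.numeric(sites$meth)
  if (any(!is.finite(sites$meth)) || any(sites$meth < 0 | sites$meth > 100)) {
    stop("methylation levels must be finite and within [0, 100]")
  }
  has_counts <- all(c("n_meth", "n_unmeth") %in% names(sites))
  if (has_counts) {
    sites$n_meth <- as.integer(sites$n_meth)
    sites$n_unmeth <- as.integer(sites$n_unmeth)
    if (any(sites$n_meth < 0) || any(sites$n_unmeth < 0)) {
      stop("read counts must be non-negative")
    }
    sites$coverage <- sites$n_meth + sites$n_unmeth
    pos_cov <- sites$coverage > 0
    mismatch <- pos_cov &
      abs(sites$meth - 100 * sites$n_meth / pmax(sites$coverage, 1L)) > 0.5
    if (any(mismatch)) {
      i <- which(mismatch)[1]
      stop(sprintf(
        "methylation level inconsistent with counts at %s:%d (%.3f vs %.3f)",
        sites$chrom[i], sites$pos[i], sites$meth[i],
        100 * sites$n_meth[i] / sites$coverage[i]))
    }
  }
  # lexicographic chromosome, numeric position: deterministic across locales
  ord <- order(sites$chrom, sites$pos, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    # identical duplicate records collapse silently; conflicting ones error
    full_key <- if (has_counts) {
      paste(key, sites$meth, sites$n_meth, sites$n_unmeth)
    } else paste(key, sites$meth)
    if (length(unique(full_key)) != length(unique(key))) {
      for (k in unique(key[duplicated(key)])) {
        if (length(unique(full_key[key == k])) > 1) {
          stop("conflicting duplicate CpG records at ", sub(" ", ":", k))
        }
      }
    }
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  rownames(sites) <- NULL
  structure(sites, label = label,
            class = c("methylome_track", "data.frame"))
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf("methylome track '%s': %d CpG sites on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(head(as.data.frame(x)), ...)
  invisible(x)
}

track_label <- function(track) attr(track, "label") %||% "track"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-CpG methylation bedGraph
#'
#' Two dialects are supported: `counts6`
#' (chrom, start, end, meth%, n_meth, n_unmeth — the canonical internal
#' dialect, carrying read depth) and `level4` (chrom, start, end, meth%;
#' coverage undefined). Records must span exactly 1 bp; `track` and `#`
#' header lines are skipped. Coverage-dependent screens reject `level4`
#' tracks with a clear error.
#'
#' @param path path to a bedGraph file.
#' @param dialect `"counts6"` or `"level4"`.
#' @param label track label; defaults to the file name.
#' @return A [methylome_track()].
#' @export
read_methylome_bedgraph <- function(path, dialect = c("counts6", "level4"),
                                    label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^track|^#|^\\s*$", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(methylome_track(
      data.frame(chrom = character(), pos = integer(), meth = numeric()),
      label = label %||% basename(path)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- if (dialect == "counts6") 6L else 4L
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    bad <- idx[which(nf < ncols)[1]]
    stop(sprintf("malformed bedGraph line %d in %s: expected %d columns",
                 bad, path, ncols))
  }
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncols))),
              ncol = ncols, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  meth <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(meth))
  if (length(bad) > 0) {
    stop(sprintf("malformed bedGraph line %d in %s: non-numeric field",
                 idx[bad[1]], path))
  }
  if (any(end - start != 1L)) {
    b <- which(end - start != 1L)[1]
    stop(sprintf("line %d in %s: record spans %d bp; per-CpG tracks must span 1 bp",
                 idx[b], path, end[b] - start[b]))
  }
  if (any(meth < 0 | meth > 100)) {
    b <- which(meth < 0 | meth > 100)[1]
    stop(sprintf("line %d in %s: methylation level %.3f outside [0, 100]",
                 idx[b], path, meth[b]))
  }
  sites <- data.frame(chrom = m[, 1], pos = start, meth = meth,
                      stringsAsFactors = FALSE)
  if (dialect == "counts6") {
    n_meth <- suppressWarnings(as.integer(m[, 5]))
    n_unmeth <- suppressWarnings(as.integer(m[, 6]))
    bad <- which(is.na(n_meth) | is.na(n_unmeth))
    if (length(bad) > 0) {
      stop(sprintf("malformed bedGraph line %d in %s: non-integer count",
                   idx[bad[1]], path))
    }
    sites$n_meth <- n_meth
    sites$n_unmeth <- n_unmeth
  }
  methylome_track(sites, label = label %||% basename(path))
}

#' Write a per-CpG methylation bedGraph
#'
#' Output is tab-separated, LF-terminated, sorted, with methylation printed
#' to six decimals; re-reading with [read_methylome_bedgraph()] recovers the
#' track, and write-read-write is byte-stable.
#'
#' @param track a [methylome_track()].
#' @param path output path.
#' @param dialect `"counts6"` (requires counts) or `"level4"`.
#' @export
write_methylome_bedgraph <- function(track, path,
                                     dialect = c("counts6", "level4")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "methylome_track"))
  if (dialect == "counts6" && !all(c("n_meth", "n_unmeth") %in% names(track))) {
    stop("counts6 dialect requires n_meth/n_unmeth columns")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(track) == 0) return(invisible(path))
  out <- if (dialect == "counts6") {
    sprintf("%s\t%d\t%d\t%.6f\t%d\t%d", track$chrom, track$pos,
            track$pos + 1L, track$meth, track$n_meth, track$n_unmeth)
  } else {
    sprintf("%s\t%d\t%d\t%.6f", track$chrom, track$pos, track$pos + 1L,
            track$meth)
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Construct a set of genomic intervals
#'
#' @param chrom,start,end vectors of equal length; 0-based half-open.
#' @param strand optional; entries in `+`, `-` or `.` (unknown).
#' @param name,score optional label and numeric score.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   validate `end`.
#' @return A `genomic_intervals` data frame.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                              score = NULL, chrom_sizes = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end))) stop("non-integer interval coordinates")
  if (any(start < 0)) stop("interval start < 0")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("invalid interval %s:[%d, %d): start must be < end",
                 chrom[i], start[i], end[i]))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df$strand <- if (is.null(strand)) rep(".", nrow(df)) else {
    s <- as.character(strand)
    if (!all(s %in% c("+", "-", "."))) stop("strand must be +, - or .")
    s
  }
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[df$chrom])
    over <- !is.na(lim) & df$end > lim
    if (any(over)) {
      i <- which(over)[1]
      stop(sprintf("interval %s:[%d, %d) extends past chromosome end (%d)",
                   df$chrom[i], df$start[i], df$end[i], lim[i]))
    }
  }
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("genomic_intervals", "data.frame"))
}

#' Read intervals from a BED file (BED3 up to BED6)
#'
#' Column 4 is taken as the interval name, column 5 as a numeric score
#' (`.` allowed) and column 6 as the strand; absent columns yield
#' unknown strand and no name/score.
#'
#' @param path path to a BED file.
#' @return A [genomic_intervals()] data frame.
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^track|^browser|^#|^\\s*$", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                 idx[which(nf < 3)[1]], path))
  }
  nmax <- min(max(nf), 6L)
  get <- function(j) vapply(fields, function(f) {
    if (length(f) >= j) f[j] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 idx[bad[1]], path))
  }
  name <- if (nmax >= 4) get(4) else NULL
  score <- if (nmax >= 5) {
    s <- get(5)
    suppressWarnings(as.numeric(ifelse(s == "." | is.na(s), NA, s)))
  } else NULL
  strand <- if (nmax >= 6) {
    s <- get(6)
    ifelse(is.na(s) | !(s %in% c("+", "-")), ".", s)
  } else NULL
  genomic_intervals(get(1), start, end, strand = strand, name = name,
                    score = score)
}

#' Write intervals to a BED file
#'
#' Emits BED3 plus whatever of name/score/strand the interval set carries,
#' tab-separated with `.` placeholders so columns stay positional.
#'
#' @param intervals a [genomic_intervals()] data frame.
#' @param path output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(intervals) == 0) return(invisible(path))
  has_name <- "name" %in% names(intervals)
  has_score <- "score" %in% names(intervals)
  has_strand <- any(intervals$strand != ".")
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(if (has_name) intervals$name else rep(".", nrow(intervals))))
  }
  if (has_score || has_strand) {
    sc <- if (has_score) {
      ifelse(is.na(intervals$score), ".", format(intervals$score, trim = TRUE,
                                                 scientific = FALSE))
    } else rep(".", nrow(intervals))
    cols <- c(cols, list(sc))
  }
  if (has_strand) cols <- c(cols, list(intervals$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated columns: gene id, chromosome, strand (+ or -), and a
#' comma-separated list of 0-based TSS coordinates (genes may have several
#' TSSs, overlapping or discrete).
#'
#' @param path path to the TSV annotation.
#' @return A `gene_table` data frame with a list-column `tss`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^\\s*$", lines)]
  if (length(lines) == 0) {
    return(gene_table(character(), character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop("gene table rows need 4 columns: gene_id, chrom, strand, tss list")
  }
  tss <- lapply(fields, function(f) {
    v <- suppressWarnings(as.integer(strsplit(f[4], ",", fixed = TRUE)[[1]]))
    if (length(v) == 0 || any(is.na(v))) {
      stop("gene ", f[1], ": empty or non-integer TSS list")
    }
    sort(v)
  })
  gene_table(vapply(fields, `[`, "", 1), vapply(fields, `[`, "", 2),
             vapply(fields, `[`, "", 3), tss)
}

#' Construct a gene table
#'
#' @param gene_id,chrom,strand character vectors; strand must be + or -.
#' @param tss list of integer vectors of 0-based TSS coordinates, one per gene.
#' @export
gene_table <- function(gene_id, chrom, strand, tss) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1])
  }
  if (length(gene_id) > 0 && !all(strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (any(lengths(tss) == 0)) stop("every gene needs at least one TSS")
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df$tss <- lapply(tss, function(v) sort(as.integer(v)))
  structure(df, class = c("gene_table", "data.frame"))
}

#' Write a gene annotation table
#'
#' @param genes a [gene_table()].
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(genes) == 0) return(invisible(path))
  out <- sprintf("%s\t%s\t%s\t%s", genes$gene_id, genes$chrom, genes$strand,
                 vapply(genes$tss, function(v) paste(v, collapse = ","), ""))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a region-by-sample count table
#'
#' First row holds sample names, first column region/gene ids; counts must
#' be non-negative numbers. Row and column order are preserved.
#'
#' @param path path to the TSV table.
#' @return A numeric matrix with `stage` attribute `"raw"`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (anyDuplicated(df[[1]])) {
    stop("duplicated row id in count table: ", df[[1]][duplicated(df[[1]])][1])
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count in ", path)
  if (any(m < 0)) stop("negative count in ", path)
  rownames(m) <- ids
  signal_matrix(m, stage = "raw")
}

#' Write a count/signal table
#'
#' @param mat a matrix with row and column names.
#' @param path output path.
#' @param id_col header for the id column.
#' @export
write_count_table <- function(mat, path, id_col = "region_id") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            format(mat[i, ], trim = TRUE, scientific = FALSE, digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
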