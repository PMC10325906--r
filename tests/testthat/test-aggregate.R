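sizes <- c(chrP = 20000L, chrQ = 15000L)

test_that("binned bedGraph round trip restores the track with zero bins", {
  set.seed(51)
  tr <- random_binned_track(sizes, bin_size = 10, norm = "raw")
  tr$values$chrP[5:10] <- 0   # omitted on write, restored as zero
  f <- withr::local_tempfile()
  write_binned_bedgraph(tr, f)
  back <- read_binned_bedgraph(f, 10, sizes, norm = "raw")
  expect_equal(back$values$chrP, tr$values$chrP, tolerance = 1e-6)
  expect_equal(back$values$chrQ, tr$values$chrQ, tolerance = 1e-6)
})

test_that("track CPM normalization scales the total to one million", {
  set.seed(52)
  tr <- random_binned_track(sizes, norm = "raw")
  cpm <- cpm_normalize_track(tr)
  expect_equal(sum(unlist(cpm$values)), 1e6)
  expect_equal(cpm$norm, "cpm")
})

test_that("signal change subtracts per bin and is antisymmetric", {
  set.seed(53)
  a <- random_binned_track(sizes)
  b <- random_binned_track(sizes)
  d <- signal_change(a, b)
  expect_equal(d$values$chrP, a$values$chrP - b$values$chrP)
  r <- signal_change(b, a)
  expect_equal(d$values$chrP, -r$values$chrP)
  expect_equal(d$values$chrQ, -r$values$chrQ)
  # identical tracks give an all-zero delta
  z <- signal_change(a, a)
  expect_true(all(unlist(z$values) == 0))
  # mismatched binning or extent errors
  expect_error(signal_change(a, random_binned_track(sizes, bin_size = 20)),
               "bin sizes")
  expect_error(signal_change(a, random_binned_track(c(chrP = 20000L))),
               "chromosomes")
  expect_error(signal_change(a, random_binned_track(sizes, norm = "raw")),
               "CPM")
})

test_that("profiles around anchors equal the naive per-anchor loop", {
  set.seed(54)
  for (rep in 1:5) {
    tr <- random_binned_track(sizes)
    start <- sample(3000:10000, 20)
    anchors <- genomic_intervals(sample(names(sizes), 20, TRUE), start,
                                 start + sample(100:900, 20, TRUE))
    for (skip in c(FALSE, TRUE)) {
      got <- profile_around_anchors(tr, anchors, flank = 2000,
                                    skip_zero_anchors = skip)
      want <- naive_profile(tr, anchors, flank = 2000, skip_zero = skip)
      expect_equal(got$value, unname(want), tolerance = 1e-12)
    }
  }
})

test_that("a constant track profiles flat; a single anchor samples the track", {
  flat <- binned_track(lapply(sizes, function(l) rep(4.5, l / 10)), 10,
                       norm = "cpm")
  set.seed(55)
  start <- sample(4000:8000, 10)
  anchors <- genomic_intervals(sample(names(sizes), 10, TRUE), start,
                               start + 200)
  p <- profile_around_anchors(flat, anchors, flank = 3000)
  expect_equal(p$value, rep(4.5, 600))
  expect_equal(nrow(p), 2 * 3000 / 10)
  expect_true(all(abs(p$offset + rev(p$offset)) < 1e-9))  # symmetric offsets
  tr <- random_binned_track(sizes)
  one <- genomic_intervals("chrP", 5000, 5400)
  p1 <- profile_around_anchors(tr, one, flank = 500)
  ctr <- 5200
  idx <- floor((ctr - 500 + (seq_len(100) - 0.5) * 10) / 10) + 1
  expect_equal(p1$value, tr$values$chrP[idx])
})

test_that("duplicated anchors do not change the profile", {
  set.seed(56)
  tr <- random_binned_track(sizes)
  start <- sample(4000:9000, 8)
  anchors <- genomic_intervals(rep("chrP", 8), start, start + 300)
  doubled <- genomic_intervals(rep("chrP", 16), c(start, start),
                               c(start, start) + 300)
  expect_equal(profile_around_anchors(tr, anchors, flank = 1000)$value,
               profile_around_anchors(tr, doubled, flank = 1000)$value)
})

test_that("anchors running off the chromosome are skipped and counted", {
  tr <- random_binned_track(sizes)
  anchors <- genomic_intervals(c("chrP", "chrP"), c(100, 10000),
                               c(300, 10400))
  p <- profile_around_anchors(tr, anchors, flank = 3000)
  expect_equal(attr(p, "n_anchors_used"), 1L)
  expect_equal(attr(p, "n_anchors_skipped"), 1L)
  expect_error(profile_around_anchors(tr, anchors[1, ], flank = 3000),
               "usable")
})

test_that("methylation profiles pool CpGs by offset bin, missing not zero", {
  d <- make_deltas("chrP", c(5000, 5004, 5100, 7990), c(-60, -60, -60, -60))
  anchors <- genomic_intervals("chrP", 4900, 5100)  # center 5000
  p <- methylation_profile(d, anchors, flank = 3000, bin_size = 10)
  at <- function(off) p$value[p$offset == off]
  expect_equal(at(5), -60)      # bin [0,10) holds 5000 and 5004
  expect_equal(p$n[p$offset == 5], 2L)
  expect_equal(at(105), -60)
  expect_equal(at(2995), -60)   # 7990 at offset 2990
  expect_true(is.na(at(55)))    # empty bin is missing, not zero
  # all CpGs at the same delta -> flat where defined
  expect_true(all(p$value[!is.na(p$value)] == -60))
})

test_that("methylation profiles match the pooled regrouping oracle", {
  set.seed(57)
  d <- make_deltas(sample(names(sizes), 300, TRUE),
                   sample.int(15000, 300), round(runif(300, -90, 10), 1))
  start <- sample(4000:9000, 12)
  anchors <- genomic_intervals(sample(names(sizes), 12, TRUE), start,
                               start + sample(200:800, 12, TRUE))
  got <- methylation_profile(d, anchors, flank = 2000, bin_size = 50)
  want <- naive_meth_profile(d, anchors, flank = 2000, bin_size = 50)
  expect_equal(got$value, want, tolerance = 1e-12)
})

test_that("a delta track far from all anchors warns with an all-missing curve", {
  d <- make_deltas("chrP", 100, -60)
  anchors <- genomic_intervals("chrQ", 7000, 7400)
  expect_warning(p <- methylation_profile(d, anchors, flank = 1000), "no CpG")
  expect_true(all(is.na(p$value)))
})

test_that("planted DMR signal loss dips at the anchor center and recovers", {
  cfg <- sim_config(seed = 3)
  chip <- simulate_chip(cfg, make_annotation(cfg))
  d <- signal_change(cpm_normalize_track(chip$tracks$Day2_DFOminus),
                     cpm_normalize_track(chip$tracks$Day0))
  p <- profile_around_anchors(d, chip$dmrs, flank = 3000)
  low <- which.min(p$value)
  bin <- p$offset[2] - p$offset[1]
  expect_lte(abs(p$offset[low]), 2 * bin + bin / 2)
  far <- abs(p$offset) >= 2000
  baseline <- mean(p$value[far])
  amplitude <- baseline - min(p$value)
  expect_true(all(abs(p$value[far] - baseline) <= 0.1 * amplitude))
})
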