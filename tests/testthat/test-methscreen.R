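test_that("coverage filter keeps the closed interval [5, 1000]", {
  tr <- make_track("chr1", c(10, 20, 30, 40, 50),
                   meth = rep(50, 5), coverage = c(4, 5, 30, 1000, 1001))
  kept <- coverage_filter(tr)
  expect_equal(kept$coverage, c(5L, 30L, 1000L))
  # all-pass input is returned unchanged
  ok <- make_track("chr1", 1:10 * 10, rep(60, 10), coverage = rep(20, 10))
  expect_equal(as.data.frame(coverage_filter(ok)), as.data.frame(ok))
})

test_that("tracks without coverage are rejected by the filter", {
  tr <- make_track("chr1", c(10, 20), c(50, 60))
  expect_error(coverage_filter(tr), "coverage")
})

test_that("methylation delta intersects jointly filtered sites", {
  base <- make_track("chr1", c(100, 200, 300), c(80, 90, 70),
                     coverage = c(10, 4, 10), label = "Day0")
  later <- make_track("chr1", c(100, 200, 400), c(20, 10, 50),
                      coverage = c(10, 10, 10), label = "Day8")
  d <- methylation_delta(base, later)
  # 200 fails coverage on Day0; 300/400 present in only one track
  expect_equal(d$pos, 100L)
  expect_equal(d$delta, -60)
  expect_equal(attr(d, "base_label"), "Day0")
  # delta of a track with itself is 0 everywhere
  self <- methylation_delta(base, base)
  expect_true(all(self$delta == 0))
  # empty intersection warns, does not error
  other <- make_track("chr2", 5, 50, coverage = 10)
  expect_warning(d0 <- methylation_delta(base, other), "no CpG")
  expect_equal(nrow(d0), 0)
})

test_that("screen qualification is strict at the drop threshold", {
  w <- genomic_intervals("chr1", 0, 1000, name = "g1")
  d <- make_deltas("chr1", c(10, 20, 30), c(-50, -51, -52))
  hits <- screen_windows(w, d, drop_gt = 50, min_sites = 2)
  # exactly -50 never qualifies ("more than" is strict)
  expect_equal(hits$n_qualifying, 2L)
  expect_equal(nrow(screen_windows(w, d, drop_gt = 50, min_sites = 3)), 0)
})

test_that("regions hit at >= min_sites qualifying CpGs, pooled across windows", {
  w <- genomic_intervals(c("chr1", "chr1"), c(0, 5000), c(1000, 6000),
                         name = c("g1", "g1"))
  d <- make_deltas("chr1", c(10, 20, 5500), c(-60, -55, -70))
  hits <- screen_windows(w, d)
  expect_equal(hits$region_id, "g1")
  expect_equal(hits$n_qualifying, 3L)
  # two qualifying CpGs are not enough at the default
  d2 <- make_deltas("chr1", c(10, 20), c(-60, -55))
  expect_equal(nrow(screen_windows(w, d2)), 0)
})

test_that("a CpG inside windows of several regions counts for each", {
  w <- genomic_intervals(c("chr1", "chr1"), c(0, 500), c(1000, 1500),
                         name = c("gA", "gB"))
  d <- make_deltas("chr1", c(600, 700, 800), rep(-80, 3))
  hits <- screen_windows(w, d)
  expect_setequal(hits$region_id, c("gA", "gB"))
  expect_equal(hits$n_qualifying, c(3L, 3L))
})

test_that("screen equals the brute-force CpG x window scan on random instances", {
  set.seed(71)
  for (rep in 1:25) {
    n_genes <- sample(5:20, 1)
    n_cpg <- sample(50:200, 1)
    start <- sample.int(5000, n_genes)
    w <- genomic_intervals(sample(c("c1", "c2"), n_genes, TRUE), start,
                           start + sample(200:800, n_genes, TRUE),
                           name = sprintf("g%02d", seq_len(n_genes)))
    d <- make_deltas(sample(c("c1", "c2"), n_cpg, TRUE),
                     sample.int(6000, n_cpg),
                     round(runif(n_cpg, -100, 20), 1))
    drop <- sample(c(30, 50), 1); ms <- sample(1:3, 1)
    got <- screen_windows(w, d, drop_gt = drop, min_sites = ms)
    expect_equal(got$region_id, brute_screen(w, d, drop, ms))
  }
})

test_that("raising thresholds never adds hits (monotonicity)", {
  set.seed(83)
  start <- sample.int(3000, 12)
  w <- genomic_intervals("c1", start, start + 400,
                         name = sprintf("g%02d", 1:12))
  d <- make_deltas("c1", sample.int(3500, 150), round(runif(150, -90, 0), 1))
  loose <- screen_windows(w, d, drop_gt = 30, min_sites = 1)$region_id
  for (drop in c(40, 60)) {
    for (ms in 1:3) {
      strict <- screen_windows(w, d, drop_gt = drop, min_sites = ms)$region_id
      expect_true(all(strict %in% loose))
    }
  }
})

test_that("relative-reduction mode scales the threshold by the baseline level", {
  w <- genomic_intervals("chr1", 0, 1000, name = "g1")
  # baseline 80%, drop of 45 points = 56% relative loss
  d <- structure(data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                            meth_base = 80, meth_later = 35, delta = -45,
                            stringsAsFactors = FALSE),
                 class = c("delta_track", "data.frame"))
  expect_equal(nrow(screen_windows(w, d, drop_gt = 50)), 0)
  expect_equal(screen_windows(w, d, drop_gt = 50,
                              relative = TRUE)$n_qualifying, 3L)
})

test_that("per-window mode screens each TSS window separately", {
  w <- genomic_intervals(c("chr1", "chr1"), c(0, 5000), c(1000, 6000),
                         name = c("g1", "g1"))
  d <- make_deltas("chr1", c(10, 20, 5500), c(-60, -55, -70))
  pooled <- screen_windows(w, d)
  expect_equal(pooled$region_id, "g1")
  split <- screen_windows(w, d, per_window = TRUE)
  expect_equal(nrow(split), 0)  # neither window alone reaches 3 CpGs
  split1 <- screen_windows(w, d, min_sites = 2, per_window = TRUE)
  expect_equal(split1$region_id, "g1#1")
})

test_that("condition contrast partitions hit sets disjointly", {
  mk <- function(ids) {
    structure(data.frame(region_id = ids,
                         n_qualifying = rep(3L, length(ids))),
              params = list(drop_gt = 50, min_sites = 3),
              sites = list(), class = c("screen_hits", "data.frame"))
  }
  ct <- condition_contrast(mk(c("g1", "g2")), mk("g2"), "A", "B")
  expect_equal(ct$only_a, "g1")
  expect_equal(ct$shared, "g2")
  expect_equal(ct$only_b, character(0))
  same <- condition_contrast(mk(c("g1", "g2")), mk(c("g1", "g2")))
  expect_equal(same$shared, c("g1", "g2"))
  expect_equal(length(same$only_a) + length(same$only_b), 0)
  disj <- condition_contrast(mk(c("a", "b", "c")), mk(c("d", "e")))
  expect_equal(lengths(disj[c("only_a", "only_b", "shared")]),
               c(only_a = 3L, only_b = 2L, shared = 0L))
  # screens run with different parameters cannot be contrasted
  bad <- mk("g1"); attr(bad, "params")$drop_gt <- 30
  expect_error(condition_contrast(mk("g1"), bad), "parameters")
})
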