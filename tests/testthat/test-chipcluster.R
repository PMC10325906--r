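test_that("CPM columns scale to one million", {
  m <- signal_matrix(matrix(c(100, 999900, 5, 5), 2, 2,
                            dimnames = list(c("a", "b"), c("s1", "s2"))),
                     "raw")
  cpm <- cpm_normalize(m)
  expect_equal(unclass(cpm)["a", "s1"], 100)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  zero <- signal_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "bad")),
                        "raw")
  expect_error(cpm_normalize(zero), "bad")
})

test_that("length normalization is per kilobase and scales inversely", {
  m <- signal_matrix(matrix(100, 1, 2, dimnames = list("g", c("s1", "s2"))),
                     "cpm")
  out <- length_normalize(m, c(g = 2000))
  expect_equal(unclass(out)["g", ], c(s1 = 50, s2 = 50))
  half <- length_normalize(m, c(g = 4000))
  expect_equal(unclass(half), unclass(out) / 2, ignore_attr = TRUE)
  expect_error(length_normalize(m, c(other = 1000)), "missing region length")
})

test_that("CV filter drops rows below 0.2 and degenerate rows", {
  m <- signal_matrix(rbind(low = c(9, 10, 11),       # cv ~ 0.1
                           high = c(7, 10, 13),      # cv = 0.3
                           flat = c(10, 10, 10),     # cv = 0
                           zero = c(0, 0, 0)), "cpm")
  kept <- cv_filter(m, cv_min = 0.2)
  expect_equal(rownames(kept), "high")
  expect_equal(sd(c(7, 10, 13)) / 10, 0.3)
})

test_that("log2 z-score standardizes rows and is permutation-equivariant", {
  m <- signal_matrix(rbind(g1 = c(1, 3)), "cpm")
  z <- log2_zscore(m, pseudocount = 1)
  expect_equal(unname(unclass(z)["g1", ]), c(-1, 1) / sqrt(2))
  set.seed(2)
  m <- signal_matrix(matrix(rexp(40, 0.1), 10, 4,
                            dimnames = list(paste0("g", 1:10), NULL)), "cpm")
  z <- log2_zscore(m)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 10), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(unclass(log2_zscore(signal_matrix(unclass(m)[, perm], "cpm"))),
               unclass(z)[, perm], ignore_attr = TRUE)
  expect_warning(log2_zscore(signal_matrix(rbind(flat = c(2, 2, 2)), "cpm")),
                 "zero-variance")
})

test_that("c = 1 gives unit memberships and the column-mean centroid", {
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  m <- fuzzy_cmeans(x, c = 1, seed = 1)
  expect_equal(unname(m$membership[, 1]), rep(1, 10))
  expect_equal(unname(m$centroids[1, ]), unname(colMeans(x)),
               tolerance = 1e-9)
  expect_equal(m$dmin, Inf)
})

test_that("two far-separated duplicate pairs recover their means exactly", {
  x <- rbind(c(0, 0), c(0, 0), c(100, 100), c(100, 100))
  m <- fuzzy_cmeans(x, c = 2, seed = 3)
  own <- apply(m$membership, 1, max)
  expect_true(all(own >= 0.99))
  ctr <- m$centroids[order(m$centroids[, 1]), ]
  expect_equal(unname(ctr), rbind(c(0, 0), c(100, 100)), tolerance = 1e-6)
})

test_that("fuzzy c-means matches the naive-loop reference implementation", {
  set.seed(8)
  x <- matrix(rnorm(200), 50, 4)
  for (seed in c(1, 2, 3)) {
    fast <- fuzzy_cmeans(x, c = 3, m = 2, seed = seed)
    slow <- naive_fcm(x, c = 3, m = 2, seed = seed)
    expect_equal(unname(fast$membership), slow$membership, tolerance = 1e-6)
    expect_equal(unname(fast$centroids), slow$centroids, tolerance = 1e-6)
  }
})

test_that("membership rows sum to 1 and the objective never increases", {
  set.seed(19)
  for (rep in 1:10) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    m <- fuzzy_cmeans(x, c = sample(2:5, 1), m = 2, seed = rep)
    expect_equal(unname(rowSums(m$membership)), rep(1, 40),
                 tolerance = 1e-9)
    expect_true(all(m$membership >= 0 & m$membership <= 1))
    expect_true(all(diff(m$objective_trace) <= 1e-9))
  }
})

test_that("a point sitting on a centroid takes full membership there", {
  # duplicated extreme point forces a zero distance at convergence
  x <- rbind(c(0, 0), c(0, 0), c(0, 0), c(50, 50))
  m <- fuzzy_cmeans(x, c = 2, seed = 5)
  far <- which.max(m$centroids[, 1])
  expect_equal(unname(m$membership[4, far]), 1)
})

test_that("clustering is row-order invariant up to relabeling", {
  set.seed(21)
  x <- matrix(rnorm(120), 30, 4,
              dimnames = list(sprintf("r%02d", 1:30), NULL))
  m1 <- fuzzy_cmeans(x, c = 3, seed = 9)
  perm <- sample(30)
  m2 <- fuzzy_cmeans(x[perm, ], c = 3, seed = 9)
  a1 <- hard_assign(m1)
  a2 <- hard_assign(m2)[names(a1)]
  # same partition: co-membership matrices agree
  expect_equal(outer(a1, a1, "=="), outer(a2, a2, "=="),
               ignore_attr = TRUE)
})

test_that("degenerate cluster requests error", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(fuzzy_cmeans(x, c = 5), "exceeds")
  expect_error(fuzzy_cmeans(x, c = 2, m = 1), "fuzzifier")
  x[1, 1] <- NA
  expect_error(fuzzy_cmeans(x, c = 2), "finite")
})

test_that("Dmin equals the brute-force all-pairs centroid minimum", {
  set.seed(33)
  x <- matrix(rnorm(150), 50, 3)
  for (cc in 2:5) {
    m <- fuzzy_cmeans(x, c = cc, seed = cc)
    expect_equal(m$dmin, brute_dmin(m$centroids), tolerance = 1e-12)
    expect_true(m$dmin >= 0)
  }
})

test_that("Dmin on two well-separated groups is approximately their distance", {
  set.seed(40)
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 10, 0.05), 20, 2))
  m <- fuzzy_cmeans(x, c = 2, seed = 1)
  expect_equal(m$dmin, sqrt(2) * 10, tolerance = 0.05)
  curve <- dmin_curve(x, c_range = 2:4, repeats = 2, seed = 1)
  expect_equal(curve$c, 2:4)
  expect_true(all(curve$dmin >= 0))
  # replicate seeds are derived deterministically
  expect_equal(curve, dmin_curve(x, c_range = 2:4, repeats = 2, seed = 1))
})

test_that("hard assignment takes the argmax with lowest-index ties", {
  model <- structure(list(c = 3L, membership = rbind(a = c(0.1, 0.7, 0.2),
                                                     b = c(0.5, 0.5, 0.0))),
                     class = "cluster_model")
  expect_equal(hard_assign(model), c(a = 2L, b = 1L))
})

test_that("planted temporal prototypes are recovered at high purity", {
  cfg <- sim_config(seed = 5)
  ann <- make_annotation(cfg)
  chip <- simulate_chip(cfg, ann)
  cpm <- cpm_normalize(chip$counts)
  groups <- sub("_rep[0-9]+$", "", colnames(cpm))
  mean_cpm <- vapply(unique(groups), function(s) {
    rowMeans(unclass(cpm)[, groups == s, drop = FALSE])
  }, numeric(nrow(cpm)))
  z <- log2_zscore(length_normalize(signal_matrix(mean_cpm, "cpm"),
                                    chip$lengths))
  model <- fuzzy_cmeans(z, c = 7, seed = 5, nstart = 5)
  labels <- hard_assign(model)
  truth <- unlist(chip$truth$cluster_labels)[names(labels)]
  purity <- sum(apply(table(labels, truth), 1, max)) / length(labels)
  expect_gte(purity, 0.95)
})
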