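# The offset statistic: centroids, invariances, the brute-force oracle,
# permutation/bootstrap behaviour, monotone recovery, and ANOSIM.

test_that("group centroids are plain coordinate means", {
  pts <- rbind(c(1, 2), c(3, 4), c(10, 0))
  rownames(pts) <- c("s1", "s2", "s3")
  ord <- ord_from_points(pts)
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         group = c("A", "A", "B"))
  cen <- group_centroids(ord, meta, n_axes = 2)
  expect_equal(cen$PCo1[cen$group == "A"], 2)
  expect_equal(cen$PCo2[cen$group == "A"], 3)
  # singleton group's centroid is the sample itself
  expect_equal(unlist(cen[cen$group == "B", c("PCo1", "PCo2")]),
               c(PCo1 = 10, PCo2 = 0))
  # order invariance
  cen2 <- group_centroids(ord_from_points(pts[c(3, 1, 2), ]),
                          meta, n_axes = 2)
  expect_equal(dplyr::arrange(cen, group), dplyr::arrange(cen2, group))
  # unlabeled sample errors
  expect_error(group_centroids(ord, meta[1:2, ], 2), class = "ms_join_error")
})

test_that("gm_offset equals the centroid distance, with oracle check", {
  # singleton groups at (0,0) and (3,4): the 3-4-5 triangle
  pts <- rbind(c(0, 0), c(3, 4))
  rownames(pts) <- c("s1", "s2")
  meta <- tibble::tibble(sample_id = c("s1", "s2"), group = c("A", "B"))
  expect_equal(gm_offset(ord_from_points(pts), meta, "A", "B"), 5.0)

  # same label on both sides: defined, zero, with a warning
  expect_warning(z <- gm_offset(ord_from_points(pts), meta, "A", "A"))
  expect_equal(z, 0)

  # brute-force oracle on <= 6 samples: hand-coded centroid arithmetic
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(2 * n), n)
    rownames(pts) <- sprintf("s%d", 1:n)
    grp <- sample(rep(c("A", "B"), length.out = n))
    meta <- tibble::tibble(sample_id = rownames(pts), group = grp)
    ca <- c(mean(pts[grp == "A", 1]), mean(pts[grp == "A", 2]))
    cb <- c(mean(pts[grp == "B", 1]), mean(pts[grp == "B", 2]))
    oracle <- sqrt(sum((ca - cb)^2))
    expect_equal(gm_offset(ord_from_points(pts), meta, "A", "B"), oracle,
                 tolerance = 1e-12)
    # symmetric in the group pair
    expect_equal(gm_offset(ord_from_points(pts), meta, "B", "A"), oracle,
                 tolerance = 1e-12)
  }
})

test_that("gm_offset is invariant under orthogonal transforms of the plane", {
  set.seed(11)
  pts <- matrix(rnorm(16), 8)
  rownames(pts) <- sprintf("s%d", 1:8)
  meta <- tibble::tibble(sample_id = rownames(pts),
                         group = rep(c("A", "B"), each = 4))
  base <- gm_offset(ord_from_points(pts), meta, "A", "B")
  for (i in 1:20) {
    q <- random_orthogonal_2d(stats::runif(1, 0, 2 * pi),
                              flip = i %% 2 == 0)
    rot <- pts %*% q
    rownames(rot) <- rownames(pts)
    expect_equal(gm_offset(ord_from_points(rot), meta, "A", "B"), base,
                 tolerance = 1e-10)
  }
  # axis sign flips
  flipped <- pts %*% diag(c(-1, 1))
  rownames(flipped) <- rownames(pts)
  expect_equal(gm_offset(ord_from_points(flipped), meta, "A", "B"), base,
               tolerance = 1e-12)
})

test_that("offset on all positive axes upper-bounds the 2-axis offset", {
  s <- simulate_counts(shifted_design(seed = 17, delta = 1))
  d <- bray_curtis(s$counts)
  ord <- suppressWarnings(pcoa(d))
  k <- ncol(ord$points)
  o2 <- gm_offset(ord, s$metadata, "A", "B", n_axes = 2)
  ok <- gm_offset(ord, s$metadata, "A", "B", n_axes = k)
  expect_gte(ok + 1e-12, o2)
})

test_that("gm_offset_test: determinism, p bounds, and separation", {
  s <- simulate_counts(null_design(seed = 3))
  d <- bray_curtis(s$counts)
  t1 <- gm_offset_test(d, s$metadata, "A", "B", n_permutations = 199,
                       n_bootstrap = 99, seed = 42)
  t2 <- gm_offset_test(d, s$metadata, "A", "B", n_permutations = 199,
                       n_bootstrap = 99, seed = 42)
  expect_identical(t1$permutation_p, t2$permutation_p)
  expect_identical(t1$bootstrap_ci, t2$bootstrap_ci)
  expect_gte(t1$permutation_p, 1 / 200)
  expect_gte(t1$gm_offset, 0)

  # two well-separated clouds attain the minimum p = 1/(B+1)
  # (12 per group so no sampled permutation recreates the exact split)
  set.seed(123)
  tb <- tibble::tibble(
    sample_id = sprintf("s%d", 1:24),
    g1 = c(rpois(12, 1000), rpois(12, 10)),
    g2 = c(rpois(12, 10), rpois(12, 1000)),
    g3 = rpois(24, 50))
  meta <- tibble::tibble(sample_id = tb$sample_id,
                         mouse_id = tb$sample_id,
                         group = rep(c("A", "B"), each = 12), week = 10L)
  ts <- gm_offset_test(bray_curtis(tb), meta, "A", "B",
                       n_permutations = 999, seed = 1)
  expect_equal(ts$permutation_p, 1 / 1000)
  expect_true(ts$bootstrap_ci[1] <= ts$gm_offset &&
                ts$gm_offset <= ts$bootstrap_ci[2])

  expect_error(gm_offset_test(d, s$metadata, "A", "B", n_permutations = 10),
               class = "ms_parameter_error")
  small <- s$metadata[1:3, ]
  expect_error(
    gm_offset_test(d[small$sample_id, small$sample_id],
                   dplyr::mutate(small, group = c("A", "A", "B")),
                   "A", "B"),
    class = "ms_parameter_error")
})

test_that("median offset shrinks with group size under the null", {
  # recovery hook: more mice concentrate the centroids
  med_at <- function(n_mice, seeds) {
    median(vapply(seeds, function(sd) {
      s <- simulate_counts(null_design(seed = sd, n_mice = n_mice))
      d <- bray_curtis(s$counts)
      ord <- suppressWarnings(pcoa(d))
      gm_offset(ord, s$metadata, "A", "B")
    }, numeric(1)))
  }
  expect_lt(med_at(40, 101:115), med_at(5, 101:115))
})

test_that("permutation power increases with effect size", {
  reject <- function(delta, seeds) {
    mean(vapply(seeds, function(sd) {
      s <- simulate_counts(shifted_design(seed = sd, delta = delta))
      d <- bray_curtis(s$counts)
      tst <- gm_offset_test(d, s$metadata, "A", "B", n_permutations = 99,
                            n_bootstrap = 0, seed = sd + 1)
      tst$permutation_p <= 0.05
    }, logical(1)))
  }
  seeds <- 201:260
  expect_gt(reject(1.0, seeds), reject(0.25, seeds))
})

test_that("anosim matches the rank-based formula and its bounds", {
  # hand-coded oracle for R on a small fixture
  anosim_oracle <- function(d, grp) {
    n <- nrow(d)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    ranks <- rank(d[upper.tri(d)])
    within <- grp[pairs[, 1]] == grp[pairs[, 2]]
    m <- length(ranks)
    (mean(ranks[!within]) - mean(ranks[within])) / (m / 2)
  }
  s <- simulate_counts(null_design(seed = 19, n_mice = 4))
  d <- bray_curtis(s$counts)
  grp <- s$metadata$group[match(rownames(d), s$metadata$sample_id)]
  res <- gm_anosim(d, s$metadata, n_permutations = 199, seed = 5)
  expect_equal(res$R, anosim_oracle(d, grp), tolerance = 1e-10)
  expect_lte(abs(res$R), 1)
  # determinism
  res2 <- gm_anosim(d, s$metadata, n_permutations = 199, seed = 5)
  expect_identical(res$permutation_p, res2$permutation_p)

  # perfect separation: all between-group distances exceed within -> R = 1
  tb <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                       g1 = c(100, 101, 99, 100, 5, 6, 5, 4),
                       g2 = c(5, 4, 6, 5, 100, 99, 101, 100))
  meta <- tibble::tibble(sample_id = tb$sample_id,
                         mouse_id = tb$sample_id,
                         group = rep(c("A", "B"), each = 4), week = 10L)
  sep <- gm_anosim(bray_curtis(tb), meta, n_permutations = 199, seed = 2)
  expect_equal(sep$R, 1)
  expect_lt(sep$permutation_p, 0.05)

  # null expectation of R is ~0 (statistic recomputed on shuffled labels)
  set.seed(33)
  r_null <- replicate(1000, anosim_oracle(d, sample(grp)))
  expect_lt(abs(mean(r_null)), 0.02)

  expect_error(gm_anosim(d, dplyr::mutate(s$metadata, group = "one")),
               class = "ms_validation_error")
})
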