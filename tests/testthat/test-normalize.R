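make_tracks <- function(t, c) {
  ts <- target_set("chr1", 0, length(t))
  list(test = coverage_track(t, ts), control = coverage_track(c, ts))
}

test_that("depth-ratio branches follow the piecewise rule", {
  # near-zero test depth against solid control -> 0
  tr <- make_tracks(c(0.0005, rep(40, 9)), c(50, rep(40, 9)))
  rt <- compute_ratio(tr$test, tr$control)
  expect_equal(rt$values[1], 0)
  # both near zero -> 1 (times omega)
  tr <- make_tracks(c(0.0001, rep(40, 9)), c(0.0002, rep(40, 9)))
  rt <- compute_ratio(tr$test, tr$control)
  expect_equal(rt$values[1], 1 * rt$omega)
  # plain ratio with equal masses: omega == 1 and value t/c
  tr <- make_tracks(c(40, rep(10, 4)), c(20, rep(15, 4)))
  expect_equal(tr$test$total_mass, tr$control$total_mass)
  rt <- compute_ratio(tr$test, tr$control)
  expect_equal(rt$omega, 1)
  expect_equal(rt$values[1], 2)
})

test_that("library-size factor omega scales every ratio", {
  t <- rep(20, 10); c <- rep(10, 10)   # mT = 200, mC = 100 -> omega 0.5
  tr <- make_tracks(t, c)
  rt <- compute_ratio(tr$test, tr$control)
  expect_equal(rt$omega, 0.5)
  expect_equal(rt$values, rep(0.5 * 2, 10))
})

test_that("strict-literal branch order makes the zero branch win", {
  tr <- make_tracks(c(0.0001, rep(40, 9)), c(0.0002, rep(40, 9)))
  rt <- compute_ratio(tr$test, tr$control, strict_literal = TRUE)
  expect_equal(rt$values[1], 0)
})

test_that("uncovered control bases give finite copy-number-scale ratios", {
  tr <- make_tracks(c(40, rep(40, 9)), c(0, rep(40, 9)))
  rt <- compute_ratio(tr$test, tr$control)
  expect_true(is.finite(rt$values[1]))
  expect_equal(rt$values[1] / rt$omega, 40)  # t / max(1, eps)
})

test_that("ratio errors on mismatched or empty inputs", {
  ts1 <- target_set("chr1", 0, 10)
  ts2 <- target_set("chr1", 0, 12)
  a <- coverage_track(rep(1, 10), ts1)
  b <- coverage_track(rep(1, 12), ts2)
  expect_error(compute_ratio(a, b), "mismatched")
  z <- coverage_track(rep(0, 10), ts1)
  expect_error(compute_ratio(z, z), "no coverage")
})

test_that("branch coverage is exhaustive and output finite, non-negative", {
  set.seed(99)
  for (i in 1:50) {
    n <- 20
    t <- ifelse(runif(n) < 0.3, 0, rpois(n, 30))
    c <- ifelse(runif(n) < 0.3, 0, rpois(n, 30))
    if (sum(t) == 0 || sum(c) == 0) next
    tr <- make_tracks(t, c)
    rt <- compute_ratio(tr$test, tr$control)
    expect_true(all(is.finite(rt$values)))
    expect_true(all(rt$values >= 0))
  }
})

test_that("noRatio passthrough preserves values and mass", {
  ts <- target_set("chr1", 0, 3)
  tr <- coverage_track(c(5, 6, 7), ts)
  rt <- passthrough_test(tr)
  expect_equal(rt$values, c(5, 6, 7))
  expect_equal(rt$omega, 1)
  expect_equal(sum(rt$values), tr$total_mass)
  z <- passthrough_test(coverage_track(c(0, 0, 0), ts))
  expect_equal(z$values, c(0, 0, 0))
})

test_that("segmentation trims remnants symmetrically", {
  # n = 100, b = 30: floor(10/2) = 5 trimmed in front, 3 segments, 5 behind
  ts <- target_set("chr1", 0, 100)
  rt <- passthrough_test(coverage_track(seq_len(100), ts))
  sp <- partition_track(rt, bin_size = 30)
  expect_equal(sp$n_segments, 3L)
  expect_equal(sp$seg_start, c(6, 36, 66))          # local 0-based offset 5
  expect_equal(range(sp$kept_idx), c(6, 95))        # local positions 5..94
  # exact multiple: nothing trimmed
  ts2 <- target_set("chr1", 0, 90)
  sp2 <- partition_track(passthrough_test(coverage_track(rep(1, 90), ts2)), 30)
  expect_equal(sp2$n_segments, 3L)
  expect_equal(range(sp2$kept_idx), c(1, 90))
  # shorter than a segment: target dropped
  ts3 <- target_set("chr1", c(0, 100), c(29, 160))
  sp3 <- partition_track(passthrough_test(
    coverage_track(rep(1, 89), ts3)), 30)
  expect_equal(sp3$n_segments, 2L)
  expect_true(all(sp3$seg_target == 2L))
  expect_error(partition_track(rt, bin_size = 1), "bin_size")
})

test_that("t-score adjustment matches the direct formula with sample sd", {
  # segment means {2,4,6}: t-scores (m - 4)/(2/sqrt(3)) = {-sqrt(3),0,sqrt(3)}
  ts <- target_set("chr1", 0, 9)
  rt <- passthrough_test(coverage_track(rep(c(2, 4, 6), each = 3), ts))
  sp <- partition_track(rt, bin_size = 3)
  st <- normalize_means(rt, sp)
  expect_equal(st$raw_mean, c(2, 4, 6))
  expect_equal(st$grand_mean, 4)
  expect_equal(st$grand_sd, 2)
  s3 <- sqrt(3)
  expect_equal(st$norm_mean, c(0, s3, 2 * s3))
  expect_equal(min(st$norm_mean), 0)
})

test_that("degenerate equal segment means give all-zero adjusted means", {
  ts <- target_set("chr1", 0, 12)
  rt <- passthrough_test(coverage_track(rep(7, 12), ts))
  sp <- partition_track(rt, bin_size = 3)
  st <- normalize_means(rt, sp)
  expect_equal(st$norm_mean, rep(0, 4))
})

test_that("min-shift postcondition holds for arbitrary inputs", {
  set.seed(4)
  for (i in 1:20) {
    ts <- target_set("chr1", 0, 300)
    rt <- passthrough_test(coverage_track(rpois(300, 40), ts))
    sp <- partition_track(rt, bin_size = 30)
    st <- normalize_means(rt, sp)
    expect_equal(min(st$norm_mean), 0)
  }
})

test_that("redistribution shifts segment means and preserves deviations", {
  ts <- target_set("chr1", 0, 3)
  rt <- passthrough_test(coverage_track(c(1, 2, 3), ts))
  sp <- partition_track(rt, bin_size = 3)
  st <- structure(list(raw_mean = 2, raw_sd = 1, norm_mean = 5,
                       grand_mean = 2, grand_sd = 0, total_segments = 1L,
                       min_shift = 0), class = "segment_stats")
  nt <- redistribute(rt, sp, st)               # mean forced from 2 to 5
  expect_equal(nt$values, c(4, 5, 6))
})

test_that("normalized track honours its per-segment mean/sd invariants", {
  set.seed(8)
  ts <- target_set("chr1", 0, 3000)
  rt <- passthrough_test(coverage_track(rpois(3000, 40) + runif(3000), ts))
  sp <- partition_track(rt, bin_size = 30)
  st <- normalize_means(rt, sp)
  nt <- redistribute(rt, sp, st)
  expect_equal(nt$n, sp$bin_size * sp$n_segments)
  M <- matrix(nt$values, nrow = sp$bin_size)
  expect_equal(colMeans(M), st$norm_mean, tolerance = 1e-9)
  sds <- apply(M, 2, sd)
  expect_equal(sds, st$raw_sd, tolerance = 1e-9)
})

test_that("ratio and noRatio agree on a constant control after rescaling", {
  # with a mean-one test signal and a constant control equal to that mean,
  # omega compensates exactly and the ratio equals the raw signal, so both
  # modes must produce the same normalized track
  set.seed(21)
  ts <- target_set("chr1", 0, 600)
  tv <- rpois(600, 40) + 1
  tv <- tv / mean(tv)
  test <- coverage_track(tv, ts)
  control <- coverage_track(rep(mean(tv), 600), ts)
  a <- normalize_coverage(test, control, mode = "ratio")
  b <- normalize_coverage(test, mode = "noRatio")
  expect_equal(a$values, b$values, tolerance = 1e-12)
  # and in general the t-score-adjusted segment means coincide for any
  # constant control, since t-scores are scale invariant
  tv2 <- rpois(600, 40) + 1
  test2 <- coverage_track(tv2, ts)
  control2 <- coverage_track(rep(7, 600), ts)
  ra <- compute_ratio(test2, control2)
  rb <- passthrough_test(test2)
  spa <- partition_track(ra); spb <- partition_track(rb)
  expect_equal(normalize_means(ra, spa)$norm_mean,
               normalize_means(rb, spb)$norm_mean, tolerance = 1e-9)
})

test_that("the normalization pipeline is deterministic", {
  sim <- fixture_sim(n_targets = 60, n_events = 2, seed = 5)
  a <- normalize_coverage(sim$test, sim$control)
  b <- normalize_coverage(sim$test, sim$control)
  expect_identical(a$values, b$values)
})
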