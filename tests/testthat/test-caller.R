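# helper: wrap plain vectors into the classed objects the caller expects
stub_space <- function(layers, sigmas = 100 * 1.1^(seq_along(layers) - 1)) {
  sch <- list(sigmas = sigmas, base_sigma = sigmas[1],
              growth = if (length(sigmas) > 1) sigmas[2] / sigmas[1] else 1.1,
              n_layers = length(layers))
  class(sch) <- "scale_schedule"
  sp <- list(image = layers, schedule = sch, n = length(layers[[1]]),
             input_mean = mean(layers[[1]]))
  class(sp) <- "scale_space"
  sp
}

stub_zmap <- function(pos, sign, n) {
  zm <- list(pos = pos, sign = sign, counts = lengths(pos), n = n,
             n_layers = length(pos))
  class(zm) <- "zero_crossing_map"
  zm
}

test_that("baselines are order statistics of the layer distribution", {
  set.seed(50)
  vals <- sample(1:1000)          # a permutation of 1..1000
  sp <- stub_space(list(as.numeric(vals)))
  zm <- stub_zmap(list(c(10L, 20L, 30L)), list(c(1L, -1L, 1L)), 1000L)
  bl <- compute_baselines(sp, zm, p_max = 0.9875, p_min = 0.0125)
  # ranking oracle: top ceil(0.0125*1000) = 13 values are 988..1000
  expect_equal(bl$upper[1], 988)
  # bottom 13 values are 1..13
  expect_equal(bl$lower[1], 13)
  # all-equal layer: upper == lower == the common value
  spc <- stub_space(list(rep(7, 1000)))
  blc <- compute_baselines(spc, zm, 0.9875, 0.0125)
  expect_equal(blc$upper[1], 7)
  expect_equal(blc$lower[1], 7)
})

test_that("layers need more than two crossings to get baselines", {
  sp <- stub_space(list(rnorm(100), rnorm(100)))
  zm <- stub_zmap(list(c(5L, 50L), c(5L, 20L, 80L)),
                  list(c(1L, -1L), c(1L, -1L, 1L)), 100L)
  bl <- compute_baselines(sp, zm)
  expect_equal(bl$valid_layers, 2L)
  expect_true(is.na(bl$upper[1]))
  zm0 <- stub_zmap(list(c(5L, 50L), c(7L, 80L)),
                   list(c(1L, -1L), c(1L, -1L)), 100L)
  expect_error(compute_baselines(sp, zm0), "no signal at any scale")
  expect_error(compute_baselines(sp, zm, p_max = 0.5, p_min = 0.6),
               "p_min < p_max")
})

test_that("auto p_min follows the zero fraction with a floor and a cap", {
  ts <- target_set("chr1", 0, 100)
  tr <- coverage_track(c(rep(0, 8), rep(40, 92)), ts)
  expect_equal(auto_pmin(tr, 0.0125), 0.08)
  tr2 <- coverage_track(rep(40, 100), ts)
  expect_equal(auto_pmin(tr2, 0.0125), 0.0125)
  tr3 <- coverage_track(rep(0, 100), ts)
  expect_warning(p <- auto_pmin(tr3, 0.0125), "capped")
  expect_equal(p, 0.5)
})

test_that("interval search enforces the three declaration conditions", {
  n <- 100L
  base <- rep(1, n); base[10:20] <- 10   # elevated stretch
  sp <- stub_space(list(base))
  zm <- stub_zmap(list(c(10L, 20L)), list(c(-1L, 1L)), n)
  bl <- list(upper = 2, lower = 0.5, valid_layers = 1L,
             p_max = 0.9875, p_min = 0.0125)
  class(bl) <- "baseline_set"
  # all three conditions hold: one interval
  iv <- find_intervals(1, zm, sp, bl)
  expect_length(iv, 1)
  expect_equal(c(iv[[1]]$left, iv[[1]]$right), c(10, 20))
  expect_equal(iv[[1]]$kind, "gain")
  # condition 3 fails when the mean sits between the baselines
  bl3 <- bl; bl3$upper <- 1e6
  expect_length(find_intervals(1, zm, sp, bl3), 0)
  # condition 1 fails when an excluded index lies inside
  expect_length(find_intervals(1, zm, sp, bl,
                               excluded = cbind(15, 15)), 0)
  # condition 2 fails for same-sign endpoints
  zm2 <- stub_zmap(list(c(10L, 20L)), list(c(1L, 1L)), n)
  expect_length(find_intervals(1, zm2, sp, bl), 0)
})

test_that("tracing returns endpoints unchanged at the base layer", {
  zm <- stub_zmap(list(c(10L, 20L)), list(c(-1L, 1L)), 100L)
  sch <- scale_schedule(1e4, n_layers = 1)
  iv <- list(layer = 1, left = 10L, right = 20L, wrap = FALSE,
             sign_left = -1L, sign_right = 1L)
  expect_equal(trace_to_base(iv, zm, sch), c(10L, 20L))
})

test_that("tracing follows the nearest same-sign contour downward", {
  # layer 2 endpoint at 100 (sign -1); layer 1 has -1 crossings at 90 & 300
  zm <- stub_zmap(list(c(90L, 150L, 300L), c(100L, 160L)),
                  list(c(-1L, 1L, -1L), c(-1L, 1L)), 1000L)
  sch <- list(sigmas = c(10, 11), base_sigma = 10, growth = 1.1,
              n_layers = 2L)
  class(sch) <- "scale_schedule"
  iv <- list(layer = 2, left = 100L, right = 160L, wrap = FALSE,
             sign_left = -1L, sign_right = 1L)
  tb <- trace_to_base(iv, zm, sch)
  expect_equal(tb, c(90L, 150L))   # within +-ceiling(3*10) of the start
  # endpoint with no same-sign crossing below is carried down unchanged
  zm2 <- stub_zmap(list(c(150L), c(100L, 160L)),
                   list(c(1L), c(-1L, 1L)), 1000L)
  iv2 <- list(layer = 2, left = 100L, right = 160L, wrap = FALSE,
              sign_left = -1L, sign_right = 1L)
  expect_equal(trace_to_base(iv2, zm2, sch), c(100L, 150L))
  # collapse is reported and dropped
  zm3 <- stub_zmap(list(c(200L), c(100L, 160L)),
                   list(c(1L), c(-1L, 1L)), 1000L)
  iv3 <- list(layer = 2, left = 170L, right = 160L, wrap = FALSE,
              sign_left = -1L, sign_right = 1L)
  expect_warning(out <- trace_to_base(iv3, zm3, sch), "collapsed")
  expect_null(out)
})

test_that("a flat track produces zero calls", {
  ts <- target_set("chr1", 0, 3000)
  tr <- coverage_track(rep(40, 3000), ts)
  ct <- coverage_track(rep(40, 3000), ts)
  fit <- suppressMessages(excnvss(tr, ct, n_layers = 2))
  expect_equal(nrow(fit$calls$calls), 0)
})

test_that("planted gain and loss are called with correct types", {
  # a ~1500 bp gain and a ~250 bp loss, each well under 1% of the panel
  # (the rank baselines assume variants are rare on the concatenated axis)
  cfg <- sim_config(n_targets = 1000, seed = 3)
  tg <- simulate_targets(cfg)
  truth <- excnvss:::.truth_set(
    first = c(150L, 600L), last = c(155L, 600L),
    kind = c("gain", "loss"), mult = c(1.5, 0.5), targets = tg)
  cov <- simulate_coverage(tg, truth, cfg)
  fit <- excnvss(cov$test, cov$control)
  df <- fit$calls$calls
  expect_gte(nrow(df), 2)
  # reciprocal overlap with the truth in concatenated coordinates
  for (i in 1:2) {
    a <- truth$concat_start[i]; b <- truth$concat_end[i]
    same <- df[df$kind == truth$kind[i], , drop = FALSE]
    ov <- pmax(0, pmin(same$concat_right, b) - pmax(same$concat_left, a) + 1)
    j <- which.max(ov)
    expect_gt(ov[j] / (b - a + 1), 0.5)
    expect_gt(ov[j] / (same$concat_right[j] - same$concat_left[j] + 1), 0.5)
  }
})

test_that("declared calls are disjoint and score beyond their baseline", {
  sim <- fixture_sim(n_targets = 400, n_events = 5, seed = 13)
  fit <- excnvss(sim$test, sim$control)
  df <- fit$calls$calls
  if (nrow(df) > 1) {
    df <- df[order(df$kept_left), ]
    nw <- df[!df$wrap, ]
    expect_true(all(nw$kept_left[-1] > nw$kept_right[-nrow(nw)]))
  }
  for (i in seq_len(nrow(df))) {
    k <- df$origin_layer[i]
    if (df$kind[i] == "gain")
      expect_gt(df$score[i], fit$baselines$upper[k])
    else
      expect_lt(df$score[i], fit$baselines$lower[k])
  }
})

test_that("an upper-layer call excludes overlapping lower-layer candidates", {
  sim <- fixture_sim(n_targets = 400, n_events = 5, seed = 13)
  prep <- excnvss_prepare(sim$test, sim$control)
  fit <- excnvss_call(prep)
  df <- fit$calls$calls
  expect_gte(nrow(df), 1)
  # every candidate at a lower layer that overlaps a declared call's traced
  # region must be absent: verified by re-running find_intervals with the
  # declared regions excluded and checking nothing overlaps
  excl <- cbind(df$kept_left, df$kept_right)
  for (k in fit$baselines$valid_layers) {
    ivs <- find_intervals(k, prep$zmap, prep$space, fit$baselines,
                          excluded = excl)
    for (iv in ivs) {
      ovl <- any(df$kept_left <= iv$right & df$kept_right >= iv$left &
                   !df$wrap)
      expect_false(ovl)
    }
  }
})

test_that("calls round-trip through the BED writer", {
  sim <- fixture_sim(n_targets = 400, n_events = 4, seed = 21)
  fit <- excnvss(sim$test, sim$control)
  path <- withr::local_tempfile(fileext = ".bed")
  write_calls(fit$calls, path)
  back <- read_calls(path)
  spans <- merge(fit$calls$spans,
                 fit$calls$calls[, c("call_id", "kind", "score",
                                     "origin_layer")], by = "call_id")
  spans <- spans[order(spans$chrom, spans$start), ]
  expect_equal(nrow(back), nrow(spans))
  expect_equal(back$start, spans$start)
  expect_equal(back$end, spans$end)
  expect_equal(back$name, toupper(spans$kind))
  expect_equal(back$score, spans$score, tolerance = 1e-9)
  expect_equal(back$origin_layer, spans$origin_layer)
  expect_equal(back$target_ids, spans$target_ids)
  # empty call set -> header-only file
  empty <- excnvss:::cnv_calls_object(list(), sim$targets,
                                      seq_len(sim$targets$total_length),
                                      sim$targets$total_length)
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_calls(empty, path2)
  expect_equal(nrow(read_calls(path2)), 0)
  expect_match(readLines(path2)[1], "^#chrom")
})

test_that("boundary recovery is accurate on seeded simulations", {
  # planted events spanning >= 2 targets at 40x: recovered with the right
  # type and small boundary error, across seeds
  errs <- c(); found <- 0; total <- 0
  for (sd in 1:6) {
    sim <- fixture_sim(n_targets = 800, n_events = 3, seed = sd,
                       event_span = 2:4)
    fit <- excnvss(sim$test, sim$control)
    df <- fit$calls$calls
    for (i in seq_len(nrow(sim$truth))) {
      total <- total + 1
      a <- sim$truth$concat_start[i]; b <- sim$truth$concat_end[i]
      same <- df[df$kind == sim$truth$kind[i], , drop = FALSE]
      if (nrow(same) == 0) next
      ov <- pmax(0, pmin(same$concat_right, b) - pmax(same$concat_left, a) + 1)
      j <- which.max(ov)
      if (ov[j] / (b - a + 1) > 0.3) {
        found <- found + 1
        errs <- c(errs, abs(same$concat_left[j] - a),
                  abs(same$concat_right[j] - b))
      }
    }
  }
  expect_gte(found / total, 0.9)
  expect_lte(median(errs), 2 * 30)
})
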