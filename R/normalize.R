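#' Per-base test/control depth ratio with library-size correction
#'
#' Forms the per-base ratio r = t/c of test over control depth on the
#' concatenated axis, guarded against near-zero depths by a small epsilon:
#' when both depths fall below epsilon the ratio is 1 (no evidence either
#' way); when only the test depth falls below epsilon the ratio is 0. The
#' uncovered case (control below epsilon but test not) is not defined by the
#' piecewise rule; the denominator is floored at one read (`max(1,
#' epsilon)`) so the ratio stays finite and on the copy-number scale while
#' preserving its "high" character. (Flooring at epsilon itself would put
#' such bases three orders of magnitude above a single-copy gain, and one
#' of them is enough to wreck the t-score normalization downstream, since
#' the grand standard deviation of segment means is global.) All ratios
#' are then scaled
#' by the library-size factor omega = (total control mass) / (total test
#' mass).
#'
#' `strict_literal = TRUE` applies the branches in their written order, in
#' which the test-below-epsilon branch shadows the joint branch.
#'
#' @param test,control `coverage_track`s over the same `target_set`.
#' @param epsilon near-zero depth guard (default `1e-3`).
#' @param strict_literal apply the zero branch before the joint branch.
#' @return Object of class `ratio_track`: list with `values`
#'   (omega-scaled ratios), `omega`, `epsilon`, `mode = "ratio"`,
#'   `target_set`, and `test_zero_fraction` (fraction of test bases at
#'   exactly zero depth, used by [auto_pmin()]).
#' @export
compute_ratio <- function(test, control, epsilon = 1e-3,
                          strict_literal = FALSE) {
  stopifnot(inherits(test, "coverage_track"), inherits(control, "coverage_track"))
  if (length(test$values) != length(control$values))
    stop("mismatched track lengths")
  if (!identical(test$target_set$concat_start, control$target_set$concat_start))
    stop("tracks built from different target sets")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (test$total_mass == 0 && control$total_mass == 0) stop("no coverage")
  if (test$total_mass == 0 || control$total_mass == 0)
    stop("no coverage in ", if (test$total_mass == 0) "test" else "control",
         " track; library-size factor undefined")
  t <- test$values; c <- control$values
  omega <- control$total_mass / test$total_mass
  r <- numeric(length(t))
  tlow <- t < epsilon; clow <- c < epsilon
  if (strict_literal) {
    zero <- tlow
    one <- rep(FALSE, length(t))
  } else {
    one <- tlow & clow
    zero <- tlow & !one
  }
  other <- !(zero | one)
  r[one] <- 1
  # floor the denominator at one read for the c < eps <= t case
  capped <- other & clow
  if (any(capped))
    r[capped] <- t[capped] / max(1, epsilon)
  plain <- other & !clow
  r[plain] <- t[plain] / c[plain]
  rt <- list(values = omega * r, omega = omega, epsilon = epsilon,
             mode = "ratio", target_set = test$target_set,
             test_zero_fraction = mean(t == 0))
  class(rt) <- "ratio_track"
  rt
}

#' Test-only (noRatio) passthrough
#'
#' Wraps the raw test depths as a ratio track with omega = 1, for the mode
#' in which no matched control is available.
#'
#' @param test a `coverage_track`.
#' @return A `ratio_track` with `mode = "noRatio"`.
#' @export
passthrough_test <- function(test) {
  stopifnot(inherits(test, "coverage_track"))
  rt <- list(values = test$values, omega = 1, epsilon = NA_real_,
             mode = "noRatio", target_set = test$target_set,
             test_zero_fraction = mean(test$values == 0))
  class(rt) <- "ratio_track"
  rt
}

#' Partition targets into fixed-size segments
#'
#' Splits each target of length n into floor(n / bin_size) segments of
#' exactly `bin_size` bases, trimming floor((n mod bin_size) / 2) bases from
#' the front and the remaining remnant from the back. Targets shorter than
#' `bin_size` contribute no segments and are dropped from the normalized
#' track.
#'
#' @param track a `ratio_track` (or anything carrying a `target_set`).
#' @param bin_size segment size in bases, >= 2 (default 30).
#' @return Object of class `segment_partition`: list with `bin_size`,
#'   `seg_target` (target id per segment), `seg_start` (1-based concatenated
#'   start index of each segment), `n_segments`, `kept_idx` (concatenated
#'   indices that survive trimming, in normalized order), `target_set`.
#' @export
partition_track <- function(track, bin_size = 30) {
  targets <- track$target_set
  stopifnot(inherits(targets, "target_set"))
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 2) stop("bin_size must be >= 2")
  n_i <- targets$length
  ns <- n_i %/% bin_size
  trim <- (n_i %% bin_size) %/% 2L
  has <- ns > 0L
  seg_target <- rep.int(seq_along(n_i)[has], ns[has])
  first <- targets$concat_start[has] + trim[has]
  # start index of every segment
  seg_start <- sequence(ns[has], from = first, by = bin_size)
  S <- length(seg_start)
  kept_idx <- rep(seg_start, each = bin_size) +
    rep.int(0:(bin_size - 1L), S)
  sp <- list(bin_size = bin_size, seg_target = seg_target,
             seg_start = seg_start, n_segments = S,
             kept_idx = kept_idx, target_set = targets)
  class(sp) <- "segment_partition"
  sp
}

#' Segment-level statistics and t-score adjusted means
#'
#' Computes each segment's raw mean and (sample) standard deviation, then
#' converts the means to t-scores against the grand mean and grand standard
#' deviation of all segment means, t = (m - grand_mean) /
#' (grand_sd / sqrt(N)) with N the total segment count, and finally shifts
#' all t-scores by their minimum so the smallest adjusted mean is exactly 0.
#' If the segment means have zero spread, all t-scores are defined as 0
#' before the shift.
#'
#' @param track a `ratio_track`.
#' @param partition a `segment_partition` over the same targets.
#' @return Object of class `segment_stats`: list with `raw_mean`, `raw_sd`,
#'   `norm_mean` (shifted t-scores), `grand_mean`, `grand_sd`,
#'   `total_segments`, `min_shift`.
#' @export
normalize_means <- function(track, partition) {
  stopifnot(inherits(partition, "segment_partition"))
  S <- partition$n_segments
  if (S < 2) stop("need at least 2 segments")
  b <- partition$bin_size
  M <- matrix(track$values[partition$kept_idx], nrow = b)
  raw_mean <- colMeans(M)
  raw_sd <- sqrt(pmax(0, (colSums(M * M) - b * raw_mean^2) / (b - 1)))
  grand_mean <- mean(raw_mean)
  grand_sd <- stats::sd(raw_mean)
  if (grand_sd == 0) {
    t <- numeric(S)
  } else {
    t <- (raw_mean - grand_mean) / (grand_sd / sqrt(S))
  }
  shift <- min(t)
  st <- list(raw_mean = raw_mean, raw_sd = raw_sd, norm_mean = t - shift,
             grand_mean = grand_mean, grand_sd = grand_sd,
             total_segments = S, min_shift = shift)
  class(st) <- "segment_stats"
  st
}

#' Redistribute adjusted segment means to base level
#'
#' Shifts the values within each kept segment so that the segment mean
#' equals the adjusted (t-score, min-shifted) mean while within-segment
#' deviations — hence the within-segment standard deviation — are preserved:
#' nR_j = tR_s + (r_j - mR_s).
#'
#' @param track a `ratio_track`.
#' @param partition a `segment_partition`.
#' @param stats `segment_stats` computed from the same partition.
#' @return Object of class `normalized_track`: list with `values` (length
#'   `bin_size * n_segments`, in normalized order), `partition`, `index_map`
#'   (normalized position -> concatenated index), `n`.
#' @export
redistribute <- function(track, partition, stats) {
  stopifnot(inherits(partition, "segment_partition"),
            inherits(stats, "segment_stats"))
  if (length(stats$raw_mean) != partition$n_segments)
    stop("stats do not match partition")
  b <- partition$bin_size
  v <- track$values[partition$kept_idx]
  shift <- rep(stats$norm_mean - stats$raw_mean, each = b)
  nt <- list(values = v + shift, partition = partition,
             index_map = partition$kept_idx,
             n = length(v), mode = track$mode,
             test_zero_fraction = track$test_zero_fraction)
  class(nt) <- "normalized_track"
  nt
}

#' Run the full four-step normalization protocol
#'
#' Convenience wrapper: ratio (or test-only passthrough), segmentation,
#' t-score adjustment of segment means, base-level redistribution.
#'
#' @param test test `coverage_track`.
#' @param control matched control `coverage_track`, or `NULL` for noRatio
#'   mode.
#' @param mode `"auto"` (ratio when a control is given), `"ratio"`, or
#'   `"noRatio"`.
#' @param bin_size segment size (default 30).
#' @param epsilon near-zero depth guard for the ratio (default `1e-3`).
#' @param strict_literal see [compute_ratio()].
#' @return A `normalized_track`.
#' @export
normalize_coverage <- function(test, control = NULL,
                               mode = c("auto", "ratio", "noRatio"),
                               bin_size = 30, epsilon = 1e-3,
                               strict_literal = FALSE) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.null(control)) "noRatio" else "ratio"
  if (mode == "ratio") {
    if (is.null(control)) stop("ratio mode requires a control track")
    rt <- compute_ratio(test, control, epsilon = epsilon,
                        strict_literal = strict_literal)
  } else {
    rt <- passthrough_test(test)
  }
  sp <- partition_track(rt, bin_size = bin_size)
  st <- normalize_means(rt, sp)
  redistribute(rt, sp, st)
}

#' Export a normalized track as a TSV for inspection
#'
#' Writes one row per normalized base: concatenated index, chromosome,
#' 0-based genomic position, normalized value.
#'
#' @param ntrack a `normalized_track`.
#' @param path output TSV path.
#' @export
write_normalized_tsv <- function(ntrack, path) {
  stopifnot(inherits(ntrack, "normalized_track"))
  g <- to_genomic(ntrack$index_map, ntrack$partition$target_set)
  utils::write.table(
    data.frame(concat_index = ntrack$index_map, chrom = g$chrom, pos = g$pos,
               value = ntrack$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
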