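#' Target-level validation of CNV calls against a truth set
#'
#' Scores a call set against planted truth at the level of target regions:
#' each capture target covered by a truth event is one truth region, and
#' it is validated when calls of matching kind cover more than
#' `min_overlap_frac` of its transcript-coordinate length (default: more
#' than 30%). FNR is the percentage of truth target regions not validated.
#' FPR, in the default `"target"` mode, is the percentage of targets
#' outside every truth event that count as called (per-target specificity
#' complement); `"precision"` mode instead reports the percentage of
#' called targets lying outside truth. A target counts as called when
#' calls cover more than `min_overlap_frac` of its length — the same
#' overlap rule applied symmetrically, so a traced boundary that merely
#' grazes a neighbouring target does not mark it as detected.
#'
#' `unit = "event"` switches to whole-event counting: a truth event
#' (possibly spanning several consecutive targets) is validated when
#' matching calls cover more than `min_overlap_frac` of its total length.
#'
#' Size classes are assigned by region length in transcript coordinates:
#' small 100-159 bp, medium 160-299 bp, large 300-8260 bp (for target
#' units this is the target's own length).
#'
#' @param calls a `cnv_calls` object.
#' @param truth a `truth_set`.
#' @param targets the shared `target_set`.
#' @param min_overlap_frac fraction of a truth region that must be called,
#'   in (0, 1] (default 0.3).
#' @param match_kind require the call kind to match the truth kind
#'   (default `TRUE`).
#' @param fpr_mode `"target"` (default) or `"precision"`.
#' @param unit `"target"` (default; the paper-style target-level regions)
#'   or `"event"`.
#' @return Object of class `eval_result`: list with counts, `fnr`, `fpr`
#'   (percent), per-size-class and per-kind breakdowns, and the per-region
#'   validation table `regions`.
#' @export
validate_regions <- function(calls, truth, targets, min_overlap_frac = 0.3,
                             match_kind = TRUE,
                             fpr_mode = c("target", "precision"),
                             unit = c("target", "event")) {
  stopifnot(inherits(calls, "cnv_calls"), inherits(targets, "target_set"))
  fpr_mode <- match.arg(fpr_mode)
  unit <- match.arg(unit)
  if (!(min_overlap_frac > 0 && min_overlap_frac <= 1))
    stop("min_overlap_frac must be in (0, 1]")
  n <- targets$total_length

  # per-kind concatenated coverage masks from the calls
  cover <- list(gain = logical(n), loss = logical(n))
  if (nrow(calls$calls)) {
    kind_of <- calls$calls$kind[match(calls$spans$call_id,
                                      calls$calls$call_id)]
    for (j in seq_len(nrow(calls$spans))) {
      a <- to_concat(calls$spans$chrom[j], calls$spans$start[j], targets)
      b <- to_concat(calls$spans$chrom[j], calls$spans$end[j] - 1, targets)
      cover[[kind_of[j]]][a:b] <- TRUE
    }
  }
  # a target counts as called when calls cover > min_overlap_frac of it
  any_cover <- cover$gain | cover$loss
  cum <- c(0, cumsum(any_cover))
  t_end <- targets$concat_start + targets$length - 1
  covered_bases <- cum[t_end + 1] - cum[targets$concat_start]
  called_targets <- covered_bases > min_overlap_frac * targets$length

  truth_targets <- logical(targets$n_targets)
  if (nrow(truth))
    for (i in seq_len(nrow(truth)))
      truth_targets[truth$first_target[i]:truth$last_target[i]] <- TRUE

  if (nrow(truth)) {
    if (unit == "target") {
      # one region per covered target, with the kind of its event
      ev <- rep(seq_len(nrow(truth)),
                truth$last_target - truth$first_target + 1)
      tid <- unlist(mapply(seq, truth$first_target, truth$last_target,
                           SIMPLIFY = FALSE))
      kind <- truth$kind[ev]
      reg_start <- targets$concat_start[tid]
      reg_len <- targets$length[tid]
      reg_tab <- data.frame(kind = kind, first_target = tid,
                            last_target = tid, length = reg_len,
                            event = ev, stringsAsFactors = FALSE)
    } else {
      reg_start <- truth$concat_start
      reg_len <- truth$length
      reg_tab <- data.frame(kind = truth$kind,
                            first_target = truth$first_target,
                            last_target = truth$last_target,
                            length = truth$length,
                            event = seq_len(nrow(truth)),
                            stringsAsFactors = FALSE)
    }
    nr <- nrow(reg_tab)
    cum_g <- c(0, cumsum(cover$gain)); cum_l <- c(0, cumsum(cover$loss))
    covered_in <- function(cum, a, b) cum[b + 1] - cum[a]
    reg_end <- reg_start + reg_len - 1
    cov_gain <- covered_in(cum_g, reg_start, reg_end)
    cov_loss <- covered_in(cum_l, reg_start, reg_end)
    cov_match <- if (match_kind)
      ifelse(reg_tab$kind == "gain", cov_gain, cov_loss)
    else pmin(cov_gain + cov_loss, reg_len)
    called_frac <- cov_match / reg_len
    validated <- called_frac > min_overlap_frac
    size_class <- cut(reg_tab$length, c(-Inf, 159, 299, Inf),
                      labels = c("small", "medium", "large"))
    fnr <- 100 * (1 - sum(validated) / nr)
    by_class <- vapply(levels(size_class), function(cl) {
      idx <- size_class == cl
      if (!any(idx)) return(NA_real_)
      100 * (1 - sum(validated[idx]) / sum(idx))
    }, numeric(1))
    by_kind <- vapply(c("gain", "loss"), function(kd) {
      idx <- reg_tab$kind == kd
      if (!any(idx)) return(NA_real_)
      100 * (1 - sum(validated[idx]) / sum(idx))
    }, numeric(1))
    regions <- data.frame(reg_tab,
                          size_class = size_class,
                          called_frac = called_frac, validated = validated)
  } else {
    validated <- logical(0)
    fnr <- NA_real_
    by_class <- c(small = NA_real_, medium = NA_real_, large = NA_real_)
    by_kind <- c(gain = NA_real_, loss = NA_real_)
    regions <- data.frame()
    message("empty truth set: FNR not applicable")
  }

  non_truth <- !truth_targets
  fp_targets <- called_targets & non_truth
  fpr <- if (fpr_mode == "target") {
    if (any(non_truth)) 100 * sum(fp_targets) / sum(non_truth) else NA_real_
  } else {
    if (any(called_targets)) 100 * sum(fp_targets) / sum(called_targets)
    else 0
  }

  res <- list(
    n_truth_regions = if (nrow(truth)) nrow(regions) else 0L,
    n_validated = sum(validated),
    n_called_target_regions = sum(called_targets),
    n_false_positive_regions = sum(fp_targets),
    fnr = fnr, fpr = fpr, fnr_by_class = by_class, fnr_by_kind = by_kind,
    min_overlap_frac = min_overlap_frac, fpr_mode = fpr_mode,
    regions = regions)
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Target-level evaluation (", x$min_overlap_frac * 100,
      "% overlap rule)\n", sep = "")
  cat("  truth regions:", x$n_truth_regions,
      " validated:", x$n_validated, "\n")
  cat(sprintf("  FNR: %s%%   FPR: %s%% (%s mode)\n",
              format(round(x$fnr, 2)), format(round(x$fpr, 2)), x$fpr_mode))
  bc <- x$fnr_by_class
  cat(sprintf("  FNR by size class: small %s  medium %s  large %s\n",
              format(round(bc[1], 1)), format(round(bc[2], 1)),
              format(round(bc[3], 1))))
  invisible(x)
}

#' Sweep baseline thresholds and tabulate the FNR/FPR trade-off
#'
#' Re-runs the caller over a grid of (p_max, p_min) threshold pairs on one
#' or more prepared pipelines (the scale space is computed once per
#' replicate and reused across the grid), evaluates each run against its
#' truth set, and averages over replicates.
#'
#' @param preps a single `excnvss_prep` or a list of them (replicates).
#' @param truths a `truth_set` or a list matching `preps`.
#' @param grid data.frame with columns `p_max`, `p_min`.
#' @param min_overlap_frac overlap rule passed to [validate_regions()].
#' @return data.frame with one row per grid point: `p_max`, `p_min`,
#'   `mean_fnr`, `mean_fpr`, `sd_fnr`, `sd_fpr`, `mean_calls`.
#' @export
sweep_thresholds <- function(preps, truths, grid, min_overlap_frac = 0.3) {
  if (inherits(preps, "excnvss_prep")) preps <- list(preps)
  if (inherits(truths, "truth_set")) truths <- list(truths)
  stopifnot(length(preps) == length(truths), nrow(grid) >= 1,
            all(c("p_max", "p_min") %in% names(grid)))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fnr <- numeric(length(preps)); fpr <- numeric(length(preps))
    ncalls <- numeric(length(preps))
    for (r in seq_along(preps)) {
      fit <- excnvss_call(preps[[r]], p_max = grid$p_max[g],
                          p_min = grid$p_min[g])
      ev <- validate_regions(fit$calls, truths[[r]],
                             preps[[r]]$targets,
                             min_overlap_frac = min_overlap_frac)
      fnr[r] <- ev$fnr; fpr[r] <- ev$fpr
      ncalls[r] <- nrow(fit$calls$calls)
    }
    rows[[g]] <- data.frame(
      p_max = grid$p_max[g], p_min = grid$p_min[g],
      mean_fnr = mean(fnr), mean_fpr = mean(fpr),
      sd_fnr = if (length(fnr) > 1) stats::sd(fnr) else NA_real_,
      sd_fpr = if (length(fpr) > 1) stats::sd(fpr) else NA_real_,
      mean_calls = mean(ncalls))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
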