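#' Per-layer empirical quantile baselines
#'
#' For every layer whose zero-crossing signal has more than two nonzero
#' entries, computes two thresholds from the empirical distribution of the
#' smoothed signal at that layer: the upper baseline is the smallest of the
#' top `ceiling((1 - p_max) * n)` values, and the lower baseline the
#' largest of the bottom `ceiling(p_min * n)` values. Only intervals whose
#' mean lies beyond a baseline become candidate CNVs.
#'
#' @param space a `scale_space`.
#' @param zmap the matching `zero_crossing_map`.
#' @param p_max upper rank threshold in (0,1), default 0.9875.
#' @param p_min lower rank threshold in (0,1), default 0.0125.
#' @return Object of class `baseline_set`: list with `upper`, `lower`
#'   (NA at invalid layers), `valid_layers`, `p_max`, `p_min`.
#' @export
compute_baselines <- function(space, zmap, p_max = 0.9875, p_min = 0.0125) {
  stopifnot(inherits(space, "scale_space"), inherits(zmap, "zero_crossing_map"))
  if (!(p_min > 0 && p_min < p_max && p_max < 1))
    stop("need 0 < p_min < p_max < 1")
  L <- space$schedule$n_layers
  n <- space$n
  # "more than two nonzero elements": strictly more than 2
  valid <- which(zmap$counts > 2L)
  if (length(valid) == 0L) stop("no signal at any scale")
  upper <- rep(NA_real_, L); lower <- rep(NA_real_, L)
  kU <- ceiling((1 - p_max) * n)
  kL <- ceiling(p_min * n)
  for (k in valid) {
    x <- space$image[[k]]
    iu <- n - kU + 1L
    upper[k] <- sort(x, partial = iu)[iu]
    lower[k] <- sort(x, partial = kL)[kL]
  }
  bs <- list(upper = upper, lower = lower, valid_layers = valid,
             p_max = p_max, p_min = p_min)
  class(bs) <- "baseline_set"
  bs
}

#' Data-driven lower rank threshold
#'
#' Returns the larger of `floor_pmin` and the fraction of test bases with
#' exactly zero depth, so that the lower baseline is not dragged down by
#' uncovered bases. Capped at 0.5 (with a warning) so the lower threshold
#' always stays below the upper one.
#'
#' @param test a `coverage_track` (or a `normalized_track`, which carries
#'   the test zero fraction through the pipeline).
#' @param floor_pmin minimum value (default 0.0125).
#' @return a single numeric p_min.
#' @export
auto_pmin <- function(test, floor_pmin = 0.0125) {
  zf <- if (inherits(test, "coverage_track")) mean(test$values == 0)
        else test$test_zero_fraction
  p <- max(floor_pmin, zf)
  if (p > 0.5) {
    warning("zero fraction ", signif(zf, 3), " capped to p_min = 0.5")
    p <- 0.5
  }
  p
}

# logical exclusion vector helper: ranges as 2-col matrix -> logical(n)
.ranges_to_mask <- function(ranges, n) {
  mask <- logical(n)
  if (is.null(ranges) || NROW(ranges) == 0L) return(mask)
  ranges <- as.matrix(ranges)
  for (i in seq_len(nrow(ranges)))
    mask[ranges[i, 1]:ranges[i, 2]] <- TRUE
  mask
}

# candidate intervals at one layer given exclusion mask and cumulative sums.
# Returns list of lists (left, right, wrap, mean_signal, sign_left,
# sign_right, kind). Internal core shared by find_intervals and call_cnvs.
.layer_intervals <- function(k, zmap, cs, upper, lower, excl_mask) {
  p <- zmap$pos[[k]]; s <- zmap$sign[[k]]
  m <- length(p)
  out <- list()
  if (m < 2L) return(out)
  n <- zmap$n
  total <- cs[n]
  cand_l <- seq_len(m - 1L)
  for (j in cand_l) {
    if (s[j] * s[j + 1L] >= 0L) next
    l <- p[j]; u <- p[j + 1L]
    if (any(excl_mask[l:u])) next
    mean_sig <- (cs[u] - if (l > 1L) cs[l - 1L] else 0) / (u - l + 1)
    kind <- if (mean_sig > upper) "gain" else if (mean_sig < lower) "loss"
            else next
    out[[length(out) + 1L]] <- list(
      layer = k, left = l, right = u, wrap = FALSE, mean_signal = mean_sig,
      sign_left = s[j], sign_right = s[j + 1L], kind = kind)
  }
  # wrap-around candidate between the last and first crossing
  if (m >= 2L && s[m] * s[1L] < 0L) {
    l <- p[m]; u <- p[1L]
    if (!any(excl_mask[l:n]) && !any(excl_mask[1:u])) {
      len <- (n - l + 1) + u
      mean_sig <- (total - (if (l > 1L) cs[l - 1L] else 0) + cs[u]) / len
      kind <- if (mean_sig > upper) "gain" else if (mean_sig < lower) "loss"
              else NA_character_
      if (!is.na(kind))
        out[[length(out) + 1L]] <- list(
          layer = k, left = l, right = u, wrap = TRUE, mean_signal = mean_sig,
          sign_left = s[m], sign_right = s[1L], kind = kind)
    }
  }
  out
}

#' Candidate CNV intervals at one layer
#'
#' Scans the zero-crossing signal of one layer for maximal intervals
#' bounded by two crossings of opposite sign with no crossing in between,
#' that contain no excluded index, and whose mean smoothed signal lies
#' beyond a baseline. Intervals are reported left to right; an interval
#' wrapping the circular boundary is reported last with `wrap = TRUE`.
#'
#' @param layer 1-based layer index; must be a valid layer of `baselines`.
#' @param zmap `zero_crossing_map`.
#' @param space `scale_space`.
#' @param baselines `baseline_set`.
#' @param excluded `NULL`, or a 2-column matrix/data.frame of 1-based
#'   inclusive concatenated index ranges to exclude.
#' @return list of interval records (fields `layer`, `left`, `right`,
#'   `wrap`, `mean_signal`, `sign_left`, `sign_right`, `kind`).
#' @export
find_intervals <- function(layer, zmap, space, baselines, excluded = NULL) {
  stopifnot(inherits(zmap, "zero_crossing_map"),
            inherits(space, "scale_space"),
            inherits(baselines, "baseline_set"))
  if (!(layer %in% baselines$valid_layers))
    stop("layer ", layer, " is not a valid layer")
  cs <- cumsum(space$image[[layer]])
  mask <- .ranges_to_mask(excluded, zmap$n)
  .layer_intervals(layer, zmap, cs, baselines$upper[layer],
                   baselines$lower[layer], mask)
}

#' Trace an interval's endpoints down to the base layer
#'
#' Follows each endpoint's zero-crossing contour downward, layer by layer:
#' at the next finer layer the endpoint moves to the nearest crossing of
#' the same sign within a window of +/- ceiling(3 * sigma) of that layer;
#' if none exists the position is carried down unchanged. The positions
#' reached at layer 1 delimit the declared region at base resolution.
#'
#' @param interval an interval record from [find_intervals()].
#' @param zmap `zero_crossing_map`.
#' @param schedule the `scale_schedule` of the space the map came from.
#' @return integer vector `c(left, right)` at layer 1, or `NULL` (with a
#'   warning) if the traced extent collapses.
#' @export
trace_to_base <- function(interval, zmap, schedule) {
  stopifnot(inherits(zmap, "zero_crossing_map"),
            inherits(schedule, "scale_schedule"))
  l <- .trace_endpoint(interval$left, interval$sign_left, interval$layer,
                       zmap, schedule)
  u <- .trace_endpoint(interval$right, interval$sign_right, interval$layer,
                       zmap, schedule)
  if (isTRUE(interval$wrap)) {
    # region runs l..n, 1..u through the boundary; it must stay wrapped
    if (l <= u) {
      warning("wrapped interval collapsed during tracing; dropped")
      return(NULL)
    }
    return(c(l, u))
  }
  if (l >= u) {
    warning("interval collapsed during tracing (left >= right); dropped")
    return(NULL)
  }
  c(l, u)
}

.trace_endpoint <- function(pos, sgn, layer, zmap, schedule) {
  if (layer <= 1L) return(pos)
  for (k in seq(layer - 1L, 1L)) {
    win <- ceiling(3 * schedule$sigmas[k])
    p <- zmap$pos[[k]]
    same <- zmap$sign[[k]] == sgn
    if (any(same)) {
      cand <- p[same]
      d <- abs(cand - pos)
      ok <- d <= win
      if (any(ok)) {
        cand <- cand[ok]; d <- d[ok]
        # nearest; ties broken toward the smaller position
        pos <- min(cand[d == min(d)])
      }
    }
  }
  pos
}

#' Declare CNVs from the fingerprint map (top-down with exclusion)
#'
#' Works down from the coarsest valid layer to the finest. At each layer,
#' candidate intervals are searched with all previously declared (traced)
#' regions excluded; each accepted interval is typed as a gain if its mean
#' smoothed signal exceeds the layer's upper baseline or a loss if it falls
#' below the lower baseline, traced to the base layer, added to the
#' exclusion set, and mapped back through the kept-index map to
#' concatenated and genomic coordinates. Intervals at the same layer are
#' processed left to right with the exclusion set updated between them.
#' Calls wrapping the circular signal boundary are split at the signal ends
#' when reported.
#'
#' @param space `scale_space` built from a `normalized_track`.
#' @param zmap `zero_crossing_map`.
#' @param baselines `baseline_set`.
#' @param targets the `target_set`.
#' @param index_map normalized position -> concatenated index (the
#'   `index_map` of the `normalized_track`).
#' @param verbose print per-layer interval counts.
#' @return Object of class `cnv_calls`; see [cnv_calls_object()].
#' @export
call_cnvs <- function(space, zmap, baselines, targets, index_map,
                      verbose = FALSE) {
  stopifnot(inherits(space, "scale_space"),
            inherits(zmap, "zero_crossing_map"),
            inherits(baselines, "baseline_set"),
            inherits(targets, "target_set"))
  n <- space$n
  if (length(index_map) != n) stop("index_map length != signal length")
  excl <- logical(n)
  acc <- list()
  layers_desc <- sort(baselines$valid_layers, decreasing = TRUE)
  for (k in layers_desc) {
    cs <- cumsum(space$image[[k]])
    declared_here <- 0L
    # single left-to-right pass; exclusion grows between intervals
    ivs <- .layer_intervals(k, zmap, cs, baselines$upper[k],
                            baselines$lower[k], excl)
    for (iv in ivs) {
      # re-check: an earlier interval this layer may have claimed indices
      rng_ok <- if (iv$wrap)
        !any(excl[iv$left:n]) && !any(excl[1:iv$right])
      else !any(excl[iv$left:iv$right])
      if (!rng_ok) next
      tb <- withCallingHandlers(
        trace_to_base(iv, zmap, space$schedule),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(tb)) next   # collapsed during tracing: dropped
      # keep declared regions disjoint: trim the traced extent off any
      # already-declared indices; drop it if that breaks it apart
      if (iv$wrap && tb[1] > tb[2]) {
        if (any(excl[tb[1]:n]) || any(excl[1:tb[2]])) next
      } else {
        while (tb[1] <= tb[2] && excl[tb[1]]) tb[1] <- tb[1] + 1L
        while (tb[2] >= tb[1] && excl[tb[2]]) tb[2] <- tb[2] - 1L
        if (tb[1] >= tb[2] || any(excl[tb[1]:tb[2]])) next
      }
      # exclude the traced region (the declared CNV)
      if (iv$wrap && tb[1] > tb[2]) {
        excl[tb[1]:n] <- TRUE; excl[1:tb[2]] <- TRUE
      } else {
        excl[tb[1]:tb[2]] <- TRUE
      }
      acc[[length(acc) + 1L]] <- list(
        kind = iv$kind, kept_left = tb[1], kept_right = tb[2],
        wrap = iv$wrap, origin_layer = k, score = iv$mean_signal)
      declared_here <- declared_here + 1L
    }
    if (verbose)
      message("layer ", k, " (sigma ",
              round(space$schedule$sigmas[k], 1), "): ",
              declared_here, " call(s)")
  }
  cnv_calls_object(acc, targets, index_map, n)
}

#' Assemble a cnv_calls object from raw declarations
#'
#' Maps declared kept-coordinate regions to concatenated indices, covered
#' targets and genomic spans. Wrapped regions are split at the signal ends.
#'
#' @param acc list of raw call records (internal layout of [call_cnvs()]).
#' @param targets `target_set`.
#' @param index_map kept position -> concatenated index.
#' @param n kept signal length.
#' @return Object of class `cnv_calls`: list with `calls` (data.frame:
#'   `call_id`, `kind`, `kept_left`, `kept_right`, `concat_left`,
#'   `concat_right`, `origin_layer`, `score`, `wrap`, `n_targets`), `spans`
#'   (data.frame: `call_id`, `chrom`, `start`, `end` 0-based half-open,
#'   `target_ids`), and `targets`.
#' @keywords internal
cnv_calls_object <- function(acc, targets, index_map, n) {
  empty_calls <- data.frame(
    call_id = integer(), kind = character(), kept_left = integer(),
    kept_right = integer(), concat_left = integer(), concat_right = integer(),
    origin_layer = integer(), score = numeric(), wrap = logical(),
    n_targets = integer(), stringsAsFactors = FALSE)
  empty_spans <- data.frame(
    call_id = integer(), chrom = character(), start = numeric(),
    end = numeric(), target_ids = character(), stringsAsFactors = FALSE)
  if (length(acc) == 0L) {
    out <- list(calls = empty_calls, spans = empty_spans, targets = targets)
    class(out) <- "cnv_calls"
    return(out)
  }
  rows <- list(); spans <- list()
  for (i in seq_along(acc)) {
    a <- acc[[i]]
    kept_pieces <- if (a$wrap) list(a$kept_left:n, 1:a$kept_right)
                   else list(a$kept_left:a$kept_right)
    concat_idx <- sort(unlist(lapply(kept_pieces, function(p) index_map[p])))
    sp <- .concat_spans(concat_idx, targets)
    rows[[i]] <- data.frame(
      call_id = i, kind = a$kind, kept_left = a$kept_left,
      kept_right = a$kept_right, concat_left = min(concat_idx),
      concat_right = max(concat_idx), origin_layer = a$origin_layer,
      score = a$score, wrap = a$wrap,
      n_targets = length(unique(.concat_target_id(concat_idx, targets))),
      stringsAsFactors = FALSE)
    sp$call_id <- i
    spans[[i]] <- sp
  }
  calls <- do.call(rbind, rows)
  spans <- do.call(rbind, spans)[, c("call_id", "chrom", "start", "end",
                                     "target_ids")]
  ord <- order(spans$chrom, spans$start)
  spans <- spans[ord, , drop = FALSE]
  rownames(calls) <- rownames(spans) <- NULL
  out <- list(calls = calls, spans = spans, targets = targets)
  class(out) <- "cnv_calls"
  out
}

# contiguous genomic spans (merged across book-ended targets) covered by a
# sorted vector of concatenated indices
.concat_spans <- function(concat_idx, targets) {
  tid <- .concat_target_id(concat_idx, targets)
  r <- rle(tid)
  ids <- r$values
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1L
  # per-target genomic piece covered by the call (0-based half-open)
  start <- targets$start[ids] + (concat_idx[starts_at] - targets$concat_start[ids])
  end <- targets$start[ids] + (concat_idx[ends_at] - targets$concat_start[ids]) + 1
  chrom <- targets$chrom[ids]
  np <- length(ids)
  if (np > 1L) {
    # merge book-ended pieces on the same chromosome
    joined <- c(FALSE, chrom[-1] == chrom[-np] & start[-1] == end[-np])
    grp <- cumsum(!joined)
  } else grp <- 1L
  data.frame(
    chrom = chrom[!duplicated(grp)],
    start = start[!duplicated(grp)],
    end = as.numeric(tapply(end, grp, max)),
    target_ids = as.character(tapply(ids, grp, paste, collapse = ",")),
    stringsAsFactors = FALSE)
}

#' @export
print.cnv_calls <- function(x, ...) {
  ng <- sum(x$calls$kind == "gain"); nl <- sum(x$calls$kind == "loss")
  cat("CNV calls:", nrow(x$calls), "(", ng, "gain,", nl, "loss ) over",
      sum(x$calls$n_targets), "target(s)\n")
  invisible(x)
}

#' Write CNV calls as BED6+
#'
#' One line per contiguous genomic span: chrom, start, end (0-based
#' half-open), name GAIN|LOSS, score (mean smoothed signal of the
#' originating interval), strand ".", plus origin_layer and the covered
#' target ids. Lines are ordered by (chrom, start).
#'
#' @param calls a `cnv_calls` object.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "cnv_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#chrom", "start", "end", "name", "score", "strand",
                   "origin_layer", "target_ids", sep = "\t"), con)
  if (nrow(calls$spans)) {
    m <- merge(calls$spans, calls$calls[, c("call_id", "kind", "score",
                                            "origin_layer")], by = "call_id")
    m <- m[order(m$chrom, m$start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.10g\t.\t%d\t%s",
                       m$chrom, as.integer(m$start), as.integer(m$end),
                       toupper(m$kind), m$score, as.integer(m$origin_layer),
                       m$target_ids), con)
  }
  invisible(path)
}

#' Read a call BED written by [write_calls()]
#'
#' @param path path to the BED6+ file.
#' @return data.frame with one row per genomic span.
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(), score = numeric(),
                      strand = character(), origin_layer = integer(),
                      target_ids = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t")
  data.frame(
    chrom = vapply(f, `[[`, "", 1),
    start = as.numeric(vapply(f, `[[`, "", 2)),
    end = as.numeric(vapply(f, `[[`, "", 3)),
    name = vapply(f, `[[`, "", 4),
    score = as.numeric(vapply(f, `[[`, "", 5)),
    strand = vapply(f, `[[`, "", 6),
    origin_layer = as.integer(vapply(f, `[[`, "", 7)),
    target_ids = vapply(f, `[[`, "", 8),
    stringsAsFactors = FALSE)
}
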