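#' Prepare a sample for CNV calling (normalization + scale space)
#'
#' Runs everything that does not depend on the baseline thresholds: the
#' four-step normalization protocol, the Gaussian scale-space
#' decomposition, and the fingerprint (zero-crossing) map. The returned
#' object can be passed to [excnvss_call()] repeatedly with different
#' thresholds, which is how [sweep_thresholds()] avoids recomputing the
#' transform.
#'
#' @inheritParams normalize_coverage
#' @param n_layers,base_sigma,growth scale schedule; see [scale_schedule()].
#' @param verbose print progress messages.
#' @return Object of class `excnvss_prep`: list with `ntrack`, `space`,
#'   `zmap`, `targets`, `mode`, `params`.
#' @export
excnvss_prepare <- function(test, control = NULL,
                            mode = c("auto", "ratio", "noRatio"),
                            bin_size = 30, epsilon = 1e-3,
                            strict_literal = FALSE, n_layers = 50,
                            base_sigma = 100, growth = 1.1,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  nt <- normalize_coverage(test, control, mode = mode, bin_size = bin_size,
                           epsilon = epsilon, strict_literal = strict_literal)
  if (verbose) message("normalized track: ", nt$n, " bases (",
                       nt$partition$n_segments, " segments of ", bin_size, ")")
  sched <- scale_schedule(nt$n, n_layers = n_layers, base_sigma = base_sigma,
                          growth = growth)
  space <- build_scale_space(nt$values, sched)
  if (verbose) message("scale space: ", sched$n_layers, " layers")
  zmap <- fingerprint(space)
  out <- list(ntrack = nt, space = space, zmap = zmap,
              targets = nt$partition$target_set, mode = nt$mode,
              params = list(bin_size = bin_size, epsilon = epsilon,
                            n_layers = n_layers, base_sigma = base_sigma,
                            growth = growth))
  class(out) <- "excnvss_prep"
  out
}

#' Call CNVs on a prepared sample
#'
#' @param prep an `excnvss_prep` from [excnvss_prepare()].
#' @param p_max upper rank threshold (default 0.9875).
#' @param p_min lower rank threshold; `NULL` selects the mode default
#'   (0.0125 in ratio mode, 0.04 in noRatio mode).
#' @param auto_pmin derive p_min from the test track's zero-depth fraction
#'   via [auto_pmin()], using `p_min` (or its mode default) as the floor.
#' @param verbose print per-layer call counts.
#' @return Object of class `excnvss`; see [excnvss()].
#' @export
excnvss_call <- function(prep, p_max = 0.9875, p_min = NULL,
                         auto_pmin = FALSE, verbose = FALSE) {
  stopifnot(inherits(prep, "excnvss_prep"))
  if (is.null(p_min))
    p_min <- if (prep$mode == "ratio") 0.0125 else 0.04
  if (auto_pmin)
    p_min <- auto_pmin(prep$ntrack, floor_pmin = p_min)
  baselines <- tryCatch(
    compute_baselines(prep$space, prep$zmap, p_max = p_max, p_min = p_min),
    error = function(e) {
      if (!grepl("no signal at any scale", conditionMessage(e))) stop(e)
      # featureless input (e.g. constant track): no layer has enough
      # crossings, hence no candidate intervals and zero calls
      bs <- list(upper = rep(NA_real_, prep$space$schedule$n_layers),
                 lower = rep(NA_real_, prep$space$schedule$n_layers),
                 valid_layers = integer(0), p_max = p_max, p_min = p_min)
      class(bs) <- "baseline_set"
      bs
    })
  calls <- if (length(baselines$valid_layers))
    call_cnvs(prep$space, prep$zmap, baselines, prep$targets,
              prep$ntrack$index_map, verbose = verbose)
  else cnv_calls_object(list(), prep$targets, prep$ntrack$index_map,
                        prep$space$n)
  fit <- list(calls = calls, baselines = baselines, zmap = prep$zmap,
              schedule = prep$space$schedule, mode = prep$mode,
              targets = prep$targets, n = prep$space$n,
              params = c(prep$params, list(p_max = p_max, p_min = p_min)))
  class(fit) <- "excnvss"
  fit
}

#' Detect copy-number variants from exome read-depth tracks
#'
#' The main entry point. Takes per-base coverage over a capture panel for a
#' test sample (and optionally a matched control), normalizes it, builds the
#' Gaussian scale space, and declares gain/loss calls from the multi-scale
#' zero-crossing fingerprint against empirical quantile baselines.
#'
#' In ratio mode the signal is the library-size-corrected test/control
#' depth ratio; in noRatio mode the raw test depth is used, so no control
#' is needed (at the cost of residual capture bias in the signal).
#'
#' @param test test `coverage_track`.
#' @param control matched control `coverage_track`, or `NULL`.
#' @inheritParams excnvss_prepare
#' @inheritParams excnvss_call
#' @return Object of class `excnvss`: list with `calls` (a `cnv_calls`
#'   object: per-call table and genomic spans), `baselines`, `zmap`,
#'   `schedule`, `mode`, `targets`, `n`, `params`. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @examples
#' cfg <- sim_config(n_targets = 300, n_events = 4, seed = 1)
#' sim <- simulate_exome(cfg)
#' fit <- excnvss(sim$test, sim$control)
#' fit
#' head(as.data.frame(fit))
#' validate_regions(fit$calls, sim$truth, sim$targets)
#' @export
excnvss <- function(test, control = NULL,
                    mode = c("auto", "ratio", "noRatio"),
                    p_max = 0.9875, p_min = NULL, auto_pmin = FALSE,
                    bin_size = 30, epsilon = 1e-3, strict_literal = FALSE,
                    n_layers = 50, base_sigma = 100, growth = 1.1,
                    verbose = FALSE) {
  prep <- excnvss_prepare(test, control, mode = mode, bin_size = bin_size,
                          epsilon = epsilon, strict_literal = strict_literal,
                          n_layers = n_layers, base_sigma = base_sigma,
                          growth = growth, verbose = verbose)
  excnvss_call(prep, p_max = p_max, p_min = p_min, auto_pmin = auto_pmin,
               verbose = verbose)
}

#' @export
print.excnvss <- function(x, ...) {
  cat("Scale-space CNV calls (", x$mode, " mode)\n", sep = "")
  cat("  signal: ", x$n, " normalized bases over ",
      x$targets$n_targets, " targets; ",
      x$schedule$n_layers, " layers (sigma ",
      format(x$schedule$base_sigma), "..",
      format(round(max(x$schedule$sigmas), 1)), ")\n", sep = "")
  cat("  thresholds: p_max ", x$params$p_max, ", p_min ", x$params$p_min,
      "\n", sep = "")
  ng <- sum(x$calls$calls$kind == "gain")
  nl <- sum(x$calls$calls$kind == "loss")
  cat("  calls: ", nrow(x$calls$calls), " (", ng, " gain, ", nl,
      " loss) covering ", sum(x$calls$calls$n_targets), " target(s)\n",
      sep = "")
  invisible(x)
}

#' @method summary excnvss
#' @export
summary.excnvss <- function(object, ...) {
  x <- object
  df <- as.data.frame(x)
  cat("Call summary (", x$mode, " mode, p_max ", x$params$p_max,
      ", p_min ", x$params$p_min, ")\n", sep = "")
  if (nrow(x$calls$calls) == 0) {
    cat("  no calls\n")
    return(invisible(df))
  }
  print(df, row.names = FALSE)
  cat("\nCalls per origin layer:\n")
  print(table(x$calls$calls$origin_layer))
  invisible(df)
}

#' @method as.data.frame excnvss
#' @export
as.data.frame.excnvss <- function(x, ...) {
  if (nrow(x$calls$spans) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(), score = numeric(),
                      origin_layer = integer(), target_ids = character()))
  m <- merge(x$calls$spans,
             x$calls$calls[, c("call_id", "kind", "score", "origin_layer")],
             by = "call_id")
  m <- m[order(m$chrom, m$start),
         c("chrom", "start", "end", "kind", "score", "origin_layer",
           "target_ids")]
  rownames(m) <- NULL
  m
}

#' Plot the fingerprint map and declared calls
#'
#' Draws the zero-crossing contours (position vs. layer, + crossings in
#' red, - in blue) and overlays the declared calls as horizontal bars at
#' their origin layer.
#'
#' @param x an `excnvss` fit.
#' @param ... passed to [graphics::plot()].
#' @method plot excnvss
#' @export
plot.excnvss <- function(x, ...) {
  zm <- x$zmap
  pos <- unlist(zm$pos)
  lay <- rep.int(seq_len(zm$n_layers), zm$counts)
  sgn <- unlist(zm$sign)
  graphics::plot(pos, lay, pch = ".", cex = 1.5,
                 col = ifelse(sgn > 0, "#D55E00", "#0072B2"),
                 xlab = "normalized position", ylab = "layer",
                 main = "Scale-space fingerprint map", ...)
  cc <- x$calls$calls
  if (nrow(cc)) {
    graphics::segments(cc$kept_left, cc$origin_layer, cc$kept_right,
                       cc$origin_layer,
                       col = ifelse(cc$kind == "gain", "#D55E00", "#0072B2"),
                       lwd = 3)
    graphics::points((cc$kept_left + cc$kept_right) / 2, cc$origin_layer,
                     pch = ifelse(cc$kind == "gain", 24, 25),
                     bg = "white")
  }
  invisible(x)
}
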