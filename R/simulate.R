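#' Configuration for the coverage-level exome simulator
#'
#' The simulator emulates a targeted-capture experiment at the depth level
#' (no reads, no alignment): a panel of targets with a right-skewed length
#' distribution, negative-binomial per-base depth around a mean of 40x, a
#' per-target multiplicative capture bias shared between test and control,
#' and CNV events planted as depth multipliers over runs of consecutive
#' targets in the test sample only. The control carries the same bias but
#' no events.
#'
#' Defaults reproduce the reference simulation setting: ~21,881 targets,
#' lengths from a truncated log-normal calibrated to (min 115, mean 240,
#' max 8551) bp, 40x mean depth for both samples, events spanning 1-5
#' consecutive targets, heterozygous single-copy multipliers 0.5 (loss) and
#' 1.5 (gain).
#'
#' @param n_targets number of capture targets (default 21881).
#' @param mean_depth mean test depth per base (default 40).
#' @param control_depth mean control depth (default `mean_depth`).
#' @param nb_size negative-binomial size (dispersion) parameter for per-base
#'   depth; `Inf` gives the Poisson limit (default 10).
#' @param bias_sdlog log-sd of the per-target log-normal capture bias,
#'   shared by test and control (default 0.3, i.e. per-target depth CV
#'   of about 0.3); 0 disables bias.
#' @param n_events number of CNV events per sample; `NULL` draws uniformly
#'   from `20:30` (default).
#' @param event_span integer vector of candidate event spans in consecutive
#'   targets (default `1:5`).
#' @param gain_mult,loss_mult depth multipliers (defaults 1.5, 0.5).
#' @param p_gain probability an event is a gain (default 0.5).
#' @param len_meanlog,len_sdlog,len_min,len_max target-length law: truncated
#'   log-normal parameters (defaults calibrated so the truncated mean is
#'   240 bp).
#' @param gap_mean mean inter-target gap in bp (default 2000).
#' @param seed integer seed; every simulator operation is deterministic
#'   given the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_targets = 21881, mean_depth = 40,
                       control_depth = mean_depth, nb_size = 10,
                       bias_sdlog = 0.3, n_events = NULL, event_span = 1:5,
                       gain_mult = 1.5, loss_mult = 0.5, p_gain = 0.5,
                       len_meanlog = 5.254994, len_sdlog = 0.5,
                       len_min = 115, len_max = 8551,
                       gap_mean = 2000, seed = NULL) {
  if (gain_mult <= 1 || loss_mult >= 1 || loss_mult <= 0)
    stop("need loss_mult in (0,1) and gain_mult > 1")
  cfg <- list(n_targets = n_targets, mean_depth = mean_depth,
              control_depth = control_depth, nb_size = nb_size,
              bias_sdlog = bias_sdlog, n_events = n_events,
              event_span = event_span, gain_mult = gain_mult,
              loss_mult = loss_mult, p_gain = p_gain,
              len_meanlog = len_meanlog, len_sdlog = len_sdlog,
              len_min = len_min, len_max = len_max, gap_mean = gap_mean,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

.sim_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed) + offset)
  invisible(NULL)
}

#' Simulate a capture-target panel
#'
#' Draws target lengths from the configured truncated log-normal (by
#' rejection) and places the targets on one synthetic chromosome with
#' geometric inter-target gaps.
#'
#' @param config a [sim_config()].
#' @return A `target_set` on chromosome `"chrS"`.
#' @export
simulate_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_targets
  if (is.null(n) || n < 1) stop("n_targets must be >= 1")
  if (config$len_min >= config$len_max)
    stop("infeasible length law: len_min >= len_max")
  .sim_seed(config, 0L)
  lens <- numeric(0)
  tries <- 0L
  while (length(lens) < n) {
    draw <- stats::rlnorm(2L * (n - length(lens)) + 16L,
                          config$len_meanlog, config$len_sdlog)
    draw <- draw[draw >= config$len_min & draw <= config$len_max]
    lens <- c(lens, draw)
    tries <- tries + 1L
    if (tries > 100L) stop("infeasible length law: rejection not converging")
  }
  lens <- round(lens[seq_len(n)])
  gaps <- 1 + stats::rgeom(n, 1 / config$gap_mean)
  start <- cumsum(gaps) + c(0, cumsum(lens[-n]))
  target_set(rep("chrS", n), start, start + lens, merge = FALSE)
}

#' Plant CNV events on a target panel
#'
#' Chooses non-overlapping runs of consecutive targets and assigns each a
#' gain or loss multiplier. Events always cover whole targets.
#'
#' @param targets a `target_set`.
#' @param config a [sim_config()].
#' @return Object of class `truth_set`: data.frame with columns `kind`,
#'   `first_target`, `last_target`, `multiplier`, `concat_start`,
#'   `concat_end` (1-based inclusive), `length` (bp in transcript
#'   coordinates), plus the `target_set` as attribute `"target_set"`.
#' @export
plant_events <- function(targets, config) {
  stopifnot(inherits(targets, "target_set"), inherits(config, "sim_config"))
  .sim_seed(config, 1L)
  n_ev <- config$n_events
  if (is.null(n_ev)) n_ev <- sample(20:30, 1L)
  if (n_ev * max(config$event_span) > targets$n_targets)
    stop("cannot place ", n_ev, " events of span up to ",
         max(config$event_span), " on ", targets$n_targets, " targets")
  spans <- if (length(config$event_span) == 1L)
    rep.int(config$event_span, n_ev)
  else sample(config$event_span, n_ev, replace = TRUE)
  first <- integer(n_ev)
  used <- logical(targets$n_targets)
  for (i in seq_len(n_ev)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      f <- sample.int(targets$n_targets - spans[i] + 1L, 1L)
      sel <- f:(f + spans[i] - 1L)
      if (!any(used[sel])) {
        used[sel] <- TRUE
        first[i] <- f
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("cannot place events without overlap after bounded retries")
  }
  kind <- ifelse(stats::runif(n_ev) < config$p_gain, "gain", "loss")
  .truth_set(first, first + spans - 1L, kind,
             ifelse(kind == "gain", config$gain_mult, config$loss_mult),
             targets)
}

.truth_set <- function(first, last, kind, mult, targets) {
  cs <- targets$concat_start[first]
  ce <- targets$concat_start[last] + targets$length[last] - 1
  tr <- data.frame(kind = kind, first_target = first, last_target = last,
                   multiplier = mult, concat_start = cs, concat_end = ce,
                   length = ce - cs + 1, stringsAsFactors = FALSE)
  tr <- tr[order(tr$first_target), , drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "target_set") <- targets
  class(tr) <- c("truth_set", "data.frame")
  tr
}

#' Plant a size-stratified truth set
#'
#' Plants events whose transcript-coordinate lengths fall in the three
#' evaluation size classes: small (100-159 bp), medium (160-299 bp) and
#' large (300-8260 bp). Small and medium events are single targets of
#' matching length; large events are single large targets or runs of up to
#' five consecutive targets whose combined length falls in the class.
#' Gains and losses are split evenly within each class.
#'
#' @param targets a `target_set`.
#' @param counts integer vector `c(small, medium, large)`.
#' @param config a [sim_config()] (multipliers and seed are used).
#' @return A `truth_set`.
#' @export
plant_events_stratified <- function(targets, counts, config) {
  stopifnot(inherits(targets, "target_set"), length(counts) == 3)
  .sim_seed(config, 1L)
  len <- targets$length
  used <- logical(targets$n_targets)
  first <- integer(0); last <- integer(0)

  pick_single <- function(lo, hi, m) {
    cand <- which(len >= lo & len <= hi & !used)
    if (length(cand) < m)
      stop("not enough targets with length in [", lo, ",", hi, "] (need ",
           m, ", have ", length(cand), ")")
    sel <- sample(cand, m)
    used[sel] <<- TRUE
    list(first = sel, last = sel)
  }

  s <- pick_single(115, 159, counts[1])
  first <- c(first, s$first); last <- c(last, s$last)
  s <- pick_single(160, 299, counts[2])
  first <- c(first, s$first); last <- c(last, s$last)

  # large: single targets >= 300 bp, topped up with multi-target runs
  cand <- which(len >= 300 & len <= 8260 & !used)
  m_single <- min(length(cand), counts[3])
  sel <- if (m_single > 0) sample(cand, m_single) else integer(0)
  used[sel] <- TRUE
  first <- c(first, sel); last <- c(last, sel)
  need <- counts[3] - m_single
  tries <- 0L
  while (need > 0L) {
    tries <- tries + 1L
    if (tries > 20000L) stop("cannot place large stratified events")
    span <- sample(2:5, 1L)
    f <- sample.int(targets$n_targets - span + 1L, 1L)
    r <- f:(f + span - 1L)
    tot <- sum(len[r])
    if (!any(used[r]) && tot >= 300 && tot <= 8260) {
      used[r] <- TRUE
      first <- c(first, f); last <- c(last, f + span - 1L)
      need <- need - 1L
    }
  }
  n_ev <- length(first)
  # even gain/loss split per class
  cls_sizes <- c(counts[1], counts[2], counts[3])
  kind <- unlist(lapply(cls_sizes, function(m) {
    k <- rep(c("gain", "loss"), length.out = m)
    sample(k)
  }))
  .truth_set(first, last, kind,
             ifelse(kind == "gain", config$gain_mult, config$loss_mult),
             targets)
}

#' Simulate test and control coverage with planted events
#'
#' Per-base depth is negative-binomial with mean
#' `depth * bias(target) * multiplier(base)`, where the log-normal
#' per-target bias is shared between test and control (capture bias) and
#' the multiplier differs from 1 only inside truth regions of the test
#' sample.
#'
#' @param targets a `target_set`.
#' @param truth a `truth_set` (may have zero rows).
#' @param config a [sim_config()].
#' @return list with elements `test` and `control`, both `coverage_track`s.
#' @export
simulate_coverage <- function(targets, truth, config) {
  stopifnot(inherits(targets, "target_set"), inherits(config, "sim_config"))
  if (nrow(truth)) {
    o <- order(truth$first_target)
    tt <- truth[o, , drop = FALSE]
    if (any(tt$first_target[-1] <= tt$last_target[-nrow(tt)]))
      stop("overlapping truth events")
    if (any(tt$last_target > targets$n_targets))
      stop("truth events outside targets")
  }
  .sim_seed(config, 2L)
  nT <- targets$n_targets
  bias <- if (config$bias_sdlog > 0)
    stats::rlnorm(nT, -config$bias_sdlog^2 / 2, config$bias_sdlog)
  else rep(1, nT)
  mult <- rep(1, nT)
  if (nrow(truth))
    for (i in seq_len(nrow(truth)))
      mult[truth$first_target[i]:truth$last_target[i]] <- truth$multiplier[i]

  base_bias <- rep.int(bias, targets$length)
  base_mult <- rep.int(mult, targets$length)
  n <- targets$total_length
  draw <- function(mu) {
    if (is.infinite(config$nb_size)) stats::rpois(n, mu)
    else stats::rnbinom(n, size = config$nb_size, mu = mu)
  }
  test <- draw(config$mean_depth * base_bias * base_mult)
  control <- draw(config$control_depth * base_bias)
  list(test = coverage_track(test, targets, "sim_test"),
       control = coverage_track(control, targets, "sim_control"))
}

#' Simulate a complete exome CNV experiment
#'
#' Convenience wrapper: panel, truth, and matched test/control coverage.
#'
#' @param config a [sim_config()].
#' @param stratified_counts if non-`NULL`, `c(small, medium, large)` counts
#'   for a size-stratified truth set instead of the span-based one.
#' @return list with `targets`, `truth`, `test`, `control`, `config`.
#' @export
simulate_exome <- function(config = sim_config(), stratified_counts = NULL) {
  targets <- simulate_targets(config)
  truth <- if (is.null(stratified_counts)) plant_events(targets, config)
           else plant_events_stratified(targets, stratified_counts, config)
  cov <- simulate_coverage(targets, truth, config)
  list(targets = targets, truth = truth, test = cov$test,
       control = cov$control, config = config)
}

#' Write a truth set as BED with kind and multiplier columns
#'
#' @param truth a `truth_set`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  ts <- attr(truth, "target_set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tkind\tmultiplier\tfirst_target\tlast_target",
             con)
  if (nrow(truth)) {
    g1 <- to_genomic(truth$concat_start, ts)
    g2 <- to_genomic(truth$concat_end, ts)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%d\t%d",
                       g1$chrom, as.integer(g1$pos), as.integer(g2$pos) + 1L,
                       truth$kind, truth$multiplier,
                       truth$first_target, truth$last_target), con)
  }
  invisible(path)
}
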