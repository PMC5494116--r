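#' Concatenated per-base coverage track
#'
#' A coverage track holds one non-negative depth value per concatenated base
#' of a [target_set()], plus the total mass (sum of all values) used for
#' library-size correction.
#'
#' @param values numeric vector of per-base depths, one per concatenated base.
#' @param targets the `target_set` the track is laid over.
#' @param sample_label free-text sample name.
#' @return Object of class `coverage_track`: list with `values`,
#'   `target_set`, `sample_label`, `total_mass`.
#' @export
coverage_track <- function(values, targets, sample_label = "sample") {
  stopifnot(inherits(targets, "target_set"))
  values <- as.numeric(values)
  if (length(values) != targets$total_length)
    stop("values length ", length(values), " != concatenated length ",
         targets$total_length)
  if (any(!is.finite(values))) stop("non-finite coverage values")
  if (any(values < 0)) stop("negative coverage values")
  tr <- list(values = values, target_set = targets,
             sample_label = sample_label, total_mass = sum(values))
  class(tr) <- "coverage_track"
  tr
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track '", x$sample_label, "': ", length(x$values),
      " bases, mean depth ", round(mean(x$values), 2),
      ", total mass ", format(x$total_mass), "\n", sep = "")
  invisible(x)
}

#' Extract per-base coverage over targets from a BAM file
#'
#' Counts, at every concatenated base, the aligned reads covering that base.
#' A read contributes to every base its aligned span covers (CIGAR-aware:
#' deletions are covered, skipped regions and soft clips are not). Unmapped,
#' secondary, supplementary and duplicate-flagged reads are excluded.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param targets a `target_set`.
#' @param min_mapq minimum mapping quality (default 0).
#' @param sample_label sample name for the track.
#' @return A `coverage_track`.
#' @export
extract_coverage <- function(bam, targets, min_mapq = 0,
                             sample_label = basename(bam)) {
  stopifnot(inherits(targets, "target_set"))
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("missing BAM index for ", bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_contigs <- setdiff(unique(targets$chrom), names(hdr))
  if (length(missing_contigs))
    stop("contigs absent from BAM header: ",
         paste(missing_contigs, collapse = ", "))

  which_gr <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1, targets$end))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isDuplicate = FALSE, isSupplementaryAlignment = FALSE),
    which = which_gr)
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = 0L, min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = FALSE, include_deletions = TRUE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)

  values <- numeric(targets$total_length)
  if (nrow(p)) {
    # targets are disjoint after merge, so each (chrom,pos) maps to one index
    idx <- .genomic_to_concat_fast(as.character(p$seqnames), p$pos - 1L, targets)
    ok <- !is.na(idx)
    values[idx[ok]] <- values[idx[ok]] + p$count[ok]
  }
  coverage_track(values, targets, sample_label)
}

# vectorised genomic(0-based) -> concat index; NA when outside all targets
.genomic_to_concat_fast <- function(chrom, pos0, targets) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1, pos0 + 1))
  tgr <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1, targets$end))
  hit <- GenomicRanges::findOverlaps(gr, tgr, select = "first")
  ifelse(is.na(hit), NA_integer_,
         targets$concat_start[hit] + (pos0 - targets$start[hit]))
}

#' Build a coverage track from a bedGraph/TSV per-base depth file
#'
#' Reads depth records `(chrom, start, end, depth)` in bedGraph convention
#' (0-based half-open), fills bases inside targets, and leaves uncovered
#' target bases at depth 0. Records outside all targets are ignored.
#' Overlapping depth records are rejected as ambiguous.
#'
#' @param path bedGraph/TSV file with four columns.
#' @param targets a `target_set`.
#' @param sample_label sample name for the track.
#' @return A `coverage_track`.
#' @export
read_depth_track <- function(path, targets, sample_label = basename(path)) {
  stopifnot(inherits(targets, "target_set"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  values <- numeric(targets$total_length)
  if (length(idx) == 0L) return(coverage_track(values, targets, sample_label))
  fields <- strsplit(lines[idx], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed depth line ", idx[which(nf < 4L)[1]], ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  depth <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(depth) |
                 end <= start)
  if (length(bad))
    stop("malformed depth line ", idx[bad[1]])
  if (any(depth < 0))
    stop("negative depth value at line ", idx[which(depth < 0)[1]])

  rec <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  self <- GenomicRanges::findOverlaps(rec, drop.self = TRUE)
  if (length(self)) stop("overlapping depth records")

  tgr <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1, targets$end))
  hits <- GenomicRanges::findOverlaps(rec, tgr)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    int <- IRanges::pintersect(IRanges::ranges(rec)[q], IRanges::ranges(tgr)[s])
    from <- targets$concat_start[s] + (GenomicRanges::start(int) - 1 -
                                         targets$start[s])
    len <- IRanges::width(int)
    pos <- sequence(len, from = from)
    values[pos] <- rep.int(depth[q], len)
  }
  coverage_track(values, targets, sample_label)
}
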