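#' Ordered capture-target set with concatenation offsets
#'
#' Builds the ordered, merged set of capture targets that defines the
#' concatenated coordinate axis on which all depth filtering operates.
#' Targets are sorted by (chromosome, start), overlapping or book-ended
#' intervals are merged, and each target is assigned a start offset on the
#' concatenated axis.
#'
#' Coordinates follow the BED convention externally (0-based, half-open).
#' Concatenated indices are 1-based in the R API: index 1 is the first base
#' of the first target.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open interval bounds.
#' @param merge merge overlapping/book-ended intervals (default `TRUE`).
#' @return An object of class `target_set`: a list with elements `chrom`,
#'   `start`, `end` (0-based half-open), `length` (per-target width),
#'   `concat_start` (1-based start index of each target on the concatenated
#'   axis), `total_length`, and `n_targets`.
#' @seealso [read_targets()], [to_genomic()], [to_concat()]
#' @export
target_set <- function(chrom, start, end, merge = TRUE) {
  if (length(start) == 0L) stop("no targets")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(chrom) != length(end))
    stop("chrom, start, end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("non-finite target coordinates")
  if (any(end <= start)) stop("invalid interval: end <= start")

  # 0-based half-open -> 1-based closed for IRanges
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (merge) gr <- GenomicRanges::reduce(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- as.numeric(GenomicRanges::end(gr))
  # deterministic (chrom, start) order, chromosomes lexicographic
  o <- order(chrom, start0)
  chrom <- chrom[o]; start0 <- start0[o]; end0 <- end0[o]
  len <- end0 - start0
  stopifnot(all(len >= 1))
  ts <- list(
    chrom = chrom,
    start = start0,
    end = end0,
    length = len,
    concat_start = c(1, cumsum(len)[-length(len)] + 1),
    total_length = sum(len),
    n_targets = length(len)
  )
  class(ts) <- "target_set"
  ts
}

#' Read capture targets from a BED file
#'
#' Parses a BED3(+) file, validates every line, merges overlapping and
#' book-ended intervals, and returns a [target_set()]. Lines beginning with
#' `#`, `track` or `browser` are skipped.
#'
#' @param path path to a BED file (0-based half-open coordinates).
#' @return A `target_set`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no targets")
  fields <- strsplit(lines[idx], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", idx[which(nf < 3L)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": end <= start")
  target_set(chrom, start, end)
}

#' @export
print.target_set <- function(x, ...) {
  cat("Target set:", x$n_targets, "targets on",
      length(unique(x$chrom)), "chromosome(s);",
      "total", x$total_length, "bp\n")
  cat("  lengths: min", min(x$length), " mean", round(mean(x$length), 1),
      " max", max(x$length), "\n")
  invisible(x)
}

#' Map a concatenated index to its genomic coordinate
#'
#' Inverse of the concatenation map: returns the chromosome and 0-based
#' genomic position of each 1-based concatenated index.
#'
#' @param track_index integer vector of 1-based concatenated indices.
#' @param targets a `target_set`.
#' @return data.frame with columns `chrom`, `pos` (0-based), `target_id`.
#' @export
to_genomic <- function(track_index, targets) {
  stopifnot(inherits(targets, "target_set"))
  if (any(track_index < 1 | track_index > targets$total_length))
    stop("track index out of range [1, ", targets$total_length, "]")
  i <- findInterval(track_index, targets$concat_start)
  data.frame(
    chrom = targets$chrom[i],
    pos = targets$start[i] + (track_index - targets$concat_start[i]),
    target_id = i,
    stringsAsFactors = FALSE
  )
}

#' Map a genomic coordinate to its concatenated index
#'
#' @param chrom chromosome name(s).
#' @param pos 0-based genomic position(s); must fall inside a target.
#' @param targets a `target_set`.
#' @return integer vector of 1-based concatenated indices.
#' @export
to_concat <- function(chrom, pos, targets) {
  stopifnot(inherits(targets, "target_set"))
  out <- integer(length(pos))
  for (j in seq_along(pos)) {
    i <- which(targets$chrom == chrom[j] &
                 targets$start <= pos[j] & pos[j] < targets$end)
    if (length(i) != 1L)
      stop("position ", chrom[j], ":", pos[j], " is not inside any target")
    out[j] <- targets$concat_start[i] + (pos[j] - targets$start[i])
  }
  out
}

# target id of each concatenated index (vectorised)
.concat_target_id <- function(idx, targets) {
  findInterval(idx, targets$concat_start)
}
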