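# Shared fixtures and independent oracles, all built in code at test time.

# small deterministic target set: lengths 50, 100, 30 on two chromosomes
fixture_targets <- function() {
  target_set(c("chr1", "chr1", "chr2"),
             c(100, 300, 0),
             c(150, 400, 30))
}

# write a SAM file + BAM/index for coverage extraction tests.
# reads: list of list(qname, flag, rname, pos1, mapq, cigar)
fixture_bam <- function(reads, contigs = c(chr1 = 1000, chr2 = 500),
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "fix.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(reads, function(r) {
    seqlen <- cigar_query_length(r$cigar)
    paste(r$qname, r$flag, r$rname, r$pos1, r$mapq, r$cigar, "*", 0, 0,
          paste(rep("A", seqlen), collapse = ""),
          paste(rep("I", seqlen), collapse = ""), sep = "\t")
  }, "")
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fix"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

cigar_query_length <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", toks))
  op <- sub("[0-9]+", "", toks)
  sum(n[op %in% c("M", "I", "S", "=", "X")])
}

# brute-force pileup oracle: per-base read counts over 0-based positions,
# iterating reads and walking the CIGAR (M/D/=/X consume+cover reference,
# N consumes but does not cover, I/S/H neither)
oracle_pileup <- function(reads, chrom, pos0) {
  counts <- integer(length(pos0))
  for (r in reads) {
    if (r$rname != chrom) next
    flag <- r$flag
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 1024L) ||
        bitwAnd(flag, 2048L)) next
    toks <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("[0-9]+", "", toks)
    ref <- r$pos1 - 1  # 0-based cursor
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X", "D")) {
        cover <- seq(ref, ref + n[i] - 1)
        counts <- counts + (pos0 %in% cover)
        ref <- ref + n[i]
      } else if (op[i] == "N") {
        ref <- ref + n[i]
      }
      # I, S, H, P consume no reference
    }
  }
  counts
}

# brute-force circular Gaussian convolution with a wide (6 sigma) window
oracle_smooth <- function(x, sigma, half_width = ceiling(6 * sigma)) {
  n <- length(x)
  off <- -half_width:half_width
  kern <- stats::dnorm(off, 0, sigma)
  vapply(seq_len(n), function(i)
    sum(kern * x[((i - off - 1) %% n) + 1]), numeric(1))
}

# simple simulated pair with planted events for caller tests
fixture_sim <- function(n_targets = 400, n_events = 4, seed = 42, ...) {
  cfg <- sim_config(n_targets = n_targets, n_events = n_events, seed = seed,
                    ...)
  simulate_exome(cfg)
}
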