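# Discrete Fourier transforms for arbitrary lengths.
#
# stats::fft() is mixed-radix and degrades to near-quadratic cost when the
# signal length has a large prime factor. Signal lengths here are data-driven
# (bin_size x segment count), so a Bluestein chirp-z fallback is used for
# rough lengths: it reduces any-length DFTs to power-of-two FFTs.

.max_prime_factor <- function(n) {
  n <- as.numeric(n)
  mx <- 1
  for (p in c(2, 3, 5, 7)) while (n %% p == 0) { n <- n / p; mx <- p }
  f <- 11
  while (f * f <= n) {
    if (n %% f == 0) { n <- n / f; mx <- max(mx, f) } else f <- f + 2
  }
  max(mx, n)
}

.fft_smooth <- function(n) .max_prime_factor(n) <= 127

# precomputed chirp-z plan for an n-point DFT (forward or inverse)
.bluestein_plan <- function(n, inverse = FALSE) {
  s <- if (inverse) 1 else -1
  # angles via squares mod 2n to keep precision at large n
  k2 <- (as.numeric(0:(n - 1))^2) %% (2 * n)
  w <- exp(complex(imaginary = s * pi * k2 / n))
  M <- stats::nextn(2L * n - 1L, c(2L, 3L))
  b <- complex(real = numeric(M))
  b[1] <- Conj(w[1])
  if (n > 1) {
    b[2:n] <- Conj(w[2:n])
    b[(M - n + 2):M] <- rev(Conj(w[2:n]))
  }
  list(n = n, M = M, w = w, B = stats::fft(b))
}

.bluestein_exec <- function(x, plan) {
  a <- complex(real = numeric(plan$M))
  a[1:plan$n] <- x * plan$w
  conv <- stats::fft(stats::fft(a) * plan$B, inverse = TRUE) / plan$M
  plan$w * conv[1:plan$n]
}

# drop-in fft for any length; same normalization convention as stats::fft
.fft_any <- function(x, inverse = FALSE) {
  n <- length(x)
  if (.fft_smooth(n)) return(stats::fft(x, inverse = inverse))
  .bluestein_exec(x, .bluestein_plan(n, inverse))
}

#' Geometric schedule of Gaussian scales
#'
#' The scale-space decomposition smooths the normalized signal with a family
#' of Gaussians whose standard deviations grow geometrically,
#' sigma_k = base_sigma * growth^(k-1) for layer k = 1..n_layers (the layer
#' index is 1-based in this package; layer 1 is the finest scale). Layers
#' whose support would exceed the signal (6 sigma > n) are dropped with a
#' message.
#'
#' @param n signal length the schedule will be applied to.
#' @param n_layers requested number of layers (default 50).
#' @param base_sigma finest scale in bases (default 100).
#' @param growth geometric growth factor (default 1.1).
#' @return Object of class `scale_schedule`: list with `sigmas`,
#'   `base_sigma`, `growth`, `n_layers` (after capping).
#' @export
scale_schedule <- function(n, n_layers = 50, base_sigma = 100, growth = 1.1) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (base_sigma <= 0 || growth <= 1) stop("need base_sigma > 0, growth > 1")
  sigmas <- base_sigma * growth^(0:(n_layers - 1))
  keep <- 6 * sigmas <= n
  if (!any(keep))
    stop("signal too short for the requested base scale (6*sigma > n)")
  if (!all(keep))
    message("dropping ", sum(!keep), " layer(s) with 6*sigma > n")
  sc <- list(sigmas = sigmas[keep], base_sigma = base_sigma, growth = growth,
             n_layers = sum(keep))
  class(sc) <- "scale_schedule"
  sc
}

#' Build the Gaussian scale space of a signal
#'
#' Decomposes the signal into layers by circular Gaussian convolution,
#' executed in the frequency domain: layer k is the inverse DFT of
#' G(w, k) * C(w), where C is the DFT of the signal and
#' G(w, k) = exp(-w^2 sigma_k^2 / 2) is the Gaussian transfer function
#' sampled on the angular frequency grid w = 2*pi*f/n of an n-point DFT.
#' The real part is returned; the imaginary residue is checked to be
#' negligible relative to the signal norm.
#'
#' @param signal numeric vector (typically `normalized_track$values`).
#' @param schedule a [scale_schedule()]; built with defaults when `NULL`.
#' @return Object of class `scale_space`: list with `image` (a list of
#'   `n_layers` numeric vectors of length n, finest scale first),
#'   `schedule`, `n`, `input_mean`.
#' @export
build_scale_space <- function(signal, schedule = NULL) {
  if (inherits(signal, "normalized_track")) signal <- signal$values
  n <- length(signal)
  if (n < 4) stop("signal too short (n < 4)")
  if (any(!is.finite(signal))) stop("non-finite values in signal")
  if (is.null(schedule)) schedule <- scale_schedule(n)
  stopifnot(inherits(schedule, "scale_schedule"))
  if (n <= 6 * schedule$base_sigma)
    warning("signal length n <= 6*base_sigma; finest layer is under-resolved")

  half <- n %/% 2
  f <- c(0:half, -rev(seq_len(n - half - 1)))
  w <- 2 * pi * f / n
  smooth <- .fft_smooth(n)
  C <- if (smooth) stats::fft(signal) else
    .bluestein_exec(as.complex(signal), .bluestein_plan(n, FALSE))
  iplan <- if (smooth) NULL else .bluestein_plan(n, TRUE)

  # The signal is real and G symmetric, so each layer spectrum C*G is
  # conjugate-symmetric and its inverse DFT real: two layers are packed
  # into one complex inverse transform (Re -> layer k, Im -> layer k+1).
  img <- vector("list", schedule$n_layers)
  w2 <- w * w
  k <- 1L
  while (k <= schedule$n_layers) {
    G1 <- exp(-0.5 * schedule$sigmas[k]^2 * w2)
    if (k + 1L <= schedule$n_layers) {
      G2 <- exp(-0.5 * schedule$sigmas[k + 1L]^2 * w2)
      y <- if (smooth) stats::fft(C * complex(real = G1, imaginary = G2),
                                  inverse = TRUE)
           else .bluestein_exec(C * complex(real = G1, imaginary = G2), iplan)
      img[[k]] <- Re(y) / n
      img[[k + 1L]] <- Im(y) / n
      k <- k + 2L
    } else {
      y <- if (smooth) stats::fft(C * G1, inverse = TRUE)
           else .bluestein_exec(C * G1, iplan)
      img[[k]] <- Re(y) / n
      k <- k + 1L
    }
  }
  ss <- list(image = img, schedule = schedule, n = n,
             input_mean = mean(signal))
  class(ss) <- "scale_space"
  ss
}

#' @export
print.scale_space <- function(x, ...) {
  cat("Scale space:", x$n, "positions x", x$schedule$n_layers, "layers,",
      "sigma", format(min(x$schedule$sigmas)), "..",
      format(round(max(x$schedule$sigmas), 1)), "\n")
  invisible(x)
}

#' Second-order difference of a layer (circular)
#'
#' Approximates the second derivative by the centered second-order
#' difference c''(i) = c(i+1) - 2 c(i) + c(i-1), with circular indexing at
#' the two ends (the frequency-domain convolution is circular, so the
#' wrapped neighbours are the consistent choice).
#'
#' @param layer numeric vector, length >= 3.
#' @return numeric vector of the same length.
#' @export
second_difference <- function(layer) {
  n <- length(layer)
  if (n < 3) stop("need length >= 3")
  # interior via diff(diff()) (C-level), circular ends patched explicitly
  c(layer[2] - 2 * layer[1] + layer[n],
    diff(layer, differences = 2L),
    layer[1] - 2 * layer[n] + layer[n - 1])
}

#' Zero-crossing signal of a second difference
#'
#' Marks inflection points: +1 where the second difference crosses zero
#' from minus to plus (next value > 0 and previous value < 0), -1 for the
#' opposite crossing, 0 otherwise. Exact zeros in a neighbour yield 0 (the
#' inequalities are strict). Neighbours are circular. Curvature values
#' with magnitude at most `tol` are treated as exact zeros; the default
#' (`1e-12` of the largest curvature magnitude) keeps floating-point
#' jitter left by the frequency-domain smoothing in genuinely flat
#' stretches from minting spurious inflections. [fingerprint()] scales the
#' floor by the layer's value range instead, which is the scale the
#' round-off actually lives on.
#'
#' @param second_diff numeric vector, length >= 3.
#' @param tol absolute curvature magnitude treated as zero.
#' @return integer vector in \{-1, 0, +1\}.
#' @export
zero_crossings <- function(second_diff,
                           tol = 1e-12 * max(abs(second_diff))) {
  n <- length(second_diff)
  if (n < 3) stop("need length >= 3")
  s <- .curv_sign(second_diff, tol)
  # s[i+1] - s[i-1] is +2 iff (next > 0 & prev < 0), -2 iff the reverse
  d <- s[c(2:n, 1)] - s[c(n, 1:(n - 1))]
  z <- integer(n)
  z[d == 2] <- 1L
  z[d == -2] <- -1L
  z
}

# sign with an absolute floor: |x| <= tol counts as zero
.curv_sign <- function(x, tol) {
  s <- sign(x)
  if (tol > 0) s[abs(x) <= tol] <- 0
  s
}

# sparse variant used by fingerprint(): returns list(pos, sign)
.zero_crossings_sparse <- function(second_diff, tol) {
  n <- length(second_diff)
  s <- .curv_sign(second_diff, tol)
  d <- numeric(n)
  d[2:(n - 1)] <- s[3:n] - s[1:(n - 2)]
  d[1] <- s[2] - s[n]
  d[n] <- s[1] - s[n - 1]
  p <- which(d == 2 | d == -2)
  list(pos = p, sign = as.integer(d[p] / 2))
}

#' Fingerprint map: zero crossings of every layer
#'
#' Computes the zero-crossing signal of the second difference of each layer
#' and stores it sparsely (positions and signs per layer).
#'
#' @param space a `scale_space`.
#' @return Object of class `zero_crossing_map`: list with `pos` (list of
#'   integer vectors per layer), `sign` (list of -1/+1 vectors), `counts`
#'   (nonzero entries per layer), `n`, `n_layers`.
#' @export
fingerprint <- function(space) {
  stopifnot(inherits(space, "scale_space"))
  L <- space$schedule$n_layers
  pos <- vector("list", L); sgn <- vector("list", L)
  counts <- integer(L)
  for (k in seq_len(L)) {
    lay <- space$image[[k]]
    zc <- .zero_crossings_sparse(second_difference(lay),
                                 tol = 1e-12 * max(abs(lay)))
    pos[[k]] <- zc$pos
    sgn[[k]] <- zc$sign
    counts[k] <- length(zc$pos)
  }
  zm <- list(pos = pos, sign = sgn, counts = counts, n = space$n,
             n_layers = L)
  class(zm) <- "zero_crossing_map"
  zm
}

#' Dense zero-crossing row of one layer
#'
#' @param zmap a `zero_crossing_map`.
#' @param layer 1-based layer index.
#' @return integer vector in \{-1, 0, +1\} of length `zmap$n`.
#' @export
zmap_row <- function(zmap, layer) {
  stopifnot(inherits(zmap, "zero_crossing_map"))
  z <- integer(zmap$n)
  z[zmap$pos[[layer]]] <- zmap$sign[[layer]]
  z
}

#' Export the fingerprint map as TSV (layer, position, sign)
#'
#' @param zmap a `zero_crossing_map`.
#' @param path output path.
#' @export
write_fingerprint_tsv <- function(zmap, path) {
  df <- data.frame(
    layer = rep.int(seq_len(zmap$n_layers), zmap$counts),
    position = unlist(zmap$pos),
    sign = unlist(zmap$sign))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
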