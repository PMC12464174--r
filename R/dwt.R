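## Discrete wavelet transform: Daubechies filter bank with symmetric signal
## extension and decimation by two. Follows the standard convolution-
## decimation convention in which a length-n signal filtered with a length-f
## wavelet yields floor((n + f - 1) / 2) coefficients per branch.

# Daubechies low-pass decomposition filters (orthonormal).
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

#' Decomposition filters of a Daubechies wavelet
#'
#' @param wavelet_name one of `"db1"` (Haar) .. `"db4"`.
#' @return list with `lo` and `hi` filter taps and `length`.
#' @export
wavelet_filters <- function(wavelet_name) {
  assert(wavelet_name %in% names(.db_filters),
         sprintf("unknown wavelet '%s' (supported: %s)", wavelet_name,
                 paste(names(.db_filters), collapse = ", ")))
  lo <- .db_filters[[wavelet_name]]
  f <- length(lo)
  hi <- (-1)^(seq_len(f)) * lo[f + 1 - seq_len(f)]
  list(lo = lo, hi = hi, length = f)
}

#' Wavelet decomposition configuration
#'
#' @param wavelet_name mother wavelet (default `"db1"`, the Haar wavelet —
#'   the only Daubechies member whose filter length reproduces dyadic
#'   coefficient lengths exactly).
#' @param level number of decomposition levels (default 3).
#' @return an object of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet_name = "db1", level = 3L) {
  assert(is_count(level), "level must be a positive integer")
  filt <- wavelet_filters(wavelet_name)
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 filter_length = filt$length),
            class = "wavelet_config")
}

# One analysis step: symmetric (half-point) extension by f-1 samples on each
# side, full convolution with the filter, decimation by two starting at
# offset f.
.dwt_step <- function(x, filt) {
  f <- length(filt)
  n <- length(x)
  ext <- c(rev(x[seq_len(f - 1L)]), x, rev(x[(n - f + 2L):n]))
  z <- .conv_full(ext, filt)
  n_out <- floor((n + f - 1L) / 2L)
  z[f + 1L + 2L * (seq_len(n_out) - 1L)]
}

# Full linear convolution via FFT for long signals, direct for short ones.
.conv_full <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  n <- na + nb - 1L
  if (na * nb < 50000) {
    out <- numeric(n)
    for (j in seq_len(nb)) {
      out[(j):(j + na - 1L)] <- out[(j):(j + na - 1L)] + b[j] * a
    }
    out
  } else {
    nf <- stats::nextn(n, 2)
    Re(stats::fft(stats::fft(c(a, numeric(nf - na))) *
                    stats::fft(c(b, numeric(nf - nb))), inverse = TRUE))[seq_len(n)] / nf
  }
}

#' Multi-level DWT of a 1D signal
#'
#' Recursively splits the signal into approximation (low-pass) and detail
#' (high-pass) coefficients, decimating by two at each level; the
#' approximation branch is re-decomposed until `level` is reached.
#'
#' @param x numeric vector, the signal (length must be at least the filter
#'   length).
#' @param cfg a [wavelet_config].
#' @return named list of coefficient vectors, coarse to fine:
#'   `A<L>, D<L>, ..., D1`.
#' @export
#' @examples
#' d <- dwt_decompose(sin(2 * pi * 10 * (0:255) / 256), wavelet_config())
#' lengths(d)  # 32 32 64 128
dwt_decompose <- function(x, cfg = wavelet_config()) {
  assert(inherits(cfg, "wavelet_config"), "cfg must be a wavelet_config")
  assert(is.numeric(x) && all(is.finite(x)), "signal must be finite numeric")
  filt <- wavelet_filters(cfg$wavelet_name)
  if (length(x) < filt$length) {
    abort(sprintf("signal length %d is shorter than the '%s' filter (%d taps)",
                  length(x), cfg$wavelet_name, filt$length),
          "seizr_invalid_input")
  }
  # feasibility: every level must leave at least filter-length samples to split
  lens <- coeff_length(length(x), filt$length, cfg$level)
  details <- vector("list", cfg$level)
  approx <- x
  for (lev in seq_len(cfg$level)) {
    details[[lev]] <- .dwt_step(approx, filt$hi)
    approx <- .dwt_step(approx, filt$lo)
  }
  out <- c(list(approx), rev(details))
  names(out) <- c(sprintf("A%d", cfg$level),
                  sprintf("D%d", rev(seq_len(cfg$level))))
  stopifnot(identical(unname(lengths(out)), unname(lens)))
  out
}

#' Closed-form DWT coefficient lengths
#'
#' Iterates the convolution-decimation length rule
#' `L_next = floor((L + f - 1) / 2)` where `f` is the filter length.
#'
#' @param n signal length.
#' @param filter_len wavelet filter length (2 for db1, 6 for db3, ...).
#' @param level number of levels.
#' @return integer vector of band lengths ordered `A<L>, D<L>, ..., D1`.
#' @export
#' @examples
#' coeff_length(4097, 2, 3)       # 513 513 1025 2049 (sums to 4100)
#' sum(coeff_length(4097, 6, 3))  # 4111: why db3 does not fit the model input
coeff_length <- function(n, filter_len, level) {
  assert(is_count(n) && is_count(filter_len) && is_count(level),
         "n, filter_len, level must be positive integers")
  assert(n >= filter_len, "signal shorter than filter")
  lens <- integer(level)
  L <- as.integer(n)
  for (lev in seq_len(level)) {
    L <- (L + as.integer(filter_len) - 1L) %/% 2L
    if (L < 1L || (lev < level && L < filter_len)) {
      abort(sprintf("level %d infeasible for signal length %d with %d-tap filter",
                    level, n, filter_len), "seizr_level_error")
    }
    lens[lev] <- L
  }
  out <- c(lens[level], rev(lens))  # A_L, then D_L .. D_1
  names(out) <- c(sprintf("A%d", level), sprintf("D%d", rev(seq_len(level))))
  out
}
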