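#' Generate a 1/f red-white wall pattern
#'
#' The tunnel walls are lined with a two-tone random pattern whose spatial
#' amplitude spectrum decays approximately as 1/f, a naturalistic statistic
#' widely used as a visual stimulus for flying insects. White Gaussian noise
#' is filtered in the Fourier domain with an amplitude envelope proportional
#' to 1/f (radial spatial frequency) and the result is binarised at its
#' median, giving two levels ("red" = 0, "white" = 1) each covering half of
#' the pixels. Deterministic for a given seed.
#'
#' @param seed integer seed controlling the pattern.
#' @param size integer vector `c(nrow, ncol)`, each >= 8.
#' @return matrix with values 0/1 of dimension `size`.
#' @examples
#' tex <- make_wall_texture(seed = 7, size = c(64, 64))
#' table(tex)
#' @export
make_wall_texture <- function(seed = 1L, size = c(256L, 256L)) {
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 8L)) stop("'size' must be at least 8 x 8", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nr <- size[1L]; nc <- size[2L]
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  # radial spatial frequency on the DFT grid (cycles per image)
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- 1 / f
  amp[1L, 1L] <- 0                      # no DC: binarisation centres at median
  field <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (nr * nc)
  tex <- (field > stats::median(field)) * 1
  storage.mode(tex) <- "double"
  tex
}

#' Radially averaged log-log spectral slope of a texture
#'
#' Diagnostic used to verify the 1/f statistic: computes the radially
#' averaged amplitude spectrum of a (square) image and fits a line to
#' log-amplitude vs log-frequency over the central frequency decade
#' (excluding DC and the highest octave, where pixelisation dominates).
#'
#' @param tex numeric matrix.
#' @return fitted slope (about -1 for a 1/f field).
#' @export
spectral_slope <- function(tex) {
  nr <- nrow(tex); nc <- ncol(tex)
  sp <- Mod(stats::fft(tex - mean(tex)))
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fy^2, fx^2, `+`))
  keep <- f > 0
  fq <- f[keep]; aq <- sp[keep]
  # log-spaced radial bins over the usable band
  lo <- 2 / min(nr, nc)                 # skip the first couple of DFT bins
  hi <- 0.25                            # stop below the Nyquist octave
  edges <- exp(seq(log(lo), log(hi), length.out = 16L))
  bin <- findInterval(fq, edges, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin < length(edges)
  m <- tapply(aq[ok], bin[ok], mean)
  fc <- sqrt(edges[-length(edges)] * edges[-1L])[as.integer(names(m))]
  stats::coef(stats::lm(log(m) ~ log(fc)))[[2L]]
}
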