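# Time-series analyses of per-frame area signals: frontal-vs-lateral
# regression, single-sided amplitude spectra and dominant stroke frequency.

#' Per-frame area time series
#'
#' @param area_pixels numeric vector of non-negative areas, one per frame.
#' @param fs_hz sampling rate in Hz (> 0); nominally the 30 fps of the
#'   recordings.
#' @param time_s optional explicit timestamps (strictly increasing and
#'   consistent with \code{fs_hz}); defaults to (0, 1, 2, ...) / fs_hz.
#' @param camera_label "frontal" or "lateral".
#' @return A data frame of class \code{area_series} with columns
#'   \code{frame_index}, \code{time_s}, \code{area_pixels} and attributes
#'   \code{fs_hz}, \code{camera_label}.
#' @export
area_series <- function(area_pixels, fs_hz = 30, time_s = NULL,
                        camera_label = "frontal") {
  area_pixels <- as.numeric(area_pixels)
  if (any(!is.finite(area_pixels)) || any(area_pixels < 0))
    stop("areas must be finite and >= 0")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0")
  n <- length(area_pixels)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fs_hz
  if (length(time_s) != n) stop("time_s length must match area_pixels")
  if (n > 1L) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time_s must be strictly increasing")
    if (any(abs(dt - 1 / fs_hz) > 1e-6 / fs_hz + 1e-9))
      stop("time_s spacing inconsistent with fs_hz = ", fs_hz)
  }
  structure(data.frame(frame_index = seq_len(n) - 1L,
                       time_s = time_s,
                       area_pixels = area_pixels),
            fs_hz = fs_hz, camera_label = camera_label,
            class = c("area_series", "data.frame"))
}

.series_values <- function(x) {
  if (inherits(x, "area_series")) x$area_pixels else as.numeric(x)
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("Area series (%s camera): %d frames at %g Hz, %.2f s\n",
              attr(x, "camera_label"), nrow(x), attr(x, "fs_hz"),
              nrow(x) / attr(x, "fs_hz")))
  cat(sprintf("  area [px]: min %g, median %g, max %g\n",
              min(x$area_pixels), stats::median(x$area_pixels),
              max(x$area_pixels)))
  invisible(x)
}

#' @export
plot.area_series <- function(x, ..., xlab = "time [s]",
                             ylab = "projected area [px]",
                             type = "l",
                             main = paste(attr(x, "camera_label"), "area")) {
  plot(x$time_s, x$area_pixels, type = type, xlab = xlab, ylab = ylab,
       main = main, ...)
  invisible(x)
}

#' Ordinary least-squares fit between two area series
#'
#' Fits y = slope * x + intercept by OLS; the coefficient of determination
#' equals the squared Pearson correlation of x and y. Used to quantify how
#' much of one camera's area signal is linearly explained by the other's.
#'
#' @param x,y numeric vectors or \code{\link{area_series}} of equal length
#'   (>= 3), paired frame by frame.
#' @return An object of class \code{area_regression}: list with
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{n}.
#' @export
linear_fit <- function(x, y) {
  xv <- .series_values(x); yv <- .series_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) < 3L) stop("need at least 3 paired samples")
  if (sd(xv) == 0) stop("x is constant: regression undefined")
  if (sd(yv) == 0) {
    warning("y is constant: r_squared defined as 0", call. = FALSE)
    res <- list(slope = 0, intercept = mean(yv), r_squared = 0,
                n = length(xv))
  } else {
    fit <- lm(yv ~ xv)
    res <- list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r_squared = stats::cor(xv, yv)^2,
                n = length(xv))
  }
  structure(res, class = "area_regression")
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.6g x + %.6g,  R^2 = %.6g\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Single-sided amplitude spectrum of an area series
#'
#' Removes the mean (DC suppression), zero-pads to \code{pad_factor} times
#' the record length, and returns the single-sided amplitude spectrum of
#' the discrete Fourier transform under a rectangular window. Amplitudes
#' are scaled by the record length so that a pure sinusoid of amplitude A
#' peaks at approximately A.
#'
#' @param series an \code{\link{area_series}} (or numeric vector) with at
#'   least 8 uniformly sampled values.
#' @param pad_factor integer >= 1; zero-padding refines the frequency grid
#'   to fs / (pad_factor * n) without adding information.
#' @param fs_hz sampling rate, taken from the series when available.
#' @return A data frame of class \code{area_spectrum} with columns
#'   \code{frequency_hz} (0 to Nyquist) and \code{magnitude}.
#' @export
compute_spectrum <- function(series, pad_factor = 8L, fs_hz = NULL) {
  if (inherits(series, "area_series")) {
    if (is.null(fs_hz)) fs_hz <- attr(series, "fs_hz")
    dt <- diff(series$time_s)
    if (length(dt) && max(abs(dt - 1 / fs_hz)) > 1e-6 / fs_hz + 1e-9)
      stop("non-uniform sampling: spectrum undefined")
    x <- series$area_pixels
  } else {
    x <- as.numeric(series)
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric series")
  }
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L) stop("pad_factor must be >= 1")
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples")
  nfft <- n * pad_factor
  X <- fft(c(x - mean(x), rep(0, nfft - n)))
  half <- seq_len(nfft %/% 2L + 1L)          # DC .. Nyquist
  mag <- Mod(X[half]) * 2 / n
  mag[1] <- mag[1] / 2                       # DC counted once
  if (nfft %% 2L == 0L) mag[length(half)] <- mag[length(half)] / 2
  structure(data.frame(frequency_hz = (half - 1) * fs_hz / nfft,
                       magnitude = mag),
            fs_hz = fs_hz, n = n, pad_factor = pad_factor,
            class = c("area_spectrum", "data.frame"))
}

#' @export
plot.area_spectrum <- function(x, ..., xlab = "frequency [Hz]",
                               ylab = "amplitude [px]", type = "l",
                               main = "area amplitude spectrum") {
  plot(x$frequency_hz, x$magnitude, type = type, xlab = xlab, ylab = ylab,
       main = main, ...)
  invisible(x)
}

#' Dominant frequency of a spectrum
#'
#' The frequency of the largest magnitude at or above \code{min_hz}; ties
#' are broken toward the lower frequency. \code{min_hz} excludes the
#' near-DC band where mean-removal leakage can dominate.
#'
#' @param spectrum an \code{\link{compute_spectrum}} result.
#' @param min_hz lower frequency bound (default 0.1 Hz).
#' @return named numeric c(frequency_hz, magnitude).
#' @export
dominant_frequency <- function(spectrum, min_hz = 0.1) {
  stopifnot(inherits(spectrum, "area_spectrum"), min_hz >= 0)
  band <- spectrum$frequency_hz >= min_hz
  if (!any(band)) stop("no spectral bins at or above ", min_hz, " Hz")
  f <- spectrum$frequency_hz[band]
  m <- spectrum$magnitude[band]
  if (max(m) <= 0) stop("all magnitudes zero: no periodicity detected")
  i <- which.max(m)  # first maximum = lowest frequency on ties
  c(frequency_hz = f[i], magnitude = m[i])
}
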