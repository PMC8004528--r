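#' Uniformly sampled time series
#'
#' The universal input container of the package: a numeric vector of samples
#' plus its sampling rate. All generators and analysis entry points consume
#' and return this class.
#'
#' @param samples numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz (positive scalar).
#' @return An object of class `pac_ts` with fields `samples`, `fs` and
#'   `duration` (seconds, `length(samples)/fs`).
#' @examples
#' x <- pac_ts(sin(2 * pi * 6 * seq(0, 1, by = 1 / 512)), fs = 512)
#' x
#' @export
pac_ts <- function(samples, fs) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (anyNA(samples)) stop("`samples` must not contain NA/NaN")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         duration = length(samples) / fs),
    class = "pac_ts"
  )
}

#' @export
print.pac_ts <- function(x, ...) {
  cat(sprintf("<pac_ts> %d samples @ %g Hz (%.3f s), range [%.3g, %.3g]\n",
              length(x$samples), x$fs, x$duration,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.pac_ts <- function(x) length(x$samples)

#' Time axis of a time series
#' @param x a [pac_ts()] object.
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
ts_time <- function(x) (seq_along(x$samples) - 1) / x$fs

is_pac_ts <- function(x) inherits(x, "pac_ts")

assert_ts <- function(x) {
  if (!is_pac_ts(x)) stop("expected a `pac_ts` object")
  invisible(x)
}
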