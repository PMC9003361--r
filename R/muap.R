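# Motor-unit action potential surrogate waveform.

#' Motor-unit action potential shape
#'
#' Parametrizes the first-order Hermite-Rodriguez surrogate used for single
#' motor-unit action potentials (MUAPs):
#' \deqn{w(t) = A \, (t/\tau) \, e^{-(t/\tau)^2}, \quad t \ge 0}
#' with time-scale `tau` (seconds) and peak scale `amplitude` (mV). The
#' waveform is zero at the origin, has its single positive extremum at
#' `t = tau / sqrt(2)` with value `amplitude / sqrt(2) * exp(-1/2)`, and has
#' decayed below 1% of that peak beyond `t = 4 * tau`.
#'
#' @param tau time-scale in seconds (> 0).
#' @param amplitude peak scale in mV (>= 0).
#' @return an object of class `muap_shape`.
#' @export
muap_shape <- function(tau, amplitude = 1) {
  check_positive(tau, "tau")
  check_number(amplitude, "amplitude", lower = 0)
  structure(list(tau = tau, amplitude = amplitude), class = "muap_shape")
}

#' Sample a MUAP waveform
#'
#' Evaluates the [muap_shape()] waveform on `[0, 5 * tau]` at sampling rate
#' `fs`. Sampling rates below 1 kHz under-resolve the waveform and are
#' rejected.
#'
#' @param shape a [muap_shape()].
#' @param fs sampling rate in Hz (>= 1000).
#' @return numeric vector of samples (mV).
#' @export
#' @examples
#' w <- muap_waveform(muap_shape(tau = 0.003, amplitude = 1), fs = 10000)
#' which.max(w) # peak near tau / sqrt(2) = 2.12 ms
muap_waveform <- function(shape, fs) {
  stopifnot(inherits(shape, "muap_shape"))
  check_number(fs, "fs")
  if (fs < 1000) stopf("fs must be >= 1000 Hz to resolve MUAPs (got %g)", fs)
  t <- seq(0, 5 * shape$tau, by = 1 / fs)
  u <- t / shape$tau
  shape$amplitude * u * exp(-u^2)
}
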