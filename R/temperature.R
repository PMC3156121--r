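# Temperature stimulus generation.

#' Generate a regularly sampled temperature trace
#'
#' Samples the sinusoidal waveform `T(t) = offset + amplitude *
#' sin(2*pi*t/period + phase)` at a fixed rate, emulating the
#' thermocouple record of the temperature-controlled stage.
#'
#' @param waveform a [TemperatureWaveform-class]
#' @param duration trace duration (s)
#' @param rate sampling rate (Hz)
#' @return data.frame with columns `time_s`, `temp_C`
#' @examples
#' tr <- generateTemperature(temperatureWaveform(amplitude = 1, period = 120), 240, 8)
#' max(tr$temp_C) - min(tr$temp_C)  # ~2 degC peak to peak
#' @export
generateTemperature <- function(waveform, duration, rate) {
  if (!is(waveform, "TemperatureWaveform"))
    stopc("larvagram_invalid_argument", "waveform must be a TemperatureWaveform")
  if (length(duration) != 1 || !is.finite(duration) || duration <= 0)
    stopc("larvagram_invalid_argument", "duration must be a positive number")
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stopc("larvagram_invalid_argument", "rate must be a positive number")
  t <- seq(0, duration, by = 1 / rate)
  data.frame(
    time_s = t,
    temp_C = waveform@offset +
      waveform@amplitude * sin(2 * pi * t / waveform@period + waveform@phase)
  )
}

## analytic dT/dt of a waveform at times t (used by the generator; the
## analysis side estimates the derivative from the sampled trace instead)
waveformRate <- function(waveform, t) {
  waveform@amplitude * (2 * pi / waveform@period) *
    cos(2 * pi * t / waveform@period + waveform@phase)
}
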