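# Pipeline configuration: every tunable with its default, plus YAML
# round-tripping for the command-line tools.

#' Pipeline configuration
#'
#' Collects every tunable of the extraction and reference branches. The
#' defaults are the monitoring parameters for adult laboratory rats:
#' certainty gate 0.99, respiration band 1--3.3 Hz (60--200 breaths/min),
#' second-order Butterworth, gradient clip 1.5 signal-units/sample on the
#' band-passed signal, 0.5 s maximum interpolable gap, breath-interval
#' outlier fraction 0.3, and the rat-tuned ECG peak-detection windows.
#'
#' @param score_threshold Certainty gate for valid segmentations.
#' @param band_low_hz,band_high_hz Respiration band edges, Hz.
#' @param butter_order Butterworth order.
#' @param clip_limit Gradient clip limit, signal units per sample.
#' @param gap_max_s Longest interpolable invalid-frame gap, seconds.
#' @param outlier_frac Breath-interval outlier fraction.
#' @param ecg_smoothwindow,ecg_avgwindow,ecg_min_delay,ecg_min_qrs,
#'   ecg_gradthresh_weight See [detect_r_peaks()].
#' @param ecg_powerline_hz Powerline frequency to notch.
#' @param edr_rate_out EDR resampling rate, samples/s.
#' @param edr_lowpass_hz Low-pass cutoff on the EDR branch, Hz.
#' @param seed Integer seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(score_threshold = 0.99,
                            band_low_hz = 1, band_high_hz = 3.3,
                            butter_order = 2L, clip_limit = 1.5,
                            gap_max_s = 0.5, outlier_frac = 0.3,
                            ecg_smoothwindow = 0.05, ecg_avgwindow = 0.1875,
                            ecg_min_delay = 0.1, ecg_min_qrs = 0.1,
                            ecg_gradthresh_weight = 1.5,
                            ecg_powerline_hz = 50,
                            edr_rate_out = 20, edr_lowpass_hz = 4,
                            seed = 1L) {
  cfg <- list(score_threshold = score_threshold, band_low_hz = band_low_hz,
              band_high_hz = band_high_hz,
              butter_order = as.integer(butter_order),
              clip_limit = clip_limit, gap_max_s = gap_max_s,
              outlier_frac = outlier_frac,
              ecg_smoothwindow = ecg_smoothwindow,
              ecg_avgwindow = ecg_avgwindow,
              ecg_min_delay = ecg_min_delay, ecg_min_qrs = ecg_min_qrs,
              ecg_gradthresh_weight = ecg_gradthresh_weight,
              ecg_powerline_hz = ecg_powerline_hz,
              edr_rate_out = edr_rate_out, edr_lowpass_hz = edr_lowpass_hz,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$band_low_hz < cfg$band_high_hz, cfg$band_low_hz > 0,
            cfg$score_threshold >= 0, cfg$score_threshold <= 1,
            cfg$clip_limit > 0, cfg$gap_max_s >= 0, cfg$outlier_frac >= 0,
            cfg$ecg_smoothwindow > 0, cfg$ecg_avgwindow > 0,
            cfg$ecg_min_delay > 0, cfg$ecg_min_qrs > 0,
            cfg$edr_rate_out > 2 * cfg$band_high_hz)
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' A written configuration reloads to an equal object.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
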