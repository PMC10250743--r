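# Analysis configuration: the numeric conventions of the whole pipeline.

#' Analysis configuration
#'
#' Bundles the numeric settings of the frequency and time-frequency
#' analyses. Defaults reproduce the study conventions: 1 s Hamming windows
#' zero-padded to 1024 points (0.25 Hz grid at 256 Hz) with 30 ms overlap;
#' the five bands delta 0-3, theta 4-7, alpha 8-12, beta 13-30 and
#' mains 45-55 Hz; 4th-order zero-phase Butterworth filters (0.1-100 Hz
#' broadband, 0.3-30 Hz for movement epochs, 0.5-30 Hz for display);
#' Hilbert-envelope outlier removal above 60 Hz at z > 5; a 250 uV trial
#' rejection ceiling; Morlet maps on 5-30 Hz at 0.25 Hz with a [-5, -2] s
#' baseline; and the 5 kOhm wet-EEG impedance quality threshold.
#'
#' The 30 ms overlap is honored literally (8 samples at 256 Hz, i.e.
#' near-disjoint windows); set `psd_overlap_s` to change it.
#'
#' @param psd_window_s Welch window length, seconds.
#' @param psd_nfft FFT length after zero-padding.
#' @param psd_overlap_s Welch window overlap, seconds.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @param broadband_filter,movement_filter,display_filter `c(lo, hi)` Hz.
#' @param filter_order Butterworth design order (applied forward-backward).
#' @param outlier_hp_hz High-pass edge of the outlier detector.
#' @param outlier_z Envelope z-score threshold for outliers.
#' @param trial_reject_uv Absolute amplitude ceiling for epoch rejection.
#' @param tfr_fmin,tfr_fmax,tfr_df Morlet frequency grid, Hz.
#' @param baseline_s Reference interval for ERD/ERS maps, seconds vs cue.
#' @param alpha_binwise,alpha_band Significance levels for the bin-wise and
#'   band-wise comparisons.
#' @param wet_impedance_threshold_ohm Impedance quality threshold, Ohm.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(psd_window_s = 1.0,
                            psd_nfft = 1024L,
                            psd_overlap_s = 0.030,
                            bands = list(delta = c(0, 3), theta = c(4, 7),
                                         alpha = c(8, 12), beta = c(13, 30),
                                         mains = c(45, 55)),
                            broadband_filter = c(0.1, 100),
                            movement_filter = c(0.3, 30),
                            display_filter = c(0.5, 30),
                            filter_order = 4L,
                            outlier_hp_hz = 60,
                            outlier_z = 5,
                            trial_reject_uv = 250,
                            tfr_fmin = 5,
                            tfr_fmax = 30,
                            tfr_df = 0.25,
                            baseline_s = c(-5, -2),
                            alpha_binwise = 0.05,
                            alpha_band = 0.05,
                            wet_impedance_threshold_ohm = 5000) {
  stopifnot(psd_window_s > 0, psd_nfft > 0, psd_overlap_s >= 0,
            psd_overlap_s < psd_window_s,
            filter_order >= 1, outlier_hp_hz > 0, outlier_z > 0,
            trial_reject_uv > 0, tfr_fmin > 0, tfr_fmax > tfr_fmin,
            tfr_df > 0, length(baseline_s) == 2,
            baseline_s[1] < baseline_s[2], baseline_s[2] <= 0,
            alpha_binwise > 0, alpha_binwise < 1,
            alpha_band > 0, alpha_band < 1,
            wet_impedance_threshold_ohm > 0)
  for (b in bands) {
    if (length(b) != 2 || b[1] < 0 || b[2] <= b[1]) {
      stop("each band must be c(lo, hi) with 0 <= lo < hi")
    }
  }
  for (f in list(broadband_filter, movement_filter, display_filter)) {
    if (length(f) != 2 || f[1] < 0 || f[2] <= f[1]) {
      stop("filters must be c(lo, hi) with 0 <= lo < hi")
    }
  }
  structure(list(psd_window_s = psd_window_s, psd_nfft = as.integer(psd_nfft),
                 psd_overlap_s = psd_overlap_s, bands = bands,
                 broadband_filter = broadband_filter,
                 movement_filter = movement_filter,
                 display_filter = display_filter,
                 filter_order = as.integer(filter_order),
                 outlier_hp_hz = outlier_hp_hz, outlier_z = outlier_z,
                 trial_reject_uv = trial_reject_uv,
                 tfr_fmin = tfr_fmin, tfr_fmax = tfr_fmax, tfr_df = tfr_df,
                 baseline_s = baseline_s,
                 alpha_binwise = alpha_binwise, alpha_band = alpha_band,
                 wet_impedance_threshold_ohm = wet_impedance_threshold_ohm),
            class = "analysis_config")
}
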