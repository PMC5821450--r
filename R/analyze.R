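#' Full single-footfall analysis pipeline
#'
#' Conditions a raw footfall record and extracts everything the package can
#' compute from a single stance phase: low-pass filtering of each channel,
#' stance detection and trimming, impulse-momentum consistency correction of
#' the vertical force, normalization to body weight and stance fraction,
#' scalar GRF features, sine-series coefficients of the fore-aft and vertical
#' profiles, and (when the duty factor and speed are known) whole-stride COM
#' mechanics.
#'
#' @param record A `footfall_record` in newtons (raw or pre-oriented).
#' @param cutoff Low-pass cutoff (Hz); `NULL` skips filtering.
#' @param threshold Stance threshold (N); `NULL` uses 3 SD of the first
#'   `baseline_n` samples as an unloaded baseline.
#' @param baseline_n Number of leading samples treated as baseline when
#'   `threshold` is `NULL` (default 50).
#' @param n_harmonics Harmonics retained in the sine-series fits.
#' @param g Gravitational acceleration (m/s^2).
#' @return A list with `record` (processed), `t_stance_s`, `alpha`,
#'   `features`, `fourier` (list with `x` and `z` coefficient sets), and,
#'   when `record$beta` and `record$v_mps` are available, `stride`
#'   (a `stride_mechanics` object).
#' @export
analyze_footfall <- function(record, cutoff = 50, threshold = NULL,
                             baseline_n = 50, n_harmonics = 10, g = 9.81) {
  stopifnot(inherits(record, "footfall_record"))
  fs <- record$sampling_rate_hz
  fx <- record$fx_n
  fy <- record$fy_n
  fz <- record$fz_n
  if (!is.null(cutoff)) {
    fx <- lowpass_filter(fx, fs, cutoff)
    fy <- lowpass_filter(fy, fs, cutoff)
    fz <- lowpass_filter(fz, fs, cutoff)
  }
  st <- if (is.null(threshold))
    detect_stance(fz, fs, baseline = fz[seq_len(min(baseline_n, length(fz)))])
  else detect_stance(fz, fs, threshold = threshold)
  idx <- st$touchdown:st$liftoff
  trimmed <- footfall_record(record$time_s[idx], fx[idx], fy[idx], fz[idx],
                             mass_kg = record$mass_kg, beta = record$beta,
                             v_mps = record$v_mps,
                             hip_height_m = record$hip_height_m,
                             side = record$side,
                             processed = union(record$processed,
                                               c("filtered", "stance-trimmed")))
  alpha <- NA_real_
  if (is.finite(trimmed$beta)) {
    ic <- impulse_correction(trimmed$fz_n, trimmed$mass_kg, st$t_stance_s,
                             trimmed$beta, time_s = trimmed$time_s -
                               trimmed$time_s[1], g = g)
    trimmed$fz_n <- ic$fz_adjusted
    trimmed$processed <- union(trimmed$processed, "impulse-corrected")
    alpha <- ic$alpha
  }
  norm <- normalize_footfall(trimmed, g = g)
  feats <- extract_features(norm$fx, norm$fz, norm$fy, t = norm$t)
  four <- list(
    x = fit_fourier(norm$fx, t = norm$t, n_max = n_harmonics,
                    component = "x"),
    z = fit_fourier(norm$fz, t = norm$t, n_max = n_harmonics,
                    component = "z"))
  stride <- NULL
  if (is.finite(trimmed$beta) && is.finite(trimmed$v_mps))
    stride <- stride_mechanics(norm$fz, norm$fx, beta = trimmed$beta,
                               mass_kg = trimmed$mass_kg,
                               v_mps = trimmed$v_mps,
                               t_stance_s = st$t_stance_s,
                               h = if (is.finite(trimmed$hip_height_m))
                                 trimmed$hip_height_m else NULL,
                               t_stance = norm$t, g = g)
  list(record = trimmed, t_stance_s = st$t_stance_s, alpha = alpha,
       features = feats, fourier = four, stride = stride)
}
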