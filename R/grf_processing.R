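#' Construct a single-footfall GRF record
#'
#' Bundles a uniformly sampled three-component ground reaction force record
#' with its trial metadata. Components are in the anatomical frame:
#' +x forward, +y medial, +z up.
#'
#' @param time_s Time vector (s), strictly increasing and uniform.
#' @param fx_n,fy_n,fz_n Force components (N).
#' @param mass_kg Body mass (kg).
#' @param beta Duty factor (optional).
#' @param v_mps Mean forward speed (m/s, optional).
#' @param hip_height_m Standing hip height (m, optional).
#' @param side `"left"` or `"right"`.
#' @param processed Character vector of processing steps already applied,
#'   subset of `c("filtered", "oriented", "stance-trimmed",
#'   "impulse-corrected")`.
#' @return An object of class `footfall_record`.
#' @export
footfall_record <- function(time_s, fx_n, fy_n, fz_n, mass_kg,
                            beta = NA_real_, v_mps = NA_real_,
                            hip_height_m = NA_real_, side = "right",
                            processed = character()) {
  n <- length(time_s)
  stopifnot(length(fx_n) == n, length(fy_n) == n, length(fz_n) == n, n >= 2)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("'time_s' must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("'time_s' must be uniformly sampled")
  if (!is.numeric(mass_kg) || mass_kg <= 0) stop("'mass_kg' must be positive")
  side <- match.arg(side, c("left", "right"))
  structure(list(
    time_s = time_s, fx_n = fx_n, fy_n = fy_n, fz_n = fz_n,
    sampling_rate_hz = 1 / dt[1], mass_kg = mass_kg, beta = beta,
    v_mps = v_mps, hip_height_m = hip_height_m, side = side,
    processed = processed
  ), class = "footfall_record")
}

#' @export
print.footfall_record <- function(x, ...) {
  cat("Single-footfall GRF record:", length(x$time_s), "samples @",
      round(x$sampling_rate_hz, 1), "Hz\n")
  cat("  mass:", x$mass_kg, "kg | side:", x$side,
      "| duty factor:", x$beta, "| speed:", x$v_mps, "m/s\n")
  cat("  processed:", if (length(x$processed))
    paste(x$processed, collapse = ", ") else "(raw)", "\n")
  invisible(x)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward then backward, giving zero
#' phase lag and a magnitude response of twice the design order (the default
#' second-order design yields an overall fourth-order response, the standard
#' conditioning for force-plate data). The signal is reflect-padded at both
#' ends before filtering to suppress end transients.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), must be below the Nyquist rate.
#' @param order Design order per pass (default 2; use 4 for an overall
#'   eighth-order response).
#' @param pad Number of reflected samples prepended/appended before filtering;
#'   defaults to `min(n - 1, max(12, 3 * round(fs/cutoff)))`.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff, order = 2,
                           pad = NULL) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("'cutoff' must lie strictly between 0 and the Nyquist rate fs/2")
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, max(12L, 3L * round(fs / cutoff)))
  pad <- min(pad, n - 1L)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y <- as.numeric(y)
  y[(pad + 1L):(pad + n)]
}

#' Orient raw plate forces into the anatomical frame
#'
#' Re-expresses raw force-plate components in a consistent animal-fixed frame
#' (+x forward, +y medial, +z up), given the direction of heading along the
#' plate axis and which foot struck the plate. The vertical component is
#' unchanged; the fore-aft component follows the heading; the lateral
#' component is flipped so that +y is always medial (towards the midline).
#'
#' @param raw_fx,raw_fy,raw_fz Raw components in the plate frame (N).
#' @param heading `+1` or `-1`: direction of travel along the plate +x axis.
#' @param side `"left"` or `"right"` foot.
#' @return A list with oriented `fx`, `fy`, `fz`.
#' @export
to_anatomical_frame <- function(raw_fx, raw_fy, raw_fz, heading = 1,
                                side = "right") {
  if (!heading %in% c(1, -1)) stop("'heading' must be +1 or -1")
  side <- match.arg(side, c("left", "right"))
  fy_lab <- heading * raw_fy
  list(fx = heading * raw_fx,
       fy = if (side == "right") fy_lab else -fy_lab,
       fz = raw_fz)
}

#' Detect the stance phase from the vertical force
#'
#' Finds touchdown and liftoff as the first and last samples of the longest
#' contiguous run of vertical force above a noise threshold. Short spurious
#' excursions (noise spikes) outside the main loaded region are ignored by
#' the longest-run rule.
#'
#' @param fz Vertical force (N).
#' @param fs Sampling rate (Hz).
#' @param threshold Force threshold (N) separating loading from baseline
#'   noise. If a `baseline` segment is given, defaults to 3 standard
#'   deviations of that segment.
#' @param baseline Optional vector of unloaded baseline samples used to set
#'   the threshold.
#' @return A list with `touchdown` and `liftoff` (sample indices) and
#'   `t_stance_s`.
#' @export
detect_stance <- function(fz, fs, threshold = NULL, baseline = NULL) {
  if (is.null(threshold)) {
    if (is.null(baseline))
      stop("supply either 'threshold' or a 'baseline' segment")
    threshold <- 3 * stats::sd(baseline)
  }
  loaded <- fz > threshold
  if (!any(loaded)) stop("no sample exceeds the stance threshold")
  r <- rle(loaded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lens <- r$lengths[runs]
  best <- runs[which.max(lens)]
  if (sum(lens >= 0.9 * max(lens)) > 1L)
    warning("multiple loaded runs of comparable length; returning the longest")
  td <- starts[best]
  lo <- ends[best]
  list(touchdown = td, liftoff = lo, t_stance_s = (lo - td) / fs)
}

#' Impulse-momentum consistency correction of the vertical force
#'
#' In steady-state locomotion the net vertical impulse over an integral
#' number of strides is zero, so for a biped the recorded vertical impulse of
#' one footfall, \eqn{I_z}, must equal half the body-weight impulse over the
#' stride: \eqn{2 I_z = I_w}. Measurement errors in mass, stance duration,
#' duty factor or force break this balance; the remedy is a proportional
#' rescaling of the vertical component,
#' \eqn{F_z' = \alpha F_z} with
#' \eqn{\alpha = m g t_{stance} / (2 \beta \int F_z\, dt)}.
#' Only the vertical component is adjusted; fore-aft and mediolateral forces
#' are untouched.
#'
#' @param fz Vertical force over the stance (N).
#' @param mass_kg Body mass (kg).
#' @param t_stance_s Stance duration (s).
#' @param beta Duty factor, in (0, 1).
#' @param time_s Optional time vector for the samples; defaults to a uniform
#'   grid spanning `t_stance_s`.
#' @param g Gravitational acceleration (m/s^2).
#' @return A list with the adjustment factor `alpha`, the `fz_adjusted`
#'   series, the recorded impulse `iz_ns` and the body-weight impulse over
#'   the stride `iw_ns`.
#' @export
impulse_correction <- function(fz, mass_kg, t_stance_s, beta,
                               time_s = NULL, g = 9.81) {
  if (beta <= 0 || beta >= 1) stop("'beta' must lie in (0, 1)")
  if (mass_kg <= 0 || t_stance_s <= 0)
    stop("'mass_kg' and 't_stance_s' must be positive")
  if (is.null(time_s)) time_s <- seq(0, t_stance_s, length.out = length(fz))
  iz <- pracma::trapz(time_s, fz)
  if (iz <= 0) stop("recorded vertical impulse must be positive")
  iw <- mass_kg * g * t_stance_s / beta   # body-weight impulse over the stride
  alpha <- iw / (2 * iz)
  list(alpha = alpha, fz_adjusted = alpha * fz, iz_ns = iz, iw_ns = iw)
}

#' Read/write single-footfall GRF records as CSV
#'
#' The CSV dialect has columns `time_s, fx_n, fy_n, fz_n`; trial metadata is
#' stored in leading comment lines beginning `#` as `key: value` pairs
#' (`mass_kg`, `beta`, `v_mps`, `hip_height_m`, `side`).
#'
#' @param path File path.
#' @return `read_footfall()` returns a `footfall_record`;
#'   `write_footfall()` invisibly returns `path`.
#' @export
read_footfall <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in hdr) {
    kv <- sub("^#\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  num <- function(k, d = NA_real_) {
    if (is.null(meta[[k]]) || meta[[k]] == "NA") return(d)
    as.numeric(meta[[k]])
  }
  footfall_record(df$time_s, df$fx_n, df$fy_n, df$fz_n,
                  mass_kg = num("mass_kg"),
                  beta = num("beta"), v_mps = num("v_mps"),
                  hip_height_m = num("hip_height_m"),
                  side = if (!is.null(meta$side)) meta$side else "right",
                  processed = if (!is.null(meta$processed))
                    strsplit(meta$processed, ",\\s*")[[1]] else character())
}

#' @rdname read_footfall
#' @param record A `footfall_record`.
#' @export
write_footfall <- function(record, path) {
  stopifnot(inherits(record, "footfall_record"))
  hdr <- c(
    paste("# mass_kg:", record$mass_kg),
    paste("# beta:", record$beta),
    paste("# v_mps:", record$v_mps),
    paste("# hip_height_m:", record$hip_height_m),
    paste("# side:", record$side),
    paste("# processed:", paste(record$processed, collapse = ", "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = record$time_s, fx_n = record$fx_n,
                              fy_n = record$fy_n, fz_n = record$fz_n),
                   con, row.names = FALSE)
  invisible(path)
}

#' Normalize a trimmed footfall to body weight and stance fraction
#'
#' Converts a stance-trimmed record to the dimensionless domain used by all
#' downstream analysis: forces in body weights (BW = m*g) and time as stance
#' fraction t in [0, 1] (touchdown = 0, liftoff = 1).
#'
#' @param record A stance-trimmed `footfall_record`.
#' @param g Gravitational acceleration (m/s^2).
#' @return A data frame with columns `t` (stance fraction), `fx`, `fy`, `fz`
#'   (BW), with the stance duration attached as attribute `t_stance_s`.
#' @export
normalize_footfall <- function(record, g = 9.81) {
  stopifnot(inherits(record, "footfall_record"))
  bw <- record$mass_kg * g
  tt <- record$time_s - record$time_s[1]
  t_stance <- tt[length(tt)]
  out <- data.frame(t = tt / t_stance, fx = record$fx_n / bw,
                    fy = record$fy_n / bw, fz = record$fz_n / bw)
  attr(out, "t_stance_s") <- t_stance
  out
}
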