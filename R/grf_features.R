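# Parabolic sub-sample refinement of a peak: fits a parabola through the
# argmax sample and its two neighbours; robust across 50 Hz-10 kHz records.
refine_peak <- function(t, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(t = t[i], y = y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(list(t = t[i], y = y[i]))
  d <- 0.5 * (y1 - y3) / den
  d <- max(min(d, 0.5), -0.5)
  dt <- t[i + 1L] - t[i]
  list(t = t[i] + d * dt, y = y2 - 0.25 * (y1 - y3) * d)
}

# Zero crossing of fx from negative (braking) to positive (propulsion).
# Slow-speed profiles can cross more than once; the rule takes the crossing
# that best separates the dominant negative impulse from the dominant
# positive impulse.
fx_zero_crossing <- function(t, fx) {
  s <- sign(fx)
  idx <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (!length(idx)) return(list(t = NA_real_, multiple = FALSE))
  cross_t <- vapply(idx, function(i) {
    if (fx[i + 1L] == fx[i]) return(t[i])
    t[i] + (0 - fx[i]) / (fx[i + 1L] - fx[i]) * (t[i + 1L] - t[i])
  }, numeric(1))
  if (length(idx) == 1L) return(list(t = cross_t, multiple = FALSE))
  # braking impulse = total negative impulse; pick the crossing where the
  # accumulated negative impulse before it best matches it
  dt <- diff(t)
  seg <- (fx[-length(fx)] + fx[-1]) / 2 * dt
  neg_total <- sum(seg[seg < 0])
  mismatch <- vapply(seq_along(idx), function(k) {
    before <- sum(seg[seq_len(idx[k])][seg[seq_len(idx[k])] < 0])
    abs(abs(before) - abs(neg_total))
  }, numeric(1))
  list(t = cross_t[which.min(mismatch)], multiple = TRUE)
}

#' Extract scalar GRF descriptors from a processed footfall
#'
#' Computes the standard catalogue of force and timing features from a
#' stance-trimmed profile normalized to body weight and stance fraction:
#' peak magnitudes of the vertical, fore-aft (positive and negative) and net
#' GRF with their timings (argmax with parabolic sub-sample refinement),
#' stance-averaged vertical force, midstance values (linear interpolation at
#' t = 0.5), and the braking-to-propulsion transition where the fore-aft
#' force crosses zero together with the vertical force at that instant.
#'
#' @param fx,fz Fore-aft and vertical force (BW) over the stance.
#' @param fy Mediolateral force (BW); defaults to zero.
#' @param t Stance fractions; defaults to a uniform grid on [0, 1].
#' @return An object of class `grf_features`: a named list of scalars.
#'   If `fx` never crosses from negative to positive, `t_fx_zero` and
#'   `fz_at_fx_zero` are `NA`. Multiple candidate crossings raise a warning
#'   and the crossing separating the dominant braking impulse from the
#'   dominant propulsive impulse is used.
#' @export
extract_features <- function(fx, fz, fy = NULL, t = NULL) {
  n <- length(fz)
  stopifnot(length(fx) == n, n >= 3)
  if (is.null(fy)) fy <- numeric(n)
  if (is.null(t)) t <- seq(0, 1, length.out = n)
  fnet <- sqrt(fx^2 + fy^2 + fz^2)

  pk <- function(y) refine_peak(t, y, which.max(y))
  p_fz <- pk(fz)
  p_net <- pk(fnet)
  p_fxp <- pk(fx)
  p_fxn <- refine_peak(t, fx, which.min(fx))

  at_mid <- function(y) stats::approx(t, y, xout = 0.5)$y
  cr <- fx_zero_crossing(t, fx)
  if (isTRUE(cr$multiple))
    warning("multiple braking-to-propulsion crossings; ",
            "using the impulse-balance crossing")
  fz_at_zero <- if (is.na(cr$t)) NA_real_ else stats::approx(t, fz,
                                                             xout = cr$t)$y
  structure(list(
    fz_peak = p_fz$y, t_fz_peak = p_fz$t,
    fz_mean = pracma::trapz(t, fz) / (max(t) - min(t)),
    fnet_peak = p_net$y, t_fnet_peak = p_net$t,
    fx_peak_pos = max(p_fxp$y, 0), t_fx_peak_pos = p_fxp$t,
    fx_peak_neg = min(p_fxn$y, 0), t_fx_peak_neg = p_fxn$t,
    t_fx_zero = cr$t, fz_at_fx_zero = fz_at_zero,
    fx_ms = at_mid(fx), fz_ms = at_mid(fz),
    fnet_ms = at_mid(fnet)
  ), class = "grf_features")
}

#' @export
print.grf_features <- function(x, ...) {
  cat("GRF features (forces in BW, times as stance fraction):\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %s\n", nm, signif(x[[nm]], 4)))
  invisible(x)
}

#' @export
as.data.frame.grf_features <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Vertical-profile asymmetry ratio
#'
#' The ratio of the second to the first vertical sine coefficient,
#' Za2/Za1. The first harmonic sets the overall magnitude of the vertical
#' profile; the second adds force to one end of the stance and removes it
#' from the other, so their ratio is a magnitude-normalized measure of
#' temporal skew: positive values give an early-skewed profile, negative
#' values a late-skewed one (second hump larger, as at very slow speeds).
#'
#' @param za Vertical sine coefficients (Za1, Za2, ...), or a
#'   `fourier_coefficients` object.
#' @return The scalar ratio Za2/Za1.
#' @export
asymmetry_ratio <- function(za) {
  if (inherits(za, "fourier_coefficients")) za <- za$a
  if (length(za) < 1 || za[1] == 0)
    stop("asymmetry ratio undefined: Za1 is zero")
  if (length(za) < 2) return(0)
  za[2] / za[1]
}

#' Export a table of features for many footfalls
#'
#' @param features_list A list of `grf_features` objects.
#' @param path Optional CSV path; when `NULL` the data frame is returned.
#' @return A data frame, one row per footfall.
#' @export
features_table <- function(features_list, path = NULL) {
  df <- do.call(rbind, lapply(features_list, as.data.frame))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
  } else df
}
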