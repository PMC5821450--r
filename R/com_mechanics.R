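#' Synthesize a whole-stride two-foot force profile from one footfall
#'
#' With the duty factor known, the total force on the body over a full stride
#' can be simulated by superimposing the recorded single-footfall profile
#' onto itself with a half-stride temporal offset (steady, symmetric
#' locomotion assumed). Each footfall occupies a window of normalized length
#' `beta` in the stride period [0, 1); footfalls wrap periodically. For
#' `beta > 0.5` the two stance windows overlap (double support), for
#' `beta < 0.5` the total force is zero in the two aerial windows.
#'
#' @param fz,fx Single-footfall profiles (BW) on the stance-fraction grid
#'   `t_stance`.
#' @param beta Duty factor in (0, 1).
#' @param t_stance Stance fractions of the input samples; defaults to a
#'   uniform grid on [0, 1].
#' @param n_samples Stride grid resolution (default 2000).
#' @return A list with `t` (stride fraction in [0, 1)), `fz_total`,
#'   `fx_total` (BW).
#' @export
synthesize_whole_stride <- function(fz, fx = NULL, beta,
                                    t_stance = NULL, n_samples = 2000) {
  if (beta <= 0 || beta >= 1) stop("'beta' must lie in (0, 1)")
  n_in <- length(fz)
  if (is.null(fx)) fx <- numeric(n_in)
  stopifnot(length(fx) == n_in)
  if (is.null(t_stance)) t_stance <- seq(0, 1, length.out = n_in)
  tg <- (seq_len(n_samples) - 1) / n_samples
  one_foot <- function(offset, y) {
    s <- ((tg - offset) %% 1) / beta
    on <- s <= 1
    out <- numeric(n_samples)
    out[on] <- stats::approx(t_stance, y, xout = s[on], rule = 2)$y
    out
  }
  list(t = tg,
       fz_total = one_foot(0, fz) + one_foot(0.5, fz),
       fx_total = one_foot(0, fx) + one_foot(0.5, fx))
}

#' Integrate whole-stride forces to centre-of-mass motion and energies
#'
#' Single and double integration of the total force-time profile under the
#' steady-state periodicity assumption: vertical acceleration is
#' \eqn{g(F_z^{tot} - 1)} (BW units), the vertical velocity integration
#' constant is chosen so the stride-mean vertical velocity is zero, the
#' vertical position is referenced to its stride mean, and the forward
#' velocity integration constant is chosen so its stride mean equals the
#' measured mean speed. Kinetic energy uses forward + vertical velocity only
#' (mediolateral forces are small, unpredictable from speed, and contribute
#' negligibly to COM energy fluctuations).
#'
#' @param fz_total,fx_total Total two-foot forces (BW) on a uniform stride
#'   grid.
#' @param mass_kg Body mass (kg).
#' @param v_mps Mean forward speed (m/s).
#' @param t_stride_s Stride duration (s).
#' @param g Gravitational acceleration (m/s^2).
#' @param demean_fx If `TRUE` (default) subtract the stride-mean fore-aft
#'   force before integrating, so forward velocity is periodic. Profiles
#'   reconstructed from fitted sine coefficients carry a small spurious net
#'   fore-aft impulse; removing it keeps the single-stride analysis
#'   well-posed.
#' @return A list with `t` (stride fraction), `vz`, `vx` (m/s), `z` (m, about
#'   its mean), `ke`, `pe` (J), and the periodic-closure residuals
#'   `net_dvz`, `net_dvx` (net change in velocity over the full stride
#'   period; zero to machine precision when the forces are
#'   impulse-balanced).
#' @export
integrate_com <- function(fz_total, fx_total, mass_kg, v_mps, t_stride_s,
                          g = 9.81, demean_fx = TRUE) {
  if (mass_kg <= 0 || t_stride_s <= 0)
    stop("'mass_kg' and 't_stride_s' must be positive")
  n <- length(fz_total)
  stopifnot(length(fx_total) == n, n >= 3)
  dt <- t_stride_s / n
  # cumulative trapezoid on a periodic grid (samples at k*dt, k = 0..n-1,
  # with the signal wrapping at t = t_stride): the net change over the full
  # period is dt * sum(y), so a zero-mean integrand integrates to an exactly
  # periodic result
  cum_per <- function(y)
    c(0, cumsum(dt * (y[-n] + y[-1]) / 2))
  az <- g * (fz_total - 1)
  vz <- cum_per(az)
  vz <- vz - mean(vz)
  z <- cum_per(vz)
  z <- z - mean(z)
  fx_use <- if (demean_fx) fx_total - mean(fx_total) else fx_total
  ax <- g * fx_use
  vx <- cum_per(ax)
  vx <- vx - mean(vx) + v_mps
  list(t = (seq_len(n) - 1) / n, vz = vz, vx = vx, z = z,
       ke = 0.5 * mass_kg * (vx^2 + vz^2), pe = mass_kg * g * z,
       net_dvz = dt * sum(az), net_dvx = dt * sum(ax))
}

#' Percent congruity of kinetic and potential energy
#'
#' The percentage of the stride over which the slopes of the KE-time and
#' PE-time curves share sign. In pure vaulting (pendular) mechanics KE and PE
#' trade off exactly and percent congruity is 0\%; in pure bouncing
#' (spring-like) mechanics they fluctuate in phase and percent congruity is
#' 100\%. Grid intervals where either slope is within a dead band of zero
#' (numerical noise at the extrema) are excluded from the denominator.
#'
#' @param ke,pe Energy series (J) over exactly one stride, on a common grid.
#' @param deadband Relative slope threshold below which an interval is
#'   treated as flat (default 1e-9 of each curve's range).
#' @return Percent congruity in [0, 100].
#' @export
percent_congruity <- function(ke, pe, deadband = 1e-9) {
  n <- length(ke)
  stopifnot(length(pe) == n, n >= 3)
  dke <- diff(ke)
  dpe <- diff(pe)
  keep <- abs(dke) > deadband * diff(range(ke)) &
    abs(dpe) > deadband * diff(range(pe))
  if (!any(keep)) stop("all intervals below dead band: congruity undefined")
  100 * mean(sign(dke[keep]) == sign(dpe[keep]))
}

#' Net vertical displacement of the COM
#'
#' The peak-to-peak excursion of the vertical COM position over one stride;
#' normalized to hip height it expresses how much the COM bobs up and down
#' relative to body size.
#'
#' @param z Vertical COM position (m) over exactly one stride.
#' @param h Standing hip height (m), used for normalization (optional).
#' @return A list with `nvd_m` and, when `h` is given, `nvd_star = nvd_m/h`.
#' @export
net_vertical_displacement <- function(z, h = NULL) {
  nvd <- max(z) - min(z)
  if (is.null(h)) return(list(nvd_m = nvd, nvd_star = NULL))
  if (h <= 0) stop("'h' must be positive")
  list(nvd_m = nvd, nvd_star = nvd / h)
}

#' Whole-stride COM mechanics from a single footfall
#'
#' Convenience pipeline: superimpose the footfall at the given duty factor,
#' rescale the vertical profile so its stride mean is exactly one body
#' weight (the impulse-momentum consistency condition), integrate to COM
#' motion, and score percent congruity and net vertical displacement.
#'
#' @param fz,fx Single-footfall profiles (BW) on a stance-fraction grid.
#' @param beta Duty factor.
#' @param mass_kg Body mass (kg).
#' @param v_mps Mean forward speed (m/s).
#' @param t_stance_s Stance duration (s).
#' @param h Standing hip height (m), optional, for NVD*.
#' @param t_stance Stance fractions of the inputs.
#' @param n_samples Stride grid resolution.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `stride_mechanics`: the stride grid and force,
#'   velocity, position and energy series plus `percent_congruity`, `nvd_m`,
#'   `nvd_star`.
#' @export
stride_mechanics <- function(fz, fx, beta, mass_kg, v_mps, t_stance_s,
                             h = NULL, t_stance = NULL, n_samples = 2000,
                             g = 9.81) {
  stride <- synthesize_whole_stride(fz, fx, beta, t_stance = t_stance,
                                    n_samples = n_samples)
  # enforce the 2Iz = Iw balance on the synthesized stride
  fz_tot <- stride$fz_total / mean(stride$fz_total)
  t_stride_s <- t_stance_s / beta
  com <- integrate_com(fz_tot, stride$fx_total, mass_kg, v_mps, t_stride_s,
                       g = g)
  nvd <- net_vertical_displacement(com$z, h)
  structure(c(list(t = stride$t, fz_total = fz_tot,
                   fx_total = stride$fx_total, t_stride_s = t_stride_s),
              com[c("vz", "vx", "z", "ke", "pe", "net_dvz", "net_dvx")],
              list(percent_congruity = percent_congruity(com$ke, com$pe),
                   nvd_m = nvd$nvd_m, nvd_star = nvd$nvd_star)),
            class = "stride_mechanics")
}

#' @export
print.stride_mechanics <- function(x, ...) {
  cat("Whole-stride COM mechanics:\n")
  cat(sprintf("  percent congruity: %.1f%%\n", x$percent_congruity))
  cat(sprintf("  net vertical displacement: %.4g m", x$nvd_m))
  if (!is.null(x$nvd_star)) cat(sprintf(" (NVD* = %.4g)", x$nvd_star))
  cat("\n  stride duration:", signif(x$t_stride_s, 4), "s on",
      length(x$t), "samples\n")
  invisible(x)
}
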