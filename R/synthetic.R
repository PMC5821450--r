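#' Generate a synthetic single-footfall force-plate record
#'
#' Builds a band-limited footfall from sine-series coefficients (so the true
#' waveform is known exactly), scales it to newtons, samples it at a
#' configurable rate over the stance duration, adds i.i.d. Gaussian sensor
#' noise, and pads unloaded margins before touchdown and after liftoff.
#' Used throughout the test suite for parameter-recovery checks of the
#' processing, Fourier and correction stages.
#'
#' @param za Vertical sine coefficients (BW).
#' @param xa Fore-aft sine coefficients (BW), default none (zero fx).
#' @param mass_kg Body mass (kg).
#' @param t_stance_s Stance duration (s).
#' @param sampling_rate_hz Sampling rate (default 1000 Hz).
#' @param noise_sd_bw Gaussian noise standard deviation, in BW (default 0).
#' @param pad_s Unloaded margin before touchdown and after liftoff (s).
#' @param beta Duty factor stored in the record metadata.
#' @param v_mps Mean speed stored in the metadata.
#' @param impulse_scale Multiplier applied to the vertical force, to emulate
#'   a dynamically inconsistent recording (default 1 = consistent).
#' @param seed Optional integer seed; fixes all randomness.
#' @param g Gravitational acceleration (m/s^2).
#' @return A `footfall_record` in newtons, with attribute `truth` holding
#'   the generating coefficients and stance window indices.
#' @export
make_footfall <- function(za, xa = NULL, mass_kg = 1, t_stance_s = 0.25,
                          sampling_rate_hz = 1000, noise_sd_bw = 0,
                          pad_s = 0.05, beta = 0.5, v_mps = NA_real_,
                          impulse_scale = 1, seed = NULL, g = 9.81) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / sampling_rate_hz
  n_pad <- round(pad_s / dt)
  n_st <- round(t_stance_s / dt) + 1L
  s <- seq(0, 1, length.out = n_st)
  bw <- mass_kg * g
  fz <- impulse_scale * reconstruct(fourier_coefficients(za), s) * bw
  fx <- if (is.null(xa)) numeric(n_st)
  else reconstruct(fourier_coefficients(xa), s) * bw
  zpad <- numeric(n_pad)
  fz_all <- c(zpad, fz, zpad)
  fx_all <- c(zpad, fx, zpad)
  n <- length(fz_all)
  if (noise_sd_bw > 0) {
    fz_all <- fz_all + stats::rnorm(n, 0, noise_sd_bw * bw)
    fx_all <- fx_all + stats::rnorm(n, 0, noise_sd_bw * bw)
  }
  rec <- footfall_record(time_s = (seq_len(n) - 1) * dt,
                         fx_n = fx_all, fy_n = numeric(n), fz_n = fz_all,
                         mass_kg = mass_kg, beta = beta, v_mps = v_mps)
  attr(rec, "truth") <- list(za = za, xa = xa, stance_idx = n_pad +
                               seq_len(n_st), t_stance_s = t_stance_s,
                             impulse_scale = impulse_scale)
  rec
}

#' Generate a multi-species speed-scaling trial table with known laws
#'
#' Draws per-trial relative speeds uniformly from a range and generates each
#' variable from its law in a generating `scaling_model` (evaluated at the
#' species mass for mass-modulated coefficients), plus additive Gaussian
#' noise. The result is the long-format table consumed by
#' [fit_scaling_protocol()], enabling end-to-end parameter-recovery tests of
#' the regression protocol.
#'
#' @param model Generating `scaling_model`.
#' @param species Data frame with columns `species` and `mass_kg`.
#' @param n_per_species Trials per species.
#' @param variables Which model variables to generate (default: all).
#' @param v_star_range Range of relative speeds sampled (default 0.3-1.5,
#'   the well-sampled span of the empirical data).
#' @param noise_sd Additive Gaussian noise SD, recycled over variables
#'   (default 0 = noiseless).
#' @param seed Optional integer seed; fixes all randomness end-to-end.
#' @return Long-format data frame: `species`, `mass_kg`, `v_star`,
#'   `variable`, `value`.
#' @export
make_scaling_dataset <- function(model, species, n_per_species = 20,
                                 variables = names(model),
                                 v_star_range = c(0.3, 1.5),
                                 noise_sd = 0, seed = NULL) {
  stopifnot(all(c("species", "mass_kg") %in% names(species)))
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- rep_len(noise_sd, length(variables))
  names(noise_sd) <- variables
  rows <- lapply(seq_len(nrow(species)), function(i) {
    vs <- stats::runif(n_per_species, v_star_range[1], v_star_range[2])
    per_var <- lapply(variables, function(var) {
      val <- evaluate_scaling(model, var, vs, species$mass_kg[i])
      if (noise_sd[var] > 0)
        val <- val + stats::rnorm(n_per_species, 0, noise_sd[var])
      data.frame(species = species$species[i],
                 mass_kg = species$mass_kg[i], v_star = vs,
                 variable = var, value = val)
    })
    do.call(rbind, per_var)
  })
  do.call(rbind, rows)
}
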