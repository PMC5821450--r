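#' Predict morphometrics from leg length and/or body mass
#'
#' Fills in missing morphometric quantities using the packaged cross-species
#' scaling relations. Standing hip height is estimated two ways: the direct
#' power law on leg length (which over-predicts at large body size), and the
#' preferred degree-of-crouch route — estimate DC from leg length (or mass
#' when L is unknown), then `h = L*(1 - DC)` — which accounts for larger
#' animals standing more erect.
#'
#' @param leg_length_m Total leg length L (m), optional.
#' @param mass_kg Body mass (kg), optional. At least one of the two must be
#'   given.
#' @return A list with `mass_kg`, `leg_length_m`, `degree_of_crouch`,
#'   `hip_height_m` (DC route, the default used downstream) and
#'   `hip_height_direct_m` (direct h-vs-L power law; `NA` when L had to be
#'   estimated from mass is not the case — it is always reported).
#' @export
predict_morphometrics <- function(leg_length_m = NULL, mass_kg = NULL) {
  if (is.null(leg_length_m) && is.null(mass_kg))
    stop("supply at least one of 'leg_length_m' or 'mass_kg'")
  fits <- morphometric_fits()
  L_given <- !is.null(leg_length_m)
  if (!L_given) leg_length_m <- eval_morph(fits, "L_vs_m", mass_kg)
  DC <- if (L_given) eval_morph(fits, "DC_vs_L", leg_length_m)
  else eval_morph(fits, "DC_vs_m", mass_kg)
  list(mass_kg = if (is.null(mass_kg)) NA_real_ else mass_kg,
       leg_length_m = leg_length_m,
       degree_of_crouch = DC,
       hip_height_m = hip_height_from_crouch(leg_length_m, DC),
       hip_height_direct_m = eval_morph(fits, "h_vs_L", leg_length_m))
}

#' Predict gait, GRF waveforms and COM mechanics from mass and speed
#'
#' The forward predictive model. From body mass, forward speed and
#' (optionally) total leg length it predicts, in order: standing hip height
#' (degree-of-crouch route), dimensionless speed v*, duty factor, stance
#' duration and stride length, the sagittal GRF waveforms reconstructed from
#' the speed-scaling laws of the fore-aft (Xa2-Xa5) and vertical (Za1-Za6)
#' sine coefficients, scalar GRF features from that reconstruction (plus the
#' direct regression predictions of the same features), and whole-stride COM
#' mechanics (percent congruity, net vertical displacement).
#'
#' Speeds outside the empirically sampled range (v* in about [0.1, 3]) or
#' masses outside 0.047-74.35 kg produce an extrapolation warning, never an
#' error: extrapolation to extinct taxa is the model's purpose, but the
#' uncertainty grows outside the calibration range.
#'
#' @param mass_kg Body mass (kg).
#' @param v_mps Forward speed (m/s).
#' @param leg_length_m Total leg length (m), optional but recommended.
#' @param model A `scaling_model` (defaults to the packaged avian model).
#' @param g Gravitational acceleration (m/s^2).
#' @param n_grid Stance reconstruction grid size (default 1001).
#' @param n_stride Whole-stride grid size (default 2000).
#' @return An object of class `locomotion_prediction`.
#' @export
predict_locomotion <- function(mass_kg, v_mps, leg_length_m = NULL,
                               model = avian_scaling_model(), g = 9.81,
                               n_grid = 1001, n_stride = 2000) {
  if (mass_kg <= 0 || v_mps <= 0)
    stop("'mass_kg' and 'v_mps' must be positive")
  morpho <- predict_morphometrics(leg_length_m, mass_kg)
  h <- morpho$hip_height_m
  v_star <- v_mps / sqrt(g * h)
  if (v_star < 0.1 || v_star > 3)
    warning(sprintf("v* = %.3g lies outside the empirical range [0.1, 3]; ",
                    v_star), "prediction is an extrapolation")
  if (mass_kg < 0.047 || mass_kg > 74.35)
    warning("mass outside the 0.047-74.35 kg calibration range; ",
            "prediction is an extrapolation")

  beta <- evaluate_scaling(model, "beta", v_star, mass_kg)
  t_stance_star <- evaluate_scaling(model, "t_stance_star", v_star, mass_kg)
  S_star <- evaluate_scaling(model, "S_star", v_star, mass_kg)
  t_stance_s <- t_stance_star * sqrt(h / g)
  S_m <- S_star * h
  t_stride_s <- t_stance_s / beta

  xa <- vapply(paste0("Xa", 2:5), evaluate_scaling, numeric(1),
               model = model, v_star = v_star, mass_kg = mass_kg)
  za <- vapply(paste0("Za", 1:6), evaluate_scaling, numeric(1),
               model = model, v_star = v_star, mass_kg = mass_kg)
  fx_coef <- fourier_coefficients(c(0, unname(xa)), component = "x")
  fz_coef <- fourier_coefficients(unname(za), component = "z")

  tg <- seq(0, 1, length.out = n_grid)
  fx_bw <- reconstruct(fx_coef, tg)
  fz_bw <- reconstruct(fz_coef, tg)
  features <- extract_features(fx_bw, fz_bw, t = tg)

  direct_vars <- c("fx_peak_pos", "fx_peak_neg", "fz_peak", "fz_mean",
                   "fnet_peak", "t_fx_peak_pos", "t_fx_peak_neg",
                   "t_fx_zero", "fz_at_fx_zero", "fx_ms", "fz_ms",
                   "fnet_ms", "nvd_star")
  direct <- vapply(direct_vars, evaluate_scaling, numeric(1),
                   model = model, v_star = v_star, mass_kg = mass_kg)

  com <- stride_mechanics(fz_bw, fx_bw, beta = beta, mass_kg = mass_kg,
                          v_mps = v_mps, t_stance_s = t_stance_s, h = h,
                          t_stance = tg, n_samples = n_stride, g = g)

  structure(list(
    inputs = list(mass_kg = mass_kg, v_mps = v_mps,
                  leg_length_m = morpho$leg_length_m),
    morphometrics = morpho,
    v_star = v_star,
    kinematics = list(beta = beta, t_stance_s = t_stance_s,
                      t_stride_s = t_stride_s, S_m = S_m,
                      t_stance_star = t_stance_star, S_star = S_star),
    fourier = list(xa = xa, za = za,
                   asymmetry_ratio = asymmetry_ratio(unname(za))),
    grf_profile = list(t = tg, fx_bw = fx_bw, fz_bw = fz_bw,
                       fx_n = fx_bw * mass_kg * g,
                       fz_n = fz_bw * mass_kg * g),
    features = features,
    features_direct = direct,
    peak_vertical_force_n = max(reconstruct(fz_coef,
                                            seq(0, 1, length.out = n_grid))) *
      mass_kg * g,
    com = list(percent_congruity = com$percent_congruity,
               nvd_m = com$nvd_m, nvd_star = com$nvd_star),
    stride = com,
    g = g
  ), class = "locomotion_prediction")
}

#' @export
print.locomotion_prediction <- function(x, ...) {
  k <- x$kinematics
  cat(sprintf("Predicted locomotion for a %.4g kg biped at %.3g m/s\n",
              x$inputs$mass_kg, x$inputs$v_mps))
  cat(sprintf("  leg length %.3g m | hip height %.3g m (crouch route; direct %.3g m) | DC %.3g\n",
              x$morphometrics$leg_length_m, x$morphometrics$hip_height_m,
              x$morphometrics$hip_height_direct_m,
              x$morphometrics$degree_of_crouch))
  cat(sprintf("  v* = %.3f | duty factor %.3f | stance %.3g s | stride %.3g s, %.3g m\n",
              x$v_star, k$beta, k$t_stance_s, k$t_stride_s, k$S_m))
  pk <- x$features
  cat(sprintf("  peak vertical force %.3f BW (%.4g kN) at %.1f%% of stance\n",
              pk$fz_peak, x$peak_vertical_force_n / 1000,
              100 * pk$t_fz_peak))
  cat(sprintf("  COM: percent congruity %.1f%% | NVD %.3g m (NVD* %.3g)\n",
              x$com$percent_congruity, x$com$nvd_m, x$com$nvd_star))
  invisible(x)
}

#' Export a prediction as JSON
#'
#' @param pred A `locomotion_prediction`.
#' @param path Optional file path.
#' @param include_profile Include the full waveform arrays (default FALSE).
#' @return JSON string, or `path` invisibly when written to file.
#' @export
prediction_to_json <- function(pred, path = NULL, include_profile = FALSE) {
  stopifnot(inherits(pred, "locomotion_prediction"))
  x <- list(inputs = pred$inputs, morphometrics = pred$morphometrics,
            v_star = pred$v_star, kinematics = pred$kinematics,
            fourier = pred$fourier,
            features = unclass(pred$features),
            features_direct = as.list(pred$features_direct),
            peak_vertical_force_n = pred$peak_vertical_force_n,
            com = pred$com)
  if (include_profile) x$grf_profile <- pred$grf_profile
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}

#' Predicted waveform family across speeds
#'
#' Reconstructs the sagittal GRF profile pair (fore-aft, vertical) at each
#' requested relative speed. At slow speeds the vertical profile is
#' double-peaked (second hump can exceed the first); with increasing speed
#' the first peak grows, the second atrophies, and by v* about 1 the profile
#' is single-peaked and early-skewed.
#'
#' @param model A `scaling_model`.
#' @param mass_kg Body mass (kg) for mass-modulated coefficients.
#' @param v_star Vector of relative speeds.
#' @param n_grid Stance grid size.
#' @return A list, one element per speed, each with `v_star`, `t`, `fx_bw`,
#'   `fz_bw`.
#' @export
waveform_family <- function(model = avian_scaling_model(), mass_kg,
                            v_star, n_grid = 1001) {
  if (!length(v_star)) stop("'v_star' must be nonempty")
  tg <- seq(0, 1, length.out = n_grid)
  lapply(v_star, function(vs) {
    xa <- vapply(paste0("Xa", 2:5), evaluate_scaling, numeric(1),
                 model = model, v_star = vs, mass_kg = mass_kg)
    za <- vapply(paste0("Za", 1:6), evaluate_scaling, numeric(1),
                 model = model, v_star = vs, mass_kg = mass_kg)
    list(v_star = vs, t = tg,
         fx_bw = reconstruct(fourier_coefficients(c(0, unname(xa))), tg),
         fz_bw = reconstruct(fourier_coefficients(unname(za)), tg))
  })
}
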