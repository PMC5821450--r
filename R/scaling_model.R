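#' Load a speed-scaling model from a coefficient table
#'
#' A scaling model maps dimensionless speed v* (and, for mass-modulated
#' entries, log10 body mass) to each kinematic/kinetic variable through one
#' of three forms: linear (`A*v* + B`), power I (`A*v*^B`) or power II
#' (`A*v*^B + C`). A coefficient can be a constant or a linear function of
#' log10 mass (`slope*log10(m) + intercept`), reflecting that larger birds
#' use shorter relative stance durations and relative stride lengths at the
#' same relative speed.
#'
#' @param path CSV with columns `variable, fit_type, A_const,
#'   A_slope_log10m, A_intercept, B_const, B_slope_log10m, B_intercept, C,
#'   footnote`. Defaults to the packaged coefficient set fitted across twelve
#'   ground-dwelling bird species.
#' @return An object of class `scaling_model`: a named list of entries.
#' @export
scaling_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table3_speed_scaling.csv",
                        package = "avigait", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  entries <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    coef_entry <- function(const, slope, intercept) {
      if (!is.na(const)) list(type = "constant", value = const)
      else list(type = "mass_modulated", slope = slope,
                intercept = intercept)
    }
    list(fit_type = row$fit_type,
         A = coef_entry(row$A_const, row$A_slope_log10m, row$A_intercept),
         B = coef_entry(row$B_const, row$B_slope_log10m, row$B_intercept),
         C = row$C)
  })
  names(entries) <- df$variable
  structure(entries, class = "scaling_model")
}

#' The packaged avian speed-scaling model
#'
#' The coefficient set fitted across twelve ground-dwelling bird species
#' (47 g to 74 kg), covering duty factor, relative stance duration and stride
#' length, GRF peak/mean/midstance features and their timings, the fore-aft
#' and vertical sine coefficients (Xa2-Xa5, Za1-Za6) and relative net
#' vertical displacement.
#'
#' @return A `scaling_model` object.
#' @export
avian_scaling_model <- function() scaling_model()

#' @export
print.scaling_model <- function(x, ...) {
  cat("Speed-scaling model with", length(x), "variables:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    lbl <- function(cf) if (cf$type == "constant") signif(cf$value, 4)
    else sprintf("%.4g*log10(m) %+.4g", cf$slope, cf$intercept)
    cat(sprintf("  %-14s %-7s A = %s, B = %s%s\n", nm, e$fit_type,
                lbl(e$A), lbl(e$B),
                if (!is.na(e$C)) sprintf(", C = %g", e$C) else ""))
  }
  invisible(x)
}

#' Evaluate a scaling-model variable at a given speed and mass
#'
#' Resolves the A and B coefficients (evaluating mass-modulated entries at
#' log10 of the supplied mass) and applies the entry's fit form at v*.
#'
#' @param model A `scaling_model`.
#' @param variable Variable name present in the model.
#' @param v_star Dimensionless speed (positive for power forms).
#' @param mass_kg Body mass (kg); required for mass-modulated entries.
#' @return The predicted value.
#' @export
evaluate_scaling <- function(model, variable, v_star, mass_kg = NULL) {
  stopifnot(inherits(model, "scaling_model"))
  e <- model[[variable]]
  if (is.null(e)) stop("unknown variable: ", variable)
  resolve <- function(cf) {
    if (cf$type == "constant") return(cf$value)
    if (is.null(mass_kg) || is.na(mass_kg))
      stop("variable '", variable, "' is mass-modulated: supply 'mass_kg'")
    cf$slope * log10(mass_kg) + cf$intercept
  }
  A <- resolve(e$A)
  B <- resolve(e$B)
  switch(e$fit_type,
         linear = A * v_star + B,
         powerI = {
           if (any(v_star <= 0)) stop("power form requires v_star > 0")
           A * v_star^B
         },
         powerII = {
           if (any(v_star <= 0)) stop("power form requires v_star > 0")
           A * v_star^B + e$C
         },
         stop("unknown fit type: ", e$fit_type))
}

#' Packaged morphometric scaling equations
#'
#' Power-law and log-linear relations among body mass m, total leg length L,
#' standing hip height h and degree of crouch DC fitted across the twelve
#' study species: `h = 0.9158*L^1.0794`, `h = 0.2168*m^0.3883`,
#' `L = 0.2657*m^0.3570`, `log10 DC = -0.6306*log10 L - 1.1332`,
#' `log10 DC = -0.2363*log10 m - 0.7615`.
#'
#' @return A data frame of relations with columns `relationship`, `form`,
#'   `A`, `B`, `r2`.
#' @export
morphometric_fits <- function() {
  utils::read.csv(system.file("extdata", "table2_morphometric_fits.csv",
                              package = "avigait", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# Evaluate one packaged morphometric relation at x.
eval_morph <- function(fits, relationship, x) {
  row <- fits[fits$relationship == relationship, ]
  if (nrow(row) != 1) stop("unknown morphometric relation: ", relationship)
  if (row$form == "powerI") row$A * x^row$B
  else 10^(row$A * log10(x) + row$B)   # loglinear: returns DC itself
}
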