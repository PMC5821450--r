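#' Fit a half-range Fourier series to a normalized force profile
#'
#' Describes a body-weight-normalized force-time profile on the stance
#' fraction domain t in [0, 1] as
#' \deqn{f(t) = a_0 + \sum_n (a_n \sin(\pi n t) + b_n \cos(\pi n t)).}
#' The sine terms are half-range harmonics that vanish at touchdown and
#' liftoff, matching the physical boundary condition of zero force at foot
#' contact and release, so a sine-only fit is the natural model-facing
#' representation. On [0, 1] the \eqn{\sin(\pi n t)} basis is orthogonal and
#' the coefficients are the projections
#' \eqn{a_n = 2\int_0^1 f(t)\sin(\pi n t)\,dt} (composite trapezoid rule).
#' Sines and cosines of half-range frequency are *not* mutually orthogonal on
#' [0, 1], so the full fit is a joint linear least squares over the basis
#' \eqn{\{1, \sin(\pi n t), \cos(\pi n t)\}}.
#'
#' @param profile Force samples (BW).
#' @param t Stance fractions of the samples; defaults to a uniform grid on
#'   [0, 1].
#' @param n_max Highest harmonic (default 10; the first ten harmonics carry
#'   99\% or more of the signal power of typical vertical profiles).
#' @param sine_only If `TRUE` (default) fit sine terms only.
#' @param component Optional label, one of `"x"`, `"y"`, `"z"`.
#' @param n_resample Number of uniform points the profile is linearly
#'   resampled to before fitting (default 1001); harmonizes heterogeneous
#'   sampling rates.
#' @return An object of class `fourier_coefficients` with elements
#'   `component`, `a0`, `a`, `b`, `n_max`, `sine_only`.
#' @export
fit_fourier <- function(profile, t = NULL, n_max = 10, sine_only = TRUE,
                        component = NA_character_, n_resample = 1001) {
  n <- length(profile)
  if (n < 2 * n_max + 2)
    stop("profile too short: need at least 2*n_max + 2 samples")
  if (is.null(t)) t <- seq(0, 1, length.out = n)
  if (min(t) < 0 || max(t) > 1) stop("'t' must lie within [0, 1]")
  tg <- seq(0, 1, length.out = n_resample)
  f <- stats::approx(t, profile, xout = tg, rule = 2)$y
  if (sine_only) {
    a <- vapply(seq_len(n_max), function(k)
      2 * pracma::trapz(tg, f * sin(pi * k * tg)), numeric(1))
    a0 <- 0
    b <- numeric(n_max)
  } else {
    X <- cbind(1, sapply(seq_len(n_max), function(k) sin(pi * k * tg)),
               sapply(seq_len(n_max), function(k) cos(pi * k * tg)))
    cf <- stats::lsfit(X, f, intercept = FALSE)$coefficients
    a0 <- cf[1]
    a <- cf[2:(n_max + 1)]
    b <- cf[(n_max + 2):(2 * n_max + 1)]
  }
  structure(list(component = component, a0 = unname(a0), a = unname(a),
                 b = unname(b), n_max = n_max, sine_only = sine_only),
            class = "fourier_coefficients")
}

#' Construct a coefficient set directly
#'
#' @param a Sine coefficients a_1..a_N (BW).
#' @param b Cosine coefficients (default all zero).
#' @param a0 Constant term (default 0).
#' @param component Optional component label.
#' @return A `fourier_coefficients` object.
#' @export
fourier_coefficients <- function(a, b = numeric(length(a)), a0 = 0,
                                 component = NA_character_) {
  stopifnot(length(b) == length(a), is.finite(a0), all(is.finite(a)),
            all(is.finite(b)))
  structure(list(component = component, a0 = a0, a = a, b = b,
                 n_max = length(a),
                 sine_only = a0 == 0 && all(b == 0)),
            class = "fourier_coefficients")
}

#' @export
print.fourier_coefficients <- function(x, ...) {
  cat("Fourier series", if (!is.na(x$component))
    paste0("(", x$component, " component)"), "- n_max =", x$n_max,
    if (x$sine_only) "(sine-only)" else "", "\n")
  cat("  a:", paste(signif(x$a, 4), collapse = " "), "\n")
  if (!x$sine_only) {
    cat("  a0:", signif(x$a0, 4), "\n")
    cat("  b:", paste(signif(x$b, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Evaluate a Fourier series on a stance-fraction grid
#'
#' @param coeffs A `fourier_coefficients` object, or a plain numeric vector
#'   of sine coefficients.
#' @param t_grid Stance fractions in [0, 1].
#' @return Force values (BW) on `t_grid`.
#' @export
reconstruct <- function(coeffs, t_grid) {
  if (is.numeric(coeffs)) coeffs <- fourier_coefficients(coeffs)
  stopifnot(inherits(coeffs, "fourier_coefficients"))
  if (any(t_grid < 0) || any(t_grid > 1)) stop("'t_grid' must lie in [0, 1]")
  out <- rep(coeffs$a0, length(t_grid))
  for (k in seq_len(coeffs$n_max))
    out <- out + coeffs$a[k] * sin(pi * k * t_grid) +
      coeffs$b[k] * cos(pi * k * t_grid)
  out
}

#' Harmonic power analysis of a fitted series
#'
#' Reports the power per harmonic (\eqn{a_n^2 + b_n^2}), the relative cosine
#' power per harmonic (\eqn{b_n^2/a_n^2}), the cumulative power fraction by
#' harmonic, and the smallest number of harmonics containing at least 99\% of
#' the power.
#'
#' @param coeffs A `fourier_coefficients` object.
#' @return A list with `power`, `rel_cosine_power`, `cumulative_fraction`,
#'   `n99`.
#' @export
power_analysis <- function(coeffs) {
  stopifnot(inherits(coeffs, "fourier_coefficients"))
  p <- coeffs$a^2 + coeffs$b^2
  if (all(p == 0)) stop("all coefficients are zero: power undefined")
  relc <- ifelse(coeffs$a == 0, ifelse(coeffs$b == 0, 0, Inf),
                 coeffs$b^2 / coeffs$a^2)
  cf <- cumsum(p) / sum(p)
  list(power = p, rel_cosine_power = relc, cumulative_fraction = cf,
       n99 = which(cf >= 0.99)[1])
}

#' Serialize coefficients to/from JSON
#'
#' @param coeffs A `fourier_coefficients` object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string or (for the reader) a `fourier_coefficients` object.
#' @export
fourier_to_json <- function(coeffs, path = NULL) {
  stopifnot(inherits(coeffs, "fourier_coefficients"))
  x <- list(component = coeffs$component, a0 = coeffs$a0,
            a = coeffs$a, b = coeffs$b)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}

#' @rdname fourier_to_json
#' @param json JSON string or file path.
#' @export
fourier_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  fourier_coefficients(a = x$a, b = x$b, a0 = x$a0,
                       component = if (is.null(x$component)) NA_character_
                       else x$component)
}
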