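#' Fit one of the three candidate speed-scaling forms
#'
#' Fits `y = A*x + B` (linear), `y = A*x^B` (power I) or `y = A*x^B + C`
#' (power II, with `C` held fixed) by least squares *on the untransformed
#' variables*. Power fits are nonlinear least squares initialized from the
#' log-log ordinary least squares solution; fitting on the untransformed
#' scale weights the upper end of the speed/size range properly, which
#' matters when the purpose of the fit is prediction rather than allometric
#' inference. Holding `C` fixed in power II restricts the nonlinear problem
#' to two free coefficients, avoiding spurious local minima.
#'
#' @param x,y Paired observations; `x` must be positive for power fits.
#' @param fit_type `"linear"`, `"powerI"` or `"powerII"`.
#' @param C_fixed Fixed vertical offset for power II (see [pooled_offset()]).
#' @return An object of class `fit_result` with elements `fit_type`, `A`,
#'   `B`, `C`, `r2` (coefficient of determination on the untransformed
#'   scale), `aic` (`n*log(SSres/n) + 2k`, with `k` = free coefficients + 1
#'   for the error variance) and `n`.
#' @export
fit_model <- function(x, y, fit_type = c("linear", "powerI", "powerII"),
                      C_fixed = NULL) {
  fit_type <- match.arg(fit_type)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (fit_type != "linear" && any(x <= 0))
    stop("power fits require positive x")
  if (fit_type == "powerII" && is.null(C_fixed))
    stop("powerII requires 'C_fixed' (see pooled_offset)")

  if (fit_type == "linear") {
    fit <- stats::lm(y ~ x)
    A <- unname(stats::coef(fit)[2])
    B <- unname(stats::coef(fit)[1])
    C <- NA_real_
    res <- stats::resid(fit)
    k <- 3
  } else {
    C <- if (fit_type == "powerII") C_fixed else 0
    yy <- y - C
    st <- power_start(x, yy)
    df <- data.frame(x = x, yy = yy)
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ A * x^B, data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("power fit failed to converge: ",
                               conditionMessage(e)))
    A <- unname(stats::coef(fit)["A"])
    B <- unname(stats::coef(fit)["B"])
    res <- stats::resid(fit)
    C <- if (fit_type == "powerII") C_fixed else NA_real_
    k <- 3
  }
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(fit_type = fit_type, A = A, B = B, C = C,
                 r2 = 1 - ss_res / ss_tot,
                 aic = n * log(ss_res / n) + 2 * k, n = n),
            class = "fit_result")
}

# Starting values for y ~ A*x^B: log-log OLS when the response is
# single-signed, else a crude slope-based guess.
power_start <- function(x, y) {
  if (all(y > 0)) {
    cf <- stats::coef(stats::lm(log(y) ~ log(x)))
    list(A = exp(unname(cf[1])), B = unname(cf[2]))
  } else if (all(y < 0)) {
    cf <- stats::coef(stats::lm(log(-y) ~ log(x)))
    list(A = -exp(unname(cf[1])), B = unname(cf[2]))
  } else {
    list(A = stats::median(y) / stats::median(x), B = 1)
  }
}

#' @export
print.fit_result <- function(x, ...) {
  eqn <- switch(x$fit_type,
                linear = sprintf("y = %.4g*x + %.4g", x$A, x$B),
                powerI = sprintf("y = %.4g*x^%.4g", x$A, x$B),
                powerII = sprintf("y = %.4g*x^%.4g + %.4g", x$A, x$B, x$C))
  cat(sprintf("%s fit (n = %d): %s  [r2 = %.3f, AIC = %.2f]\n",
              x$fit_type, x$n, eqn, x$r2, x$aic))
  invisible(x)
}

#' Pooled vertical offset for power II fits
#'
#' Fits the unconstrained three-parameter model `y = A*x^B + C` to data
#' pooled across all species and returns `C`. This pooled offset is then held
#' fixed in the per-species power II fits, so that each species estimates
#' only two free coefficients.
#'
#' @param x,y Pooled observations spanning more than one species.
#' @param species Species labels, used only to check the pool is not
#'   degenerate.
#' @return The fitted offset `C`.
#' @export
pooled_offset <- function(x, y, species = NULL) {
  if (!is.null(species) && length(unique(species)) < 2)
    stop("pooled offset requires data from more than one species")
  c0 <- if (all(y > 0)) 0 else min(y) - 0.1 * diff(range(y)) - 1e-8
  st0 <- power_start(x, y - c0)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * x^B + C, data = df,
                      start = c(st0, list(C = c0)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("pooled power II fit failed to converge: ",
                             conditionMessage(e)))
  unname(stats::coef(fit)["C"])
}

#' Majority-rules model selection across species
#'
#' Each species votes for the candidate form with its lowest AIC; the form
#' with most votes across species wins. Ties are broken towards the simpler
#' form (linear over power I over power II) with a warning.
#'
#' @param per_species_fits A list, one element per species, each a list of
#'   `fit_result` objects for the candidate forms.
#' @return The chosen fit type as a string.
#' @export
select_fit <- function(per_species_fits) {
  order_pref <- c("linear", "powerI", "powerII")
  votes <- vapply(per_species_fits, function(fits) {
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    types <- vapply(fits, function(f) f$fit_type, character(1))
    best <- aics == min(aics)
    if (sum(best) > 1) # within-species AIC tie: simpler form
      types[best][order(match(types[best], order_pref))][1]
    else types[which.min(aics)]
  }, character(1))
  tab <- table(factor(votes, levels = order_pref))
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1)
    warning("tied vote; choosing the simpler form (",
            winners[1], ")")
  winners[1]
}

#' Mass modulation of fitted coefficients
#'
#' Regresses a per-species fit coefficient against log10 body mass. When the
#' slope is significant at P = 0.05 the linear relation on log10(mass) is
#' returned ("mass-modulated" coefficient); otherwise the cross-species mean
#' is returned.
#'
#' @param mass_kg Per-species body masses.
#' @param coef_values Per-species values of the coefficient (A or B).
#' @return A list with `modulated` (logical), `slope`, `intercept` (when
#'   modulated), `value` (the mean, when not), and `p_value` of the slope.
#' @export
mass_modulate <- function(mass_kg, coef_values) {
  if (length(mass_kg) < 3) stop("need at least 3 species")
  lx <- log10(mass_kg)
  fit <- stats::lm(coef_values ~ lx)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.nan(sm$coefficients[2, 4])) 1
  else sm$coefficients[2, 4]
  if (p < 0.05) {
    list(modulated = TRUE, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), p_value = p)
  } else {
    list(modulated = FALSE, value = mean(coef_values), p_value = p)
  }
}

#' Major-axis regression
#'
#' The major-axis (first principal axis) line through bivariate data, used
#' for parity comparisons where both variables carry error. With
#' `through_origin = TRUE` the axis is constrained to pass through (0, 0)
#' (eigenvector of the uncentred cross-product matrix).
#'
#' @param x,y Paired observations.
#' @param through_origin Constrain the axis through the origin.
#' @return A list with `slope` and `r2` (squared Pearson correlation).
#' @export
ma_regression <- function(x, y, through_origin = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate input: no variance in x or y")
  M <- if (through_origin) crossprod(cbind(x, y)) / n
  else stats::cov(cbind(x, y))
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] == 0) stop("major axis is vertical: slope undefined")
  list(slope = v[2] / v[1], r2 = stats::cor(x, y)^2)
}

#' Permutation test for a regression slope
#'
#' Tests the ordinary least squares slope of `y` on `x` against the null of
#' no association by randomly re-pairing `y` with `x`. The p-value is the
#' proportion of replicates whose slope is equal to or more extreme in
#' magnitude than the observed slope (two-sided on magnitude). Appropriate
#' when residuals are non-normal or heteroscedastic, where the parametric
#' slope test is invalid.
#'
#' @param x,y Paired observations (n >= 3).
#' @param n_reps Number of permutation replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `slope_obs`, `p_value`, `n_reps`.
#' @export
permutation_slope_test <- function(x, y, n_reps = 10000, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  if (ssx == 0) stop("x has no variance: slope undefined")
  slope_obs <- sum(xc * y) / ssx
  # permuted slopes via one matrix product
  P <- vapply(seq_len(n_reps), function(i) sample.int(n), integer(n))
  slopes <- as.numeric(crossprod(matrix(y[P], nrow = n), xc)) / ssx
  list(slope_obs = slope_obs,
       p_value = mean(abs(slopes) >= abs(slope_obs)),
       n_reps = n_reps)
}

#' Run the full scaling protocol on a long-format trial table
#'
#' For each variable in a long-format table (columns `species`, `mass_kg`,
#' `v_star`, `variable`, `value`): fit all three candidate forms per species
#' (power II uses the pooled offset), choose the form by AIC majority rule,
#' refit every species with the chosen form, and test each coefficient for
#' mass modulation.
#'
#' @param trials Long-format data frame.
#' @return A named list per variable: `fit_type`, `A`, `B` (each a
#'   [mass_modulate()] result), `C` (pooled offset, power II only), and the
#'   per-species coefficient table.
#' @export
fit_scaling_protocol <- function(trials) {
  stopifnot(all(c("species", "mass_kg", "v_star", "variable", "value") %in%
                  names(trials)))
  out <- list()
  for (var in unique(trials$variable)) {
    d <- trials[trials$variable == var, ]
    C_pool <- tryCatch(pooled_offset(d$v_star, d$value, d$species),
                       error = function(e) NA_real_)
    sp <- split(d, d$species)
    sp <- sp[vapply(sp, nrow, integer(1)) >= 3]
    fits <- lapply(sp, function(ds) {
      cand <- list(tryCatch(fit_model(ds$v_star, ds$value, "linear"),
                            error = function(e) NULL),
                   tryCatch(fit_model(ds$v_star, ds$value, "powerI"),
                            error = function(e) NULL),
                   if (!is.na(C_pool))
                     tryCatch(fit_model(ds$v_star, ds$value, "powerII",
                                        C_fixed = C_pool),
                              error = function(e) NULL))
      Filter(Negate(is.null), cand)
    })
    type <- select_fit(fits)
    per <- do.call(rbind, lapply(names(sp), function(s) {
      f <- tryCatch(fit_model(sp[[s]]$v_star, sp[[s]]$value, type,
                              C_fixed = if (type == "powerII") C_pool),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(species = s, mass_kg = sp[[s]]$mass_kg[1], A = f$A, B = f$B)
    }))
    out[[var]] <- list(
      fit_type = type,
      A = mass_modulate(per$mass_kg, per$A),
      B = mass_modulate(per$mass_kg, per$B),
      C = if (type == "powerII") C_pool else NA_real_,
      per_species = per)
  }
  out
}
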