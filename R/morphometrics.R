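#' Dimensionless normalization of stride kinematics
#'
#' Normalizes forward speed, stance duration and stride length to standing
#' hip height, the standard size correction in comparative gait analysis.
#' Relative speed is the square root of the Froude number,
#' \eqn{v^* = v/\sqrt{gh}}; relative stance duration is
#' \eqn{t^*_{stance} = t_{stance}\sqrt{g/h}}; relative stride length is
#' \eqn{S^* = S/h}.
#'
#' @param v Mean forward speed (m/s), or `NULL` if not measured.
#' @param t_stance Stance duration (s), or `NULL`.
#' @param S Stride length (m), or `NULL`.
#' @param h Standing hip height (m); must be positive.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return A list with elements `v_star`, `t_stance_star`, `S_star`.
#'   Quantities not supplied come back as `NULL`.
#' @examples
#' normalize_kinematics(v = 5, h = 2.99)
#' @export
normalize_kinematics <- function(v = NULL, t_stance = NULL, S = NULL,
                                 h, g = 9.81) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("hip height 'h' must be a single positive number")
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("'g' must be a single positive number")
  list(
    v_star        = if (is.null(v)) NULL else v / sqrt(g * h),
    t_stance_star = if (is.null(t_stance)) NULL else t_stance * sqrt(g / h),
    S_star        = if (is.null(S)) NULL else S / h
  )
}

#' Degree of crouch
#'
#' A dimensionless measure of limb posture, \eqn{DC = 1 - h/L}: an animal
#' standing fully erect (hip height equal to summed limb segment length) has
#' DC = 0, and more crouched postures have larger values. Across
#' ground-dwelling birds DC decreases predictably with size, which is what
#' makes it useful for estimating hip height in extinct taxa.
#'
#' @param h Standing hip height (m), 0 < h <= L.
#' @param L Total leg length (m): summed interarticular lengths of femur,
#'   tibiotarsus and tarsometatarsus.
#' @return Degree of crouch in `[0, 1)`.
#' @seealso [hip_height_from_crouch()] for the inverse.
#' @export
degree_of_crouch <- function(h, L) {
  if (any(h <= 0) || any(L <= 0))
    stop("'h' and 'L' must be positive")
  if (any(h > L))
    stop("hip height above total leg length is unphysical (h > L)")
  1 - h / L
}

#' Hip height from leg length and degree of crouch
#'
#' Inverts the degree-of-crouch definition: \eqn{h = L(1 - DC)}. This is the
#' preferred route for estimating standing hip height for a fossil biped,
#' because leg length is measurable from the skeleton while hip height is not.
#'
#' @param L Total leg length (m).
#' @param DC Degree of crouch, in `[0, 1)`.
#' @return Standing hip height (m).
#' @export
hip_height_from_crouch <- function(L, DC) {
  if (any(L <= 0)) stop("'L' must be positive")
  if (any(DC < 0) || any(DC >= 1)) stop("'DC' must lie in [0, 1)")
  L * (1 - DC)
}

#' Read a species morphometrics table
#'
#' Reads a CSV of per-species morphometric means with columns `species`,
#' `mass_kg`, `hip_height_m`, `leg_length_m` (additional columns such as
#' sample sizes or standard deviations are carried along but not used in
#' computation).
#'
#' @param path CSV file path.
#' @return A data frame of species morphometrics.
#' @export
read_morphometrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "mass_kg", "hip_height_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("morphometrics table lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Packaged bird morphometrics
#'
#' The morphometric means (body mass, standing hip height, total leg length)
#' for the twelve ground-dwelling bird species underlying the packaged
#' scaling laws, from 47 g painted quail to 74 kg ostriches.
#'
#' @return A data frame with one row per species.
#' @export
bird_morphometrics <- function() {
  read_morphometrics(system.file("extdata", "table1_species.csv",
                                 package = "avigait", mustWork = TRUE))
}
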