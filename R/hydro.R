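#' Hydrodynamic inputs for native molecular-weight determination
#'
#' @param rs Stokes radius (nm), from size-exclusion chromatography
#' @param s sedimentation coefficient (Svedberg; 1 S = 1e-13 s), from
#'   density-gradient centrifugation
#' @param vbar partial specific volume (cm^3/g); 0.73 is a typical protein
#'   value
#' @param eta solvent viscosity (Pa s); default water at 20 C
#' @param rho solvent density (g/cm^3); default water at 20 C
#' @return object of class `hydro_input`
#' @export
hydro_input <- function(rs, s, vbar = 0.73, eta = 1.002e-3, rho = 0.9982) {
  stop_if_not_scalar_pos(rs, "rs", strict = FALSE)
  stop_if_not_scalar_pos(s, "s", strict = FALSE)
  stop_if_not_scalar_pos(vbar, "vbar")
  stop_if_not_scalar_pos(eta, "eta")
  stop_if_not_scalar_pos(rho, "rho")
  if (vbar * rho >= 1)
    stop("vbar * rho >= 1: buoyancy term undefined (particle would float)")
  structure(list(rs = rs, s = s, vbar = vbar, eta = eta, rho = rho),
            class = "hydro_input")
}

#' Native molecular weight from Stokes radius and sedimentation coefficient
#'
#' Combines the two hydrodynamic measurements by the Siegel-Monty relation
#' `M = 6 pi eta N_A Rs s / (1 - vbar rho)`, which eliminates the unknown
#' frictional coefficient of a non-spherical particle. Inputs in nm and
#' Svedberg; result in kDa (kg/mol).
#'
#' @param h a [hydro_input()], or a Stokes radius in nm if `s` is given
#' @param s sedimentation coefficient (S) when `h` is numeric
#' @param ... passed to [hydro_input()] when `h` is numeric
#' @return native molecular weight in kDa
#' @examples
#' native_mw(9.1, 5.6)  # ~214 kDa
#' @export
native_mw <- function(h, s = NULL, ...) {
  if (!inherits(h, "hydro_input")) h <- hydro_input(h, s, ...)
  N_A <- 6.02214076e23
  rs_m <- h$rs * 1e-9
  s_s <- h$s * 1e-13
  rho_kg_m3 <- h$rho * 1000
  vbar_m3_kg <- h$vbar * 1e-3
  m_kg_mol <- 6 * pi * h$eta * N_A * rs_m * s_s /
    (1 - vbar_m3_kg * rho_kg_m3)
  m_kg_mol  # kg/mol == kDa
}

#' Calibration table for chromatography / gradient standards
#'
#' @param observed observed coordinates (elution volume, fraction index)
#' @param known known values of the standards (Stokes radius nm, or s in S)
#' @param names optional standard names
#' @return object of class `calibration_table`
#' @export
calibration_table <- function(observed, known, names = NULL) {
  stopifnot(length(observed) == length(known))
  if (length(observed) < 2) stop("need >= 2 standards")
  ord <- order(observed)
  kn <- known[ord]
  if (!(all(diff(kn) >= 0) || all(diff(kn) <= 0)))
    stop("known values must be monotone in the observed coordinate")
  structure(data.frame(name = if (is.null(names)) paste0("std", seq_along(observed))
                       else names,
                       observed = observed, known = known),
            class = c("calibration_table", "data.frame"))
}

#' Interpolate a standard curve at an observed coordinate
#'
#' Least-squares line through the standards (`known ~ observed`), evaluated
#' at the query. Queries beyond 10% of the calibrated span trigger an
#' extrapolation warning.
#'
#' @param cal a [calibration_table()]
#' @param observed query coordinate(s)
#' @return interpolated value(s), same units as the standards
#' @examples
#' cal <- calibration_table(c(10, 20), c(2, 4))
#' interpolate_standard(cal, 15)  # 3
#' @export
interpolate_standard <- function(cal, observed) {
  stopifnot(inherits(cal, "calibration_table"))
  fit <- lm(known ~ observed, data = cal)
  span <- diff(range(cal$observed))
  lo <- min(cal$observed) - 0.1 * span
  hi <- max(cal$observed) + 0.1 * span
  if (any(observed < lo | observed > hi))
    warning("query beyond 10% of the calibrated span: extrapolating")
  as.numeric(coef(fit)[1] + coef(fit)[2] * observed)
}
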