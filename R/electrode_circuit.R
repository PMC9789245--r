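#' Double-layer capacitance of a spherical electrode
#'
#' The interfacial (polarization) capacitance of a metal contact in
#' electrolyte is modeled as an areal capacitance times the electrode
#' surface area. The default areal density of 15 uF/cm^2 is the midpoint of
#' the 10-20 uF/cm^2 range typical for metal in aqueous solution.
#'
#' @param areal_cdl areal capacitance in F/cm^2 (> 0)
#' @param radius electrode radius in meters (> 0)
#' @return capacitance in farads
#' @export
#' @examples
#' cdl_from_radius(15e-6, 150e-6)   # 4.241e-8 F
cdl_from_radius <- function(areal_cdl = 15e-6, radius = 150e-6) {
  stopifnot(is.numeric(areal_cdl), is.numeric(radius))
  if (any(areal_cdl <= 0) || any(radius <= 0))
    stop("areal_cdl and radius must be > 0")
  r_cm <- radius * 100
  areal_cdl * 4 * pi * r_cm^2
}

#' Series resistance of a spherical scar-tissue shell
#'
#' Encapsulation (scar) tissue around an implanted electrode is represented
#' as a concentric shell of conductivity \code{sigma_scar}; its lumped
#' series resistance between radii \eqn{r_1} (electrode surface) and
#' \eqn{r_2 = r_1 + \mathrm{thickness}} is
#' \eqn{R = (1/(4\pi\sigma))(1/r_1 - 1/r_2)}.
#'
#' @param thickness shell thickness in meters (>= 0; 0 gives 0 ohms)
#' @param radius electrode radius in meters
#' @param sigma_scar scar conductivity in S/m (default 0.1)
#' @return resistance in ohms
#' @export
scar_resistance <- function(thickness = 500e-6, radius = 150e-6,
                            sigma_scar = 0.1) {
  stopifnot(thickness >= 0, radius > 0, sigma_scar > 0)
  if (thickness == 0) return(0)
  (1 / (4 * pi * sigma_scar)) * (1 / radius - 1 / (radius + thickness))
}

#' Lumped electrode-tissue interface model
#'
#' @param C_dl double-layer capacitance in farads (> 0)
#' @param R_scar scar resistance in ohms (>= 0)
#' @param P_max stimulation power cap in watts (default 5 mW)
#' @return object of class \code{interface_model}
#' @export
interface_model <- function(C_dl = cdl_from_radius(), R_scar = 0,
                            P_max = 5e-3) {
  stopifnot(C_dl > 0, R_scar >= 0, P_max > 0)
  structure(list(C_dl = C_dl, R_scar = R_scar, P_max = P_max),
            class = "interface_model")
}

#' Contact impedance of the electrode-tissue interface
#'
#' \eqn{Z_{ET}(f) = R_{scar} + 1/(j 2\pi f C_{dl})}. At DC the capacitor is
#' an open circuit; because charge-balanced stimuli carry essentially no DC
#' content, the DC bin is treated as \code{R_scar} only and a warning is
#' raised.
#'
#' @param model an [interface_model()]
#' @param f frequency in Hz (vectorized, >= 0)
#' @return complex impedance in ohms
#' @export
z_et <- function(model, f) {
  stopifnot(inherits(model, "interface_model"), is.numeric(f), all(f >= 0))
  z <- rep(complex(real = model$R_scar, imaginary = 0), length(f))
  pos <- f > 0
  z[pos] <- model$R_scar + 1 / (1i * 2 * pi * f[pos] * model$C_dl)
  if (any(!pos))
    warning("Z_ET at DC treated as R_scar only (open-circuit capacitance)")
  z
}

#' Apply the stimulation power limit
#'
#' The instantaneous power drawn at the active electrode is
#' \eqn{P(t) = I(t) V_E(t)}. If its maximum exceeds \code{P_max}, the whole
#' stimulus is rescaled by \eqn{s = \sqrt{P_{max}/\max P}}; by linearity of
#' the volume conductor every voltage scales by the same factor, so the
#' limited peak power equals \code{P_max} exactly. This single global
#' rescaling coincides with recomputing
#' \eqn{I_{new} = \sqrt{P_{max}/Z_{tot}}} at the binding time step.
#'
#' @param V_E electrode terminal voltage time series in volts
#' @param I stimulation current time series in amperes, same grid
#' @param P_max power cap in watts
#' @return list with \code{scale} (dimensionless, <= 1), \code{V_E}
#'   and \code{I} (limited series), \code{P_peak} (pre-limit peak power, W)
#' @export
apply_power_limit <- function(V_E, I, P_max = 5e-3) {
  stopifnot(is.numeric(V_E), is.numeric(I), length(V_E) == length(I),
            P_max > 0)
  if (any(!is.finite(V_E)) || any(!is.finite(I)))
    stop("non-finite series")
  P <- V_E * I
  P_peak <- max(P)
  scale <- if (P_peak > P_max) sqrt(P_max / P_peak) else 1
  list(scale = scale, V_E = scale * V_E, I = scale * I, P_peak = P_peak)
}
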