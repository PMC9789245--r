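# vacuum permittivity (F/m), value used throughout the solver
EPS0 <- 8.854e-12

#' Cole-Cole dispersion parameters
#'
#' Container for a multi-term Cole-Cole parameterization of the complex
#' relative permittivity of a tissue,
#' \deqn{\hat\varepsilon(\omega) = \varepsilon_\infty +
#'   \sum_k \frac{\Delta\varepsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}} +
#'   \frac{\sigma_i}{j\omega\varepsilon_0}.}
#'
#' @param eps_inf high-frequency relative permittivity (dimensionless, > 0)
#' @param terms list of dispersion terms, each a numeric vector
#'   \code{c(delta_eps, tau, alpha)} with \code{delta_eps >= 0},
#'   \code{tau > 0} seconds and \code{0 <= alpha < 1}
#' @param sigma_ionic ionic (static) conductivity in S/m, >= 0
#' @return an object of class \code{cole_cole_params}
#' @export
#' @examples
#' csf <- tissue_library()$cole_cole$csf
#' evaluate_cole_cole(csf, 2e3)
cole_cole_params <- function(eps_inf, terms = list(), sigma_ionic = 0) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L, is.finite(eps_inf),
            eps_inf > 0, is.list(terms), is.numeric(sigma_ionic),
            length(sigma_ionic) == 1L, is.finite(sigma_ionic),
            sigma_ionic >= 0)
  for (tm in terms) {
    if (!is.numeric(tm) || length(tm) != 3L || any(!is.finite(tm)))
      stop("each Cole-Cole term must be c(delta_eps, tau, alpha)")
    if (tm[1L] < 0) stop("delta_eps must be >= 0")
    if (tm[2L] <= 0) stop("tau must be > 0")
    if (tm[3L] < 0 || tm[3L] >= 1) stop("alpha must lie in [0, 1)")
  }
  structure(list(eps_inf = eps_inf, terms = terms,
                 sigma_ionic = sigma_ionic),
            class = "cole_cole_params")
}

#' Evaluate a Cole-Cole dispersion model
#'
#' Returns the effective conductivity and relative permittivity at the given
#' frequencies. The permittivity is the real part of the dispersion sum
#' (the purely imaginary ionic term does not contribute); the conductivity
#' is the ionic conductivity plus the dielectric-loss contribution
#' \eqn{-\omega\varepsilon_0\,\mathrm{Im}\sum_k(\cdot)}.
#'
#' @param params a [cole_cole_params()] object
#' @param f frequency in Hz, a non-negative numeric vector
#' @return list with components \code{sigma} (S/m) and \code{eps_r}
#'   (dimensionless), each the length of \code{f}
#' @export
evaluate_cole_cole <- function(params, f) {
  stopifnot(inherits(params, "cole_cole_params"), is.numeric(f))
  if (any(!is.finite(f)) || any(f < 0)) stop("f must be finite and >= 0")
  w <- 2 * pi * f
  disp <- rep(0 + 0i, length(f))
  for (tm in params$terms) {
    jwt <- (1i * w * tm[2L])^(1 - tm[3L])
    disp <- disp + tm[1L] / (1 + jwt)
  }
  eps_r <- params$eps_inf + Re(disp)
  sigma <- params$sigma_ionic - w * EPS0 * Im(disp)
  if (any(eps_r <= 0) || any(sigma <= 0))
    stop("Cole-Cole evaluation produced non-positive sigma or eps_r")
  list(sigma = sigma, eps_r = eps_r)
}

#' Complex admittivity
#'
#' \eqn{\gamma = \sigma + j\,2\pi f\,\varepsilon_0\,\varepsilon_r} in S/m.
#'
#' @param sigma conductivity in S/m (> 0)
#' @param eps_r relative permittivity (>= 0)
#' @param f frequency in Hz (>= 0)
#' @return complex admittivity in S/m (vectorized)
#' @export
admittivity <- function(sigma, eps_r, f) {
  stopifnot(is.numeric(sigma), is.numeric(eps_r), is.numeric(f))
  if (any(!is.finite(sigma)) || any(!is.finite(eps_r)) || any(!is.finite(f)))
    stop("non-finite input")
  if (any(sigma <= 0) || any(eps_r < 0) || any(f < 0))
    stop("require sigma > 0, eps_r >= 0, f >= 0")
  complex(real = sigma, imaginary = 2 * pi * f * EPS0 * eps_r)
}

#' Quasi-static validity ratio
#'
#' The quasi-static (purely resistive) treatment of tissue is admissible
#' only where \eqn{\omega\varepsilon_0\varepsilon_r/\sigma \ll 1}; this
#' function returns that ratio.
#'
#' @inheritParams admittivity
#' @return dimensionless ratio, >= 0 (vectorized)
#' @export
qs_ratio <- function(sigma, eps_r, f) {
  stopifnot(is.numeric(sigma), is.numeric(eps_r), is.numeric(f))
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(f < 0) || any(eps_r < 0)) stop("require eps_r >= 0, f >= 0")
  2 * pi * f * EPS0 * eps_r / sigma
}

#' Tabulated frequency-dependent tissue property
#'
#' Stores conductivity and relative permittivity knots over frequency, used
#' by the solver through cubic-spline interpolation (see
#' [interp_property()]).
#'
#' @param name tissue label
#' @param freq knot frequencies in Hz, strictly increasing
#' @param sigma conductivity at the knots in S/m, > 0
#' @param eps_r relative permittivity at the knots, > 0
#' @param bound_tag one of \code{"default"}, \code{"upper"}, \code{"lower"}
#' @return an object of class \code{tissue_property}
#' @export
tissue_property <- function(name, freq, sigma, eps_r,
                            bound_tag = "default") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(freq), is.numeric(sigma), is.numeric(eps_r),
            length(freq) == length(sigma), length(freq) == length(eps_r))
  if (any(diff(freq) <= 0)) stop("knot frequencies must be strictly increasing")
  if (any(sigma <= 0) || any(eps_r <= 0))
    stop("sigma and eps_r must be > 0 at every knot")
  bound_tag <- match.arg(bound_tag, c("default", "upper", "lower"))
  structure(list(name = name, freq = freq, sigma = sigma, eps_r = eps_r,
                 bound_tag = bound_tag),
            class = "tissue_property")
}

#' @exportS3Method base::print
print.tissue_property <- function(x, ...) {
  cat(sprintf("<tissue_property '%s' (%s), %d knots %g-%g Hz>\n",
              x$name, x$bound_tag, length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Built-in dielectric parameter library
#'
#' Published four-term Cole-Cole parameter sets for cerebrospinal fluid,
#' cortical bone and nerve (spinal-cord) tissue, together with canonical
#' knot tables generated from them on a logarithmic grid (10 knots per
#' decade, 100 Hz to 500 kHz). Endolymph/perilymph and the saline shell
#' share the CSF properties.
#'
#' @param f_min,f_max frequency range of the canonical knot grid (Hz)
#' @param per_decade knots per decade of the canonical grid
#' @return list with elements \code{cole_cole} (named
#'   [cole_cole_params()] sets) and \code{tables} (named
#'   [tissue_property()] objects: \code{csf}, \code{bone}, \code{nerve})
#' @export
tissue_library <- function(f_min = 100, f_max = 5e5, per_decade = 10) {
  cc <- list(
    csf = cole_cole_params(4.0, list(c(65, 7.958e-12, 0.10),
                                     c(40, 1.592e-9, 0.00)), 2.0),
    bone = cole_cole_params(2.5, list(c(10, 13.263e-12, 0.20),
                                      c(180, 79.577e-9, 0.20),
                                      c(5e3, 159.155e-6, 0.20),
                                      c(1e5, 15.915e-3, 0.00)), 0.02),
    nerve = cole_cole_params(4.0, list(c(26, 7.958e-12, 0.10),
                                       c(500, 106.103e-9, 0.15),
                                       c(7e4, 15.915e-6, 0.20),
                                       c(4e7, 15.915e-3, 0.00)), 0.006))
  lo <- log10(f_min)
  hi <- log10(f_max)
  grid <- 10^seq(lo, ceiling(hi * per_decade) / per_decade, by = 1 / per_decade)
  tables <- lapply(names(cc), function(nm) {
    v <- evaluate_cole_cole(cc[[nm]], grid)
    tissue_property(nm, grid, v$sigma, v$eps_r)
  })
  names(tables) <- names(cc)
  list(cole_cole = cc, tables = tables)
}

#' Rescale nerve conductivity to a directional reference value
#'
#' Nerve tissue is anisotropic; the isotropic literature table is rescaled
#' so that its conductivity at 100 Hz matches a given longitudinal or
#' transversal reference value. All conductivity knots are multiplied by
#' the same factor; permittivity knots are left unchanged.
#'
#' @param base a [tissue_property()] whose knot range covers 100 Hz
#' @param target_sigma_100Hz desired conductivity at 100 Hz in S/m (> 0)
#' @return a rescaled \code{tissue_property}
#' @export
scale_nerve_conductivity <- function(base, target_sigma_100Hz) {
  stopifnot(inherits(base, "tissue_property"))
  if (!is.numeric(target_sigma_100Hz) || length(target_sigma_100Hz) != 1L ||
      !is.finite(target_sigma_100Hz) || target_sigma_100Hz <= 0)
    stop("target conductivity must be a single positive number")
  s100 <- interp_property(base, 100, what = "sigma")
  k <- target_sigma_100Hz / s100
  tissue_property(base$name, base$freq, base$sigma * k, base$eps_r,
                  base$bound_tag)
}

#' Uncertainty bounds on a tissue property table
#'
#' Two rules are supported. \code{"fractional"} takes
#' \eqn{(1\pm\mathrm{fraction})} times the default at every knot (used for
#' nerve tissue). \code{"median_log_distance"} computes, separately for
#' conductivity and permittivity, the median over knots of
#' \eqn{|\log_{10}(\mathrm{literature}) - \log_{10}(\mathrm{default})|}
#' and returns \eqn{\mathrm{default}\cdot 10^{\pm d}} (used for bone and
#' CSF, whose alternative literature values set the spread).
#'
#' @param default a [tissue_property()] with \code{bound_tag = "default"}
#' @param mode \code{"fractional"} or \code{"median_log_distance"}
#' @param literature a \code{tissue_property} on the same knot grid
#'   (required in median mode)
#' @param fraction fractional half-width in (0, 1) (fractional mode)
#' @return list with \code{lower} and \code{upper} \code{tissue_property}
#' @export
property_bounds <- function(default,
                            mode = c("fractional", "median_log_distance"),
                            literature = NULL, fraction = 0.5) {
  stopifnot(inherits(default, "tissue_property"))
  mode <- match.arg(mode)
  if (mode == "fractional") {
    if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
      stop("fraction must lie in (0, 1)")
    lower <- tissue_property(default$name, default$freq,
                             (1 - fraction) * default$sigma,
                             (1 - fraction) * default$eps_r, "lower")
    upper <- tissue_property(default$name, default$freq,
                             (1 + fraction) * default$sigma,
                             (1 + fraction) * default$eps_r, "upper")
  } else {
    if (is.null(literature) || !inherits(literature, "tissue_property"))
      stop("median_log_distance mode requires literature values")
    if (length(literature$freq) != length(default$freq) ||
        any(literature$freq != default$freq))
      stop("literature knots must coincide with the default knots")
    ds <- stats::median(abs(log10(literature$sigma) - log10(default$sigma)))
    de <- stats::median(abs(log10(literature$eps_r) - log10(default$eps_r)))
    lower <- tissue_property(default$name, default$freq,
                             default$sigma * 10^(-ds),
                             default$eps_r * 10^(-de), "lower")
    upper <- tissue_property(default$name, default$freq,
                             default$sigma * 10^ds,
                             default$eps_r * 10^de, "upper")
  }
  list(lower = lower, upper = upper)
}

#' Interpolate a tissue property table
#'
#' Cubic-spline interpolation through the knots. By default the spline is
#' fitted on (log10 frequency, log10 value) pairs, since tissue properties
#' span several decades and a log-space spline cannot overshoot into
#' non-physical negative values; a plain linear-space spline is available
#' for verification.
#'
#' @param prop a [tissue_property()]
#' @param f_query query frequencies in Hz, inside the knot range
#' @param what \code{"sigma"}, \code{"eps_r"} or \code{"both"}
#' @param space \code{"loglog"} (default) or \code{"linear"}
#' @return numeric vector, or a list when \code{what = "both"}
#' @export
interp_property <- function(prop, f_query, what = c("both", "sigma", "eps_r"),
                            space = c("loglog", "linear")) {
  stopifnot(inherits(prop, "tissue_property"), is.numeric(f_query))
  what <- match.arg(what)
  space <- match.arg(space)
  if (any(f_query < min(prop$freq) - 1e-9 * min(prop$freq)) ||
      any(f_query > max(prop$freq) + 1e-9 * max(prop$freq)))
    stop("query frequency outside the knot range; extrapolation refused")
  one <- function(vals) {
    if (space == "loglog") {
      fn <- stats::splinefun(log10(prop$freq), log10(vals), method = "fmm")
      10^fn(log10(f_query))
    } else {
      fn <- stats::splinefun(prop$freq, vals, method = "fmm")
      fn(f_query)
    }
  }
  switch(what,
         sigma = one(prop$sigma),
         eps_r = one(prop$eps_r),
         both = list(sigma = one(prop$sigma), eps_r = one(prop$eps_r)))
}

#' Write / read a tissue property table as plain text
#'
#' Tab-separated columns \code{frequency_Hz}, \code{sigma_S_per_m},
#' \code{eps_r}; the tissue name and bound tag are kept in comment headers.
#'
#' @param prop a [tissue_property()]
#' @param path file path
#' @return \code{write_property_table} returns \code{path} invisibly;
#'   \code{read_property_table} returns a \code{tissue_property}
#' @export
write_property_table <- function(prop, path) {
  stopifnot(inherits(prop, "tissue_property"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tissue: %s", prop$name),
               sprintf("# bound: %s", prop$bound_tag),
               "frequency_Hz\tsigma_S_per_m\teps_r"), con)
  utils::write.table(data.frame(prop$freq, prop$sigma, prop$eps_r),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  name <- sub("^# tissue: ", "", hdr[1L])
  tag <- sub("^# bound: ", "", hdr[2L])
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tissue_property(name, d[[1L]], d[[2L]], d[[3L]], tag)
}
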