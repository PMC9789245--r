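# Cole-Cole evaluation, admittivity, QS criterion, property scaling,
# bounds and spline interpolation. Reference numbers were computed with
# an independent high-precision complex-arithmetic evaluation of the
# dispersion sum.

test_that("Cole-Cole evaluation matches the independent oracle", {
  lib <- tissue_library()

  # no dispersion terms: (sigma_ionic, eps_inf) at any frequency
  flat <- cole_cole_params(5, list(), sigma_ionic = 0.7)
  v <- evaluate_cole_cole(flat, c(0, 50, 2e3, 5e5))
  expect_equal(v$sigma, rep(0.7, 4))
  expect_equal(v$eps_r, rep(5, 4))

  v <- evaluate_cole_cole(lib$cole_cole$csf, 2e3)
  expect_equal(v$eps_r, 108.99999488763748, tolerance = 1e-9)
  expect_equal(v$sigma, 2.0000000000926152, tolerance = 1e-12)

  v <- evaluate_cole_cole(lib$cole_cole$bone, 2e3)
  expect_equal(v$eps_r, 1700.4361991596481, tolerance = 1e-9)
  expect_equal(v$sigma, 0.020236067996650755, tolerance = 1e-9)
})

test_that("invalid Cole-Cole parameters and frequencies are rejected", {
  expect_error(cole_cole_params(4, list(c(10, -1e-9, 0))), "tau")
  expect_error(cole_cole_params(4, list(c(10, 1e-9, 1))), "alpha")
  expect_error(cole_cole_params(4, list(c(-1, 1e-9, 0))), "delta_eps")
  expect_error(evaluate_cole_cole(cole_cole_params(4), -1), "f must")
})

test_that("admittivity follows sigma + j 2 pi f eps0 eps_r", {
  expect_equal(admittivity(3.2, 0, 1e4), 3.2 + 0i)
  expect_equal(admittivity(3.2, 500, 0), 3.2 + 0i)
  g <- admittivity(2.0, 109, 2e3)
  expect_equal(Re(g), 2.0)
  expect_equal(Im(g), 1.2127628350729435e-05, tolerance = 1e-9)
  expect_error(admittivity(Inf, 1, 1), "non-finite")
  expect_error(admittivity(-1, 1, 1), "sigma > 0")
})

test_that("QS ratio behaves as omega eps0 eps_r / sigma", {
  expect_equal(qs_ratio(2, 109, 0), 0)
  expect_error(qs_ratio(0, 1, 1), "sigma")
  f <- 10^seq(2, 5.7, by = 0.25)
  r <- qs_ratio(0.02, 1700, f)
  expect_true(all(diff(r) > 0))                 # increasing in f
  # |Im gamma| = sigma * qs_ratio exactly
  g <- admittivity(0.02, 1700, f)
  expect_equal(Im(g), 0.02 * r, tolerance = 1e-15)
})

test_that("published conductivities are non-decreasing over 100 Hz-500 kHz", {
  lib <- tissue_library()
  f <- 10^seq(2, log10(5e5), length.out = 60)
  for (nm in names(lib$cole_cole)) {
    v <- evaluate_cole_cole(lib$cole_cole[[nm]], f)
    expect_true(all(diff(v$sigma) >= -1e-12 * max(v$sigma)), label = nm)
    expect_true(all(v$sigma > 0) && all(v$eps_r > 0), label = nm)
  }
})

test_that("nerve conductivity scaling multiplies all sigma knots", {
  lib <- tissue_library()
  nerve <- lib$tables$nerve
  s100 <- interp_property(nerve, 100, what = "sigma")

  same <- scale_nerve_conductivity(nerve, s100)
  expect_equal(same$sigma, nerve$sigma, tolerance = 1e-12)

  dbl <- scale_nerve_conductivity(nerve, 2 * s100)
  expect_equal(dbl$sigma, 2 * nerve$sigma, tolerance = 1e-12)
  expect_equal(dbl$eps_r, nerve$eps_r)          # permittivity untouched

  # base 0.0295 S/m at 100 Hz scaled to 1.1 S/m: factor 37.29
  base <- tissue_property("x", c(50, 100, 200), c(0.029, 0.0295, 0.0305),
                          c(1e5, 9e4, 8e4))
  sc <- scale_nerve_conductivity(base, 1.1)
  expect_equal(sc$sigma[2] / base$sigma[2], 37.288135593220346,
               tolerance = 1e-9)
  expect_error(scale_nerve_conductivity(base, -1), "positive")
})

test_that("property bounds bracket the defaults under both rules", {
  base <- tissue_property("nerve", c(100, 1e3, 1e4), rep(0.0295, 3),
                          c(4e5, 6e4, 3e4))
  b <- property_bounds(base, "fractional", fraction = 0.5)
  expect_equal(b$lower$sigma, rep(0.01475, 3))
  expect_equal(b$upper$sigma, rep(0.04425, 3))
  expect_identical(b$lower$bound_tag, "lower")

  lit_same <- base
  b <- property_bounds(base, "median_log_distance", literature = lit_same)
  expect_equal(b$lower$sigma, base$sigma)
  expect_equal(b$upper$eps_r, base$eps_r)

  lit10 <- tissue_property("nerve", base$freq, base$sigma * 10,
                           base$eps_r * 10)
  b <- property_bounds(base, "median_log_distance", literature = lit10)
  expect_equal(b$upper$sigma, base$sigma * 10, tolerance = 1e-12)
  expect_equal(b$lower$sigma, base$sigma / 10, tolerance = 1e-12)
  expect_true(all(b$lower$sigma < base$sigma) &&
                all(base$sigma < b$upper$sigma))
  expect_error(property_bounds(base, "median_log_distance"), "literature")
})

test_that("spline interpolation is exact at knots and reproduces cubics", {
  f <- c(100, 300, 1e3, 3e3, 1e4)
  prop <- tissue_property("t", f, c(1, 1.2, 1.5, 1.9, 2.4),
                          c(100, 80, 60, 50, 45))
  expect_equal(interp_property(prop, f, what = "sigma"), prop$sigma,
               tolerance = 1e-10)

  # knots on a straight line reproduce the line (linear space)
  lin <- tissue_property("t", f, 2 + 3e-4 * f, 1 + 1e-4 * f)
  q <- c(200, 650, 2000, 7000)
  expect_equal(interp_property(lin, q, what = "sigma", space = "linear"),
               2 + 3e-4 * q, tolerance = 1e-10)

  # knots on a cubic polynomial: spline reproduces the polynomial
  poly <- function(x) 1 + 2 * x + 0.5 * x^2 + 0.1 * x^3
  x <- 1:6
  cub <- tissue_property("t", x, poly(x), rep(1, 6))
  mid <- x[-6] + 0.5
  expect_equal(interp_property(cub, mid, what = "sigma", space = "linear"),
               poly(mid), tolerance = 1e-9)

  expect_error(interp_property(prop, 50), "extrapolation")
  expect_error(interp_property(prop, 2e4), "extrapolation")
})

test_that("property tables survive a text round trip", {
  lib <- tissue_library()
  p <- property_bounds(lib$tables$bone, "fractional", fraction = 0.3)$upper
  path <- tempfile(fileext = ".tsv")
  write_property_table(p, path)
  q <- read_property_table(path)
  expect_equal(q$freq, p$freq)
  expect_equal(q$sigma, p$sigma)
  expect_equal(q$eps_r, p$eps_r)
  expect_identical(q$bound_tag, "upper")
  expect_identical(q$name, p$name)
})
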