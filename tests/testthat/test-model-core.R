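test_that("sphere shape function is stable at small x and hits known values", {
  expect_equal(sphere_shape(1e-6), 1, tolerance = 1e-9)
  expect_equal(sphere_shape(0), 1)
  expect_equal(sphere_shape(pi), 3 / pi^2, tolerance = 1e-12)
  # first root of tan x = x
  expect_lt(abs(sphere_shape(4.4934)), 1e-4)
  # continuity across the series/closed-form switch at x = 1e-2
  eps <- 1e-6
  expect_equal(sphere_shape(1e-2 - eps), sphere_shape(1e-2 + eps),
               tolerance = 1e-7)
  expect_error(sphere_shape(-1))
})

test_that("sphere volume is (4/3) pi r^3 with cubic scaling", {
  expect_equal(sphere_volume(1), 4 * pi / 3)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(2) / sphere_volume(1), 8)
})

test_that("shell amplitude telescopes and matches the direct contrast sum", {
  # zero contrast everywhere -> zero amplitude
  sh0 <- shell_stack(Rc0 = 25, rho_c = 0.3, rho_1 = 0.3, rho_2 = 0.3,
                     rho_3 = 0.3, rho_s = 0.3)
  q <- c(0.07, 0.5, 2, 4.5)
  expect_equal(shell_amplitude(q, 25, sh0), rep(0, 4))

  # all shell SLDs equal to the solvent -> uniform sphere of the core
  shu <- shell_stack(Rc0 = 25, rho_c = 0.01, rho_1 = 0, rho_2 = 0,
                     rho_3 = 0, rho_s = 0)
  expect_equal(shell_amplitude(q, 25, shu),
               0.01 * sphere_volume(25) * sphere_shape(q * 25),
               tolerance = 1e-12)

  # q -> 0+ limit equals the direct sum of the four V * drho terms
  sh <- base_params()$shells
  radii <- 25 + cumsum(c(0, 2, 0.3, 4))
  drho <- c(0.01 - (-0.01), -0.01 - 0.01, 0.01 - 0.001, 0.001 - 0)
  direct <- sum(drho * 4 / 3 * pi * radii^3)
  expect_equal(shell_amplitude(1e-8, 25, sh), direct, tolerance = 1e-9)
})

test_that("Gaussian size distribution has correct mode, width and mass", {
  n <- 3.7
  expect_equal(size_distribution(20, 20, 2, n = n), n / (2 * sqrt(2 * pi)))
  expect_equal(size_distribution(22, 20, 2) / size_distribution(20, 20, 2),
               exp(-1 / 2))
  rc <- seq(20 - 16, 20 + 16, length.out = 20001)
  mass <- pracma::trapz(rc, size_distribution(rc, 20, 2, n = n))
  expect_equal(mass, n, tolerance = 1e-6)
  expect_error(size_distribution(20, 20, 0), "monodisperse")
})

test_that("polydisperse intensity matches the delta limit and a Riemann oracle", {
  q <- default_q_grid(n = 60)
  p <- base_params(sigma = 1e-4)
  p$background <- 1e-3
  mono <- base_params()
  ref <- mono$scale * shell_amplitude(q, 25, mono$shells)^2 + 1e-3
  expect_equal(lnp_intensity(q, p), ref, tolerance = 1e-5)

  p2 <- base_params(sigma = 2.5)
  p2$background <- 1e-3
  expect_equal(lnp_intensity(q, p2), riemann_intensity(q, p2, n_grid = 1e4),
               tolerance = 1e-4)
})

test_that("uniform-sphere closed form is recovered at zero shell contrast", {
  q <- default_q_grid(n = 80)
  sh <- shell_stack(Rc0 = 22, sigma = 0, rho_c = 0.02, rho_1 = 0.005,
                    rho_2 = 0.005, rho_3 = 0.005, rho_s = 0.005)
  p <- lnp_params(sh, scale = 2.5, background = 0.1)
  ref <- 2.5 * ((0.02 - 0.005) * sphere_volume(22) * sphere_shape(q * 22))^2
  expect_equal(lnp_intensity(q, p) - 0.1, ref, tolerance = 1e-6)
})

test_that("scaling every contrast by k scales the net intensity by k^2", {
  q <- default_q_grid(n = 50)
  p <- base_params(sigma = 2)
  p$background <- 0.5
  k <- 3.7
  sh <- p$shells
  p2 <- lnp_params(shell_stack(Rc0 = sh$Rc0, sigma = sh$sigma, t1 = sh$t1,
                               t2 = sh$t2, t3 = sh$t3, rho_c = k * sh$rho_c,
                               rho_1 = k * sh$rho_1, rho_2 = k * sh$rho_2,
                               rho_3 = k * sh$rho_3, rho_s = k * sh$rho_s),
                   scale = p$scale, background = p$background)
  expect_equal(lnp_intensity(q, p2) - 0.5, k^2 * (lnp_intensity(q, p) - 0.5),
               tolerance = 1e-12)
})

test_that("quasi-Bragg peak is a unit-convention Gaussian and purely additive", {
  pk <- gaussian_peak(2.5, 1.27, 0.28)
  expect_equal(quasi_bragg_peak(1.27, pk), 2.5)
  expect_equal(quasi_bragg_peak(1.27 + 0.28, pk), 2.5 * exp(-1 / 2))
  expect_equal(quasi_bragg_peak(1.27 - 0.28, pk), 2.5 * exp(-1 / 2))
  qq <- seq(1.27 - 8 * 0.28, 1.27 + 8 * 0.28, length.out = 40001)
  expect_equal(pracma::trapz(qq, quasi_bragg_peak(qq, pk)),
               2.5 * 0.28 * sqrt(2 * pi), tolerance = 1e-6)

  # additivity on the full model
  q <- default_q_grid(n = 50)
  p <- base_params(sigma = 2)
  p$background <- 0.2
  p_pk <- lnp_params(p$shells, peak = pk, scale = p$scale,
                     background = p$background)
  expect_equal(lnp_intensity(q, p_pk) - lnp_intensity(q, p),
               quasi_bragg_peak(q, pk), tolerance = 1e-9)

  expect_error(gaussian_peak(-1, 1.2, 0.3))
  expect_error(gaussian_peak(1, 0, 0.3))
})

test_that("derived structural metrics follow their closed forms", {
  expect_equal(d_spacing(2 * pi), 1)
  expect_equal(d_spacing(1.21), 5.193, tolerance = 1e-3)
  expect_equal(polydispersity_index(0, 42), 0)
  expect_equal(polydispersity_index(2.50, 22.94), 0.109, tolerance = 1e-2)
  expect_equal(polydispersity_index(5.18, 17.74), 0.292, tolerance = 1e-3)
  expect_equal(contrast_change(2, 2), 0)
  expect_equal(contrast_change(0.22, 0.55), -150)
  expect_error(contrast_change(0, 1), "non-zero")
})

test_that("parameter containers validate their invariants", {
  expect_error(shell_stack(Rc0 = -1))
  expect_error(shell_stack(sigma = -0.1))
  expect_error(lnp_params(shell_stack(), scale = 0))
  expect_error(lnp_params(shell_stack(), background = -1))
  expect_error(saxs_curve(c(1, 2), c(1, -1)))          # negative intensity
  expect_error(saxs_curve(c(2, 1), c(1, 1)))           # non-increasing q
  expect_error(saxs_curve(c(0, 1), c(1, 1)))           # q must be positive
  expect_error(saxs_curve(c(1, 2), c(1, 1), c(0, 1)))  # zero uncertainty
  # round trip through the flat vector representation
  p <- preset_params("mrna-lnp")
  expect_equal(vector_to_params(params_to_vector(p)), p)
})
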