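# Shared fixtures: all synthetic, built in code.

# canonical simulation base: monodisperse Rc0 = 25 nm particle with the
# standard shell stack (SLDs in arbitrary units)
base_params <- function(sigma = 0) {
  lnp_params(shell_stack(Rc0 = 25, sigma = sigma, t1 = 2, t2 = 0.3, t3 = 4,
                         rho_c = 0.01, rho_1 = -0.01, rho_2 = 0.01,
                         rho_3 = 0.001, rho_s = 0))
}

# fit configuration matching the standard conventions, with the core SLD
# pinned at the preset reference so that contrasts are identifiable
preset_fit_config <- function(with_peak = FALSE, rho_c = 1e-4, ...) {
  free <- c("sigma", "Rc0", "t1", "rho_1", "rho_2", "rho_3", "scale",
            "background")
  if (with_peak) {
    free <- c(free, "peak_amplitude", "peak_center", "peak_width")
  }
  fit_config(free = free,
             fixed = c(rho_s = 0, t3 = 4, t2 = 0.3, rho_c = rho_c), ...)
}

# independent brute-force oracle: Riemann-sum polydisperse intensity with
# the amplitude written out from first principles (no package quadrature)
riemann_intensity <- function(q, params, n_grid = 1e4, k_sigma = 6,
                              chunk = 1e4) {
  s <- params$shells
  lo <- max(1e-3, s$Rc0 - k_sigma * s$sigma)
  hi <- s$Rc0 + k_sigma * s$sigma
  rc <- seq(lo, hi, length.out = n_grid)
  dr <- rc[2] - rc[1]
  drho <- c(s$rho_c - s$rho_1, s$rho_1 - s$rho_2, s$rho_2 - s$rho_3,
            s$rho_3 - s$rho_s)
  offs <- cumsum(c(0, s$t1, s$t2, s$t3))
  acc <- numeric(length(q))
  for (start in seq(1, n_grid, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_grid)
    a <- matrix(0, nrow = length(q), ncol = length(idx))
    for (i in 1:4) {
      ri <- rc[idx] + offs[i]
      x <- outer(q, ri)
      j <- 3 * (sin(x) - x * cos(x)) / x^3
      a <- a + j * matrix(drho[i] * 4 / 3 * pi * ri^3, nrow = length(q),
                          ncol = length(idx), byrow = TRUE)
    }
    acc <- acc + a^2 %*% dnorm(rc[idx], s$Rc0, s$sigma) * dr
  }
  out <- params$scale * as.vector(acc) + params$background
  if (!is.null(params$peak)) {
    pk <- params$peak
    out <- out + pk$amplitude * exp(-(q - pk$center)^2 / (2 * pk$width^2))
  }
  out
}
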