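#' Spherical shape function j(x)
#'
#' Normalised scattering shape function of a homogeneous sphere,
#' `j(x) = 3 * (sin(x) - x * cos(x)) / x^3`, where `x = q * R` is the
#' dimensionless product of momentum transfer and radius. `j(0) = 1` by
#' continuous extension; below `x = 1e-2` the Taylor series
#' `1 - x^2/10 + x^4/280` is used to avoid catastrophic cancellation.
#'
#' @param x numeric vector, `x >= 0`.
#' @return numeric vector of the same length as `x`.
#' @examples
#' sphere_shape(0)          # 1
#' sphere_shape(pi)         # 3 / pi^2
#' @export
sphere_shape <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Volume of a sphere
#'
#' @param r radius in nm, `r >= 0` (vectorised).
#' @return volume in nm^3, `(4/3) * pi * r^3`.
#' @export
sphere_volume <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0))
  4 / 3 * pi * r^3
}

#' Core-triple-shell geometry and scattering length densities
#'
#' Describes a spherical particle with a core of mean radius `Rc0` (Gaussian
#' distributed with standard deviation `sigma`) wrapped in three concentric
#' shells: the inner lipid layer (`t1`, `rho_1`), the hydrophilic headgroup
#' layer (`t2`, `rho_2`) and the hydrated PEG corona (`t3`, `rho_3`).
#' Scattering length densities (SLDs) are in arbitrary units; only contrasts
#' relative to the solvent `rho_s` are observable, and `rho_s = 0` is the
#' conventional reference. `rho_1` is typically negative relative to water
#' because the inner layer is dominated by hydrophobic hydrocarbon chains.
#'
#' @param Rc0 mean core radius, nm (> 0).
#' @param sigma standard deviation of the core-radius distribution, nm (>= 0).
#' @param t1,t2,t3 shell thicknesses, nm (>= 0).
#' @param rho_c,rho_1,rho_2,rho_3,rho_s scattering length densities of the
#'   core, the three shells, and the solvent (arbitrary units, finite).
#' @return object of class `shell_stack`.
#' @export
shell_stack <- function(Rc0 = 25, sigma = 0, t1 = 2, t2 = 0.3, t3 = 4,
                        rho_c = 0.01, rho_1 = -0.01, rho_2 = 0.01,
                        rho_3 = 0.001, rho_s = 0) {
  stopifnot(Rc0 > 0, sigma >= 0, t1 >= 0, t2 >= 0, t3 >= 0)
  slds <- c(rho_c, rho_1, rho_2, rho_3, rho_s)
  stopifnot(all(is.finite(slds)))
  structure(
    list(Rc0 = Rc0, sigma = sigma, t1 = t1, t2 = t2, t3 = t3,
         rho_c = rho_c, rho_1 = rho_1, rho_2 = rho_2, rho_3 = rho_3,
         rho_s = rho_s),
    class = "shell_stack"
  )
}

#' Gaussian quasi-Bragg peak parameters
#'
#' The broad diffraction-like maximum near q ~ 1.2 nm^-1 produced by the
#' quasi-periodic packing of mRNA-ionizable-lipid assemblies inside the core
#' is described by a Gaussian in q. `width` is the Gaussian standard
#' deviation (not FWHM). The repeat distance is `2 * pi / center` (see
#' [d_spacing()]).
#'
#' @param amplitude peak height, intensity units (>= 0).
#' @param center peak position, nm^-1 (> 0).
#' @param width Gaussian standard deviation, nm^-1 (> 0).
#' @return object of class `gaussian_peak`.
#' @export
gaussian_peak <- function(amplitude, center, width) {
  stopifnot(amplitude >= 0, center > 0, width > 0)
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "gaussian_peak")
}

#' Full LNP model parameter set
#'
#' Bundles the core-triple-shell geometry, an optional quasi-Bragg peak
#' (present for mRNA-loaded particles, absent for empty ones), an overall
#' multiplicative `scale` absorbing the particle number density, and an
#' additive q-independent `background`.
#'
#' @param shells a [shell_stack()].
#' @param peak a [gaussian_peak()] or `NULL`.
#' @param scale overall multiplicative factor (> 0), arbitrary units.
#' @param background additive constant Bg, intensity units (>= 0).
#' @return object of class `lnp_params`.
#' @export
lnp_params <- function(shells, peak = NULL, scale = 1, background = 0) {
  stopifnot(inherits(shells, "shell_stack"), scale > 0, background >= 0)
  if (!is.null(peak)) stopifnot(inherits(peak, "gaussian_peak"))
  structure(list(shells = shells, peak = peak, scale = scale,
                 background = background),
            class = "lnp_params")
}

#' @export
print.lnp_params <- function(x, ...) {
  s <- x$shells
  cat("LNP core-triple-shell parameters\n")
  cat(sprintf("  core:   Rc0 = %g nm, sigma = %g nm (sigma/Rc0 = %.3g)\n",
              s$Rc0, s$sigma, s$sigma / s$Rc0))
  cat(sprintf("  shells: t1 = %g, t2 = %g, t3 = %g nm\n", s$t1, s$t2, s$t3))
  cat(sprintf("  SLDs:   rho_c = %g, rho_1 = %g, rho_2 = %g, rho_3 = %g, rho_s = %g\n",
              s$rho_c, s$rho_1, s$rho_2, s$rho_3, s$rho_s))
  if (!is.null(x$peak)) {
    cat(sprintf("  peak:   A = %g, C = %g nm^-1, W = %g nm^-1 (d = %.3f nm)\n",
                x$peak$amplitude, x$peak$center, x$peak$width,
                d_spacing(x$peak$center)))
  } else {
    cat("  peak:   none\n")
  }
  cat(sprintf("  scale = %g, background = %g\n", x$scale, x$background))
  invisible(x)
}

# radii of the four concentric interfaces for an explicit core radius
.shell_radii <- function(Rc, shells) {
  Rc + cumsum(c(0, shells$t1, shells$t2, shells$t3))
}

# the four contrast steps, outermost referenced to the solvent
.shell_contrasts <- function(shells) {
  c(shells$rho_c - shells$rho_1,
    shells$rho_1 - shells$rho_2,
    shells$rho_2 - shells$rho_3,
    shells$rho_3 - shells$rho_s)
}

#' Core-triple-shell scattering amplitude
#'
#' The amplitude for a single particle with explicit core radius `Rc` is the
#' telescoping four-term contrast sum
#' `A(q) = sum_i (rho_i - rho_{i+1}) * V(R_i) * j(q * R_i)` over the four
#' concentric interfaces at `Rc`, `Rc + t1`, `Rc + t1 + t2` and
#' `Rc + t1 + t2 + t3`, with `V` the sphere volume and `j` the shape
#' function [sphere_shape()]. The forward-scattering delta contribution at
#' q = 0 is excluded; evaluation grids must keep q > 0.
#'
#' @param q momentum transfer, nm^-1 (> 0, vectorised).
#' @param Rc explicit core radius, nm (> 0) -- not the mean radius.
#' @param shells a [shell_stack()]; its `Rc0`/`sigma` are ignored here.
#' @return amplitude, arbitrary units, same length as `q`.
#' @export
shell_amplitude <- function(q, Rc, shells) {
  stopifnot(all(q > 0), Rc > 0, inherits(shells, "shell_stack"))
  radii <- .shell_radii(Rc, shells)
  drho <- .shell_contrasts(shells)
  a <- numeric(length(q))
  for (i in seq_along(radii)) {
    a <- a + drho[i] * sphere_volume(radii[i]) * sphere_shape(q * radii[i])
  }
  a
}

#' Gaussian core-radius number density
#'
#' `N(Rc) = n / (sigma * sqrt(2*pi)) * exp(-(Rc - Rc0)^2 / (2 * sigma^2))`,
#' the Gaussian size distribution of the core radius with total particle
#' number density `n`.
#'
#' @param Rc core radius at which to evaluate, nm (vectorised).
#' @param Rc0 mean core radius, nm.
#' @param sigma standard deviation, nm (> 0; `sigma = 0` is rejected --
#'   callers must take the monodisperse path instead).
#' @param n total number of particles per unit volume (default 1).
#' @return number density at `Rc`.
#' @export
size_distribution <- function(Rc, Rc0, sigma, n = 1) {
  if (sigma <= 0) {
    stop("sigma must be > 0; use the monodisperse evaluation path for sigma = 0")
  }
  n * stats::dnorm(Rc, mean = Rc0, sd = sigma)
}

#' Polydisperse core-triple-shell intensity
#'
#' Model intensity
#' `I(q) = scale * integral N(Rc) A(q; Rc)^2 dRc + peak(q) + Bg`,
#' where the Gaussian size distribution `N` (normalised, the number density
#' being absorbed into `scale`) runs over the core radius only -- the shell
#' thicknesses ride rigidly on `Rc`. The integral is evaluated by fixed
#' Gauss-Legendre quadrature with `n_nodes` nodes on
#' `[max(1e-3, Rc0 - k_sigma * sigma), Rc0 + k_sigma * sigma]`; mass outside
#' (including any negative-radius tail) is truncated without renormalisation,
#' negligible (< 1e-8) for sigma/Rc0 <= 0.3. For `sigma = 0` the exact
#' monodisperse expression `scale * A(q; Rc0)^2` is used.
#'
#' @param q momentum transfer grid, nm^-1, all > 0.
#' @param params an [lnp_params()].
#' @param n_nodes number of Gauss-Legendre nodes (default 201).
#' @param k_sigma half-width of the integration window in units of sigma
#'   (default 6).
#' @return intensity vector, arbitrary units, same length as `q`.
#' @export
lnp_intensity <- function(q, params, n_nodes = 201, k_sigma = 6) {
  stopifnot(inherits(params, "lnp_params"), all(q > 0), n_nodes >= 2)
  s <- params$shells
  if (s$sigma == 0) {
    iform <- shell_amplitude(q, s$Rc0, s)^2
  } else {
    lo <- max(1e-3, s$Rc0 - k_sigma * s$sigma)
    hi <- s$Rc0 + k_sigma * s$sigma
    gl <- pracma::gaussLegendre(n_nodes, lo, hi)
    dens <- stats::dnorm(gl$x, mean = s$Rc0, sd = s$sigma)
    amp2 <- matrix(0, nrow = length(q), ncol = n_nodes)
    drho <- .shell_contrasts(s)
    offs <- cumsum(c(0, s$t1, s$t2, s$t3))
    a <- matrix(0, nrow = length(q), ncol = n_nodes)
    for (i in 1:4) {
      ri <- gl$x + offs[i]
      a <- a + outer(q, ri, function(qq, rr) sphere_shape(qq * rr)) *
        matrix(drho[i] * sphere_volume(ri), nrow = length(q),
               ncol = n_nodes, byrow = TRUE)
    }
    amp2 <- a^2
    iform <- as.vector(amp2 %*% (gl$w * dens))
  }
  out <- params$scale * iform + params$background
  if (!is.null(params$peak)) out <- out + quasi_bragg_peak(q, params$peak)
  if (any(!is.finite(out))) {
    stop("non-finite model intensity: invalid parameter combination")
  }
  out
}

#' Gaussian quasi-Bragg peak contribution
#'
#' `A_p * exp(-(q - C)^2 / (2 * W^2))` with `W` the Gaussian standard
#' deviation; additive to the form-factor intensity.
#'
#' @param q momentum transfer, nm^-1 (vectorised).
#' @param peak a [gaussian_peak()].
#' @return intensity contribution, same length as `q`.
#' @export
quasi_bragg_peak <- function(q, peak) {
  stopifnot(inherits(peak, "gaussian_peak"))
  peak$amplitude * exp(-(q - peak$center)^2 / (2 * peak$width^2))
}

#' Repeat distance from a quasi-Bragg peak position
#'
#' The quasi-periodic packing distance of the mRNA-lipid assemblies,
#' `d = 2 * pi / center`.
#'
#' @param center peak position, nm^-1 (> 0).
#' @return periodic distance, nm.
#' @export
d_spacing <- function(center) {
  stopifnot(all(center > 0))
  2 * pi / center
}

#' Polydispersity ratio sigma / Rc0
#'
#' Dimensionless width of the core-size distribution; the standard metric of
#' LNP size uniformity.
#'
#' @param sigma standard deviation of the core radius, nm (>= 0).
#' @param Rc0 mean core radius, nm (> 0).
#' @return `sigma / Rc0`.
#' @export
polydispersity_index <- function(sigma, Rc0) {
  stopifnot(all(sigma >= 0), all(Rc0 > 0))
  sigma / Rc0
}

#' Signed percent change of one SLD relative to another
#'
#' `100 * (a - b) / a`: positive when `b` is lower than the reference `a`
#' (a contrast reduction), negative when higher.
#'
#' @param value_a reference SLD (non-zero).
#' @param value_b comparison SLD.
#' @return signed percent change.
#' @export
contrast_change <- function(value_a, value_b) {
  if (any(value_a == 0)) stop("reference SLD must be non-zero")
  100 * (value_a - value_b) / value_a
}
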