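# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Noise model for synthetic curves
#'
#' Stands in for counting noise on short-exposure synchrotron 1D data.
#' `"multiplicative"` perturbs each point by `I * (1 + level * N(0,1))`
#' (default level 1 percent, representative of averaged synchrotron
#' curves); `"poisson"` draws `Poisson(I * level) / level` with `level`
#' acting as an effective count scale; `"none"` is exact.
#'
#' @param kind one of `"none"`, `"multiplicative"`, `"poisson"`.
#' @param level relative noise fraction (multiplicative) or count scale
#'   (poisson); `>= 0`.
#' @param seed integer seed; generation is reproducible given the seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative", "poisson"),
                        level = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(level >= 0)
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_model")
}

#' Default momentum-transfer grid
#'
#' Log-spaced grid over the instrument range 0.07-4.5 nm^-1, 400 points.
#'
#' @param n number of points.
#' @param qmin,qmax endpoints, nm^-1.
#' @return numeric vector, strictly increasing.
#' @export
default_q_grid <- function(n = 400, qmin = 0.07, qmax = 4.5) {
  stopifnot(n >= 2, qmin > 0, qmax > qmin)
  exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Generate a synthetic scattering curve
#'
#' Forward-evaluates the polydisperse core-triple-shell model (plus
#' quasi-Bragg peak and background, when present) on a q grid and applies
#' the noise model. The uncertainty column carries the nominal noise
#' magnitude; identical seeds yield bit-identical curves.
#'
#' @param params an [lnp_params()].
#' @param q_grid momentum-transfer grid (default [default_q_grid()]).
#' @param noise a [noise_model()] (default: none).
#' @param metadata metadata tags attached to the curve.
#' @param n_nodes quadrature nodes for [lnp_intensity()].
#' @return a [saxs_curve()].
#' @export
generate_curve <- function(params, q_grid = default_q_grid(),
                           noise = noise_model("none"), metadata = list(),
                           n_nodes = 201) {
  stopifnot(inherits(params, "lnp_params"), inherits(noise, "noise_model"))
  I0 <- lnp_intensity(q_grid, params, n_nodes = n_nodes)
  n <- length(q_grid)
  if (noise$kind == "none" || noise$level == 0) {
    return(saxs_curve(q_grid, I0, uncertainty = NULL, metadata = metadata))
  }
  if (noise$kind == "multiplicative") {
    I <- .with_seed(noise$seed, I0 * (1 + noise$level * stats::rnorm(n)))
    err <- noise$level * I0
  } else { # poisson
    counts <- .with_seed(noise$seed, stats::rpois(n, I0 * noise$level))
    I <- counts / noise$level
    err <- sqrt(pmax(I0 * noise$level, 1)) / noise$level
  }
  I <- pmax(I, 0)
  saxs_curve(q_grid, I, uncertainty = err, metadata = metadata)
}

#' Single-parameter sweep specification
#'
#' Defines a family of noiseless model curves obtained by varying exactly
#' one parameter of a base parameter set on a shared q grid — the standard
#' simulation study for understanding how each structural parameter shapes
#' the scattering profile. The default base reproduces the canonical
#' simulation conditions: Rc0 = 25 nm, t1 = 2 nm, t2 = 0.3 nm, t3 = 4 nm,
#' rho_c = 0.01, rho_1 = -0.01, rho_2 = 0.01, rho_3 = 0.001, rho_s = 0
#' (SLDs in arbitrary units), monodisperse unless sigma is swept.
#'
#' @param vary name of the parameter to vary (flat names, see
#'   [params_to_vector()]).
#' @param values non-empty numeric vector of values for `vary`.
#' @param base base [lnp_params()].
#' @param q_grid shared grid (default [default_q_grid()]).
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(vary, values,
                       base = lnp_params(shell_stack(
                         Rc0 = 25, sigma = 0, t1 = 2, t2 = 0.3, t3 = 4,
                         rho_c = 0.01, rho_1 = -0.01, rho_2 = 0.01,
                         rho_3 = 0.001, rho_s = 0)),
                       q_grid = default_q_grid()) {
  stopifnot(is.character(vary), length(vary) == 1, length(values) >= 1,
            inherits(base, "lnp_params"))
  v <- params_to_vector(base)
  if (!vary %in% names(v)) {
    stop("unknown sweep parameter '", vary, "'; valid names: ",
         paste(names(v), collapse = ", "))
  }
  structure(list(vary = vary, values = values, base = base, q_grid = q_grid),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' One noiseless curve per value of the swept parameter, all on the shared
#' grid; exactly reproducible.
#'
#' @param spec a [sweep_spec()].
#' @param n_nodes quadrature nodes.
#' @return named list of [saxs_curve()] (names = formatted values), in the
#'   order of `spec$values`.
#' @export
run_sweep <- function(spec, n_nodes = 201) {
  stopifnot(inherits(spec, "sweep_spec"))
  out <- lapply(spec$values, function(val) {
    v <- params_to_vector(spec$base)
    v[[spec$vary]] <- val
    generate_curve(vector_to_params(v), q_grid = spec$q_grid,
                   metadata = stats::setNames(list(val), spec$vary),
                   n_nodes = n_nodes)
  })
  names(out) <- format(spec$values, trim = TRUE)
  out
}

#' Count local maxima of a curve on log intensity
#'
#' A point is a local maximum when it is the strict largest within a
#' +/- `window`-point neighbourhood of the log-intensity sequence — robust
#' to float ripple on smooth model curves. Used to assess how form-factor
#' oscillations wash out with polydispersity.
#'
#' @param curve a [saxs_curve()].
#' @param window half-width in points (default 5).
#' @param qmin,qmax optional q range restriction.
#' @return integer count of local maxima; attribute `"q"` carries their
#'   positions.
#' @export
count_local_maxima <- function(curve, window = 5, qmin = -Inf, qmax = Inf) {
  stopifnot(inherits(curve, "saxs_curve"))
  sel <- curve$q >= qmin & curve$q <= qmax
  q <- curve$q[sel]
  y <- log10(pmax(curve$intensity[sel], .Machine$double.xmin))
  n <- length(y)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - window)
    hi <- min(n, i + window)
    nb <- y[c(if (lo < i) lo:(i - 1), if (hi > i) (i + 1):hi)]
    is_max[i] <- i > window && i <= n - window && all(y[i] > nb)
  }
  structure(sum(is_max), q = q[is_max])
}

#' Parameter-recovery experiment
#'
#' Generates `n_replicates` noisy curves from known true parameters (seeds
#' derived as `noise$seed + replicate - 1`), fits each with the given
#' configuration, and summarises per-parameter recovery: median, relative
#' bias of the median, and spread (median absolute deviation) against the
#' truth. Per-replicate fit failures are recorded without aborting.
#'
#' The initial point for each fit is taken from [initial_guess()] on the
#' noisy curve, with pinned parameters overlaid from `config$fixed`; the
#' core SLD reference is taken from the truth (only SLD contrasts relative
#' to that reference are identifiable when `scale` is free).
#'
#' @param true_params an [lnp_params()] — the generating truth.
#' @param noise a [noise_model()]; its seed is the base replicate seed.
#' @param n_replicates number of replicates (>= 1).
#' @param config a [fit_config()].
#' @param q_grid q grid for generation.
#' @param n_nodes quadrature nodes.
#' @return object of class `recovery_summary`: data.frame `summary` (one
#'   row per free parameter: truth, median, relative bias, spread),
#'   `fits`, `failures`, and `n_ok`.
#' @export
recovery_experiment <- function(true_params, noise, n_replicates, config,
                                q_grid = default_q_grid(), n_nodes = 201) {
  stopifnot(n_replicates >= 1)
  with_peak <- !is.null(true_params$peak)
  truth_v <- params_to_vector(true_params)
  fits <- vector("list", n_replicates)
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    nm <- noise_model(noise$kind, noise$level, seed = noise$seed + r - 1L)
    curve <- generate_curve(true_params, q_grid = q_grid, noise = nm,
                            metadata = list(replicate = r),
                            n_nodes = n_nodes)
    res <- tryCatch({
      init <- initial_guess(curve, with_peak = with_peak,
                            rho_c = true_params$shells$rho_c)
      fit_curve(curve, config, init, n_nodes = n_nodes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[as.character(r)] <- conditionMessage(res)
    } else {
      fits[[r]] <- res
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  free <- config$free[config$free %in% names(truth_v)]
  rows <- lapply(free, function(nm) {
    vals <- vapply(fits[ok], function(f) params_to_vector(f$params)[[nm]],
                   numeric(1))
    med <- stats::median(vals)
    truth <- truth_v[[nm]]
    data.frame(parameter = nm, truth = truth, median = med,
               rel_bias = if (truth != 0) (med - truth) / truth else NA_real_,
               spread = stats::mad(vals, constant = 1),
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), fits = fits[ok],
                 failures = failures, n_ok = sum(ok)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d successful fits, %d failures\n",
              x$n_ok, length(x$failures)))
  df <- x$summary
  df$rel_bias <- sprintf("%+.2f%%", 100 * df$rel_bias)
  print(df, row.names = FALSE)
  invisible(x)
}
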