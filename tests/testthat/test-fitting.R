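test_that("fit configuration rejects inconsistent and unidentifiable setups", {
  expect_error(fit_config(free = character(0)))
  expect_error(fit_config(free = c("Rc0", "t3"),
                          fixed = c(t3 = 4)), "overlap")
  expect_error(fit_config(free = c("scale", "rho_c", "rho_1", "rho_2",
                                   "rho_3", "rho_s"),
                          fixed = numeric(0)), "unidentifiable")
  # pinning one SLD restores identifiability
  expect_s3_class(fit_config(free = c("scale", "rho_1", "rho_2", "rho_3"),
                             fixed = c(rho_s = 0, rho_c = 1e-4)),
                  "fit_config")
})

test_that("initial guess locates the core radius, background and peak", {
  # noiseless canonical curve: core radius within 20% of 25 nm
  cv <- generate_curve(base_params())
  g <- initial_guess(cv, rho_c = 0.01)
  expect_false(attr(g, "low_confidence"))
  expect_lt(abs(g$shells$Rc0 - 25) / 25, 0.2)

  # flat curve: defaults plus low-confidence flag
  flat <- saxs_curve(default_q_grid(n = 100), rep(1, 100))
  gf <- initial_guess(flat)
  expect_true(attr(gf, "low_confidence"))
  expect_equal(gf$shells$Rc0, 25)

  # mRNA-like curve: peak-center guess within 0.05 nm^-1 of the truth
  truth <- preset_params("mrna-lnp")
  cvm <- generate_curve(truth,
                        noise = noise_model("multiplicative", 0.01, seed = 2))
  gm <- initial_guess(cvm, with_peak = TRUE, rho_c = 1e-4)
  expect_lt(abs(gm$peak$center - 1.27), 0.05)
})

test_that("noiseless self-consistency: perturbed start recovers the truth", {
  truth <- preset_params("empty-lnp")
  cv <- generate_curve(truth)
  cfg <- preset_fit_config()
  # deterministic +/-10% perturbation of the generating values
  v <- params_to_vector(truth)
  pert <- c(sigma = 1.1, Rc0 = 0.9, t1 = 1.1, rho_1 = 0.9, rho_2 = 1.1,
            rho_3 = 0.9, scale = 1.1, background = 0.9)
  v[names(pert)] <- v[names(pert)] * pert
  fit <- fit_curve(cv, cfg, vector_to_params(v))
  expect_true(fit$diagnostics$converged)
  got <- params_to_vector(fit$params)
  for (nm in cfg$free) {
    expect_lt(abs(got[[nm]] - params_to_vector(truth)[[nm]]) /
                abs(params_to_vector(truth)[[nm]]), 0.005)
  }
  # objective decreases from the starting point
  expect_lte(fit$reduced_chi2, fit$diagnostics$initial_reduced_chi2)
  # fixed parameters are bit-identical in the result
  expect_identical(fit$params$shells$t3, 4)
  expect_identical(fit$params$shells$t2, 0.3)
  expect_identical(fit$params$shells$rho_s, 0)
  # derived metrics recompute from the fitted parameters
  expect_equal(fit$derived$pdi,
               fit$params$shells$sigma / fit$params$shells$Rc0)
})

test_that("two different perturbed starts agree to 0.1% on exact data", {
  truth <- preset_params("empty-lnp")
  cv <- generate_curve(truth)
  cfg <- preset_fit_config()
  v <- params_to_vector(truth)
  nm <- c("sigma", "Rc0", "t1", "rho_1", "rho_2", "rho_3", "scale",
          "background")
  v1 <- v; v1[nm] <- v[nm] * c(1.1, 0.92, 1.08, 0.9, 1.1, 0.9, 1.05, 0.95)
  v2 <- v; v2[nm] <- v[nm] * c(0.9, 1.07, 0.93, 1.1, 0.9, 1.1, 0.95, 1.05)
  f1 <- fit_curve(cv, cfg, vector_to_params(v1))
  f2 <- fit_curve(cv, cfg, vector_to_params(v2))
  g1 <- params_to_vector(f1$params)[nm]
  g2 <- params_to_vector(f2$params)[nm]
  expect_true(all(abs(g1 - g2) / abs(g1) < 1e-3))
})

test_that("fit preconditions are enforced", {
  truth <- preset_params("empty-lnp")
  cv <- generate_curve(truth, q_grid = default_q_grid(n = 5))
  cfg <- preset_fit_config()
  expect_error(fit_curve(cv, cfg, truth), "fewer points")
  cv2 <- generate_curve(truth, q_grid = default_q_grid(n = 50))
  cfgp <- preset_fit_config(with_peak = TRUE)
  expect_error(fit_curve(cv2, cfgp, truth), "no peak")
})

test_that("derive_metrics fills sigma/Rc0 and d-spacing and is idempotent", {
  truth <- preset_params("mrna-lnp")
  cv <- generate_curve(truth)
  cfg <- preset_fit_config(with_peak = TRUE)
  fit <- fit_curve(cv, cfg, truth)
  expect_equal(fit$derived$pdi, 0.120, tolerance = 2e-2)
  expect_equal(fit$derived$d_spacing, 4.947, tolerance = 2e-2)
  expect_identical(derive_metrics(fit)$derived, fit$derived)
})

test_that("batch fitting isolates per-curve failures and keeps column order", {
  expect_identical(nrow(batch_fit(list(), preset_fit_config())$table), 0L)

  truth <- preset_params("empty-lnp")
  good1 <- generate_curve(truth,
                          noise = noise_model("multiplicative", 0.01, 11))
  good2 <- generate_curve(truth,
                          noise = noise_model("multiplicative", 0.01, 12))
  corrupt <- saxs_curve(default_q_grid(n = 6), rep(1, 6))  # too few points
  res <- batch_fit(list(a = good1, bad = corrupt, b = good2),
                   preset_fit_config(), initials = list(truth, truth, truth))
  expect_identical(nrow(res$table), 2L)
  expect_named(res$failures, "bad")
  expect_identical(res$table$tag, c("a", "b"))
  expect_identical(names(res$table)[1:9],
                   c("tag", "sigma", "Rc0", "t1", "rho_1", "rho_2", "rho_3",
                     "peak_center", "peak_width"))
})

test_that("fit reports serialize to CSV and JSON", {
  truth <- preset_params("empty-lnp")
  cv <- generate_curve(truth)
  fit <- fit_curve(cv, preset_fit_config(), truth)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_fit_report(fit, json_path = js, csv_path = csv)
  tab <- read.csv(csv)
  expect_equal(tab$Rc0, 22.94, tolerance = 1e-3)
  parsed <- jsonlite::read_json(js, simplifyVector = FALSE)
  expect_equal(parsed$results[[1]]$Rc0, tab$Rc0, tolerance = 1e-9)
})
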