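test_that("Guinier intensity matches its closed form and limits", {
  ## q -> 0 limit: exponent vanishes
  expect_equal(guinier_intensity(1e-9, i_zero = 3, rg = 10, background = 0.5),
               3.5, tolerance = 1e-12)
  ## exp(-1/3) at q*rg = 1
  expect_equal(guinier_intensity(0.1, i_zero = 1, rg = 10, background = 0),
               0.7165313, tolerance = 1e-6)
  ## q = sqrt(3)/rg gives i_zero / e
  expect_equal(guinier_intensity(sqrt(3) / 10, i_zero = 2, rg = 10,
                                 background = 0),
               2 / exp(1), tolerance = 1e-12)
  expect_true(all(diff(guinier_intensity(q_grid(n = 50), 1, 20, 0)) < 0))
  expect_error(guinier_intensity(0.1, i_zero = NaN, rg = 10),
               class = "autosas_domain_error")
})

test_that("sphere form factor has its first zero at q*r = 4.4934095", {
  ## independent oracle: bracketed root of tan(x) = x
  x_star <- uniroot(function(x) sin(x) - x * cos(x), c(4, 4.6), tol = 1e-10)$root
  expect_equal(x_star, 4.4934095, tolerance = 1e-6)
  r <- 50
  I <- sphere_intensity(x_star / r, scale = 1, radius = r, sld = 1e-3,
                        background = 0.321)
  expect_equal(I, 0.321, tolerance = 1e-10)
})

test_that("sphere q->0 limit is scale * V * drho^2 + background", {
  r <- 45; drho <- 2e-3
  V <- 4 / 3 * pi * r^3
  expect_equal(sphere_intensity(1e-9, scale = 3, radius = r, sld = drho,
                                sld_solvent = 0, background = 0.1),
               3 * V * drho^2 + 0.1, tolerance = 1e-9)
  ## only the contrast sld - sld_solvent enters
  q <- q_grid(n = 30)
  expect_equal(sphere_intensity(q, 1, r, 5e-3, 3e-3),
               sphere_intensity(q, 1, r, 2e-3, 0), tolerance = 1e-12)
})

test_that("polydisperse sphere matches a Monte-Carlo oracle", {
  r <- 45; pd <- 0.1; drho <- DRHO
  q <- q_grid(0.005, 0.4, 50)
  I <- sphere_intensity(q, 1, r, drho, 0, 0, pd_width = pd, pd_nbins = 81L)
  ## Monte-Carlo oracle: 1e5 stratified (inverse-CDF) samples of the same
  ## truncated Gaussian radius distribution, averaging the monodisperse
  ## formula; stratification removes the sampling noise a plain average
  ## would add near the form-factor minima
  u <- (seq_len(1e5) - 0.5) / 1e5
  lo_p <- pnorm(-3); hi_p <- pnorm(3)
  rs <- r + pd * r * qnorm(lo_p + u * (hi_p - lo_p))
  mono <- function(qi) {
    x <- qi * rs
    mean(4 / 3 * pi * rs^3 * drho^2 * (3 * (sin(x) - x * cos(x)) / x^3)^2)
  }
  I_mc <- vapply(q, mono, 0)
  expect_lt(max(abs(I - I_mc) / I_mc), 1e-3)
})

test_that("doubling polydispersity bins changes the sphere by < 1e-4", {
  q <- q_grid(0.005, 0.4, 100)
  for (pd in c(0.1, 0.3)) {
    a <- sphere_intensity(q, 1, 45, DRHO, 0, 0, pd, pd_nbins = 81L)
    b <- sphere_intensity(q, 1, 45, DRHO, 0, 0, pd, pd_nbins = 162L)
    expect_lt(max(abs(a - b) / b), 1e-4)
  }
  expect_error(sphere_intensity(0.1, 1, 45, DRHO, 0, 0, 0.1, pd_nbins = 2L),
               class = "autosas_config_error")
})

test_that("the coil model reproduces hand-evaluated Schulz-Zimm values", {
  ## Debye limit at Z = 1: P = 2/e
  expect_equal(poly_gauss_coil_intensity(0.1, 1, 1, 10, pdi = 1, 0),
               2 * exp(-1), tolerance = 1e-12)
  ## pdi = 2 (U = 1), Z = 3: P = 2 * (1/4 + 2) / (2 * 9) = 1/4
  expect_equal(poly_gauss_coil_intensity(sqrt(3) / 10, 1, 1, 10, pdi = 2, 0),
               0.25, tolerance = 1e-12)
  ## Z -> 0: P -> 1
  expect_equal(poly_gauss_coil_intensity(1e-9, 2, 3, 10, 1.5, 0.5),
               6.5, tolerance = 1e-9)
  expect_error(poly_gauss_coil_intensity(0.1, 1, 1, 10, pdi = 0.5),
               class = "autosas_domain_error")
})

test_that("the coil model approaches the Debye form as pdi -> 1", {
  rg <- 10
  Z <- 10^seq(-3, 3, length.out = 200)
  q <- sqrt(Z) / rg
  near <- poly_gauss_coil_intensity(q, 1, 1, rg, pdi = 1 + 1e-9, 0)
  debye <- 2 * (exp(-Z) + Z - 1) / Z^2
  debye[Z < 1e-4] <- 1 - Z[Z < 1e-4] / 3
  expect_lt(max(abs(near - debye) / debye), 1e-6)
})

test_that("the mixed model is the exact linear composition of its parts", {
  q <- q_grid(n = 60)
  coil <- list(i_zero = 2, rg = 70, pdi = 1.2)
  sph <- list(radius = 45, sld = DRHO, sld_solvent = 0, pd_width = 0.12)
  ic <- poly_gauss_coil_intensity(q, 1, coil$i_zero, coil$rg, coil$pdi, 0)
  is <- sphere_intensity(q, 1, sph$radius, sph$sld, 0, 0, sph$pd_width)
  expect_equal(mixed_intensity(q, 1, 1, coil, sph, background = 0.1),
               ic + is + 0.1, tolerance = 1e-12)
  ## degeneracy to either component
  expect_equal(mixed_intensity(q, 2.5, 0, coil, sph, 0.01),
               poly_gauss_coil_intensity(q, 2.5, coil$i_zero, coil$rg,
                                         coil$pdi, 0.01),
               tolerance = 1e-12)
  expect_equal(mixed_intensity(q, 0, 3, coil, sph, 0.01),
               sphere_intensity(q, 3, sph$radius, sph$sld, 0, 0.01,
                                sph$pd_width),
               tolerance = 1e-12)
})

test_that("smearing is exact for dq = 0 and for constant models", {
  q <- q_grid(n = 40)
  model <- function(qq) guinier_intensity(qq, 10, 30, 0.01)
  expect_identical(smear_curve(model, q, 0), model(q))
  expect_equal(smear_curve(function(qq) rep(7, length(qq)), q, 0.05 * q),
               rep(7, length(q)), tolerance = 1e-12)
  expect_error(smear_curve(model, q, 0.05 * q, n_nodes = 4L),
               class = "autosas_config_error")
  expect_error(smear_curve(model, q, -0.01), class = "autosas_domain_error")
})

test_that("smearing matches a dense trapezoid convolution oracle", {
  q <- q_grid(0.01, 0.4, 60)
  dq <- 0.05 * q
  model <- function(qq) sphere_intensity(qq, 1, 45, DRHO, 0, 1e-4)
  smeared <- smear_curve(model, q, dq)
  ## oracle: 1e4-point trapezoid over +-3 sigma of the Gaussian kernel
  oracle <- vapply(seq_along(q), function(i) {
    x <- seq(-3, 3, length.out = 1e4)
    w <- dnorm(x)
    qp <- q[i] + x * dq[i]
    keep <- qp > 0
    sum(w[keep] * model(qp[keep])) / sum(w[keep])
  }, 0)
  expect_lt(max(abs(smeared - oracle) / oracle), 1e-3)
  ## oscillation minima are filled in (strictly shallower than unsmeared)
  unsm <- model(q)
  i_min <- which.min(unsm)
  expect_gt(smeared[i_min], unsm[i_min])
})

test_that("evaluate_model windows the curve and applies smearing", {
  cv <- noiseless_curve("poly_gauss_coil", truth_coil(), q = q_grid(n = 80),
                        dq_frac = 0.02)
  spec <- default_model_pool()$poly_gauss_coil
  full <- evaluate_model(spec, vapply(spec$params, `[[`, 0, "init"), cv)
  expect_identical(full$indices, seq_along(cv$q))

  spec2 <- spec; spec2$q_min <- 0.01; spec2$q_max <- 0.1
  win <- evaluate_model(spec2, vapply(spec$params, `[[`, 0, "init"), cv)
  expect_identical(win$indices, which(cv$q >= 0.01 & cv$q <= 0.1))
  expect_length(win$intensity, length(win$indices))

  spec3 <- spec; spec3$q_min <- 0.5; spec3$q_max <- 0.9
  expect_error(evaluate_model(spec3, vapply(spec$params, `[[`, 0, "init"), cv),
               class = "autosas_insufficient_data_error")
})

test_that("a low-q Guinier fit of a monodisperse sphere recovers Rg/r = sqrt(3/5)", {
  r <- 45
  rg_true <- sqrt(3 / 5) * r
  cv <- noiseless_curve("sphere",
                        c(scale = 5, radius = r, sld = DRHO, sld_solvent = 0,
                          background = 0, pd_width = 0),
                        q = q_grid(0.005, 0.4, 200), dq_frac = 0)
  ## conservative Guinier window (q*Rg <= 0.9, inside the < 1.0 restriction)
  gsp <- guinier_model_spec(q_min = 0.005, q_max = 0.9 / rg_true)
  gsp$params$background <- param_spec("background", 0, 0, 0, fixed = TRUE)
  fit <- fit_sas(gsp, cv, fit_settings(seed = 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["rg"]] / r - sqrt(3 / 5)) / sqrt(3 / 5), 0.01)
})

test_that("mid-q slopes separate coil-like and sphere-like scattering", {
  ## window 0.03-0.11 1/Ang; noiseless presets
  q <- exp(seq(log(0.03), log(0.11), length.out = 40))
  coil <- poly_gauss_coil_intensity(q, 1, 5, 70, 1.2, 0)
  s_coil <- coef(lm(log(coil) ~ log(q)))[[2]]
  expect_gt(s_coil, -2.3)
  expect_lt(s_coil, -1.7)
  sph <- smear_curve(function(qq)
    sphere_intensity(qq, 5, 45, DRHO, 0, 0, 0.12), q, 0.02 * q)
  s_sph <- coef(lm(log(sph) ~ log(q)))[[2]]
  expect_lt(s_sph, -3)
})

test_that("intensities are finite and bounded below by the background", {
  q <- q_grid(n = 100)
  cases <- list(
    guinier_intensity(q, 2, 30, 0.05),
    sphere_intensity(q, 1, 45, DRHO, 0, 0.05, 0.12),
    poly_gauss_coil_intensity(q, 1, 5, 70, 1.3, 0.05),
    mixed_intensity(q, 1, 0.5, list(i_zero = 1, rg = 70, pdi = 1.2),
                    list(radius = 45, sld = DRHO, sld_solvent = 0,
                         pd_width = 0.12), 0.05))
  for (I in cases) {
    expect_true(all(is.finite(I)))
    expect_true(all(I >= 0.05))
  }
})
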