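test_that("lowest-chi2 selection takes the argmin with deterministic tie-breaks", {
  fits <- list(coil = stub_fit("coil", 30, n = 10, k = 3),
               sphere = stub_fit("sphere", 12, n = 10, k = 4),
               mixed = stub_fit("mixed", 11, n = 10, k = 7))
  expect_identical(select_lowest_chi2(fits)$best, "mixed")
  ## exact tie: fewer varied parameters wins
  tie <- list(A = stub_fit("A", 10, n = 10, k = 3),
              B = stub_fit("B", 10, n = 10, k = 5))
  expect_identical(select_lowest_chi2(tie)$best, "A")
  ## equal chi2 and k: lexicographic
  tie2 <- list(zeta = stub_fit("zeta", 10, k = 3),
               alpha = stub_fit("alpha", 10, k = 3))
  expect_identical(select_lowest_chi2(tie2)$best, "alpha")
  ## single model
  expect_identical(select_lowest_chi2(fits["coil"])$best, "coil")
  ## no converged fit gates to NONE_OF_THE_ABOVE
  none <- select_lowest_chi2(list(A = stub_fit("A", 5, converged = FALSE)))
  expect_identical(none$best, "NONE_OF_THE_ABOVE")
  expect_true(none$gated)
})

test_that("the Occam window prefers the simplest comparable model", {
  st <- selection_settings("occam", occam_delta = 1)
  ## delta = 0.7 < 1: simpler coil wins despite higher chi2
  fits <- list(coil = stub_fit("coil", 22, n = 10, k = 3),
               mixed = stub_fit("mixed", 15, n = 10, k = 7))
  expect_identical(select_occam(fits, st)$best, "coil")
  ## delta = 1.2 >= 1: the better-fitting mixed model wins
  fits2 <- list(coil = stub_fit("coil", 22, n = 10, k = 3),
                mixed = stub_fit("mixed", 10, n = 10, k = 7))
  expect_identical(select_occam(fits2, st)$best, "mixed")
  ## all equal: lexicographic, deterministic
  eq <- list(b = stub_fit("b", 10, k = 3), a = stub_fit("a", 10, k = 3))
  expect_identical(select_occam(eq, st)$best, "a")
})

test_that("AIC is chi2_total + 2k and drives argmin selection", {
  expect_equal(aic_score(stub_fit("m", 10, k = 3)), 16)
  expect_equal(aic_score(stub_fit("m", 10, k = 0)), 10)
  ## equal chi2: k = 3 has AIC lower by 8 than k = 7
  expect_equal(aic_score(stub_fit("m", 10, k = 7)) -
                 aic_score(stub_fit("m", 10, k = 3)), 8)
  fits <- list(A = stub_fit("A", 10, k = 3), B = stub_fit("B", 6, k = 4))
  expect_identical(select_aic(fits)$best, "B")
  ## AIC tie: smaller k wins
  tie <- list(A = stub_fit("A", 10, k = 3), B = stub_fit("B", 8, k = 4))
  expect_identical(select_aic(tie)$best, "A")
  expect_identical(select_aic(fits["A"])$best, "A")
  ## non-converged fits are excluded
  expect_error(aic_score(stub_fit("m", 10, converged = FALSE)),
               class = "autosas_domain_error")
})

test_that("Laplace log-evidence matches its closed form on the Gaussian case", {
  ## one datum y = 0 with sigma = 1, constant model, prior width 20:
  ## ln Z = 0.5 * ln(2*pi) - ln(20)
  fit <- stub_fit("m", chi2_total = 0, n = 1, k = 1,
                  covariance = matrix(1), bounds_width = 20)
  lz <- laplace_log_evidence(fit)
  expect_equal(lz, 0.5 * log(2 * pi) - log(20), tolerance = 1e-12)
  expect_equal(lz, -2.0768, tolerance = 1e-4)
  ## exact quadrature of the Gaussian likelihood over the prior
  quad <- integrate(function(th) exp(-th^2 / 2) / 20, -10, 10,
                    rel.tol = 1e-12)$value
  expect_equal(lz, log(quad), tolerance = 1e-6)
  ## k = 0: ln Z = -chi2/2
  expect_equal(laplace_log_evidence(stub_fit("m", 6, k = 0)), -3)
  ## halving every prior width raises ln Z by k * ln 2
  fit2 <- stub_fit("m", 4, n = 5, k = 2, covariance = diag(c(0.5, 2)))
  expect_equal(laplace_log_evidence(fit2, prior_widths = c(p1 = 5, p2 = 5)) -
                 laplace_log_evidence(fit2, prior_widths = c(p1 = 10, p2 = 10)),
               2 * log(2), tolerance = 1e-12)
})

test_that("Laplace evidence agrees with direct quadrature on linear toys", {
  ## 1-parameter linear model y = theta * x, weighted least squares
  x <- c(-1, 0.5, 1, 2); y <- c(-0.8, 0.6, 1.1, 1.7); sigma <- 0.5
  J <- x / sigma
  theta_hat <- sum(y * x / sigma^2) / sum(x^2 / sigma^2)
  chi2 <- sum(((y - theta_hat * x) / sigma)^2)
  C <- matrix(1 / sum(J^2))
  w <- 8
  fit1 <- stub_fit("lin1", chi2, n = 4, k = 1, covariance = C,
                   bounds_width = w)
  quad1 <- integrate(function(th)
    vapply(th, function(t) exp(-sum(((y - t * x) / sigma)^2) / 2) / w, 0),
    -w / 2, w / 2, rel.tol = 1e-10)$value
  expect_lt(abs(laplace_log_evidence(fit1) - log(quad1)), 0.1)

  ## 2-parameter linear model y = a + b x
  X <- cbind(1, x) / sigma
  beta <- solve(crossprod(X), crossprod(X, y / sigma))
  resid <- y / sigma - X %*% beta
  chi2b <- sum(resid^2)
  Cb <- solve(crossprod(X))
  fit2 <- stub_fit("lin2", chi2b, n = 4, k = 2, covariance = Cb,
                   bounds_width = w)
  gr <- seq(-w / 2, w / 2, length.out = 400)
  h <- diff(gr)[1]
  ll <- outer(gr + beta[1], gr + beta[2], Vectorize(function(a, b)
    exp(-sum(((y - a - b * x) / sigma)^2) / 2)))
  quad2 <- sum(ll) * h^2 / w^2
  expect_lt(abs(laplace_log_evidence(fit2) - log(quad2)), 0.1)
})

test_that("model probabilities are a stabilized softmax of the evidence", {
  ## stubs with prior width sqrt(2*pi) and unit covariance have
  ## ln Z = -chi2_total / 2, so chi2 = -2 * lz carries the target evidence
  mk <- function(id, lz) {
    stub_fit(id, chi2_total = -2 * lz, n = 3, k = 1,
             covariance = matrix(1), bounds_width = sqrt(2 * pi))
  }
  ## two equal evidences -> 1/2 each
  p2 <- model_probabilities(list(A = mk("A", -1), B = mk("B", -1)))
  expect_equal(unname(p2), c(0.5, 0.5), tolerance = 1e-9)
  ## softmax of (0, -1, -2)
  p3 <- model_probabilities(list(A = mk("A", 0), B = mk("B", -1),
                                 C = mk("C", -2)))
  expect_equal(unname(p3), c(0.66524, 0.24473, 0.09003), tolerance = 1e-5)
  expect_equal(sum(p3), 1, tolerance = 1e-9)
  ## extreme differences do not overflow
  px <- model_probabilities(list(A = mk("A", 0), B = mk("B", -500)))
  expect_equal(unname(px[1]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(px)))
  ## invariance to a constant shift of all ln Z
  ps <- model_probabilities(list(A = mk("A", -10), B = mk("B", -11),
                                 C = mk("C", -12)))
  expect_equal(unname(ps), unname(p3), tolerance = 1e-6)
  ## argmax selection mirrors the probabilities
  sel <- select_most_probable(list(A = mk("A", 0), B = mk("B", -1),
                                   C = mk("C", -2)))
  expect_identical(sel$best, "A")
  expect_equal(sum(sel$probabilities), 1, tolerance = 1e-9)
})

test_that("the goodness-of-fit gate replaces bad winners with NONE_OF_THE_ABOVE", {
  st <- selection_settings("chi2", gof_threshold = 10)
  ok <- list(m = stub_fit("m", 12, n = 10, k = 2))     # chi2_red = 1.2
  sel <- apply_gof_gate(select_lowest_chi2(ok, st), ok, st)
  expect_identical(sel$best, "m")
  expect_false(sel$gated)
  bad <- list(m = stub_fit("m", 500, n = 10, k = 2))   # chi2_red = 50
  sel2 <- apply_gof_gate(select_lowest_chi2(bad, st), bad, st)
  expect_identical(sel2$best, "NONE_OF_THE_ABOVE")
  expect_true(sel2$gated)
  ## threshold exactly equal: not gated (strict >)
  edge <- list(m = stub_fit("m", 100, n = 10, k = 2))  # chi2_red = 10
  sel3 <- apply_gof_gate(select_lowest_chi2(edge, st), edge, st)
  expect_identical(sel3$best, "m")
  expect_false(sel3$gated)
})

test_that("AIC and Occam selections are invariant to intensity rescaling", {
  cv <- simulate_sas_curve("mixed", truth_mixed(), q = q_grid(n = 80),
                           noise = noise_model(0.02), seed = 31,
                           sample_id = "scale1")$curve
  cv10 <- sas_curve("scale10", cv$q, 10 * cv$intensity, 10 * cv$d_intensity,
                    d_q = cv$d_q)
  pool <- default_model_pool(n_restarts_multimodal = 1L)
  st <- fit_settings(seed = 4)
  ## rescale scale-bearing inits/bounds so both datasets are in-range;
  ## the weighted residuals (hence chi2 and selection) are scale-free
  pool10 <- pool
  for (m in names(pool10)) for (p in c("i_zero", "scale", "scale_a", "scale_b"))
    if (p %in% names(pool10[[m]]$params) && !pool10[[m]]$params[[p]]$fixed) {
      pool10[[m]]$params[[p]]$init <- pool10[[m]]$params[[p]]$init * 10
      pool10[[m]]$params[[p]]$upper <- pool10[[m]]$params[[p]]$upper * 10
      pool10[[m]]$params[[p]]$lower <- pool10[[m]]$params[[p]]$lower * 10
    }
  fits1 <- fit_sas_pool(pool, list(cv), st)[[1]]
  fits10 <- fit_sas_pool(pool10, list(cv10), st)[[1]]
  for (cr in c("aic", "occam")) {
    s1 <- select_model(fits1, selection_settings(cr))
    s10 <- select_model(fits10, selection_settings(cr))
    expect_identical(s10$best, s1$best)
  }
  expect_equal(fits10$mixed$chi2_total, fits1$mixed$chi2_total,
               tolerance = 1e-3)
})
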