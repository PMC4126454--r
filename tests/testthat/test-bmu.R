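test_that("paracrine exponents follow the stimulus response and its limits", {
  p <- bmu_params("trabecular")
  g0 <- paracrine_exponents(0, p)
  expect_equal(g0$g12, 1.11)
  expect_equal(g0$g21, -1.00)
  # strong overload: exponential term vanishes
  ginf <- paracrine_exponents(50, p)
  expect_equal(ginf$g12, p$A1, tolerance = 1e-8)
  expect_equal(ginf$g21, p$A2, tolerance = 1e-8)
  # stimulus-independent limit
  pflat <- bmu_params("trabecular", B1 = 0, B2 = 0)
  for (S in c(-0.3, 0, 2)) {
    g <- paracrine_exponents(S, pflat)
    expect_equal(c(g$g12, g$g21), c(pflat$A1, pflat$A2))
  }
  # clamping under strongly negative stimulus
  gneg <- paracrine_exponents(-5, p)
  expect_equal(gneg$g21, p$g_clamp)
  expect_equal(gneg$g12, -p$g_clamp)
  expect_error(paracrine_exponents(NaN, p), "non-finite")
})

test_that("steady-state cells solve both nullclines (printed and default sets)", {
  for (p in list(bmu_params_printed(), bmu_params("trabecular"))) {
    g <- paracrine_exponents(0, p)
    ss <- steady_state_cells(g, p)
    r <- cell_population_rates(ss$xC_bar, ss$xB_bar, g, p)
    expect_lt(abs(r$dxC) / (p$beta1 * ss$xC_bar), 1e-10)
    expect_lt(abs(r$dxB) / (p$beta2 * ss$xB_bar), 1e-10)
  }
  # frozen values for the printed trabecular block at S = 0
  ssp <- steady_state_cells(paracrine_exponents(0, bmu_params_printed()),
                            bmu_params_printed())
  expect_equal(ssp$xC_bar, 0.0910897, tolerance = 1e-6)
  expect_equal(ssp$xB_bar, 164.6728, tolerance = 1e-6)
  # degenerate coupling rejected
  pdeg <- bmu_params("trabecular", B1 = 0, B2 = 0, A1 = 1, A2 = 1)
  expect_error(steady_state_cells(paracrine_exponents(0, pdeg), pdeg),
               "degenerate")
})

test_that("fixed point zeroes the rates for randomized parameter sets", {
  set.seed(42)
  p0 <- bmu_params("trabecular")
  for (i in 1:25) {
    mult <- stats::runif(6, 0.5, 1.5)
    p <- bmu_params("trabecular",
                    alpha1 = p0$alpha1 * mult[1], beta1 = p0$beta1 * mult[2],
                    alpha2 = p0$alpha2 * mult[3], beta2 = p0$beta2 * mult[4],
                    A1 = p0$A1 * mult[5], A2 = p0$A2 * mult[6])
    g <- paracrine_exponents(stats::runif(1, -0.01, 0.01), p)
    gamma_exp <- g$g12 * g$g21 - 1
    if (abs(gamma_exp) < 1e-6) next
    ss <- steady_state_cells(g, p)
    r <- cell_population_rates(ss$xC_bar, ss$xB_bar, g, p)
    expect_lt(abs(r$dxC) / (p$beta1 * ss$xC_bar + 1e-300), 1e-8)
    expect_lt(abs(r$dxB) / (p$beta2 * ss$xB_bar + 1e-300), 1e-8)
  }
})

test_that("steady state agrees with brute-force 2D nullcline root finding", {
  p <- bmu_params("trabecular")
  g <- paracrine_exponents(0, p)
  ss <- steady_state_cells(g, p)
  # independent route: solve the scalar fixed-point equation for xC on a
  # bracketing interval, then back out xB from the osteoblast nullcline
  fx <- function(xC) {
    xB <- (p$alpha2 / p$beta2) * xC^g$g12
    p$alpha1 * xB^g$g21 - p$beta1 * xC
  }
  root <- stats::uniroot(fx, c(1e-4, 1e3), tol = 1e-14)$root
  expect_equal(ss$xC_bar, root, tolerance = 1e-9)
  expect_equal(ss$xB_bar, (p$alpha2 / p$beta2) * root^g$g12, tolerance = 1e-9)
})

test_that("active cell counts threshold at the steady state", {
  a <- active_cell_counts(0.0910897, 1, 0.0910897, 164.6728)
  expect_equal(a$XC, 0)
  expect_equal(a$XB, 0)
  a2 <- active_cell_counts(15, 1, 0.0910897, 164.6728)
  expect_equal(a2$XC, 14.9089103)
  expect_equal(a2$XB, 0)
})

test_that("population rates match hand evaluation and decay limits", {
  p <- bmu_params_printed()
  g <- paracrine_exponents(0, p)
  # the printed initial state sits on the osteoclast nullcline
  r <- cell_population_rates(15, 1, g, p)
  expect_equal(r$dxC, 3 * 1^-1 - 0.2 * 15)
  expect_equal(r$dxC, 0)
  p0 <- bmu_params("trabecular", alpha1 = 1e-300, alpha2 = 1e-300)
  r0 <- cell_population_rates(2, 3, paracrine_exponents(0, p0), p0)
  expect_equal(r0$dxC, -p0$beta1 * 2, tolerance = 1e-12)
  expect_equal(r0$dxB, -p0$beta2 * 3, tolerance = 1e-12)
  expect_error(cell_population_rates(-1, 1, g, p), "positive")
})

test_that("daily stepping matches the adaptive oracle", {
  skip_if_not_installed("deSolve")
  # one day, printed parameter block at S = 0: density decrement vs oracle
  p <- bmu_params_printed()
  st <- step_bmu_day(list(xC = p$xC0, xB = p$xB0, rho_hat = 1), 0, p)
  oracle <- integrate_bmu_oracle(p, 0, c(0, 1))
  expect_equal(1 - st$rho_hat, 1 - oracle$rho[2], tolerance = 0.05)
  expect_gt(1 - st$rho_hat, 0.025)   # a few percent resorbed on day one
  # 100 days, default parameter set, three stimulus levels, cells to 1e-3
  pd <- bmu_params("trabecular")
  for (S in c(-0.01, 0, 0.01)) {
    oracle <- integrate_bmu_oracle(pd, S, 0:100)
    st <- list(xC = pd$xC0, xB = pd$xB0, rho_hat = 1)
    for (d in 1:100) st <- step_bmu_day(st, S, pd, substeps = 24)
    expect_equal(st$xC, oracle$xC[101], tolerance = 1e-3)
    expect_equal(st$xB, oracle$xB[101], tolerance = 1e-3)
  }
})

test_that("stepping respects decoupling, steady starts and activity monotonicity", {
  p <- bmu_params("trabecular")
  # k1 = k2 = 0: density exactly frozen while cells evolve
  p00 <- bmu_params("trabecular", k1 = 0, k2 = 0)
  st <- step_bmu_day(list(xC = 15, xB = 1, rho_hat = 1), 0, p00)
  expect_identical(st$rho_hat, 1)
  expect_false(st$xC == 15 && st$xB == 1)
  # starting at the steady state: no active cells, density unchanged
  ss <- steady_state_cells(paracrine_exponents(0, p), p)
  st2 <- step_bmu_day(list(xC = ss$xC_bar, xB = ss$xB_bar, rho_hat = 1), 0, p)
  expect_equal(st2$rho_hat, 1, tolerance = 1e-12)
  # higher k2 never lowers density; higher k1 never raises it
  run_k <- function(k1, k2) {
    pk <- bmu_params("trabecular", k1 = k1, k2 = k2)
    st <- list(xC = pk$xC0, xB = pk$xB0, rho_hat = 1)
    for (d in 1:60) st <- step_bmu_day(st, 0, pk)
    st$rho_hat
  }
  base <- run_k(0.24, 0.0017)
  expect_gte(run_k(0.24, 0.0017 * 2), base)
  expect_lte(run_k(0.24 * 2, 0.0017), base)
})

test_that("positivity floor and density clamps hold under +/-50% perturbations", {
  set.seed(7)
  p0 <- bmu_params("trabecular")
  for (i in 1:20) {
    m <- stats::runif(8, 0.5, 1.5)
    p <- bmu_params("trabecular",
                    alpha1 = 3 * m[1], beta1 = 0.2 * m[2],
                    alpha2 = 4 * m[3], beta2 = 0.02 * m[4],
                    k1 = 0.24 * m[5], k2 = 0.0017 * m[6],
                    gamma1 = 16.67 * m[7], gamma2 = 33.37 * m[8])
    st <- list(xC = p$xC0, xB = p$xB0, rho_hat = 1)
    for (d in 1:30) {
      st <- step_bmu_day(st, stats::runif(1, -0.005, 0.005), p)
      expect_true(all(st$xC >= p$xmin), info = sprintf("perturbation %d", i))
      expect_true(all(st$xB >= p$xmin))
      expect_true(st$rho_hat >= 0.01 && st$rho_hat <= 1.74 / 0.764 + 1e-12)
    }
  }
})

test_that("site simulation is vectorization-consistent with scalar stepping", {
  p <- bmu_params("trabecular")
  tr <- simulate_bmu_site(p, days = 10, S = 0.001)
  st <- list(xC = rep(p$xC0, 3), xB = rep(p$xB0, 3), rho_hat = rep(1, 3))
  for (d in 1:10) st <- step_bmu_day(st, rep(0.001, 3), p)
  expect_equal(rep(tr$rho_hat[11], 3), st$rho_hat)
  expect_equal(rep(tr$xC[11], 3), st$xC)
})
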