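test_that("a zero-force schedule produces net resorption on day one", {
  cfg <- coarse_config(days = 1, schedule = "disuse")
  fit <- run_remodeling(cfg)
  h <- fit$history
  # no load: local energy density zero, sensed stimulus negative
  expect_true(all(fit$state$Sk == 0))
  expect_true(all(fit$state$S < 0))
  expect_lt(h$roi_density[nrow(h)], h$roi_density[1])
})

test_that("k1 = k2 = 0 freezes the density field exactly", {
  cfg <- coarse_config(days = 8,
                       trabecular = bmu_params("trabecular", k1 = 0, k2 = 0),
                       cortical = bmu_params("cortical", k1 = 0, k2 = 0))
  fit <- run_remodeling(cfg)
  expect_identical(fit$state$rho_hat, rep(1, nrow(fit$mesh$elements)))
  expect_false(all(fit$state$xB == 1))   # cells still evolve
})

test_that("identical configurations give bit-identical runs", {
  cfg <- coarse_config(days = 6)
  f1 <- run_remodeling(cfg)
  f2 <- run_remodeling(cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$state, f2$state)
})

test_that("a zero-day run returns the initial condition", {
  cfg <- coarse_config(days = 0)
  fit <- run_remodeling(cfg)
  expect_equal(nrow(fit$history), 1)
  expect_identical(fit$history$day, 0)
  expect_true(all(fit$state$rho_hat == 1))
})

test_that("checkpoint restart reproduces the uninterrupted run exactly", {
  ck <- withr::local_tempfile(fileext = ".rds")
  cfg <- coarse_config(days = 10)
  cfg$checkpoint <- ck
  cfg$checkpoint_every <- 5L
  full <- run_remodeling(cfg)
  # rewind: run only 5 days to regenerate the mid-run checkpoint
  cfg5 <- cfg; cfg5$days <- 5L
  run_remodeling(cfg5)
  resumed <- run_remodeling(cfg, resume = ck)
  expect_identical(resumed$state, full$state)
})

test_that("ROI density is the area-weighted mean", {
  m <- synthetic_femur_mesh(femur_geometry(elem_size = 5))
  rho <- rep(0.9, nrow(m$elements))
  expect_equal(roi_density(rho, m), 0.9)
  # two-element toy mesh with areas 1 and 3
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                 c(4, 0), c(4, 1))
  el <- rbind(c(1, 2, 3, 4), c(2, 5, 6, 3))
  m2 <- mesh2d(nodes, el, c("trabecular", "trabecular"), roi = c(TRUE, TRUE),
               sets = list(distal = c(1L, 4L)))
  expect_equal(roi_density(c(1, 0.5), m2), (1 * 1 + 0.5 * 3) / 4)
  expect_equal(roi_density(c(0.5, 1), m2, roi = c(TRUE, FALSE)), 0.5)
  expect_error(roi_density(c(1, 1), m2, roi = c(FALSE, FALSE)), "empty ROI")
})

test_that("homeostatic start leaves the density field untouched", {
  # cells at their zero-stimulus steady state, setpoints accommodated to
  # the experienced energy: nothing should move
  cfg <- coarse_config(days = 5, schedule = "disuse", init_cells = "steady",
                       stimulus = stimulus_params(Sk0 = 1e-12))
  fit <- run_remodeling(cfg)
  expect_equal(fit$state$rho_hat, rep(1, nrow(fit$mesh$elements)),
               tolerance = 1e-8 * 5)
})

test_that("setpoint calibration pins the median element energy", {
  cfg <- coarse_config(days = 1, calibrate_setpoint = TRUE)
  fit <- run_remodeling(cfg)
  expect_equal(fit$stimulus$Sk0, stats::median(fit$state$Sk), tolerance = 0.2)
  expect_false(isTRUE(all.equal(fit$stimulus$Sk0, 0.0025)))
})

test_that("history bookkeeping respects the recording cadence", {
  cfg <- coarse_config(days = 10)
  cfg$record_every <- 3L
  fit <- run_remodeling(cfg)
  expect_equal(fit$history$day, c(0, 3, 6, 9, 10))
  expect_true(all(diff(fit$history$day) > 0))
})

test_that("configuration validation catches bad inputs", {
  expect_error(simulation_config(schedule = "WALK"), "unknown schedule")
  expect_error(simulation_config(substeps = 0), "substeps")
  expect_error(simulation_config(nu = 0.7), "Poisson")
  cfg <- simulation_config()
  expect_s3_class(cfg, "simulation_config")
  expect_output(print(cfg), "Remodeling simulation configuration")
})

test_that("YAML configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yml")
  cfg <- simulation_config(days = 42, nu = 0.28,
                           trabecular = bmu_params("trabecular", k1 = 0.3),
                           stimulus = stimulus_params(Sk0 = 0.004))
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$days, 42L)
  expect_equal(cfg2$nu, 0.28)
  expect_equal(cfg2$trabecular$k1, 0.3)
  expect_equal(cfg2$stimulus$Sk0, 0.004)
  expect_equal(cfg2$cortical$k2, cfg$cortical$k2)
})

test_that("sensitivity analysis is order-invariant and flags failed runs", {
  cfg <- coarse_config(days = 20)
  sa1 <- sensitivity_analysis(cfg, factors = c("k1", "mu"))
  sa2 <- sensitivity_analysis(cfg, factors = c("mu", "k1"))
  for (f in c("k1", "mu")) for (d in c("-50%", "+50%")) {
    expect_equal(sa1$roi_density[sa1$factor == f & sa1$direction == d],
                 sa2$roi_density[sa2$factor == f & sa2$direction == d])
  }
  expect_true(all(sa1$status == "ok"))
  # alpha0 + 50% violates alpha0 <= alpha_max: recorded, not fatal
  sa3 <- sensitivity_analysis(cfg, factors = "alpha0")
  expect_identical(sa3$status, c("ok", "failed"))
  expect_true(is.na(sa3$pct_change[2]))
})

test_that("simulation summaries and plots are well formed", {
  cfg <- coarse_config(days = 4)
  fit <- run_remodeling(cfg)
  expect_output(print(fit), "ROI density")
  s <- summary(fit)
  expect_s3_class(s, "summary.bone_remodeling")
  expect_output(print(s), "region means")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, type = "map"))
  expect_silent(plot(fit, type = "history"))
})
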