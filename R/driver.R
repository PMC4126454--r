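#' Run a bone remodeling simulation
#'
#' Executes the daily remodeling loop over the configured duration. Each
#' day, in fixed order: (1) the element moduli are updated from density,
#' mineralization and damage and each gait load case is solved statically;
#' (2) fatigue damage is accumulated per case from the element principal
#' strain amplitudes and daily cycle counts; (3) the cycle-weighted
#' strain-damage energy density is formed, damage shutdown applied,
#' setpoints accommodated and the net osteocyte stimulus computed; (4) the
#' BMU cell populations and the site density are advanced; (5) fatigue
#' damage is repaired in proportion to newly formed mass; (6) the ash
#' fraction and porosity are updated. Loads within a day are held static;
#' the daily unloading to zero force matters only through cycle counting.
#'
#' @param config a [simulation_config()].
#' @param resume optional path to a checkpoint written by a previous run
#'   of the same configuration; the simulation continues from it.
#' @param verbose print progress every 100 days.
#' @return An object of class `bone_remodeling`: the final per-element
#'   state, the daily history, the mesh and the resolved configuration.
#' @examples
#' cfg <- simulation_config(geometry = femur_geometry(elem_size = 6),
#'                          days = 5, record_every = 1)
#' fit <- run_remodeling(cfg)
#' fit
#' @export
run_remodeling <- function(config, resume = NULL, verbose = FALSE) {
  validate_config(config)
  mesh <- config$mesh
  if (is.null(mesh)) {
    g <- config$geometry
    g$seed <- config$seed
    mesh <- synthetic_femur_mesh(g, thickness = config$thickness)
  }
  schedule <- if (is.character(config$schedule)) load_schedule(config$schedule)
  else config$schedule
  setup <- fem_setup(mesh, config$nu)
  ne <- nrow(mesh$elements)
  cort <- mesh$region == "cortical"
  if (any(mesh$roi) == FALSE) stop("mesh has an empty ROI", call. = FALSE)

  bmu <- list(trabecular = config$trabecular, cortical = config$cortical)
  mat <- list(trabecular = config$mat_trabecular, cortical = config$mat_cortical)
  rho0 <- ifelse(cort, mat$cortical$rho0, mat$trabecular$rho0)
  Cc <- ifelse(cort, mat$cortical$C, mat$trabecular$C)
  p_exp <- ifelse(cort, mat$cortical$p_exp, mat$trabecular$p_exp)
  q_exp <- ifelse(cort, mat$cortical$q_exp, mat$trabecular$q_exp)
  E_min <- ifelse(cort, mat$cortical$E_min, mat$trabecular$E_min)
  D_crit <- ifelse(cort, mat$cortical$D_crit, mat$trabecular$D_crit)
  clamp_lo <- ifelse(cort, mat$cortical$rho_hat_min, mat$trabecular$rho_hat_min)
  clamp_hi <- ifelse(cort, mat$cortical$rho_max, mat$trabecular$rho_max) / rho0

  sp <- config$stimulus
  W <- influence_matrix(setup$centroid, sp)
  cycles <- vapply(schedule, `[[`, 0, "cycles")
  wts <- if (sum(cycles) > 0) cycles / sum(cycles) else rep(0, length(schedule))
  zero_load <- all(vapply(schedule, function(l)
    l$head_force == 0 && l$abductor_force == 0, TRUE))

  state <- list(
    xC = ifelse(cort, bmu$cortical$xC0, bmu$trabecular$xC0),
    xB = ifelse(cort, bmu$cortical$xB0, bmu$trabecular$xB0),
    rho_hat = rep(1, ne),
    D = rep(0, ne), Neq_c = rep(0, ne), Neq_t = rep(0, ne),
    alpha = ifelse(cort, mat$cortical$alpha0, mat$trabecular$alpha0),
    porosity = rep(NA_real_, ne), E = rep(NA_real_, ne),
    Sk = rep(0, ne), Skbar = rep(sp$Sk0, ne), S = rep(0, ne))
  if (config$init_cells == "steady") {
    for (rg in c("trabecular", "cortical")) {
      sel <- if (rg == "cortical") cort else !cort
      ss <- steady_state_cells(paracrine_exponents(0, bmu[[rg]]), bmu[[rg]])
      state$xC[sel] <- ss$xC_bar
      state$xB[sel] <- ss$xB_bar
    }
  }
  day0 <- 0L
  if (!is.null(resume)) {
    ck <- readRDS(resume)
    state <- ck$state
    day0 <- ck$day
    sp <- ck$stimulus
  } else if (config$calibrate_setpoint && !zero_load) {
    E0 <- pmax(Cc * rho0^p_exp * state$alpha^q_exp, E_min)
    sol0 <- solve_load_case(mesh, E0, config$nu, schedule[[1]], setup)
    sp$Sk0 <- stats::median(sol0$sed)
  }

  nrec <- length(seq_day_records(day0, config$days, config$record_every))
  hist <- matrix(NA_real_, nrec, 14)
  colnames(hist) <- c("day", "rho_cort_mean", "rho_cort_min", "rho_cort_max",
                      "rho_trab_mean", "rho_trab_min", "rho_trab_max",
                      "roi_density", "damage_mean", "stimulus_mean",
                      "xC_mean", "xB_mean", "sed_mean", "E_mean")
  irec <- 0L
  record <- function(day) {
    rho <- state$rho_hat * rho0
    irec <<- irec + 1L
    hist[irec, ] <<- c(day,
                       mean(rho[cort]), min(rho[cort]), max(rho[cort]),
                       mean(rho[!cort]), min(rho[!cort]), max(rho[!cort]),
                       sum(rho[mesh$roi] * setup$area[mesh$roi]) /
                         sum(setup$area[mesh$roi]),
                       mean(state$D), mean(state$S),
                       mean(state$xC), mean(state$xB),
                       mean(state$Sk), if (all(is.na(state$E))) NA else mean(state$E))
  }
  if (day0 == 0L) record(0L)

  days <- config$days
  for (day in seq_len(days)) {
    if (day <= day0) next
    t <- day - 1L   # start-of-day simulation time, days

    ## (1) mechanics
    rho <- state$rho_hat * rho0
    E <- pmax(Cc * (1 - state$D) * rho^p_exp * state$alpha^q_exp, E_min)
    state$E <- E
    if (!zero_load) {
      K <- fem_assemble(setup, E)
      F <- vapply(schedule, function(l) load_vector(mesh, l),
                  numeric(setup$ndof))
      sol <- fem_solve(setup, K, F)
      # near-failed elements (E at the E_min floor under a load pad) can
      # stall iterative refinement around 1e-8; only a genuinely bad
      # solve aborts the run
      if (any(sol$residual > 1e-6))
        stop(sprintf("day %d: linear solve residual %.2g exceeds 1e-6",
                     day, max(sol$residual)), call. = FALSE)
      fields <- lapply(seq_along(schedule), function(i)
        recover_fields(setup, E, sol$u[, i]))
    } else {
      fields <- lapply(schedule, function(l)
        list(sed = rep(0, ne), delta_eps = rep(0, ne),
             mode = rep("tensile", ne)))
    }

    ## (2) fatigue damage accumulation
    for (i in seq_along(schedule)) {
      state[c("D", "Neq_c", "Neq_t")] <-
        accumulate_fatigue(state[c("D", "Neq_c", "Neq_t")],
                           fields[[i]]$delta_eps, fields[[i]]$mode,
                           cycles[i], mat$trabecular)[c("D", "Neq_c", "Neq_t")]
    }

    ## (3) stimulus
    Sk <- rep(0, ne)
    for (i in seq_along(schedule)) Sk <- Sk + wts[i] * fields[[i]]$sed
    if (config$damage_squared) Sk <- Sk * (1 - state$D)
    shutdown <- state$D >= D_crit
    Skbar <- if (config$accommodation) update_setpoint(Sk, t, sp)
    else rep(sp$Sk0, ne)
    S <- sensed_stimulus(Sk, Skbar, W, sp, shutdown)
    state$Sk <- Sk; state$Skbar <- Skbar; state$S <- S

    ## (4) cell dynamics and density
    rho_before <- state$rho_hat
    for (rg in c("trabecular", "cortical")) {
      sel <- if (rg == "cortical") cort else !cort
      if (!any(sel)) next
      sub <- step_bmu_day(list(xC = state$xC[sel], xB = state$xB[sel],
                               rho_hat = state$rho_hat[sel]),
                          S[sel], bmu[[rg]], config$substeps,
                          rho_clamp = c(clamp_lo[which(sel)[1]],
                                        clamp_hi[which(sel)[1]]),
                          label = paste(rg, "element"))
      state$xC[sel] <- sub$xC
      state$xB[sel] <- sub$xB
      state$rho_hat[sel] <- sub$rho_hat
    }

    ## (5) damage repair by formation
    formed <- pmax(state$rho_hat - rho_before, 0) / state$rho_hat
    state[c("D", "Neq_c", "Neq_t")] <-
      repair_damage(state[c("D", "Neq_c", "Neq_t")], formed)[
        c("D", "Neq_c", "Neq_t")]

    ## (6) mineralization and porosity
    state$alpha <- ifelse(cort, ash_fraction(day, mat$cortical),
                          ash_fraction(day, mat$trabecular))
    state$porosity <- bone_porosity(state$rho_hat * rho0, state$alpha)

    for (nm in c("xC", "xB", "rho_hat", "D", "alpha", "S"))
      if (any(!is.finite(state[[nm]])))
        stop(sprintf("day %d: non-finite %s at element %d", day, nm,
                     which(!is.finite(state[[nm]]))[1]), call. = FALSE)

    if (day %% config$record_every == 0L || day == days) record(day)
    if (!is.null(config$checkpoint) &&
        (day %% config$checkpoint_every == 0L || day == days))
      saveRDS(list(day = day, state = state, stimulus = sp), config$checkpoint)
    if (verbose && day %% 100L == 0L)
      message(sprintf("day %d / %d: ROI density %.3f g/cm^3",
                      day, days, hist[irec, "roi_density"]))
  }

  res <- structure(list(config = config, mesh = mesh, state = state,
                        history = as.data.frame(hist[seq_len(irec), , drop = FALSE]),
                        area = setup$area, rho0 = rho0,
                        stimulus = sp, days = days),
                   class = "bone_remodeling")
  res
}

seq_day_records <- function(day0, days, every) {
  d <- seq(0L, days, by = every)
  unique(c(d[d >= day0], days))
}

#' Region-of-interest mean density
#'
#' Area-weighted mean apparent density (g/cm^3) over the femoral-neck ROI
#' elements: `sum(rho * area) / sum(area)`.
#'
#' @param x a `bone_remodeling` result, or a numeric vector of per-element
#'   densities.
#' @param mesh required when `x` is a density vector.
#' @param roi optional logical selector (defaults to the mesh ROI flag).
#' @return Scalar density, g/cm^3.
#' @export
roi_density <- function(x, mesh = NULL, roi = NULL) {
  if (inherits(x, "bone_remodeling")) {
    rho <- x$state$rho_hat * x$rho0
    area <- x$area
    if (is.null(roi)) roi <- x$mesh$roi
  } else {
    if (is.null(mesh)) stop("mesh required for a bare density vector", call. = FALSE)
    rho <- x
    area <- element_areas(mesh)
    if (is.null(roi)) roi <- mesh$roi
  }
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  sum(rho[roi] * area[roi]) / sum(area[roi])
}

#' Element areas of a quadrilateral mesh
#'
#' @param mesh a [mesh2d()] object.
#' @return Numeric vector of element areas (mm^2) by the shoelace formula.
#' @export
element_areas <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$elements, 1], nrow(mesh$elements), 4)
  y <- matrix(mesh$nodes[mesh$elements, 2], nrow(mesh$elements), 4)
  0.5 * abs((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
              (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
              (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
              (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

#' One-factor-at-a-time sensitivity analysis
#'
#' Re-runs the remodeling simulation with each listed parameter scaled by
#' `1 - delta` and `1 + delta` (one factor per run, all others at their
#' reference values) and reports the relative change of the femoral-neck
#' ROI density against the unperturbed baseline. Parameters shared by the
#' cortical and trabecular blocks are perturbed in both simultaneously. A
#' perturbed run that fails validation or diverges is recorded as failed,
#' not fatal to the sweep.
#'
#' @param config a [simulation_config()]; for a desk-scale sweep pass a
#'   coarse mesh and a reduced duration.
#' @param factors character vector of factor names (see
#'   [sensitivity_factors()]); default is the full registry.
#' @param delta relative perturbation (default 0.5, i.e. +/-50%).
#' @param days optional duration override for all runs.
#' @param verbose print one line per run.
#' @return A data.frame of class `remodeling_sa` with columns `factor`,
#'   `direction`, `multiplier`, `roi_density`, `pct_change`, `status`, and
#'   the baseline ROI density as attribute `baseline`.
#' @export
sensitivity_analysis <- function(config, factors = sensitivity_factors(),
                                 delta = 0.5, days = NULL, verbose = FALSE) {
  if (!is.null(days)) config$days <- as.integer(days)
  base <- run_remodeling(config)
  rho_base <- roi_density(base)
  rows <- list()
  for (f in factors) for (mult in c(1 - delta, 1 + delta)) {
    dir <- sprintf("%+d%%", round(100 * (mult - 1)))
    cfg2 <- tryCatch(perturb_config(config, f, mult), error = function(e) e)
    val <- if (inherits(cfg2, "error")) cfg2 else
      tryCatch(roi_density(run_remodeling(cfg2)), error = function(e) e)
    ok <- !inherits(val, "error")
    rows[[length(rows) + 1L]] <- data.frame(
      factor = f, direction = dir, multiplier = mult,
      roi_density = if (ok) val else NA_real_,
      pct_change = if (ok) 100 * (val - rho_base) / rho_base else NA_real_,
      status = if (ok) "ok" else "failed")
    if (verbose)
      message(sprintf("SA %s %s: %s", f, dir,
                      if (ok) sprintf("%.4f g/cm^3 (%+.2f%%)", val,
                                      100 * (val - rho_base) / rho_base)
                      else conditionMessage(val)))
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- rho_base
  class(out) <- c("remodeling_sa", class(out))
  out
}

#' @rdname sensitivity_analysis
#' @export
sensitivity_factors <- function() {
  c("alpha1", "beta1", "alpha2", "beta2", "k1", "k2",
    "A1", "B1", "gamma1", "A2", "B2", "gamma2",
    "C", "p_exp", "q_exp", "rho0", "gamma_dmg", "beta_dmg",
    "alpha0", "alpha_max", "k_min",
    "mu", "Noc", "d0", "lambda_acc", "Sk0", "nu")
}

perturb_config <- function(cfg, factor, mult) {
  bmu_fields <- c("alpha1", "beta1", "alpha2", "beta2", "k1", "k2",
                  "A1", "B1", "gamma1", "A2", "B2", "gamma2")
  mat_fields <- c("E0", "C", "p_exp", "q_exp", "rho0", "gamma_dmg", "beta_dmg",
                  "alpha0", "alpha_max", "k_min")
  stim_fields <- c("mu", "Noc", "d0", "lambda_acc", "Sk0")
  rebuild <- function(block, ctor) {
    args <- unclass(block)
    args[[factor]] <- args[[factor]] * mult
    # E0 anchors C unless C is the perturbed factor itself
    if (factor == "E0") args$C <- NULL
    keep <- names(args) %in% names(formals(ctor))
    do.call(ctor, args[keep])
  }
  if (factor %in% bmu_fields) {
    cfg$trabecular <- rebuild(cfg$trabecular, bmu_params)
    cfg$cortical <- rebuild(cfg$cortical, bmu_params)
  } else if (factor %in% mat_fields) {
    cfg$mat_trabecular <- rebuild(cfg$mat_trabecular, material_params)
    cfg$mat_cortical <- rebuild(cfg$mat_cortical, material_params)
  } else if (factor %in% stim_fields) {
    cfg$stimulus <- rebuild(cfg$stimulus, stimulus_params)
  } else if (factor == "nu") {
    cfg$nu <- cfg$nu * mult
    validate_config(cfg)
  } else {
    stop("unknown sensitivity factor: ", factor, call. = FALSE)
  }
  cfg
}

#' Disuse experiment at an isolated site
#'
#' Runs the zero-dimensional BMU model under mechanical disuse for the
#' given duration and reports the bone loss. `stimulus = "zero"` holds the
#' net stimulus exactly at zero; `stimulus = "unloaded"` emulates an
#' unloaded site inside the tissue, where the local energy density is zero
#' and the sensed stimulus is `-mu * Skbar(t)`, with the setpoint
#' accommodating from `Sk0` toward the experienced (zero) level.
#'
#' @param p a [bmu_params()] block.
#' @param sp a [stimulus_params()] block (used by `"unloaded"`).
#' @param days duration, days.
#' @param stimulus `"zero"` or `"unloaded"`.
#' @param substeps cell sub-steps per day.
#' @param rho_clamp normalized density clamp.
#' @return A list: `loss_pct` (percent of initial density lost, negative
#'   for net gain), `trajectory` (the [simulate_bmu_site()] data.frame).
#' @export
disuse_experiment <- function(p = bmu_params("trabecular"),
                              sp = stimulus_params(),
                              days = 1825,
                              stimulus = c("zero", "unloaded"),
                              substeps = 24,
                              rho_clamp = c(0.01, 1.74 / 0.764)) {
  stimulus <- match.arg(stimulus)
  Sfun <- switch(stimulus,
                 zero = function(day) 0,
                 unloaded = function(day) -sp$mu * sp$Noc *
                   (sp$Sk0 * exp(-sp$lambda_acc * day)))
  tr <- simulate_bmu_site(p, days, Sfun, substeps, rho_clamp)
  list(loss_pct = 100 * (1 - tr$rho_hat[nrow(tr)]), trajectory = tr)
}
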