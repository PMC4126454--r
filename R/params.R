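#' BMU cell-dynamics parameters
#'
#' Parameters of the basic multicellular unit (BMU) population model: the
#' coupled osteoclast/osteoblast ODEs with power-law autocrine/paracrine
#' regulation, the resorption/formation activities converting active cell
#' counts into a density rate, and the stimulus response of the paracrine
#' exponents.
#'
#' Defaults are the trabecular reference set. Cortical bone uses the same
#' cell kinetics but 10x lower activities `k1`, `k2`, reflecting the much
#' slower turnover of cortical tissue. Note that the removal rate `beta2`
#' and the formation activity `k2` default to the values of the original
#' cell-dynamics literature (`beta2 = 0.02`/day, i.e. an osteoblast lifespan
#' of ~2 months, and `k2 = 0.0017` %/cell/day); see the methods vignette for
#' why this pairing, and not its transposition, is the internally consistent
#' one.
#'
#' @param region `"trabecular"` or `"cortical"`; selects the default
#'   activity scaling (cortical `k1`, `k2` are 0.1x trabecular).
#' @param alpha1,beta1 osteoclast production (cells/day) and removal (1/day).
#' @param alpha2,beta2 osteoblast production (cells/day) and removal (1/day).
#' @param k1,k2 resorption/formation activity, percent of initial site mass
#'   per active cell per day.
#' @param A1,B1,gamma1 response of the osteoclast-derived paracrine exponent
#'   `g12 = A1 + B1 exp(-gamma1 S)` to the stimulus `S`.
#' @param A2,B2,gamma2 response of the osteoblast-derived paracrine exponent
#'   `g21 = A2 + B2 exp(-gamma2 S)`.
#' @param g11,g22 autocrine exponents (0 in the default model).
#' @param xC0,xB0 initial osteoclast/osteoblast counts.
#' @param g_clamp symmetric bound applied to `g12`, `g21` (prevents overflow
#'   of the power laws under strongly negative stimulus).
#' @param xmin positivity floor for the cell counts.
#' @return An object of class `bmu_params` (a named list).
#' @examples
#' p <- bmu_params("trabecular")
#' paracrine_exponents(0, p)
#' @export
bmu_params <- function(region = c("trabecular", "cortical"),
                       alpha1 = 3, beta1 = 0.2,
                       alpha2 = 4, beta2 = 0.02,
                       k1 = NULL, k2 = NULL,
                       A1 = 1.6, B1 = -0.49, gamma1 = 16.67,
                       A2 = -1.6, B2 = 0.6, gamma2 = 33.37,
                       g11 = 0, g22 = 0,
                       xC0 = 15, xB0 = 1,
                       g_clamp = 5, xmin = 1e-8) {
  region <- match.arg(region)
  scale <- if (region == "cortical") 0.1 else 1
  if (is.null(k1)) k1 <- 0.24 * scale
  if (is.null(k2)) k2 <- 0.0017 * scale
  p <- list(region = region,
            alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
            k1 = k1, k2 = k2,
            A1 = A1, B1 = B1, gamma1 = gamma1,
            A2 = A2, B2 = B2, gamma2 = gamma2,
            g11 = g11, g22 = g22, xC0 = xC0, xB0 = xB0,
            g_clamp = g_clamp, xmin = xmin)
  class(p) <- "bmu_params"
  validate_bmu_params(p)
  p
}

validate_bmu_params <- function(p) {
  stopifnot(p$alpha1 > 0, p$beta1 > 0, p$alpha2 > 0, p$beta2 > 0,
            p$k1 >= 0, p$k2 >= 0, p$g_clamp > 0, p$xmin > 0,
            p$xC0 > 0, p$xB0 > 0)
  invisible(p)
}

#' @export
print.bmu_params <- function(x, ...) {
  cat("BMU parameters (", x$region, ")\n", sep = "")
  cat(sprintf("  osteoclasts: alpha1=%g beta1=%g k1=%g\n", x$alpha1, x$beta1, x$k1))
  cat(sprintf("  osteoblasts: alpha2=%g beta2=%g k2=%g\n", x$alpha2, x$beta2, x$k2))
  cat(sprintf("  paracrine:   g12 = %g %+g exp(-%g S), g21 = %g %+g exp(-%g S)\n",
              x$A1, x$B1, x$gamma1, x$A2, x$B2, x$gamma2))
  cat(sprintf("  init: xC=%g xB=%g; exponent clamp +/-%g\n", x$xC0, x$xB0, x$g_clamp))
  invisible(x)
}

#' Bone tissue material parameters
#'
#' Constitutive constants for the fatigue-damage law, mineralization kinetics
#' and the density-ash-damage elastic modulus law
#' `E = C (1 - D) rho^p alpha^q` (MPa, rho in g/cm^3).
#'
#' @param region `"trabecular"` or `"cortical"` (selects `E0` and `rho0`).
#' @param gamma_dmg,beta_dmg exponents of the nonlinear (Chaboche-type)
#'   damage accumulation law.
#' @param E0 initial (undamaged, unremodeled) elastic modulus, MPa; 2000
#'   trabecular, 17000 cortical. Used to anchor the modulus law: by
#'   default `C = E0 / (rho0^p_exp alpha0^q_exp)`, so the initial state
#'   reproduces `E0` exactly.
#' @param C modulus coefficient (MPa per (g/cm^3)^p). `NULL` (default)
#'   derives it from `E0`; pass a value to fix the coefficient directly.
#' @param p_exp,q_exp density and ash-fraction exponents.
#' @param rho0 initial apparent density, g/cm^3.
#' @param alpha0,alpha_max initial and maximum ash fraction.
#' @param k_min mineralization velocity, 1/day.
#' @param D_crit damage level at which the local stimulus is shut down and
#'   targeted resorption of the damaged site takes over.
#' @param E_min modulus floor (MPa) keeping the stiffness matrix regular in
#'   fully resorbed or fully damaged elements.
#' @param rho_max fully mineralized density ceiling, g/cm^3.
#' @param rho_hat_min lower clamp on density normalized to its initial value.
#' @return An object of class `material_params`.
#' @export
material_params <- function(region = c("trabecular", "cortical"),
                            gamma_dmg = 0.2, beta_dmg = 0.4,
                            E0 = NULL, C = NULL, p_exp = 3, q_exp = 2.74,
                            rho0 = NULL,
                            alpha0 = 0.6, alpha_max = 0.7,
                            k_min = 0.0003387,
                            D_crit = 0.95, E_min = 0.01,
                            rho_max = 1.74, rho_hat_min = 0.01) {
  region <- match.arg(region)
  if (is.null(E0)) E0 <- if (region == "cortical") 17000 else 2000
  if (is.null(rho0)) rho0 <- if (region == "cortical") 1.4 else 0.764
  if (is.null(C)) C <- E0 / (rho0^p_exp * alpha0^q_exp)
  mp <- list(region = region,
             gamma_dmg = gamma_dmg, beta_dmg = beta_dmg,
             E0 = E0, C = C, p_exp = p_exp, q_exp = q_exp, rho0 = rho0,
             alpha0 = alpha0, alpha_max = alpha_max, k_min = k_min,
             D_crit = D_crit, E_min = E_min,
             rho_max = rho_max, rho_hat_min = rho_hat_min)
  class(mp) <- "material_params"
  stopifnot(mp$gamma_dmg > 0, mp$gamma_dmg < 1, mp$beta_dmg > 0, mp$C > 0,
            mp$p_exp >= 2, mp$p_exp <= 3,
            mp$alpha0 > 0, mp$alpha0 <= mp$alpha_max, mp$alpha_max <= 1,
            mp$rho0 > 0, mp$k_min >= 0, mp$E0 > 0)
  mp
}

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters (", x$region, ")\n", sep = "")
  cat(sprintf("  E = %.4g (1-D) rho^%g alpha^%g MPa (E0 = %g), rho0 = %g g/cm^3\n",
              x$C, x$p_exp, x$q_exp, x$E0, x$rho0))
  cat(sprintf("  damage: gamma=%g beta=%g, D_crit=%g; mineralization: alpha %g -> %g, k=%g/day\n",
              x$gamma_dmg, x$beta_dmg, x$D_crit, x$alpha0, x$alpha_max, x$k_min))
  invisible(x)
}

#' Mechanotransduction parameters
#'
#' Parameters of the osteocyte sensing layer: each element carries one
#' aggregate osteocyte sensor at its centroid. The sensed net stimulus is
#' `S(x) = sum_k f_k(x) mu (Sk_k - Skbar_k)` over sensors within
#' `influence_cutoff * d0` of `x`, with the spatial influence
#' `f(d) = exp(-d/d0)`. The setpoint accommodates toward the experienced
#' stimulus as `Skbar = Sk0 + (Sk - Sk0)(1 - exp(-lambda_acc t))`.
#'
#' All energies are in model units of MPa (stress in MPa times dimensionless
#' strain); `Sk0 = 0.0025` is expressed in the same units.
#'
#' @param mu osteocyte mechanosensitivity (dimensionless gain).
#' @param Noc relative osteocyte-density multiplier applied to the sensed
#'   signal (normalized to 1; retained so the sensitivity analysis can
#'   perturb sensor density).
#' @param d0 spatial influence decay length, mm.
#' @param lambda_acc accommodation velocity, 1/day.
#' @param Sk0 initial stimulus setpoint (MPa strain-energy units).
#' @param influence_cutoff truncation radius of the influence kernel, in
#'   multiples of `d0`; beyond it the weight is exactly zero.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(mu = 0.5, Noc = 1, d0 = 0.1,
                            lambda_acc = 0.002, Sk0 = 0.0025,
                            influence_cutoff = 12) {
  sp <- list(mu = mu, Noc = Noc, d0 = d0, lambda_acc = lambda_acc,
             Sk0 = Sk0, influence_cutoff = influence_cutoff)
  class(sp) <- "stimulus_params"
  stopifnot(sp$mu > 0, sp$d0 > 0, sp$Sk0 > 0, sp$lambda_acc >= 0,
            sp$Noc > 0, sp$influence_cutoff > 0)
  sp
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat(sprintf("Stimulus parameters: mu=%g Noc=%g d0=%g mm (cutoff %g d0), lambda=%g/day, Sk0=%g\n",
              x$mu, x$Noc, x$d0, x$influence_cutoff, x$lambda_acc, x$Sk0))
  invisible(x)
}

#' Full simulation configuration
#'
#' Bundles everything a remodeling run needs: the mesh source, the daily
#' load schedule, the per-region BMU and material parameter blocks, the
#' stimulus parameters and the numerical controls. The object validates its
#' parts on construction and can be round-tripped through a YAML file with
#' [write_config()] / [read_config()].
#'
#' @param mesh a `mesh2d` object, or `NULL` to generate the synthetic femur
#'   fixture from `geometry` at run time.
#' @param geometry a [femur_geometry()] parameter set (used when `mesh` is
#'   `NULL`).
#' @param schedule name of a built-in load schedule (`"NFC"`, `"LFC"`,
#'   `"HFC"`, `"disuse"`) or a list of [load_case()] objects.
#' @param days simulated duration in days (daily remodeling steps).
#' @param trabecular,cortical [bmu_params()] blocks per region.
#' @param mat_trabecular,mat_cortical [material_params()] blocks per region.
#' @param stimulus a [stimulus_params()] block.
#' @param nu Poisson ratio (plane stress).
#' @param thickness effective out-of-plane thickness of the coronal
#'   section, mm.
#' @param substeps Runge-Kutta sub-steps per day for the cell ODEs.
#' @param accommodation logical; enable setpoint accommodation.
#' @param damage_squared logical; apply the `(1-D)` factor a second time in
#'   the stimulus energy (the literal double-damage reading).
#' @param calibrate_setpoint logical; rescale `Sk0` to the median element
#'   strain-energy density of an initial solve of the first load case.
#' @param init_cells `"table"` starts the cell populations at `(xC0, xB0)`;
#'   `"steady"` starts them at the zero-stimulus steady state.
#' @param record_every history record cadence, days.
#' @param checkpoint optional path; a restartable checkpoint is written
#'   there every `checkpoint_every` days and on failure.
#' @param checkpoint_every checkpoint cadence, days.
#' @param seed integer seed (the mesh jitter is the only randomness).
#' @return An object of class `simulation_config`.
#' @seealso [run_remodeling()]
#' @export
simulation_config <- function(mesh = NULL,
                              geometry = femur_geometry(),
                              schedule = "NFC",
                              days = 1825,
                              trabecular = bmu_params("trabecular"),
                              cortical = bmu_params("cortical"),
                              mat_trabecular = material_params("trabecular"),
                              mat_cortical = material_params("cortical"),
                              stimulus = stimulus_params(),
                              nu = 0.3, thickness = 120,
                              substeps = 24,
                              accommodation = TRUE,
                              damage_squared = FALSE,
                              calibrate_setpoint = FALSE,
                              init_cells = c("table", "steady"),
                              record_every = 1,
                              checkpoint = NULL, checkpoint_every = 100,
                              seed = 1L) {
  init_cells <- match.arg(init_cells)
  cfg <- list(mesh = mesh, geometry = geometry, schedule = schedule,
              days = as.integer(days),
              trabecular = trabecular, cortical = cortical,
              mat_trabecular = mat_trabecular, mat_cortical = mat_cortical,
              stimulus = stimulus,
              nu = nu, thickness = thickness,
              substeps = as.integer(substeps),
              accommodation = isTRUE(accommodation),
              damage_squared = isTRUE(damage_squared),
              calibrate_setpoint = isTRUE(calibrate_setpoint),
              init_cells = init_cells,
              record_every = as.integer(record_every),
              checkpoint = checkpoint,
              checkpoint_every = as.integer(checkpoint_every),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$days < 0) stop("duration must be >= 0 days", call. = FALSE)
  if (cfg$substeps < 1) stop("substeps must be >= 1", call. = FALSE)
  if (cfg$nu <= -1 || cfg$nu >= 0.5) stop("Poisson ratio out of range", call. = FALSE)
  validate_bmu_params(cfg$trabecular)
  validate_bmu_params(cfg$cortical)
  if (is.character(cfg$schedule)) {
    if (!cfg$schedule %in% c("NFC", "LFC", "HFC", "disuse"))
      stop("unknown schedule name: ", cfg$schedule, call. = FALSE)
  } else if (!is.list(cfg$schedule) || !all(vapply(cfg$schedule, inherits, TRUE, "load_case"))) {
    stop("schedule must be a name or a list of load_case objects", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  sched <- if (is.character(x$schedule)) x$schedule else
    sprintf("custom (%d cases)", length(x$schedule))
  mesh <- if (is.null(x$mesh)) "synthetic femur fixture" else
    sprintf("supplied mesh (%d elements)", nrow(x$mesh$elements))
  cat("Remodeling simulation configuration\n")
  cat("  mesh:     ", mesh, "\n", sep = "")
  cat("  schedule: ", sched, ", ", x$days, " days\n", sep = "")
  cat(sprintf("  numerics: %d cell substeps/day, nu=%g, thickness=%g mm\n",
              x$substeps, x$nu, x$thickness))
  cat(sprintf("  options:  accommodation=%s damage_squared=%s init_cells=%s\n",
              x$accommodation, x$damage_squared, x$init_cells))
  invisible(x)
}

## ---- YAML serialization -------------------------------------------------

#' Read or write a simulation configuration file
#'
#' The configuration is stored as plain YAML; any field omitted from the
#' file keeps its default. Parameter blocks are nested maps mirroring the
#' constructor arguments; meshes are referenced by an `inp` path rather
#' than inlined.
#'
#' @param path file path.
#' @param cfg a [simulation_config()] object.
#' @return `read_config()` returns a `simulation_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor, region = NULL) {
    if (is.null(block)) {
      if (is.null(region)) ctor() else ctor(region)
    } else {
      args <- block
      if (!is.null(region)) args$region <- region
      do.call(ctor, args)
    }
  }
  mesh <- NULL
  if (!is.null(y$mesh_inp)) mesh <- read_inp(y$mesh_inp)
  geometry <- take(y$geometry, femur_geometry)
  schedule <- if (is.null(y$schedule)) "NFC" else y$schedule
  args <- list(
    mesh = mesh, geometry = geometry, schedule = schedule,
    trabecular = take(y$trabecular, bmu_params, "trabecular"),
    cortical = take(y$cortical, bmu_params, "cortical"),
    mat_trabecular = take(y$mat_trabecular, material_params, "trabecular"),
    mat_cortical = take(y$mat_cortical, material_params, "cortical"),
    stimulus = take(y$stimulus, stimulus_params))
  for (f in c("days", "nu", "thickness", "substeps", "accommodation",
              "damage_squared", "calibrate_setpoint", "init_cells",
              "record_every", "checkpoint", "checkpoint_every", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(simulation_config, args)
}

#' @rdname read_config
#' @param mesh_inp optional path to write the mesh as an Abaqus-INP subset
#'   and reference from the YAML file.
#' @export
write_config <- function(cfg, path, mesh_inp = NULL) {
  strip <- function(b, drop = "region") {
    b <- unclass(b)
    b[setdiff(names(b), drop)]
  }
  y <- list(
    schedule = if (is.character(cfg$schedule)) cfg$schedule else
      lapply(cfg$schedule, unclass),
    days = cfg$days,
    geometry = strip(cfg$geometry),
    trabecular = strip(cfg$trabecular),
    cortical = strip(cfg$cortical),
    mat_trabecular = strip(cfg$mat_trabecular),
    mat_cortical = strip(cfg$mat_cortical),
    stimulus = strip(cfg$stimulus),
    nu = cfg$nu, thickness = cfg$thickness, substeps = cfg$substeps,
    accommodation = cfg$accommodation, damage_squared = cfg$damage_squared,
    calibrate_setpoint = cfg$calibrate_setpoint, init_cells = cfg$init_cells,
    record_every = cfg$record_every, checkpoint_every = cfg$checkpoint_every,
    seed = cfg$seed)
  if (!is.null(cfg$mesh) && !is.null(mesh_inp)) {
    write_inp(cfg$mesh, mesh_inp)
    y$mesh_inp <- mesh_inp
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
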