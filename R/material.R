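#' Cycles to fatigue failure
#'
#' Strain-life law for bone tissue: `Nf = 1.479e-21 de^-10.3` under
#' compressive loading and `Nf = 3.630e-32 de^-14.1` under tensile loading,
#' with `de` the strain amplitude expressed as dimensionless strain
#' (0.002, not 2000 microstrain -- the coefficients only produce
#' physiological lives on that scale).
#'
#' @param delta_eps strain amplitude (> 0), vectorized.
#' @param mode `"compressive"` or `"tensile"`, scalar or vector.
#' @return Cycles to failure (vector).
#' @examples
#' cycles_to_failure(0.002, "compressive") # ~9.3e6 cycles
#' @export
cycles_to_failure <- function(delta_eps, mode = c("compressive", "tensile")) {
  if (any(delta_eps <= 0) || any(!is.finite(delta_eps)))
    stop("strain amplitude must be positive and finite", call. = FALSE)
  mode <- match.arg(mode, several.ok = TRUE)
  mode <- rep_len(mode, length(delta_eps))
  ifelse(mode == "compressive",
         1.479e-21 * delta_eps^-10.3,
         3.630e-32 * delta_eps^-14.1)
}

#' Nonlinear fatigue damage law
#'
#' Damage after `N` constant-amplitude cycles out of a life of `Nf`:
#' \deqn{D = 1 - [1 - (N/N_f)^{1/(1-\gamma)}]^{1/(1+\beta)}.}
#' `D` grows monotonically from 0 at `N = 0` to 1 at `N = Nf`. `N > Nf`
#' clamps to 1 with a warning. [fatigue_damage_inverse()] recovers the
#' cycle ratio from a damage value; the pair round-trips to machine
#' precision and underpins the variable-amplitude accumulation rule.
#'
#' @param N applied cycles (vector).
#' @param Nf cycles to failure.
#' @param mp a [material_params()] object (uses `gamma_dmg`, `beta_dmg`).
#' @return Damage in `[0, 1]`.
#' @export
fatigue_damage <- function(N, Nf, mp) {
  stopifnot(all(N >= 0), all(Nf > 0))
  r <- N / Nf
  if (any(r > 1)) {
    warning("N > Nf: damage clamped to 1")
    r <- pmin(r, 1)
  }
  1 - (1 - r^(1 / (1 - mp$gamma_dmg)))^(1 / (1 + mp$beta_dmg))
}

#' @rdname fatigue_damage
#' @param D damage value in `[0, 1]`.
#' @return `fatigue_damage_inverse()`: the equivalent cycle ratio `N/Nf`.
#' @export
fatigue_damage_inverse <- function(D, mp) {
  stopifnot(all(D >= 0), all(D <= 1))
  (1 - (1 - D)^(1 + mp$beta_dmg))^(1 - mp$gamma_dmg)
}

#' Variable-amplitude fatigue accumulation
#'
#' The constant-amplitude damage law is extended to variable amplitudes by
#' a damage-equivalent-cycle rule: the current damage is converted to an
#' equivalent cycle ratio at the new amplitude (inverting the damage law),
#' `n/Nf(delta_eps, mode)` is added, and the damage law is re-applied. For
#' constant amplitude this reduces exactly to the underlying law and is
#' independent of how the cycles are partitioned.
#'
#' @param ms material state: a list with vectors `D`, `Neq_c`, `Neq_t`.
#' @param delta_eps strain amplitude per site (vector); entries with zero
#'   amplitude are skipped.
#' @param mode `"compressive"`/`"tensile"` per site.
#' @param n_cycles cycles applied (scalar or vector, >= 0).
#' @param mp a [material_params()] object.
#' @return The updated material state; `D` is non-decreasing and capped at 1.
#' @export
accumulate_fatigue <- function(ms, delta_eps, mode, n_cycles, mp) {
  stopifnot(all(n_cycles >= 0))
  n <- rep_len(n_cycles, length(ms$D))
  act <- which(delta_eps > 0 & n > 0 & ms$D < 1)
  if (length(act)) {
    Nf <- cycles_to_failure(delta_eps[act], mode[act])
    ratio <- fatigue_damage_inverse(ms$D[act], mp) + n[act] / Nf
    ms$D[act] <- ifelse(ratio >= 1, 1, fatigue_damage(pmin(ratio, 1), Nf = 1, mp = mp))
    comp <- mode[act] == "compressive"
    ms$Neq_c[act] <- ms$Neq_c[act] + ifelse(comp, n[act] / Nf, 0)
    ms$Neq_t[act] <- ms$Neq_t[act] + ifelse(comp, 0, n[act] / Nf)
  }
  ms
}

#' Damage repair by new bone formation
#'
#' Newly formed tissue carries no fatigue damage, so depositing a mass
#' fraction `formed_fraction` dilutes the damage (and the equivalent-cycle
#' counters) linearly: `D <- D (1 - formed_fraction)`.
#'
#' @param ms material state list (`D`, `Neq_c`, `Neq_t`).
#' @param formed_fraction new bone mass formed this day over current mass,
#'   in `[0, 1]` (vectorized).
#' @return The updated material state.
#' @export
repair_damage <- function(ms, formed_fraction) {
  stopifnot(all(formed_fraction >= 0), all(formed_fraction <= 1))
  keep <- 1 - formed_fraction
  ms$D <- ms$D * keep
  ms$Neq_c <- ms$Neq_c * keep
  ms$Neq_t <- ms$Neq_t * keep
  ms
}

#' Mineralization kinetics (ash fraction)
#'
#' The mineral (ash) fraction of tissue of age `t` days relaxes
#' exponentially from its initial value toward the physiological maximum:
#' `alpha(t) = alpha_max + (alpha0 - alpha_max) exp(-k_min t)`.
#'
#' @param t tissue age, days (vectorized).
#' @param mp a [material_params()] object.
#' @return Ash fraction in `[alpha0, alpha_max]`.
#' @export
ash_fraction <- function(t, mp) {
  stopifnot(all(t >= 0))
  mp$alpha_max + (mp$alpha0 - mp$alpha_max) * exp(-mp$k_min * t)
}

#' Apparent bone porosity
#'
#' `p = 1 - rho / (1.41 + 1.29 alpha)`, clamped to `[0, 1]`: the
#' denominator is the fully dense tissue density implied by the ash
#' fraction.
#'
#' @param rho apparent density, g/cm^3.
#' @param alpha ash fraction.
#' @return Porosity in `[0, 1]`.
#' @export
bone_porosity <- function(rho, alpha) {
  stopifnot(all(rho >= 0))
  pmin(pmax(1 - rho / (1.41 + 1.29 * alpha), 0), 1)
}

#' Density-ash-damage elastic modulus
#'
#' `E = C (1 - D) rho^p alpha^q` MPa, floored at `mp$E_min` so fully
#' resorbed or fully damaged elements keep a regular stiffness.
#'
#' @param rho apparent density, g/cm^3 (> 0).
#' @param alpha ash fraction.
#' @param D fatigue damage in `[0, 1]`.
#' @param mp a [material_params()] object.
#' @return Elastic modulus, MPa.
#' @examples
#' mp <- material_params("trabecular")
#' elastic_modulus(0.764, 0.6, 0, mp) # 2000 MPa (the initial modulus)
#' @export
elastic_modulus <- function(rho, alpha, D, mp) {
  stopifnot(all(rho > 0), all(D >= 0), all(D <= 1))
  pmax(mp$C * (1 - D) * rho^mp$p_exp * alpha^mp$q_exp, mp$E_min)
}
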