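#' Strain-damage energy density
#'
#' The local stimulus is the elastic energy density of the damaged
#' material, `Sk = 1/2 sigma : eps`. The stress tensor already carries one
#' `(1 - D)` factor through the damaged constitutive law, so the plain
#' contraction applies the damage coupling exactly once; setting
#' `damage_squared = TRUE` multiplies by `(1 - D)` again to reproduce the
#' literal double-damage reading.
#'
#' Tensors are given in Voigt plane-stress form `(xx, yy, xy)` with
#' tensorial shear strain `eps_xy` (the off-diagonal component, not the
#' engineering shear), as 3-vectors or 3-column matrices (one row per
#' element).
#'
#' @param stress damaged stress, MPa.
#' @param strain strain (dimensionless).
#' @param D fatigue damage (used only when `damage_squared = TRUE`).
#' @param damage_squared apply the `(1-D)` factor a second time.
#' @return Energy density in MPa (= MJ/m^3), one value per row; always
#'   non-negative.
#' @export
strain_damage_sed <- function(stress, strain, D = 0, damage_squared = FALSE) {
  stress <- rbind(stress); strain <- rbind(strain)
  sed <- 0.5 * (stress[, 1] * strain[, 1] + stress[, 2] * strain[, 2] +
                  2 * stress[, 3] * strain[, 3])
  if (damage_squared) sed <- sed * (1 - D)
  unname(pmax(sed, 0))
}

#' Osteocyte spatial influence
#'
#' Exponential decay of an osteocyte's influence with distance,
#' `f(d) = exp(-d/d0)`, truncated to exactly zero beyond
#' `cutoff * d0` (the kernel tail below `exp(-12)` is negligible).
#'
#' @param d distance, mm (>= 0, vectorized).
#' @param d0 decay length, mm.
#' @param cutoff truncation radius in multiples of `d0`.
#' @return Weight in `[0, 1]`.
#' @export
spatial_influence <- function(d, d0, cutoff = 12) {
  stopifnot(all(d >= 0), d0 > 0)
  # the boundary itself truncates; guard the comparison against round-off
  ifelse(d / d0 >= cutoff * (1 - 1e-12), 0, exp(-d / d0))
}

#' Sensor influence matrix
#'
#' Precomputes the sparse matrix `W[i, k] = f(|x_i - x_k|)` of influence
#' weights between sensor locations within the truncation radius (the
#' diagonal is 1). With the default decay length, sensors separated by more
#' than `cutoff * d0` never interact, so the matrix is built from a cheap
#' grid-bucket neighbor search and is typically diagonal at ordinary mesh
#' resolutions.
#'
#' @param positions n x 2 matrix of sensor coordinates, mm.
#' @param sp a [stimulus_params()] object.
#' @return A sparse `dgCMatrix`.
#' @export
influence_matrix <- function(positions, sp) {
  n <- nrow(positions)
  r <- sp$influence_cutoff * sp$d0
  cell <- pmax(r, 1e-9)
  ix <- floor(positions[, 1] / cell)
  iy <- floor(positions[, 2] / cell)
  key <- paste(ix, iy)
  buckets <- split(seq_len(n), key)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (b in buckets) {
    # candidate neighbors: same bucket and the 8 surrounding buckets
    bx <- ix[b[1]]; by <- iy[b[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(bx + dx, by + dy)
      if (!is.null(buckets[[k]])) cand <- c(cand, buckets[[k]])
    }
    for (i in b) {
      d <- sqrt((positions[cand, 1] - positions[i, 1])^2 +
                  (positions[cand, 2] - positions[i, 2])^2)
      keep <- d < r
      ii <- c(ii, rep(i, sum(keep)))
      jj <- c(jj, cand[keep])
      ww <- c(ww, exp(-d[keep] / sp$d0))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
}

#' Net sensed stimulus field
#'
#' Collects the osteocyte signals into the net remodeling stimulus at each
#' sensor location,
#' `S(x_i) = Noc * sum_k W[i,k] mu (Sk_k - Skbar_k)`,
#' where `W` is the truncated exponential influence matrix. Sensors at
#' sites whose fatigue damage has reached `D_crit` neither emit nor
#' receive: their contribution is zeroed and their own stimulus is set to
#' zero, which hands the failed site over to targeted osteoclastic
#' resorption.
#'
#' @param Sk local strain-damage energy density per sensor.
#' @param Skbar current setpoint per sensor.
#' @param W influence matrix from [influence_matrix()] (or `NULL` for
#'   collocated, purely local sensing).
#' @param sp a [stimulus_params()] object.
#' @param shutdown logical vector: sites with stimulus shut down by damage.
#' @return Net stimulus vector `S`.
#' @export
sensed_stimulus <- function(Sk, Skbar, W = NULL, sp, shutdown = FALSE) {
  sig <- sp$mu * (Sk - Skbar)
  shutdown <- rep_len(shutdown, length(sig))
  sig[shutdown] <- 0
  S <- if (is.null(W)) sig else as.numeric(W %*% sig)
  S <- sp$Noc * S
  S[shutdown] <- 0
  S
}

#' Setpoint accommodation
#'
#' The remodeling setpoint drifts from its initial value toward the
#' currently experienced stimulus level (cellular accommodation):
#' `Skbar(t) = Sk0 + (Sk - Sk0)(1 - exp(-lambda_acc t))`, with `t` the
#' global simulation time in days. At `t = 0` the setpoint is `Sk0`; as
#' `t -> Inf` it approaches the current `Sk`, so a constant load is
#' eventually perceived as neutral.
#'
#' @param Sk current local stimulus per sensor.
#' @param t days since simulation start (>= 0).
#' @param sp a [stimulus_params()] object.
#' @return Setpoint vector `Skbar`.
#' @export
update_setpoint <- function(Sk, t, sp) {
  stopifnot(all(t >= 0))
  sp$Sk0 + (Sk - sp$Sk0) * (1 - exp(-sp$lambda_acc * t))
}
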