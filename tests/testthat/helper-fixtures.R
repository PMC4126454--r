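# Shared fixtures built in code.

# BMU parameter block exactly as the reference table prints it (the
# package default swaps beta2/k2 back to the source model's pairing).
bmu_params_printed <- function(region = "trabecular") {
  bmu_params(region, beta2 = 0.0017,
             k2 = if (region == "cortical") 0.002 else 0.02)
}

# single unit-square plane-stress element, left edge fixed
unit_square_mesh <- function(thickness = 1) {
  mesh2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
         matrix(1:4, 1), "trabecular", roi = TRUE,
         sets = list(distal = c(1L, 4L), head = c(2L, 3L),
                     trochanter = integer(0)),
         thickness = thickness, marks = list(head_center = c(0.5, 0.5)))
}

# irregular 5-element patch on the unit square (one interior node off-center)
patch_mesh <- function(thickness = 1) {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                 c(0.35, 0.21), c(0.82, 0.31), c(0.71, 0.78), c(0.26, 0.69))
  elements <- rbind(c(1, 2, 6, 5), c(2, 3, 7, 6), c(3, 4, 8, 7),
                    c(4, 1, 5, 8), c(5, 6, 7, 8))
  mesh2d(nodes, elements, rep("trabecular", 5), roi = rep(TRUE, 5),
         sets = list(distal = 1:4, head = integer(0), trochanter = integer(0)),
         thickness = thickness)
}

# slender cantilever: length L along x, height H, fixed at x = 0
cantilever_mesh <- function(L = 20, H = 2, nx = 40, ny = 4, thickness = 1) {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(-H / 2, H / 2, length.out = ny + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))[, 1:2]
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  elements <- do.call(rbind, lapply(seq_len(ny), function(j)
    t(vapply(seq_len(nx), function(i)
      as.integer(c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))),
      integer(4)))))
  mesh2d(nodes, elements, rep("trabecular", nrow(elements)),
         roi = rep(TRUE, nrow(elements)),
         sets = list(distal = vapply(seq_len(ny + 1), function(j) nid(1L, j), 0),
                     head = vapply(seq_len(ny + 1), function(j) nid(nx + 1L, j), 0),
                     trochanter = integer(0)),
         thickness = thickness)
}

# independent high-accuracy integrator for the cell ODEs (deSolve),
# with the active-count density quadrature included
integrate_bmu_oracle <- function(p, S, times, rho_clamp = c(0.01, 1.74 / 0.764)) {
  g <- paracrine_exponents(S, p)
  ss <- steady_state_cells(g, p)
  rhs <- function(t, y, parms) {
    xC <- max(y[1], p$xmin); xB <- max(y[2], p$xmin)
    list(c(p$alpha1 * xC^g$g11 * xB^g$g21 - p$beta1 * xC,
           p$alpha2 * xC^g$g12 * xB^g$g22 - p$beta2 * xB,
           (p$k2 * max(xB - ss$xB_bar, 0) - p$k1 * max(xC - ss$xC_bar, 0)) / 100))
  }
  out <- deSolve::ode(c(xC = p$xC0, xB = p$xB0, rho = 1), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-13)
  as.data.frame(out)
}

coarse_config <- function(days, ...) {
  simulation_config(geometry = femur_geometry(elem_size = 5),
                    days = days, record_every = max(1, days %/% 20), ...)
}
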