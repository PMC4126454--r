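#' Construct a 2D quadrilateral mesh
#'
#' Container for the plane-stress mesh: node coordinates (mm), 4-node
#' quadrilateral connectivity (counter-clockwise), per-element region
#' labels (`"cortical"`/`"trabecular"`), a femoral-neck region-of-interest
#' flag, and the three boundary node sets used by the load cases
#' (`distal` fixed edge, `head` joint-contact arc, `trochanter` abductor
#' attachment arc). Element Jacobians must be positive at every Gauss
#' point; [validate_mesh()] enforces this.
#'
#' @param nodes n x 2 numeric matrix of coordinates, mm.
#' @param elements ne x 4 integer matrix of node indices (1-based,
#'   counter-clockwise).
#' @param region character vector of length ne.
#' @param roi logical vector of length ne.
#' @param sets named list of integer node-index vectors (`distal`, `head`,
#'   `trochanter`).
#' @param thickness out-of-plane thickness, mm.
#' @param marks optional named list of marker coordinates (e.g. the head
#'   and trochanter arc centers used to orient surface loads).
#' @return An object of class `mesh2d`.
#' @export
mesh2d <- function(nodes, elements, region, roi = rep(FALSE, nrow(elements)),
                   sets = list(), thickness = 120, marks = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 2, ncol(elements) == 4,
            length(region) == nrow(elements), length(roi) == nrow(elements))
  m <- structure(list(nodes = nodes, elements = elements,
                      region = as.character(region), roi = as.logical(roi),
                      sets = sets, thickness = thickness, marks = marks),
                 class = "mesh2d")
  validate_mesh(m)
  m
}

#' @rdname mesh2d
#' @param mesh a `mesh2d` object.
#' @export
validate_mesh <- function(mesh) {
  ne <- nrow(mesh$elements)
  if (any(mesh$elements < 1L) || any(mesh$elements > nrow(mesh$nodes)))
    stop("element connectivity references nonexistent nodes", call. = FALSE)
  J <- element_jacobians(mesh)
  if (any(J <= 0)) {
    bad <- which(apply(J <= 0, 1, any))[1]
    stop(sprintf("non-positive Jacobian in element %d (node ordering or geometry)", bad),
         call. = FALSE)
  }
  if (!all(mesh$region %in% c("cortical", "trabecular")))
    stop("region labels must be 'cortical' or 'trabecular'", call. = FALSE)
  invisible(mesh)
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("mesh2d: %d nodes, %d quad elements (%d cortical, %d trabecular, %d in ROI)\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$region == "cortical"), sum(x$region == "trabecular"),
              sum(x$roi)))
  if (length(x$sets))
    cat("  node sets:", paste(sprintf("%s[%d]", names(x$sets),
                                      lengths(x$sets)), collapse = " "), "\n")
  invisible(x)
}

# 2x2 Gauss points and bilinear shape-function derivatives on the
# reference square [-1,1]^2
gauss_pts <- (1 / sqrt(3)) * matrix(c(-1, -1, 1, -1, 1, 1, -1, 1),
                                    ncol = 2, byrow = TRUE)
shape_deriv <- function(xi, eta) {
  # rows: dN/dxi, dN/deta; columns: the 4 corner nodes (CCW from (-1,-1))
  rbind(0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

element_jacobians <- function(mesh) {
  ne <- nrow(mesh$elements)
  J <- matrix(NA_real_, ne, 4)
  X <- mesh$nodes[, 1]; Y <- mesh$nodes[, 2]
  for (gp in 1:4) {
    dN <- shape_deriv(gauss_pts[gp, 1], gauss_pts[gp, 2])
    xe <- matrix(X[mesh$elements], ne, 4)
    ye <- matrix(Y[mesh$elements], ne, 4)
    j11 <- xe %*% dN[1, ]; j12 <- ye %*% dN[1, ]
    j21 <- xe %*% dN[2, ]; j22 <- ye %*% dN[2, ]
    J[, gp] <- j11 * j22 - j12 * j21
  }
  J
}

#' Precompute finite-element arrays for a mesh
#'
#' Assembles everything that depends only on geometry and the Poisson
#' ratio: per-element unit-modulus stiffness blocks (2x2 Gauss quadrature,
#' isotropic plane stress), Gauss-averaged strain-displacement matrices for
#' centroid field recovery, element areas and centroids, sparse-assembly
#' triplet indices, and the constrained/free degree-of-freedom partition
#' (the distal node set is fully fixed). The per-day stiffness matrix is
#' then linear in the element moduli, so daily reassembly is a cheap
#' vectorized scaling of these blocks.
#'
#' @param mesh a [mesh2d()] object.
#' @param nu Poisson ratio.
#' @return An opaque list used by [fem_assemble()], [solve_load_case()] and
#'   the remodeling driver.
#' @export
fem_setup <- function(mesh, nu) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  th <- mesh$thickness
  # plane-stress constitutive matrix for E = 1, engineering shear
  D1 <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
  K0 <- matrix(0, ne, 64)        # row-major 8x8 unit stiffness per element
  Bxx <- Byy <- Bxy <- matrix(0, ne, 8)  # Gauss-averaged B rows
  area <- numeric(ne)
  X <- mesh$nodes[, 1]; Y <- mesh$nodes[, 2]
  xe <- matrix(X[mesh$elements], ne, 4)
  ye <- matrix(Y[mesh$elements], ne, 4)
  for (gp in 1:4) {
    dN <- shape_deriv(gauss_pts[gp, 1], gauss_pts[gp, 2])
    j11 <- drop(xe %*% dN[1, ]); j12 <- drop(ye %*% dN[1, ])
    j21 <- drop(xe %*% dN[2, ]); j22 <- drop(ye %*% dN[2, ])
    detJ <- j11 * j22 - j12 * j21
    # dN/dx_i = inv(J) %*% dN/dxi_i, vectorized over elements
    for (a in 1:4) {
      dNdx <- (j22 * dN[1, a] - j12 * dN[2, a]) / detJ
      dNdy <- (-j21 * dN[1, a] + j11 * dN[2, a]) / detJ
      ix <- 2 * a - 1; iy <- 2 * a
      Bxx[, ix] <- Bxx[, ix] + dNdx / 4
      Byy[, iy] <- Byy[, iy] + dNdy / 4
      Bxy[, ix] <- Bxy[, ix] + dNdy / 4
      Bxy[, iy] <- Bxy[, iy] + dNdx / 4
    }
    # accumulate B' D B detJ at this Gauss point
    Bg <- array(0, c(ne, 3, 8))
    for (a in 1:4) {
      dNdx <- (j22 * dN[1, a] - j12 * dN[2, a]) / detJ
      dNdy <- (-j21 * dN[1, a] + j11 * dN[2, a]) / detJ
      Bg[, 1, 2 * a - 1] <- dNdx
      Bg[, 2, 2 * a] <- dNdy
      Bg[, 3, 2 * a - 1] <- dNdy
      Bg[, 3, 2 * a] <- dNdx
    }
    for (r in 1:8) for (cc in r:8) {
      v <- numeric(ne)
      for (p in 1:3) for (q in 1:3) {
        if (D1[p, q] != 0)
          v <- v + Bg[, p, r] * D1[p, q] * Bg[, q, cc]
      }
      v <- v * detJ * th
      K0[, (r - 1) * 8 + cc] <- K0[, (r - 1) * 8 + cc] + v
      if (cc != r) K0[, (cc - 1) * 8 + r] <- K0[, (cc - 1) * 8 + r] + v
    }
    area <- area + detJ
  }
  centroid <- cbind(rowMeans(xe), rowMeans(ye))
  # global dof indices per element (x1 y1 x2 y2 ...)
  edof <- matrix(0L, ne, 8)
  for (a in 1:4) {
    edof[, 2 * a - 1] <- 2L * mesh$elements[, a] - 1L
    edof[, 2 * a] <- 2L * mesh$elements[, a]
  }
  trip_i <- edof[, rep(1:8, each = 8)]
  trip_j <- edof[, rep(1:8, times = 8)]
  # K0 is stored row-major: entry (r, c) at column (r-1)*8+c matches
  # rep(1:8, each = 8) x rep(1:8, times = 8) ordering
  fixed_nodes <- mesh$sets$distal
  if (is.null(fixed_nodes) || !length(fixed_nodes))
    stop("mesh has no distal boundary set: system would be unconstrained",
         call. = FALSE)
  fixed <- sort(c(2L * fixed_nodes - 1L, 2L * fixed_nodes))
  list(mesh = mesh, nu = nu, D1 = D1, ndof = 2L * nn,
       K0 = K0, Bxx = Bxx, Byy = Byy, Bxy = Bxy,
       area = area, centroid = centroid, edof = edof,
       trip_i = as.integer(trip_i), trip_j = as.integer(trip_j),
       fixed = fixed)
}

#' Assemble the global stiffness matrix
#'
#' @param setup output of [fem_setup()].
#' @param E_field per-element elastic modulus, MPa.
#' @return Sparse symmetric stiffness matrix (all dofs, unconstrained).
#' @export
fem_assemble <- function(setup, E_field) {
  ne <- nrow(setup$K0)
  stopifnot(length(E_field) == ne)
  vals <- as.numeric(setup$K0) * rep(E_field, times = 64)
  Matrix::sparseMatrix(i = setup$trip_i, j = setup$trip_j, x = vals,
                       dims = c(setup$ndof, setup$ndof))
}

# Solve K u = F with Dirichlet constraints. Returns displacements,
# reactions at constrained dofs and the relative residual on free dofs.
fem_solve <- function(setup, K, F, fixed = setup$fixed, ufix = 0) {
  ndof <- setup$ndof
  free <- setdiff(seq_len(ndof), fixed)
  uc <- rep_len(ufix, length(fixed))
  F <- as.matrix(F)
  rhs <- F[free, , drop = FALSE]
  if (any(uc != 0))
    rhs <- rhs - as.matrix(K[free, fixed, drop = FALSE] %*% uc)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  # symmetric Jacobi scaling removes the modulus-contrast part of the
  # condition number (fully resorbed elements sit at E_min, up to ~1e6
  # below the cortical modulus); iterative refinement then holds the
  # relative residual at the 1e-8 contract
  d <- Matrix::diag(Kff)
  if (any(d <= 0))
    stop("singular stiffness system: non-positive diagonal at free dof ",
         which(d <= 0)[1], call. = FALSE)
  s <- 1 / sqrt(d)
  S <- Matrix::Diagonal(x = s)
  Ks <- Matrix::forceSymmetric(S %*% Kff %*% S)
  ch <- tryCatch(
    Matrix::Cholesky(Ks, LDL = FALSE),
    error = function(e) stop("singular stiffness system: check boundary constraints (",
                             conditionMessage(e), ")", call. = FALSE))
  rhs_s <- rhs * s
  uf <- s * as.matrix(Matrix::solve(ch, rhs_s))
  rhsn <- pmax(sqrt(colSums(rhs^2)), 1e-300)
  for (it in 1:10) {
    res <- as.matrix(Kff %*% uf) - rhs
    if (all(sqrt(colSums(res^2)) / rhsn <= 1e-10)) break
    uf <- uf - s * as.matrix(Matrix::solve(ch, res * s))
  }
  u <- matrix(0, ndof, ncol(F))
  u[fixed, ] <- uc
  u[free, ] <- uf
  res <- as.matrix(Kff %*% uf) - rhs
  rel <- sqrt(colSums(res^2)) / rhsn
  reactions <- as.matrix(K[fixed, , drop = FALSE] %*% u) - F[fixed, , drop = FALSE]
  list(u = u, residual = rel, fixed = fixed, reactions = reactions)
}

# Distributed surface load: spreads a total force over an arc node set
# with weights proportional to the cosine of the angle between the node's
# outward radial direction (from the arc center) and the force line of
# action, so the traction is strongest where the surface faces the load.
# Weights are normalized, preserving the total applied force exactly.
surface_load <- function(nodes, set, center, magnitude, direction) {
  Fv <- numeric(2 * nrow(nodes))
  if (magnitude == 0 || !length(set)) return(Fv)
  radial <- nodes[set, , drop = FALSE] - matrix(center, length(set), 2, byrow = TRUE)
  nr <- sqrt(rowSums(radial^2))
  nr[nr == 0] <- 1
  radial <- radial / nr
  w <- pmax(-(radial[, 1] * direction[1] + radial[, 2] * direction[2]), 0)
  if (sum(w) <= 0) w <- rep(1, length(set))
  w <- w / sum(w)
  Fv[2 * set - 1] <- magnitude * direction[1] * w
  Fv[2 * set] <- magnitude * direction[2] * w
  Fv
}

#' Static solve of one gait load case
#'
#' Assembles the plane-stress stiffness for the given modulus field,
#' applies the joint-reaction force as a cosine-distributed load over the
#' femoral-head node set and the abductor muscle force over the greater
#' trochanter set, fixes the distal boundary, and solves the linear
#' system. Element strain, stress and strain-energy density are recovered
#' at the centroid (Gauss average).
#'
#' Orientation convention: angles are measured from the vertical femoral
#' shaft axis (+y), positive toward medial (+x). The joint reaction pushes
#' down onto the head (direction `(sin a, -cos a)`); the abductor pulls
#' the trochanter up toward the pelvis (direction `(sin a, cos a)`).
#'
#' @param mesh a [mesh2d()] object.
#' @param E_field per-element modulus, MPa.
#' @param nu Poisson ratio.
#' @param lc a [load_case()].
#' @param setup optional precomputed [fem_setup()] (must match `mesh`,
#'   `nu`).
#' @return A list of class `field_solution`: nodal displacements `u`
#'   (n x 2, mm), element centroid `strain` (`xx`, `yy`, engineering
#'   `gxy`), `stress` (MPa), `sed` (MPa), principal-strain `delta_eps` and
#'   `mode`, the solver `residual` and the reaction-force sum.
#' @export
solve_load_case <- function(mesh, E_field, nu, lc, setup = NULL) {
  if (is.null(setup)) setup <- fem_setup(mesh, nu)
  K <- fem_assemble(setup, E_field)
  F <- load_vector(mesh, lc)
  sol <- fem_solve(setup, K, F)
  out <- recover_fields(setup, E_field, sol$u[, 1])
  out$u <- matrix(sol$u, ncol = 2, byrow = TRUE)
  out$residual <- sol$residual
  xdof <- setup$fixed %% 2L == 1L
  out$reaction_sum <- c(sum(sol$reactions[xdof, 1]),
                        sum(sol$reactions[!xdof, 1]))
  out$applied_sum <- c(sum(F[seq(1, setup$ndof, 2)]), sum(F[seq(2, setup$ndof, 2)]))
  class(out) <- "field_solution"
  out
}

load_vector <- function(mesh, lc) {
  hc <- mesh$marks$head_center
  tc <- mesh$marks$troch_center
  if (is.null(hc)) hc <- colMeans(mesh$nodes[mesh$sets$head, , drop = FALSE])
  if (is.null(tc)) tc <- colMeans(mesh$nodes[mesh$sets$trochanter, , drop = FALSE])
  ah <- lc$head_angle * pi / 180
  aa <- lc$abductor_angle * pi / 180
  surface_load(mesh$nodes, mesh$sets$head, hc,
               lc$head_force, c(sin(ah), -cos(ah))) +
    surface_load(mesh$nodes, mesh$sets$trochanter, tc,
                 lc$abductor_force, c(sin(aa), cos(aa)))
}

# Centroid strain/stress/SED recovery from a displacement vector
recover_fields <- function(setup, E_field, u) {
  U8 <- matrix(u[setup$edof], nrow(setup$edof), 8)
  exx <- rowSums(U8 * setup$Bxx)
  eyy <- rowSums(U8 * setup$Byy)
  gxy <- rowSums(U8 * setup$Bxy)
  nu <- setup$nu
  f <- E_field / (1 - nu^2)
  sxx <- f * (exx + nu * eyy)
  syy <- f * (nu * exx + eyy)
  sxy <- f * (1 - nu) / 2 * gxy
  sed <- pmax(0.5 * (sxx * exx + syy * eyy + sxy * gxy), 0)
  amp <- principal_amplitude(exx, eyy, gxy)
  list(strain = cbind(xx = exx, yy = eyy, gxy = gxy),
       stress = cbind(xx = sxx, yy = syy, xy = sxy),
       sed = sed, delta_eps = amp$delta_eps, mode = amp$mode)
}

principal_amplitude <- function(exx, eyy, gxy) {
  m <- (exx + eyy) / 2
  r <- sqrt(((exx - eyy) / 2)^2 + (gxy / 2)^2)
  e1 <- m + r
  e2 <- m - r
  # largest-magnitude principal strain; exact tie (pure shear) -> tensile
  pick1 <- abs(e1) >= abs(e2)
  eps <- ifelse(pick1, e1, e2)
  list(delta_eps = abs(eps),
       mode = ifelse(eps < 0, "compressive", "tensile"))
}

#' Per-element fatigue amplitude of a solved load case
#'
#' Extracts the strain amplitude feeding the fatigue law: the magnitude of
#' the largest-magnitude principal strain at the element centroid, with
#' its sign selecting the compressive or tensile strain-life curve. The
#' daily cycle unloads to zero force, so the amplitude equals the peak
#' value of the static solve.
#'
#' @param sol a `field_solution` from [solve_load_case()].
#' @return A list with vectors `delta_eps` and `mode`.
#' @export
element_amplitude <- function(sol) {
  list(delta_eps = sol$delta_eps, mode = sol$mode)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: %d elements, max |u| = %.4g mm, max SED = %.4g MPa, residual %.2g\n",
              nrow(x$strain), max(abs(x$u)), max(x$sed), max(x$residual)))
  invisible(x)
}
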