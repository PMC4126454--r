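#' Stimulus-dependent paracrine exponents
#'
#' The net stimulus sensed at a remodeling site modulates the paracrine
#' regulation between the two cell lineages through
#' `g12 = A1 + B1 exp(-gamma1 S)` (factors produced by osteoclasts acting on
#' osteoblast production) and `g21 = A2 + B2 exp(-gamma2 S)` (factors
#' produced by osteoblasts acting on osteoclast production). A positive
#' stimulus (overload) pushes `g12` up and `g21` down: stimulatory to
#' osteoblasts, inhibitory to osteoclasts. Both exponents are clamped to
#' `+/- p$g_clamp` so the power laws cannot overflow under strongly
#' negative (disuse) stimulus.
#'
#' @param S net stimulus, scalar or vector (one value per site).
#' @param p a [bmu_params()] object.
#' @return A list with components `g12`, `g21`, `g11`, `g22` (vectors the
#'   length of `S`).
#' @export
paracrine_exponents <- function(S, p) {
  if (!all(is.finite(S)))
    stop("non-finite stimulus passed to paracrine_exponents(); ",
         "upstream stimulus computation failed", call. = FALSE)
  cl <- p$g_clamp
  g12 <- pmin(pmax(p$A1 + p$B1 * exp(-p$gamma1 * S), -cl), cl)
  g21 <- pmin(pmax(p$A2 + p$B2 * exp(-p$gamma2 * S), -cl), cl)
  list(g12 = g12, g21 = g21,
       g11 = rep(p$g11, length(S)), g22 = rep(p$g22, length(S)))
}

#' Steady-state cell populations
#'
#' Closed-form fixed point of the coupled osteoclast/osteoblast ODEs,
#' \deqn{\bar x_C = (\beta_1/\alpha_1)^{(1-g_{22})/\gamma}
#'                 (\beta_2/\alpha_2)^{g_{21}/\gamma},\quad
#'       \bar x_B = (\beta_1/\alpha_1)^{g_{12}/\gamma}
#'                 (\beta_2/\alpha_2)^{(1-g_{11})/\gamma}}
#' with \eqn{\gamma = g_{12} g_{21} - (1-g_{11})(1-g_{22})}. The fixed point
#' is isolated only when \eqn{\gamma \neq 0}; a degenerate coupling is an
#' error.
#'
#' @param g paracrine exponents as returned by [paracrine_exponents()].
#' @param p a [bmu_params()] object.
#' @param tol degeneracy tolerance on \eqn{|\gamma|}.
#' @return A list with vectors `xC_bar`, `xB_bar`.
#' @export
steady_state_cells <- function(g, p, tol = 1e-6) {
  gamma_exp <- g$g12 * g$g21 - (1 - g$g11) * (1 - g$g22)
  if (any(abs(gamma_exp) < tol))
    stop("degenerate paracrine coupling (gamma ~ 0): no isolated fixed point",
         call. = FALSE)
  r1 <- p$beta1 / p$alpha1
  r2 <- p$beta2 / p$alpha2
  xC_bar <- r1^((1 - g$g22) / gamma_exp) * r2^(g$g21 / gamma_exp)
  xB_bar <- r1^(g$g12 / gamma_exp) * r2^((1 - g$g11) / gamma_exp)
  list(xC_bar = xC_bar, xB_bar = xB_bar)
}

#' Actively resorbing and forming cell counts
#'
#' Only cells in excess of the steady-state population take part in matrix
#' turnover: `XC = max(xC - xC_bar, 0)`, `XB = max(xB - xB_bar, 0)`.
#'
#' @param xC,xB current cell counts (vectors).
#' @param xC_bar,xB_bar steady-state thresholds.
#' @return A list with vectors `XC`, `XB`.
#' @export
active_cell_counts <- function(xC, xB, xC_bar, xB_bar) {
  stopifnot(all(xC_bar >= 0), all(xB_bar >= 0))
  list(XC = pmax(xC - xC_bar, 0), XB = pmax(xB - xB_bar, 0))
}

#' Cell population growth rates
#'
#' Right-hand side of the BMU ODE system,
#' \deqn{dx_C/dt = \alpha_1 x_C^{g_{11}} x_B^{g_{21}} - \beta_1 x_C,\quad
#'       dx_B/dt = \alpha_2 x_C^{g_{12}} x_B^{g_{22}} - \beta_2 x_B.}
#' The power laws carry negative exponents, so both populations must be
#' strictly positive.
#'
#' @param xC,xB current cell counts (vectors, > 0).
#' @param g paracrine exponents ([paracrine_exponents()]).
#' @param p a [bmu_params()] object.
#' @return A list with vectors `dxC`, `dxB`.
#' @export
cell_population_rates <- function(xC, xB, g, p) {
  if (any(xC <= 0) || any(xB <= 0))
    stop("cell counts must be positive (power laws with negative exponents)",
         call. = FALSE)
  list(dxC = p$alpha1 * xC^g$g11 * xB^g$g21 - p$beta1 * xC,
       dxB = p$alpha2 * xC^g$g12 * xB^g$g22 - p$beta2 * xB)
}

#' Advance a BMU site by one day
#'
#' Integrates the cell ODEs over one day with `substeps` internal classical
#' Runge-Kutta sub-steps, holding the stimulus (hence the paracrine
#' exponents and the steady-state thresholds) frozen for the day. The
#' density is advanced by forward Euler accumulated per sub-step,
#' `rho_hat += h (k2 XB - k1 XC) / 100`, with the active counts evaluated
#' from the end-of-sub-step populations. Cell counts are floored at
#' `p$xmin`; the normalized density is clamped to
#' `[rho_hat_min, rho_max/rho0]`.
#'
#' All arguments are vectorized over sites; `S` may be a scalar or a vector.
#'
#' @param state list with vectors `xC`, `xB`, `rho_hat`.
#' @param S net stimulus for the day.
#' @param p a [bmu_params()] object.
#' @param substeps sub-steps per day (>= 1).
#' @param rho_clamp length-2 clamp on `rho_hat`.
#' @param label context string used in numerical-failure errors.
#' @return The updated state list.
#' @export
step_bmu_day <- function(state, S, p, substeps = 24,
                         rho_clamp = c(0.01, 1.74 / 0.764),
                         label = "site") {
  stopifnot(substeps >= 1)
  g <- paracrine_exponents(S, p)
  ss <- steady_state_cells(g, p)
  xC <- pmax(state$xC, p$xmin)
  xB <- pmax(state$xB, p$xmin)
  rho <- state$rho_hat
  h <- 1 / substeps
  a1 <- p$alpha1; b1 <- p$beta1; a2 <- p$alpha2; b2 <- p$beta2
  g11 <- g$g11; g21 <- g$g21; g12 <- g$g12; g22 <- g$g22
  for (s in seq_len(substeps)) {
    k1C <- a1 * xC^g11 * xB^g21 - b1 * xC
    k1B <- a2 * xC^g12 * xB^g22 - b2 * xB
    xC2 <- pmax(xC + h / 2 * k1C, p$xmin); xB2 <- pmax(xB + h / 2 * k1B, p$xmin)
    k2C <- a1 * xC2^g11 * xB2^g21 - b1 * xC2
    k2B <- a2 * xC2^g12 * xB2^g22 - b2 * xB2
    xC3 <- pmax(xC + h / 2 * k2C, p$xmin); xB3 <- pmax(xB + h / 2 * k2B, p$xmin)
    k3C <- a1 * xC3^g11 * xB3^g21 - b1 * xC3
    k3B <- a2 * xC3^g12 * xB3^g22 - b2 * xB3
    xC4 <- pmax(xC + h * k3C, p$xmin); xB4 <- pmax(xB + h * k3B, p$xmin)
    k4C <- a1 * xC4^g11 * xB4^g21 - b1 * xC4
    k4B <- a2 * xC4^g12 * xB4^g22 - b2 * xB4
    xC <- pmax(xC + h / 6 * (k1C + 2 * k2C + 2 * k3C + k4C), p$xmin)
    xB <- pmax(xB + h / 6 * (k1B + 2 * k2B + 2 * k3B + k4B), p$xmin)
    XC <- pmax(xC - ss$xC_bar, 0)
    XB <- pmax(xB - ss$xB_bar, 0)
    rho <- rho + h * (p$k2 * XB - p$k1 * XC) / 100
    rho <- pmin(pmax(rho, rho_clamp[1]), rho_clamp[2])
  }
  if (any(!is.finite(xC)) || any(!is.finite(xB)) || any(!is.finite(rho))) {
    bad <- which(!(is.finite(xC) & is.finite(xB) & is.finite(rho)))[1]
    stop(sprintf("numerical failure in BMU sub-stepping at %s %d", label, bad),
         call. = FALSE)
  }
  list(xC = xC, xB = xB, rho_hat = rho)
}

#' Simulate an isolated remodeling site
#'
#' Runs the BMU population/density model at a single uncoupled site for a
#' given number of daily steps under a prescribed stimulus history. This is
#' the zero-dimensional counterpart of the full finite-element run, used
#' for the disuse experiment and for studying the cell dynamics in
#' isolation.
#'
#' @param p a [bmu_params()] object.
#' @param days number of daily steps.
#' @param S stimulus: a scalar held constant, or a function of the day
#'   index (0-based) returning the stimulus for that day.
#' @param substeps sub-steps per day.
#' @param rho_clamp clamp on normalized density.
#' @return A data.frame with columns `day`, `xC`, `xB`, `rho_hat`
#'   (`day = 0` is the initial condition).
#' @examples
#' p <- bmu_params("trabecular")
#' tr <- simulate_bmu_site(p, days = 30, S = 0)
#' tail(tr, 3)
#' @export
simulate_bmu_site <- function(p, days, S = 0, substeps = 24,
                              rho_clamp = c(0.01, 1.74 / 0.764)) {
  Sfun <- if (is.function(S)) S else function(day) S
  out <- matrix(NA_real_, nrow = days + 1, ncol = 3,
                dimnames = list(NULL, c("xC", "xB", "rho_hat")))
  st <- list(xC = p$xC0, xB = p$xB0, rho_hat = 1)
  out[1, ] <- c(st$xC, st$xB, st$rho_hat)
  for (d in seq_len(days)) {
    st <- step_bmu_day(st, Sfun(d - 1), p, substeps, rho_clamp)
    out[d + 1, ] <- c(st$xC, st$xB, st$rho_hat)
  }
  data.frame(day = 0:days, out)
}
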