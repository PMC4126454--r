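#' Synthetic proximal-femur geometry parameters
#'
#' Parameterization of the stylized coronal proximal-femur fixture: a
#' single structured block following a curved centerline (vertical shaft,
#' circular bend, inclined neck ending in a circular head bulge) with a
#' lateral greater-trochanter bump. All lengths in mm. The medial
#' direction is +x, proximal is +y.
#'
#' @param shaft_length length of the straight distal shaft segment.
#' @param bend_radius centerline radius of the shaft-to-neck bend.
#' @param neck_angle neck inclination from the vertical shaft axis, degrees.
#' @param neck_length length of the straight neck segment.
#' @param head_radius radius of the femoral head.
#' @param head_cap fraction of the head radius meshed beyond the head
#'   center (blunt cap; 1 would close the mesh to a degenerate tip).
#' @param shaft_width,neck_width full widths of shaft and neck.
#' @param troch_height,troch_halfwidth lateral trochanter bump height and
#'   half-extent along the centerline.
#' @param cortical_thickness outer shell labeled cortical.
#' @param elem_size target element size.
#' @param jitter interior-node jitter amplitude as a fraction of
#'   `elem_size` (0 = clean structured mesh).
#' @param seed integer seed for the jitter.
#' @return An object of class `femur_geometry`.
#' @export
femur_geometry <- function(shaft_length = 55, bend_radius = 40,
                           neck_angle = 50, neck_length = 18,
                           head_radius = 22, head_cap = 0.55,
                           shaft_width = 35, neck_width = 30,
                           troch_height = 8, troch_halfwidth = 20,
                           cortical_thickness = 3.5,
                           elem_size = 1.8, jitter = 0, seed = 1L) {
  g <- list(shaft_length = shaft_length, bend_radius = bend_radius,
            neck_angle = neck_angle, neck_length = neck_length,
            head_radius = head_radius, head_cap = head_cap,
            shaft_width = shaft_width, neck_width = neck_width,
            troch_height = troch_height, troch_halfwidth = troch_halfwidth,
            cortical_thickness = cortical_thickness,
            elem_size = elem_size, jitter = jitter, seed = as.integer(seed))
  class(g) <- "femur_geometry"
  if (g$elem_size <= 0) stop("element size must be positive", call. = FALSE)
  if (g$cortical_thickness >= g$shaft_width / 2)
    stop("cortical shell thicker than the shaft half-width", call. = FALSE)
  if (g$neck_width / 2 >= g$head_radius)
    stop("neck wider than the head diameter", call. = FALSE)
  if (g$neck_angle <= 0 || g$neck_angle >= 90)
    stop("neck angle must lie in (0, 90) degrees", call. = FALSE)
  if (g$bend_radius <= g$shaft_width / 2 + g$troch_height)
    stop("bend radius too small for the lateral width: elements would invert",
         call. = FALSE)
  g
}

#' Generate the synthetic proximal-femur mesh
#'
#' Builds a structured quadrilateral mesh of the stylized coronal femur
#' described by [femur_geometry()]: the outer shell (within
#' `cortical_thickness` of the medial/lateral surface) is labeled
#' cortical, the interior trabecular; a transverse femoral-neck band is
#' flagged as the region of interest; the distal edge, the femoral-head
#' arc and the greater-trochanter arc are exported as boundary node sets.
#' The mesh is deterministic for a fixed seed, and every element Jacobian
#' is checked positive.
#'
#' @param g a [femur_geometry()] parameter set.
#' @param thickness out-of-plane thickness passed to the mesh, mm.
#' @return A [mesh2d()] object.
#' @examples
#' m <- synthetic_femur_mesh(femur_geometry(elem_size = 4))
#' m
#' @export
synthetic_femur_mesh <- function(g = femur_geometry(), thickness = 120) {
  th_n <- g$neck_angle * pi / 180
  L1 <- g$shaft_length
  L2 <- g$bend_radius * th_n
  x0 <- sqrt(g$head_radius^2 - (g$neck_width / 2)^2)
  s_hc <- L1 + L2 + g$neck_length + x0         # head center arclength
  s_end <- s_hc + g$head_cap * g$head_radius
  bend_end <- L1 + L2

  centerline <- function(s) {
    # returns position (x, y) and unit tangent for arclength s
    if (s <= L1) {
      list(p = c(0, s), t = c(0, 1))
    } else if (s <= bend_end) {
      phi <- (s - L1) / g$bend_radius
      list(p = c(g$bend_radius * (1 - cos(phi)), L1 + g$bend_radius * sin(phi)),
           t = c(sin(phi), cos(phi)))
    } else {
      e <- centerline(bend_end)
      list(p = e$p + (s - bend_end) * c(sin(th_n), cos(th_n)),
           t = c(sin(th_n), cos(th_n)))
    }
  }
  base_halfwidth <- function(s) {
    ws <- g$shaft_width / 2; wn <- g$neck_width / 2
    if (s <= L1) ws
    else if (s <= bend_end) ws + (wn - ws) * (s - L1) / L2
    else if (s <= s_hc - x0) wn
    else sqrt(pmax(g$head_radius^2 - (s - s_hc)^2, (0.25 * wn)^2))
  }
  s_troch <- L1 + 0.5 * L2
  troch_bump <- function(s) {
    d <- abs(s - s_troch)
    ifelse(d < g$troch_halfwidth,
           g$troch_height * 0.5 * (1 + cos(pi * d / g$troch_halfwidth)), 0)
  }

  ns <- max(round(s_end / g$elem_size), 8L)
  mean_w <- mean(vapply(seq(0, s_end, length.out = 40), base_halfwidth, 0)) * 2
  nv <- max(2L * round(mean_w / g$elem_size / 2), 4L)
  svals <- seq(0, s_end, length.out = ns + 1)
  vvals <- seq(-1, 1, length.out = nv + 1)

  nn <- (ns + 1) * (nv + 1)
  nodes <- matrix(0, nn, 2)
  nid <- function(i, j) as.integer((i - 1L) * (nv + 1L) + j)   # i along s, j along v
  for (i in seq_len(ns + 1)) {
    cl <- centerline(svals[i])
    nrm <- c(-cl$t[2], cl$t[1])                    # lateral (-x side) normal
    wb <- base_halfwidth(svals[i])
    wlat <- wb + troch_bump(svals[i])
    for (j in seq_len(nv + 1)) {
      v <- vvals[j]
      w <- if (v >= 0) wlat else wb
      nodes[nid(i, j), ] <- cl$p + nrm * (v * w)
    }
  }

  if (g$jitter > 0) {
    set.seed(g$seed)
    interior <- as.vector(outer(2:ns, 2:nv, nid))
    amp <- g$jitter * g$elem_size
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(2 * length(interior), -amp, amp), ncol = 2)
  }

  ne <- ns * nv
  elements <- matrix(0L, ne, 4)
  eseg <- numeric(ne)     # centroid arclength parameter
  emidv <- numeric(ne)    # centroid transverse parameter
  e <- 0L
  for (i in seq_len(ns)) for (j in seq_len(nv)) {
    e <- e + 1L
    # CCW for the (+s up, +v lateral/left) parameterization
    elements[e, ] <- c(nid(i, j), nid(i, j + 1L), nid(i + 1L, j + 1L), nid(i + 1L, j))
    eseg[e] <- (svals[i] + svals[i + 1]) / 2
    emidv[e] <- (vvals[j] + vvals[j + 1]) / 2
  }
  # fix orientation if the parameterization came out clockwise
  a <- elements[1, ]
  cr <- (nodes[a[2], 1] - nodes[a[1], 1]) * (nodes[a[3], 2] - nodes[a[1], 2]) -
    (nodes[a[2], 2] - nodes[a[1], 2]) * (nodes[a[3], 1] - nodes[a[1], 1])
  if (cr < 0) elements <- elements[, 4:1]

  # region labels: distance from the lateral/medial surface
  wb <- vapply(eseg, base_halfwidth, 0)
  wl <- wb + troch_bump(eseg)
  wside <- ifelse(emidv >= 0, wl, wb)
  surf_dist <- (1 - abs(emidv)) * wside
  region <- ifelse(surf_dist < g$cortical_thickness, "cortical", "trabecular")
  if (g$cortical_thickness <= 0)
    warning("zero cortical shell thickness: all-trabecular mesh")
  roi <- eseg >= bend_end & eseg <= bend_end + g$neck_length

  # boundary node sets
  distal <- vapply(seq_len(nv + 1), function(j) nid(1L, j), 0L)
  boundary <- unique(c(vapply(seq_len(ns + 1), function(i) nid(i, 1L), 0L),
                       vapply(seq_len(ns + 1), function(i) nid(i, nv + 1L), 0L),
                       vapply(seq_len(nv + 1), function(j) nid(ns + 1L, j), 0L)))
  hc <- centerline(s_hc)$p
  dhead <- sqrt((nodes[boundary, 1] - hc[1])^2 + (nodes[boundary, 2] - hc[2])^2)
  head <- boundary[dhead <= g$head_radius * 1.02]
  lat_edge <- vapply(seq_len(ns + 1), function(i) nid(i, nv + 1L), 0L)
  troch <- lat_edge[abs(svals - s_troch) <= g$troch_halfwidth * 0.7]
  tc_cl <- centerline(s_troch)
  tc <- tc_cl$p + c(-tc_cl$t[2], tc_cl$t[1]) *
    (base_halfwidth(s_troch) + g$troch_height)

  mesh2d(nodes, elements, region, roi,
         sets = list(distal = as.integer(distal), head = as.integer(head),
                     trochanter = as.integer(troch)),
         thickness = thickness,
         marks = list(head_center = hc, troch_center = tc))
}

#' Daily gait load case
#'
#' One static load case of the daily loading history: a joint-reaction
#' force on the femoral head and an abductor muscle force on the greater
#' trochanter, each with a magnitude (N) and an orientation (degrees from
#' the vertical femoral axis, positive toward medial), applied for a
#' number of cycles per day.
#'
#' @param head_force,head_angle joint reaction magnitude and orientation.
#' @param abductor_force,abductor_angle abductor magnitude and orientation.
#' @param cycles cycles per day.
#' @return An object of class `load_case`.
#' @export
load_case <- function(head_force, head_angle, abductor_force, abductor_angle,
                      cycles) {
  stopifnot(head_force >= 0, abductor_force >= 0, cycles >= 0)
  structure(list(head_force = head_force, head_angle = head_angle,
                 abductor_force = abductor_force,
                 abductor_angle = abductor_angle, cycles = cycles),
            class = "load_case")
}

#' Built-in daily load schedules
#'
#' The three walking-load schedules (three load cases each, 10000 cycles
#' per day in total): `NFC`, the normal standard-gait force case; `LFC`,
#' the low-force (disuse, 10% of normal) case; and `HFC`, the high-force
#' (overload) case. Magnitudes and orientations are the published values;
#' `"disuse"` returns the same cycle structure with all forces zero.
#'
#' @param case_name `"NFC"`, `"LFC"`, `"HFC"` or `"disuse"`.
#' @return A list of three [load_case()] objects.
#' @examples
#' load_schedule("NFC")[[1]]
#' @export
load_schedule <- function(case_name = c("NFC", "LFC", "HFC", "disuse")) {
  case_name <- match.arg(case_name)
  tab <- switch(case_name,
    NFC = list(c(2317, 24, 703, 28), c(1158, -15, 351, -8), c(1548, 56, 468, 35)),
    LFC = list(c(232, 24, 70, 28), c(116, -15, 35, -8), c(155, 56, 47, 35)),
    HFC = list(c(3244, 24, 984, 28), c(1621, -15, 491, -8), c(2167, 56, 655, 35)),
    disuse = list(c(0, 24, 0, 28), c(0, -15, 0, -8), c(0, 56, 0, 35)))
  cycles <- c(6000, 2000, 2000)
  lapply(seq_along(tab), function(i)
    load_case(tab[[i]][1], tab[[i]][2], tab[[i]][3], tab[[i]][4], cycles[i]))
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("load_case: head %g N @ %g deg, abductor %g N @ %g deg, %g cycles/day\n",
              x$head_force, x$head_angle, x$abductor_force, x$abductor_angle,
              x$cycles))
  invisible(x)
}
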