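#' @export
print.bone_remodeling <- function(x, ...) {
  h <- x$history
  cat("Bone remodeling simulation\n")
  cat(sprintf("  %d elements, %d days, schedule %s\n",
              nrow(x$mesh$elements), x$days,
              if (is.character(x$config$schedule)) x$config$schedule else "custom"))
  cat(sprintf("  ROI density: %.3f -> %.3f g/cm^3 (%+.2f%%)\n",
              h$roi_density[1], h$roi_density[nrow(h)],
              100 * (h$roi_density[nrow(h)] / h$roi_density[1] - 1)))
  cat(sprintf("  mean damage %.3g, mean stimulus %.3g\n",
              mean(x$state$D), mean(x$state$S)))
  invisible(x)
}

#' @export
summary.bone_remodeling <- function(object, ...) {
  h <- object$history
  cort <- object$mesh$region == "cortical"
  rho <- object$state$rho_hat * object$rho0
  out <- list(
    days = object$days,
    n_elements = nrow(object$mesh$elements),
    roi_initial = h$roi_density[1],
    roi_final = h$roi_density[nrow(h)],
    roi_min = min(h$roi_density),
    day_roi_min = h$day[which.min(h$roi_density)],
    cortical_mean = mean(rho[cort]),
    trabecular_mean = mean(rho[!cort]),
    density_range = range(rho),
    damage_max = max(object$state$D),
    cells = c(xC = mean(object$state$xC), xB = mean(object$state$xB)))
  class(out) <- "summary.bone_remodeling"
  out
}

#' @export
print.summary.bone_remodeling <- function(x, ...) {
  cat(sprintf("Remodeling summary after %d days (%d elements)\n",
              x$days, x$n_elements))
  cat(sprintf("  ROI density:   %.3f -> %.3f g/cm^3 (minimum %.3f on day %d)\n",
              x$roi_initial, x$roi_final, x$roi_min, x$day_roi_min))
  cat(sprintf("  region means:  cortical %.3f, trabecular %.3f g/cm^3\n",
              x$cortical_mean, x$trabecular_mean))
  cat(sprintf("  density range: [%.3f, %.3f] g/cm^3; max damage %.3g\n",
              x$density_range[1], x$density_range[2], x$damage_max))
  cat(sprintf("  mean cells:    %.3g osteoclasts, %.3g osteoblasts\n",
              x$cells["xC"], x$cells["xB"]))
  invisible(x)
}

#' Plot a remodeling result
#'
#' `type = "map"` draws the mesh colored by a per-element field (apparent
#' density by default); `type = "history"` plots the ROI density over
#' time.
#'
#' @param x a `bone_remodeling` result.
#' @param type `"map"` or `"history"`.
#' @param field per-element values for the map (default: apparent
#'   density, g/cm^3).
#' @param palette color ramp for the map.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.bone_remodeling <- function(x, type = c("map", "history"),
                                 field = NULL,
                                 palette = grDevices::gray.colors(64, 0.95, 0.05),
                                 ...) {
  type <- match.arg(type)
  if (type == "history") {
    graphics::plot(x$history$day, x$history$roi_density, type = "l",
                   xlab = "day", ylab = "ROI density (g/cm^3)", ...)
    return(invisible(x))
  }
  if (is.null(field)) field <- x$state$rho_hat * x$rho0
  plot_mesh_field(x$mesh, field, palette = palette, ...)
  invisible(x)
}

#' Draw a per-element field on a mesh
#'
#' @param mesh a [mesh2d()] object.
#' @param field numeric vector, one value per element.
#' @param palette color ramp.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_mesh_field <- function(mesh, field, palette = grDevices::hcl.colors(64),
                            main = NULL, ...) {
  stopifnot(length(field) == nrow(mesh$elements))
  rng <- range(field, finite = TRUE)
  idx <- if (diff(rng) == 0) rep(1L, length(field)) else
    pmax(1L, ceiling((field - rng[1]) / diff(rng) * length(palette)))
  graphics::plot(NA, xlim = range(mesh$nodes[, 1]), ylim = range(mesh$nodes[, 2]),
                 asp = 1, xlab = "x (mm)", ylab = "y (mm)", main = main, ...)
  for (e in seq_len(nrow(mesh$elements))) {
    v <- mesh$elements[e, ]
    graphics::polygon(mesh$nodes[v, 1], mesh$nodes[v, 2],
                      col = palette[idx[e]], border = NA)
  }
  invisible(mesh)
}

#' @export
print.remodeling_sa <- function(x, ...) {
  cat(sprintf("One-factor sensitivity analysis: %d runs, baseline ROI density %.4f g/cm^3\n",
              nrow(x), attr(x, "baseline")))
  df <- as.data.frame(x)
  df$pct_change <- round(df$pct_change, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.remodeling_sa <- function(x, ...) {
  ok <- x$status == "ok"
  f <- unique(x$factor)
  lo <- x$pct_change[match(paste(f, "-50%"), paste(x$factor, x$direction))]
  hi <- x$pct_change[match(paste(f, "+50%"), paste(x$factor, x$direction))]
  o <- order(pmax(abs(lo), abs(hi), na.rm = TRUE))
  graphics::barplot(rbind(lo[o], hi[o]), beside = TRUE, horiz = TRUE,
                    names.arg = f[o], las = 1, cex.names = 0.7,
                    col = c("steelblue", "firebrick"),
                    xlab = "ROI density change (%)", ...)
  graphics::legend("bottomright", c("-50%", "+50%"),
                   fill = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
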