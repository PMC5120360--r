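#' Tumour front position
#'
#' The front is located at the point of maximum absolute slope of the glioma
#' density on the rightward (decreasing) front — the tumour is seeded at the
#' left boundary, so invasion proceeds rightward. The discrete-gradient
#' minimum (most negative slope) is refined by quadratic interpolation over
#' its two neighbours, giving sub-grid accuracy for smooth profiles.
#'
#' @param state a \code{sim_state} (or any list with a \code{rho} field).
#' @param grid a \code{\link{build_grid}} object.
#' @return Front location, mm.
#' @export
front_position <- function(state, grid) {
  rho <- state$rho
  nx <- grid$nx
  g <- numeric(nx)
  g[2:(nx - 1)] <- (rho[3:nx] - rho[1:(nx - 2)]) / (2 * grid$dx)
  g[1] <- (rho[2] - rho[1]) / grid$dx
  g[nx] <- (rho[nx] - rho[nx - 1]) / grid$dx
  if (max(abs(g)) < 1e-9 * max(max(abs(rho)), 1) / grid$L)
    stop(structure(class = c("gliovasc_nofront_error", "error", "condition"),
                   list(message = "profile is flat: no front to locate", call = NULL)))
  i <- which.min(g)  # steepest descent = rightward front
  if (g[i] >= 0)
    stop(structure(class = c("gliovasc_nofront_error", "error", "condition"),
                   list(message = "no decreasing front segment found", call = NULL)))
  if (i == 1 || i == nx) return(grid$x[i])
  # quadratic vertex through (x[i-1], g[i-1]), (x[i], g[i]), (x[i+1], g[i+1])
  denom <- g[i - 1] - 2 * g[i] + g[i + 1]
  delta <- if (abs(denom) < .Machine$double.eps) 0
           else 0.5 * (g[i - 1] - g[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  grid$x[i] + delta * grid$dx
}

#' Tumour front speed
#'
#' Slope of a least-squares line through the front positions over the final
#' part of the run (default: last 25\% of the simulated interval). A
#' least-squares window is preferred to a two-point end difference for
#' robustness to the output discretisation while still measuring the speed
#' "at the end" of the simulation, where the travelling front has developed.
#'
#' @param trajectory a \code{glioma_trajectory}.
#' @param window fraction of the run, from the end, used for the fit.
#' @return A list: \code{speed} (mm/day, the fitted slope),
#'   \code{rms_residual} (mm), \code{n} points used.
#' @export
front_speed <- function(trajectory, window = 0.25) {
  t_all <- trajectory$times
  fp <- trajectory$front_positions
  t0 <- max(t_all) - window * (max(t_all) - min(t_all))
  keep <- t_all >= t0 - 1e-9 & is.finite(fp)
  if (sum(keep) < 4)
    stop("fewer than 4 usable front positions in the fitting window")
  L <- trajectory$grid$L
  if (any(fp[keep] > 0.95 * L))
    stop(structure(class = c("gliovasc_boundary_error", "error", "condition"),
                   list(message = "front reached within 5% of the right boundary during the speed window; enlarge L",
                        call = NULL)))
  tt <- t_all[keep]; xx <- fp[keep]
  fit <- stats::lm.fit(cbind(1, tt), xx)
  list(speed = unname(fit$coefficients[2]),
       rms_residual = sqrt(mean(fit$residuals^2)),
       n = sum(keep))
}

#' Tumour infiltration width
#'
#' Distance between the points where the glioma density falls to 80\% and to
#' 2\% of its maximum, measured on the rightward (monotone decreasing) front
#' and located by linear interpolation between bracketing nodes. A proxy for
#' the diffuseness of invasion: flat, infiltrative fronts are wide; steep,
#' nodular fronts are narrow.
#'
#' @param state a \code{sim_state}.
#' @param grid a \code{\link{build_grid}} object.
#' @param levels the two fractions of the maximum density (high, low).
#' @return Width, mm (non-negative).
#' @export
infiltration_width <- function(state, grid, levels = c(0.80, 0.02)) {
  rho <- state$rho
  rmax <- max(rho)
  if (rmax <= 0)
    stop(structure(class = c("gliovasc_width_error", "error", "condition"),
                   list(message = "empty tumour: width undefined", call = NULL)))
  imax <- max(which(rho == rmax))
  x_at <- function(level) {
    target <- level * rmax
    seg <- rho[imax:grid$nx]
    below <- which(seg < target)
    if (!length(below))
      stop(structure(class = c("gliovasc_width_error", "error", "condition"),
                     list(message = sprintf(
                       "density never falls below %g%% of maximum on the front (front beyond domain?)",
                       100 * level), call = NULL)))
    j <- imax + below[1] - 1L   # first node below target; j-1 is at/above
    x1 <- grid$x[j - 1L]; x2 <- grid$x[j]
    r1 <- rho[j - 1L]; r2 <- rho[j]
    x1 + (r1 - target) / (r1 - r2) * (x2 - x1)
  }
  w <- x_at(levels[2]) - x_at(levels[1])
  max(w, 0)
}

#' Effective diffusion and proliferation rates
#'
#' Domain averages of the oxygen-modulated motility and growth coefficients
#' at the evaluation time:
#' \deqn{D_{eff} = \frac{1}{L}\int_0^L D_\rho\,\alpha(\sigma(x))\,dx, \qquad
#'       b_{eff} = \frac{1}{L}\int_0^L b_\rho\,\beta(\sigma(x))\,dx,}
#' with \code{D_rho = D / alpha(sigma0)} and \code{b_rho = b / beta(sigma0)},
#' so that under uniform physiological oxygen they reduce exactly to the
#' intrinsic rates \code{D} and \code{b}. They summarise the emergent
#' migratory/proliferative balance of a run: hypoxia raises \code{D_eff} and
#' lowers \code{b_eff}. Quadrature is trapezoidal on the grid.
#'
#' @param state a \code{sim_state} (normally the final snapshot).
#' @param params a \code{\link{glioma_params}} object.
#' @param grid a \code{\link{build_grid}} object.
#' @param rho_weighted if \code{TRUE}, weight the averages by the glioma
#'   density profile instead of uniformly (sensitivity variant).
#' @return A list with \code{D_eff} (mm^2/day) and \code{b_eff} (1/day).
#' @export
effective_rates <- function(state, params, grid, rho_weighted = FALSE) {
  sigma <- state$sigma
  if (any(sigma < 0) || any(sigma > params$lambda1))
    stop("oxygen field outside admissible range [0, lambda1]")
  sw <- switch_fractions(sigma, params)
  sw0 <- switch_fractions(params$sigma0, params)
  D_rho <- params$D / sw0$alpha
  b_rho <- params$b / sw0$beta
  if (rho_weighted) {
    wmass <- trapz_uniform(state$rho, grid$dx)
    if (wmass <= 0) stop("empty density profile: rho-weighted averages undefined")
    list(D_eff = trapz_uniform(D_rho * sw$alpha * state$rho, grid$dx) / wmass,
         b_eff = trapz_uniform(b_rho * sw$beta * state$rho, grid$dx) / wmass)
  } else {
    list(D_eff = trapz_uniform(D_rho * sw$alpha, grid$dx) / grid$L,
         b_eff = trapz_uniform(b_rho * sw$beta, grid$dx) / grid$L)
  }
}

#' Invasion observables of a completed run
#'
#' Bundles the four invasion metrics evaluated at the end of a trajectory:
#' front speed, infiltration width, and the effective diffusion and
#' proliferation rates.
#'
#' @param trajectory a \code{glioma_trajectory}.
#' @param window speed-fit window, see \code{\link{front_speed}}.
#' @param rho_weighted see \code{\link{effective_rates}}.
#' @return An \code{observable_set}: list with \code{front_speed} (mm/day),
#'   \code{infiltration_width} (mm), \code{D_eff}, \code{b_eff},
#'   \code{t_eval} (day) and \code{speed_rms_residual}.
#' @export
observables <- function(trajectory, window = 0.25, rho_weighted = FALSE) {
  final <- trajectory$states[[length(trajectory$states)]]
  sp <- front_speed(trajectory, window = window)
  eff <- effective_rates(final, trajectory$params, trajectory$grid,
                         rho_weighted = rho_weighted)
  structure(list(front_speed = sp$speed,
                 infiltration_width = infiltration_width(final, trajectory$grid),
                 D_eff = eff$D_eff, b_eff = eff$b_eff,
                 t_eval = final$t,
                 speed_rms_residual = sp$rms_residual),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat("<observable_set>\n")
  cat(sprintf("  front speed:        %.5g mm/day\n", x$front_speed))
  cat(sprintf("  infiltration width: %.5g mm\n", x$infiltration_width))
  cat(sprintf("  D_eff:              %.5g mm^2/day\n", x$D_eff))
  cat(sprintf("  b_eff:              %.5g 1/day\n", x$b_eff))
  cat(sprintf("  evaluated at t =    %g days\n", x$t_eval))
  invisible(x)
}
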