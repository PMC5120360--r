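#' Build a uniform 1-D grid
#'
#' @param L domain length, mm.
#' @param nx number of nodes (>= 16).
#' @return A \code{grid1d} object: list with \code{L}, \code{nx}, \code{dx}
#'   and node coordinates \code{x} spanning \code{[0, L]}.
#' @examples
#' g <- build_grid(200, 2001)  # dx = 0.1 mm
#' @export
build_grid <- function(L, nx) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a single positive finite number")
  if (!is.numeric(nx) || length(nx) != 1L || !is.finite(nx) || nx < 16 || nx != round(nx))
    stop("nx must be an integer >= 16")
  nx <- as.integer(nx)
  structure(list(L = L, nx = nx, dx = L / (nx - 1),
                 x = seq(0, L, length.out = nx)),
            class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> L = %g mm, nx = %d, dx = %g mm\n", x$L, x$nx, x$dx))
  invisible(x)
}

#' Discrete Laplacian with no-flux (Neumann) boundaries
#'
#' Standard 3-point second difference on a uniform grid; at the two
#' boundaries a ghost node mirrors the first interior neighbour, which
#' enforces a zero-gradient (no-flux) condition to second order.
#'
#' @param field numeric vector of nodal values.
#' @param grid a \code{\link{build_grid}} object.
#' @return Numeric vector of the same length: the discrete second derivative.
#' @export
laplacian_neumann <- function(field, grid) {
  nx <- grid$nx
  if (length(field) != nx)
    stop("field length (", length(field), ") does not match grid nx (", nx, ")")
  idx2 <- 1 / grid$dx^2
  lap <- numeric(nx)
  lap[2:(nx - 1)] <- (field[1:(nx - 2)] - 2 * field[2:(nx - 1)] + field[3:nx]) * idx2
  lap[1] <- 2 * (field[2] - field[1]) * idx2
  lap[nx] <- 2 * (field[nx - 1] - field[nx]) * idx2
  lap
}

# Flux-form divergence of a(x) * d(field)/dx with no-flux boundaries,
# using arithmetic-mean face coefficients. Used by the alternative
# "gradient" discretisation of the glioma diffusion term.
divergence_flux_neumann <- function(a, field, grid) {
  nx <- grid$nx
  idx2 <- 1 / grid$dx^2
  a_face <- (a[-nx] + a[-1]) / 2            # nx-1 faces
  flux <- a_face * (field[-1] - field[-nx]) # ~ a dF/dx * dx at faces
  out <- numeric(nx)
  out[2:(nx - 1)] <- (flux[2:(nx - 1)] - flux[1:(nx - 2)]) * idx2
  out[1] <- flux[1] * idx2                  # zero flux through left boundary
  out[nx] <- -flux[nx - 1] * idx2
  out
}

#' Initial state of a simulation
#'
#' The tumour is seeded at the left boundary: a smoothed indicator of the
#' segment \code{[0, eps]} of amplitude \code{rho0} with sigmoid steepness
#' \code{gamma} at \code{x = eps}. Vasculature and oxygen start uniform at
#' their normal-tissue values \code{v0} and \code{sigma0}.
#'
#' @param params a \code{\link{glioma_params}} object.
#' @param grid a \code{\link{build_grid}} object.
#' @return A \code{sim_state}: list with \code{t = 0} and nodal fields
#'   \code{rho}, \code{v}, \code{sigma}.
#' @export
initial_state <- function(params, grid) {
  if (params$eps >= grid$L)
    stop("initial tumour segment eps must be smaller than the domain length")
  structure(list(t = 0,
                 rho = params$rho0 * smooth_heaviside(grid$x - params$eps, params$gamma),
                 v = rep.int(params$v0, grid$nx),
                 sigma = rep.int(params$sigma0, grid$nx)),
            class = "sim_state")
}

# Clamp transient numerical overshoot of a field to [lo, hi]; error if the
# excursion exceeds `slack` (distinguishes roundoff from instability).
clamp_field <- function(f, lo, hi, slack, what, t = NA) {
  worst <- max(c(lo - min(f), max(f) - hi, 0))
  if (worst > slack)
    stop(structure(class = c("gliovasc_integration_error", "error", "condition"),
                   list(message = sprintf(
                     "%s out of bounds by %.3g at t = %s: integration unstable (refine grid or tolerances)",
                     what, worst, format(t)), call = NULL)))
  pmin(pmax(f, lo), hi)
}

# deSolve right-hand sides. State vectors are interleaved per node so the
# Jacobian is banded: variant I y = rho; variant II y = (rho_i, sigma_i);
# variant III y = (rho_i, v_i, sigma_i).
rhs_variant_I <- function(t, y, ctx) {
  p <- ctx$p
  rho <- clamp_field(y, 0, p$N, ctx$slack_rho, "rho", t)
  du <- if (ctx$composite) p$D * laplacian_neumann(rho, ctx$grid)
        else divergence_flux_neumann(rep.int(p$D, ctx$grid$nx), rho, ctx$grid)
  list(du + p$b * rho * (1 - rho / p$N))
}

rhs_variant_II <- function(t, y, ctx) {
  p <- ctx$p; grid <- ctx$grid
  y <- matrix(y, nrow = 2L)
  rho <- clamp_field(y[1L, ], 0, p$N, ctx$slack_rho, "rho", t)
  sigma <- clamp_field(y[2L, ], 0, p$lambda1 - 1e-12, ctx$slack_sigma, "sigma", t)
  sw <- switch_fractions(sigma, p)
  a_coef <- ctx$D_rho * sw$alpha
  du_rho <- if (ctx$composite) laplacian_neumann(a_coef * rho, grid)
            else divergence_flux_neumann(a_coef, rho, grid)
  d_rho <- du_rho + ctx$b_rho * sw$beta * rho * (1 - rho / p$N)
  d_sigma <- p$D_sigma * laplacian_neumann(sigma, grid) +
    p$h1 * ctx$v0 * (p$sigma0 - sigma) - p$h2 * rho * sigma
  list(as.vector(rbind(d_rho, d_sigma)))
}

rhs_variant_III <- function(t, y, ctx) {
  p <- ctx$p; grid <- ctx$grid
  y <- matrix(y, nrow = 3L)
  rho <- clamp_field(y[1L, ], 0, p$N, ctx$slack_rho, "rho", t)
  v <- clamp_field(y[2L, ], 0, 1, ctx$slack_v, "v", t)
  sigma <- clamp_field(y[3L, ], 0, p$lambda1 - 1e-12, ctx$slack_sigma, "sigma", t)
  sw <- switch_fractions(sigma, p)
  a_coef <- ctx$D_rho * sw$alpha
  du_rho <- if (ctx$composite) laplacian_neumann(a_coef * rho, grid)
            else divergence_flux_neumann(a_coef, rho, grid)
  d_rho <- du_rho + ctx$b_rho * sw$beta * rho * (1 - rho / p$N)
  occl <- p$g2 * v * rho^p$n
  if (ctx$occlusion_gate)
    occl <- occl * smooth_heaviside(p$N / 2 - rho, 0.01 * p$N)
  d_v <- p$D_v * laplacian_neumann(v, grid) +
    p$g1 * mm_activation(rho, sigma, v, p) * v * (1 - v) - occl
  d_sigma <- p$D_sigma * laplacian_neumann(sigma, grid) +
    p$h1 * v * (p$sigma0 - sigma) - p$h2 * rho * sigma
  list(as.vector(rbind(d_rho, d_v, d_sigma)))
}

#' Integrate a model variant to the final time
#'
#' Method-of-lines integration of the selected model variant on a uniform
#' 1-D grid with no-flux boundaries. Spatial derivatives use 3-point central
#' differences; time integration uses \code{deSolve}'s adaptive, stiff-capable
#' \code{lsoda} with an internally estimated banded Jacobian (the state is
#' interleaved per node to keep the band narrow). The run is deterministic:
#' identical inputs and solver settings reproduce the trajectory bitwise.
#'
#' Variant I holds oxygen and vasculature constant (classical
#' Fisher-Kolmogorov); variant II evolves oxygen at constant vasculature;
#' variant III evolves all three fields.
#'
#' @param params a \code{\link{glioma_params}} object.
#' @param variant model variant tag \code{"I"}, \code{"II"} or \code{"III"}.
#' @param grid a \code{\link{build_grid}} object; default
#'   \code{build_grid(params$L, 2001)} (dx = 0.1 mm at the default L).
#' @param output_times increasing times (days) at which snapshots are kept;
#'   default every 10 days from 0 to \code{params$T_f}.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param diffusion_form \code{"composite"} applies the Laplacian to the
#'   composite field \code{D_rho * alpha(sigma) * rho} (the form obtained by
#'   summing the two phenotype equations with Fickian migratory diffusion);
#'   \code{"gradient"} uses the flux form \code{div(D_rho alpha grad rho)}
#'   for sensitivity checks.
#' @param occlusion_gate see \code{\link{reaction_terms}}.
#' @param maxsteps maximum internal solver steps between outputs.
#' @return A \code{glioma_trajectory}: list with \code{times}, \code{states}
#'   (list of \code{sim_state}), \code{front_positions}, the \code{grid},
#'   \code{params}, \code{variant} and solver settings.
#' @examples
#' \donttest{
#' p <- glioma_params(D = 0.273, b = 0.0273, T_f = 100)
#' tr <- integrate_model(p, "I", build_grid(p$L, 801))
#' }
#' @export
integrate_model <- function(params, variant = c("III", "II", "I"),
                            grid = build_grid(params$L, 2001),
                            output_times = NULL,
                            rtol = 1e-6, atol = 1e-9,
                            diffusion_form = c("composite", "gradient"),
                            occlusion_gate = FALSE,
                            maxsteps = 1e5) {
  variant <- match.arg(variant)
  diffusion_form <- match.arg(diffusion_form)
  validate_glioma_params(params)
  if (is.null(output_times))   # 41 snapshots: every 10 days at the default T_f
    output_times <- seq(0, params$T_f, length.out = 41)
  if (is.unsorted(output_times, strictly = TRUE) ||
      min(output_times) < 0 || max(output_times) > params$T_f)
    stop("output_times must be strictly increasing within [0, T_f]")
  times <- if (output_times[1] > 0) c(0, output_times) else output_times

  s0 <- initial_state(params, grid)
  sw0 <- switch_fractions(params$sigma0, params)
  ctx <- list(p = params, grid = grid,
              D_rho = params$D / sw0$alpha, b_rho = params$b / sw0$beta,
              v0 = params$v0,
              composite = diffusion_form == "composite",
              occlusion_gate = occlusion_gate,
              slack_rho = 0.01 * params$N,
              slack_v = 0.01,
              slack_sigma = 0.01 * params$sigma0)

  setup <- switch(variant,
    I   = list(y0 = s0$rho, rhs = rhs_variant_I, bup = 1L, bdn = 1L),
    II  = list(y0 = as.vector(rbind(s0$rho, s0$sigma)), rhs = rhs_variant_II,
               bup = 3L, bdn = 2L),
    III = list(y0 = as.vector(rbind(s0$rho, s0$v, s0$sigma)), rhs = rhs_variant_III,
               bup = 5L, bdn = 3L))

  out <- deSolve::ode(y = setup$y0, times = times, func = setup$rhs, parms = ctx,
                      method = "lsoda", jactype = "bandint",
                      bandup = setup$bup, banddown = setup$bdn,
                      rtol = rtol, atol = atol, maxsteps = maxsteps)
  diagn <- attributes(out)[c("istate", "rstate")]
  if (nrow(out) < length(times))
    stop(structure(class = c("gliovasc_integration_error", "error", "condition"),
                   list(message = sprintf(
                     "integration failed at t ~ %.4g days (stiffness or step-size underflow)",
                     out[nrow(out), 1]), call = NULL)))

  # Unpack snapshots; clip solver roundoff onto the physical bounds, but
  # treat excursions well beyond the accumulated solver error as instability.
  tol <- 100 * rtol
  states <- lapply(seq_len(nrow(out)), function(i) {
    yi <- out[i, -1]
    ti <- unname(out[i, 1])
    st <- switch(variant,
      I = list(rho = yi, v = rep.int(params$v0, grid$nx),
               sigma = rep.int(params$sigma0, grid$nx)),
      II = {
        m <- matrix(yi, nrow = 2L)
        list(rho = m[1L, ], v = rep.int(params$v0, grid$nx), sigma = m[2L, ])
      },
      III = {
        m <- matrix(yi, nrow = 3L)
        list(rho = m[1L, ], v = m[2L, ], sigma = m[3L, ])
      })
    st$rho <- clamp_field(st$rho, 0, params$N, tol * params$N, "rho", ti)
    st$v <- clamp_field(st$v, 0, 1, tol, "v", ti)
    st$sigma <- clamp_field(st$sigma, 0, params$sigma0, tol * params$sigma0, "sigma", ti)
    structure(list(t = ti, rho = unname(st$rho), v = unname(st$v),
                   sigma = unname(st$sigma)), class = "sim_state")
  })
  if (output_times[1] > 0) {
    keep <- times %in% output_times
    states <- states[keep]
  }
  tms <- vapply(states, `[[`, numeric(1), "t")
  fp <- vapply(states, function(s) {
    tryCatch(front_position(s, grid), error = function(e) NA_real_)
  }, numeric(1))

  structure(list(times = tms, states = states, front_positions = fp,
                 grid = grid, params = params, variant = variant,
                 solver = list(method = "lsoda", rtol = rtol, atol = atol,
                               diffusion_form = diffusion_form,
                               occlusion_gate = occlusion_gate),
                 diagnostics = diagn),
            class = "glioma_trajectory")
}

#' @export
print.glioma_trajectory <- function(x, ...) {
  cat(sprintf("<glioma_trajectory> variant %s, %d snapshots over [0, %g] days\n",
              x$variant, length(x$times), max(x$times)))
  cat(sprintf("  grid: L = %g mm, nx = %d (dx = %g mm)\n",
              x$grid$L, x$grid$nx, x$grid$dx))
  fp <- x$front_positions
  if (any(is.finite(fp)))
    cat(sprintf("  front position: %.3g -> %.3g mm\n",
                fp[which(is.finite(fp))[1]], fp[length(fp)]))
  invisible(x)
}

#' Total mass (spatial integral) of a field
#'
#' Trapezoidal integral over the grid; used for conservation checks.
#'
#' @param field nodal values.
#' @param grid a \code{\link{build_grid}} object.
#' @return The integral, in field units times mm.
#' @export
field_mass <- function(field, grid) {
  trapz_uniform(field, grid$dx)
}

trapz_uniform <- function(f, dx) {
  n <- length(f)
  dx * (sum(f) - (f[1] + f[n]) / 2)
}
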