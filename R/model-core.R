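#' Oxygen-dependent phenotype switch fractions
#'
#' Under the migration/proliferation dichotomy (Go-or-Grow), glioma cells
#' switch between a migratory (hypoxic) and a proliferative (normoxic)
#' phenotype with linear, oxygen-dependent rates: migratory -> proliferative
#' at \code{lambda2 * sigma} and proliferative -> migratory at
#' \code{lambda1 - sigma}. Because intracellular switching is fast relative to
#' migration and proliferation, the two subpopulations equilibrate and the
#' migratory and proliferative fractions of the total density are
#' \deqn{\alpha(\sigma) = \frac{\lambda_1-\sigma}{(\lambda_1-\sigma)+\lambda_2\sigma},
#'       \qquad \beta(\sigma) = 1 - \alpha(\sigma).}
#' \code{alpha} decreases and \code{beta} increases with oxygen: hypoxic cells
#' migrate, normoxic cells proliferate.
#'
#' @param sigma oxygen concentration(s), nmol/mm; must lie in
#'   \code{[0, lambda1]}.
#' @param params a \code{\link{glioma_params}} object (uses \code{lambda1},
#'   \code{lambda2}).
#' @return A list with numeric components \code{alpha} and \code{beta}
#'   (same length as \code{sigma}), satisfying \code{alpha + beta == 1}.
#' @examples
#' switch_fractions(1, glioma_params())       # alpha = 0.5 at lambda1=2, lambda2=1
#' switch_fractions(0, glioma_params())$alpha # fully migratory under anoxia
#' @export
switch_fractions <- function(sigma, params) {
  l1 <- params$lambda1
  l2 <- params$lambda2
  if (any(sigma < 0) || any(sigma > l1))
    stop(structure(class = c("gliovasc_domain_error", "error", "condition"),
                   list(message = sprintf(
                     "oxygen concentration outside [0, lambda1] = [0, %g] (range [%g, %g]); solver blow-up or bad parameters",
                     l1, min(sigma), max(sigma)), call = sys.call(-1))))
  f21 <- l1 - sigma    # proliferative -> migratory
  f12 <- l2 * sigma    # migratory -> proliferative
  alpha <- f21 / (f21 + f12)
  list(alpha = alpha, beta = 1 - alpha)
}

#' Smoothed decreasing Heaviside step
#'
#' Continuous logistic approximation of the decreasing step H(xi) = 1 for
#' xi <= 0, 0 for xi > 0:
#' \deqn{\tilde H(\xi) = \frac{1}{1 + e^{\xi/\theta}}.}
#' Converges pointwise (xi != 0) to the sharp step as \code{theta -> 0} and
#' equals 1/2 at \code{xi = 0}. Used to gate hypoxic pro-angiogenic factor
#' production (argument \code{sigma - sigma_hat}) and to shape the initial
#' tumour profile (argument \code{x - eps}).
#'
#' @param xi signed argument(s).
#' @param theta steepness parameter, > 0, in the units of \code{xi}.
#' @return Values in (0, 1), same length as \code{xi}.
#' @export
smooth_heaviside <- function(xi, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("theta must be a single positive number")
  1 / (1 + exp(xi / theta))
}

#' Michaelis-Menten vasculature activation
#'
#' Saturating activation of functional vessel formation by the effective
#' pro-angiogenic factor concentration at quasi-steady state. Hypoxic glioma
#' cells (oxygen below \code{sigma_hat}) produce the factor in proportion to
#' their density; endothelial cells take it up in proportion to the functional
#' vasculature, giving
#' \deqn{M(\rho,\sigma,v)=\frac{\rho \tilde H(\sigma-\hat\sigma)}
#'                             {\rho \tilde H(\sigma-\hat\sigma) + K v}}
#' with \code{M = 0} at the degenerate point where both numerator and
#' denominator vanish (no factor sources and no vessels).
#'
#' @param rho glioma cell density, cells/mm.
#' @param sigma oxygen concentration, nmol/mm.
#' @param v functional vasculature density, dimensionless.
#' @param params a \code{\link{glioma_params}} object (uses \code{sigma_hat},
#'   \code{theta}, \code{K}).
#' @return Activation in [0, 1], same length as the inputs.
#' @export
mm_activation <- function(rho, sigma, v, params) {
  num <- rho * smooth_heaviside(sigma - params$sigma_hat, params$theta)
  den <- num + params$K * v
  m <- ifelse(den > 0, num / den, 0)
  m
}

#' Non-diffusive reaction terms of the model hierarchy
#'
#' Evaluates the local (reaction) right-hand sides of the coupled system for
#' one of the three model variants:
#' \describe{
#'   \item{I}{Fisher-Kolmogorov: logistic glioma growth at constant oxygen
#'     \code{sigma0} and vasculature \code{v0}; v- and sigma-rates are 0.}
#'   \item{II}{Go-or-Grow with oxygen dynamics at constant vasculature
#'     (\code{g1 = g2 = 0}); v-rate is 0.}
#'   \item{III}{Full glioma-vasculature interplay with angiogenesis and
#'     vaso-occlusion.}
#' }
#' The glioma reaction is \code{b_rho * beta(sigma) * rho * (1 - rho/N)} with
#' the normalisation \code{b_rho = b / beta(sigma0)} so that Model I reduces
#' exactly to logistic growth at rate \code{b}. The vasculature reaction is
#' logistic formation activated by \code{\link{mm_activation}} minus the
#' power-law vaso-occlusion sink \code{g2 * v * rho^n}; the steep exponent
#' (default n = 6) makes occlusion negligible below half carrying capacity.
#' The oxygen reaction is vascular supply \code{h1 * v * (sigma0 - sigma)}
#' minus consumption \code{h2 * rho * sigma}.
#'
#' @param state a list with numeric fields \code{rho}, \code{v}, \code{sigma}
#'   (equal lengths).
#' @param params a \code{\link{glioma_params}} object.
#' @param variant model variant tag: \code{"I"}, \code{"II"} or \code{"III"}.
#' @param occlusion_gate if \code{TRUE}, multiply the vaso-occlusion sink by a
#'   smooth gate \code{smooth_heaviside(N/2 - rho, 0.01 * N)} enforcing a hard
#'   half-capacity onset; off by default (the power law already realises it).
#' @return A list with fields \code{rho}, \code{v}, \code{sigma}: reaction
#'   rates for each field (v and sigma identically 0 where the variant holds
#'   them constant).
#' @export
reaction_terms <- function(state, params, variant = c("III", "II", "I"),
                           occlusion_gate = FALSE) {
  variant <- match.arg(variant)
  rho <- state$rho; v <- state$v; sigma <- state$sigma
  if (any(rho < 0) || any(v < 0) || any(sigma < 0))
    stop(structure(class = c("gliovasc_domain_error", "error", "condition"),
                   list(message = "negative field values passed to reaction_terms",
                        call = sys.call(-1))))
  zero <- numeric(length(rho))

  beta0 <- switch_fractions(params$sigma0, params)$beta
  b_rho <- params$b / beta0
  beta_sig <- if (variant == "I") rep.int(beta0, length(rho))
              else switch_fractions(sigma, params)$beta
  d_rho <- b_rho * beta_sig * rho * (1 - rho / params$N)

  d_sigma <- if (variant == "I") zero
             else params$h1 * v * (params$sigma0 - sigma) - params$h2 * rho * sigma

  if (variant == "III") {
    occl <- params$g2 * v * rho^params$n
    if (occlusion_gate)
      occl <- occl * smooth_heaviside(params$N / 2 - rho, 0.01 * params$N)
    d_v <- params$g1 * mm_activation(rho, sigma, v, params) * v * (1 - v) - occl
  } else {
    d_v <- zero
  }

  list(rho = d_rho, v = d_v, sigma = d_sigma)
}

#' Spatially uniform oxygen fixed point
#'
#' Closed-form long-time limit of the uniform oxygen dynamics
#' \code{dsigma/dt = h1 v (sigma0 - sigma) - h2 rho sigma} at constant glioma
#' density and vasculature:
#' \deqn{\sigma^* = \frac{h_1 v \sigma_0}{h_1 v + h_2 \rho}.}
#'
#' @param rho glioma cell density, cells/mm.
#' @param v functional vasculature density, dimensionless.
#' @param params a \code{\link{glioma_params}} object.
#' @return The equilibrium oxygen concentration, nmol/mm.
#' @examples
#' homogeneous_oxygen_steady_state(0, 0.5, glioma_params())   # = sigma0
#' @export
homogeneous_oxygen_steady_state <- function(rho, v, params) {
  den <- params$h1 * v + params$h2 * rho
  if (any(den <= 0))
    stop("degenerate input: no oxygen supply (h1*v) and no consumption (h2*rho)")
  params$h1 * v * params$sigma0 / den
}
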