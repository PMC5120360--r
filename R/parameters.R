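#' Model parameters for the glioma-vasculature interplay model
#'
#' Constructs and validates the full parameter set of the coupled
#' glioma / vasculature / oxygen reaction-diffusion system. Defaults are the
#' published baseline parameterisation of the model; the intrinsic glioma
#' diffusion and proliferation rates \code{D} and \code{b} default to the
#' geometric midpoints of their two-decade physiological ranges.
#'
#' @param D intrinsic glioma cell diffusion rate, mm^2/day. Physiological
#'   range \code{[2.73e-3, 2.73e-1]}.
#' @param b intrinsic glioma cell proliferation rate, 1/day. Physiological
#'   range \code{[2.73e-4, 2.73e-2]}.
#' @param N brain tissue carrying capacity, cells/mm.
#' @param sigma0 physiological oxygen concentration in normal brain tissue,
#'   nmol/mm.
#' @param lambda1 phenotypic switching parameter (proliferative to migratory
#'   rate is \code{lambda1 - sigma}), nmol/mm. Must exceed \code{sigma0}.
#' @param lambda2 phenotypic switching parameter (migratory to proliferative
#'   rate is \code{lambda2 * sigma}), dimensionless.
#' @param D_sigma oxygen diffusion rate, mm^2/day.
#' @param h1 oxygen supply rate (vessel permeability coefficient), 1/day.
#' @param h2 glioma cell oxygen consumption rate, mm/cell/day. May be zero
#'   (Model I limit).
#' @param D_v vasculature dispersal rate, mm^2/day.
#' @param g1 functional vasculature formation rate, 1/day. May be zero
#'   (Model II limit).
#' @param sigma_hat hypoxic oxygen threshold below which glioma cells secrete
#'   pro-angiogenic factors, nmol/mm.
#' @param K pro-angiogenic factor concentration at which vessel formation is
#'   half-maximal, nmol/mm.
#' @param g2 vaso-occlusion rate, cell^-n mm^n / day. May be zero
#'   (Model II limit).
#' @param n vaso-occlusion degree (power-law exponent on glioma density),
#'   positive integer.
#' @param theta steepness of the smoothed Heaviside gate on hypoxic
#'   pro-angiogenic production, nmol/mm.
#' @param v0 initial (normal-tissue) functional vasculature density,
#'   dimensionless in (0, 1].
#' @param rho0 initial glioma density amplitude, cells/mm, in (0, N].
#'   The default seeds the tumour at a tenth of carrying capacity, well below
#'   the half-capacity onset of vaso-occlusion, so that vessel collapse is an
#'   emergent consequence of proliferation rather than of the seed itself.
#' @param eps length of the initially seeded tumour segment, mm.
#' @param gamma steepness of the initial density profile at \code{x = eps}, mm.
#' @param L length of the one-dimensional computational domain, mm.
#' @param T_f final simulation time, days.
#'
#' @return An object of class \code{glioma_params}: a validated named list of
#'   the above fields.
#' @examples
#' p <- glioma_params()
#' p$D
#' glioma_params(D = 0.273, b = 0.0273)
#' @export
glioma_params <- function(D = sqrt(2.73e-3 * 2.73e-1),
                          b = sqrt(2.73e-4 * 2.73e-2),
                          N = 1e2,
                          sigma0 = 1.0,
                          lambda1 = 2.0,
                          lambda2 = 1.0,
                          D_sigma = 1.51e2,
                          h1 = 3.37e-1,
                          h2 = 5.73e-3,
                          D_v = 5.0e-4,
                          g1 = 1e-1,
                          sigma_hat = 2.5e-1,
                          K = 1.0,
                          g2 = 5.0e-13,
                          n = 6L,
                          theta = 0.01,
                          v0 = 0.5,
                          rho0 = 10,
                          eps = 2,
                          gamma = 0.1,
                          L = 200,
                          T_f = 400) {
  p <- list(D = D, b = b, N = N, sigma0 = sigma0,
            lambda1 = lambda1, lambda2 = lambda2,
            D_sigma = D_sigma, h1 = h1, h2 = h2,
            D_v = D_v, g1 = g1, sigma_hat = sigma_hat, K = K,
            g2 = g2, n = n, theta = theta,
            v0 = v0, rho0 = rho0, eps = eps, gamma = gamma,
            L = L, T_f = T_f)
  validate_glioma_params(p)
  structure(p, class = "glioma_params")
}

#' Validate a glioma parameter set
#'
#' Checks all physical invariants of the parameter set and reports every
#' violation found, not only the first.
#'
#' @param p a named list or \code{glioma_params} object.
#' @return Invisibly \code{TRUE}; signals a condition of class
#'   \code{gliovasc_param_error} listing all violations otherwise.
#' @export
validate_glioma_params <- function(p) {
  errs <- character(0)
  need <- names(formals(glioma_params))
  missing_f <- setdiff(need, names(p))
  if (length(missing_f)) {
    errs <- c(errs, paste0("missing fields: ", paste(missing_f, collapse = ", ")))
  } else {
    num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1))
    if (!all(num)) {
      errs <- c(errs, paste0("non-finite or non-scalar fields: ",
                             paste(need[!num], collapse = ", ")))
    } else {
      # g1, g2, h2 may be zero (model-hierarchy limits), as may b (the
      # pure-diffusion limit used for conservation diagnostics)
      may_zero <- c("g1", "g2", "h2", "b")
      strict <- setdiff(need, may_zero)
      bad <- strict[vapply(p[strict], function(x) x <= 0, logical(1))]
      if (length(bad))
        errs <- c(errs, paste0("fields must be strictly positive: ",
                               paste(bad, collapse = ", ")))
      badz <- may_zero[vapply(p[may_zero], function(x) x < 0, logical(1))]
      if (length(badz))
        errs <- c(errs, paste0("fields must be non-negative: ",
                               paste(badz, collapse = ", ")))
      if (p$lambda1 <= p$sigma0)
        errs <- c(errs, "lambda1 > sigma0 required (switching rate lambda1 - sigma must stay positive)")
      if (p$v0 > 1)
        errs <- c(errs, "v0 must lie in (0, 1]")
      if (p$rho0 > p$N)
        errs <- c(errs, "rho0 must lie in (0, N]")
      if (p$n < 1 || p$n != round(p$n))
        errs <- c(errs, "n must be a positive integer")
      if (p$eps >= p$L)
        errs <- c(errs, "eps must be smaller than the domain length L")
    }
  }
  if (length(errs)) {
    stop(structure(class = c("gliovasc_param_error", "error", "condition"),
                   list(message = paste0("invalid model parameters:\n  - ",
                                         paste(errs, collapse = "\n  - ")),
                        call = sys.call(-1))))
  }
  invisible(TRUE)
}

#' @export
print.glioma_params <- function(x, ...) {
  cat("<glioma_params>\n")
  cat(sprintf("  glioma:      D = %.4g mm^2/day, b = %.4g 1/day, N = %g cells/mm\n",
              x$D, x$b, x$N))
  cat(sprintf("  switching:   lambda1 = %g, lambda2 = %g, sigma0 = %g\n",
              x$lambda1, x$lambda2, x$sigma0))
  cat(sprintf("  oxygen:      D_sigma = %g, h1 = %g, h2 = %.4g\n",
              x$D_sigma, x$h1, x$h2))
  cat(sprintf("  vasculature: D_v = %g, g1 = %g, g2 = %.4g, n = %d, K = %g, sigma_hat = %g\n",
              x$D_v, x$g1, x$g2, as.integer(x$n), x$K, x$sigma_hat))
  cat(sprintf("  initial:     rho0 = %g, v0 = %g, eps = %g mm, gamma = %g mm\n",
              x$rho0, x$v0, x$eps, x$gamma))
  cat(sprintf("  domain:      L = %g mm, T_f = %g days\n", x$L, x$T_f))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a revalidated copy of \code{p} with the named fields replaced.
#'
#' @param p a \code{glioma_params} object.
#' @param ... named replacement values, e.g. \code{h2 = 5.73e-2}.
#' @return A new \code{glioma_params} object.
#' @examples
#' p <- update_params(glioma_params(), h2 = 0, g1 = 0, g2 = 0)
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- repl
  validate_glioma_params(p)
  structure(p, class = "glioma_params")
}
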