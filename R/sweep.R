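#' Logarithmically spaced values
#'
#' @param lo,hi positive endpoints.
#' @param n number of values.
#' @return \code{n} values geometrically spaced from \code{lo} to \code{hi}.
#' @export
log_spaced <- function(lo, hi, n) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Default (D, b) parameter-plane grid
#'
#' Log-spaced grids over the physiological two-decade ranges of the intrinsic
#' glioma diffusion rate, D in [2.73e-3, 2.73e-1] mm^2/day, and proliferation
#' rate, b in [2.73e-4, 2.73e-2] 1/day.
#'
#' @param n cells per axis.
#' @return List with \code{D_values} and \code{b_values}.
#' @export
db_plane_grid <- function(n = 8) {
  list(D_values = log_spaced(2.73e-3, 2.73e-1, n),
       b_values = log_spaced(2.73e-4, 2.73e-2, n))
}

#' Specify a (D, b)-plane sweep
#'
#' Defines a full-factorial simulation campaign over intrinsic glioma
#' diffusion and proliferation rates at one or more levels of a varied
#' microenvironmental parameter: the oxygen consumption rate \code{h2}
#' (Model II or III) or the vaso-occlusion rate \code{g2} (Model III only).
#' All numerical settings are frozen in the spec so that every cell runs
#' under identical conditions and results are order-independent.
#'
#' @param D_values,b_values strictly increasing grids of intrinsic rates.
#' @param varied_name \code{"h2"} or \code{"g2"}.
#' @param varied_values strictly increasing levels of the varied parameter.
#' @param base a \code{\link{glioma_params}} object giving every other
#'   parameter.
#' @param variant \code{"II"} or \code{"III"}.
#' @param L,T_f domain length (mm) and horizon (days) used for every cell.
#'   Regime maps need the slowest mechanism on the grid -- logistic growth to
#'   the half-capacity occlusion threshold, roughly \code{2.2/b} days -- to
#'   complete over the upper half of the b range, and the fastest fronts
#'   (~0.17 mm/day) to stay clear of the right boundary, hence the defaults
#'   (1000 days, 300 mm).
#' @param dx node spacing, mm (sweeps run at 0.25 mm).
#' @param output_every snapshot interval, days.
#' @param rtol,atol solver tolerances.
#' @return A \code{sweep_spec} object.
#' @export
sweep_spec <- function(D_values, b_values,
                       varied_name = c("h2", "g2"),
                       varied_values,
                       base = glioma_params(),
                       variant = c("II", "III", "I"),
                       L = 300, T_f = 1000, dx = 0.25,
                       output_every = 10,
                       rtol = 1e-6, atol = 1e-9) {
  varied_name <- match.arg(varied_name)
  variant <- match.arg(variant)
  if (is.unsorted(D_values, strictly = TRUE) || is.unsorted(b_values, strictly = TRUE))
    stop("D_values and b_values must be strictly increasing")
  if (is.unsorted(varied_values))  # repeats permitted: their diff maps are 0
    stop("varied_values must be non-decreasing")
  if (variant == "II" && varied_name != "h2")
    stop("variant II holds the vasculature constant: only h2 can be varied")
  base <- update_params(base, L = L, T_f = T_f)
  nx <- as.integer(round(L / dx)) + 1L
  structure(list(D_values = D_values, b_values = b_values,
                 varied_name = varied_name, varied_values = varied_values,
                 base = base, variant = variant,
                 nx = nx, output_every = output_every,
                 rtol = rtol, atol = atol),
            class = "sweep_spec")
}

#' Run a (D, b)-plane sweep
#'
#' Integrates the model once per (varied value, D, b) cell and collects the
#' invasion observables into a tidy map. Cells whose integration fails carry
#' their error message in the \code{status} column, never a silent default.
#' Runs are independent and deterministic, so execution order cannot affect
#' the result. Difference maps between consecutive varied levels are
#' computed for every observable.
#'
#' @param spec a \code{\link{sweep_spec}}.
#' @param progress print one line per completed cell.
#' @return A \code{sweep_result}: list with \code{map} (one row per cell:
#'   \code{varied_name}, \code{varied_value}, \code{D}, \code{b}, the four
#'   observables, \code{status}), \code{diff} (pairwise differences between
#'   consecutive varied levels), and the \code{spec}.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- build_grid(spec$base$L, spec$nx)
  cells <- expand.grid(b = spec$b_values, D = spec$D_values,
                       level = seq_along(spec$varied_values),
                       KEEP.OUT.ATTRS = FALSE)
  cells$varied_value <- spec$varied_values[cells$level]
  out_times <- seq(0, spec$base$T_f, by = spec$output_every)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    repl <- list(D = ci$D, b = ci$b)
    repl[[spec$varied_name]] <- ci$varied_value
    p <- do.call(update_params, c(list(spec$base), repl))
    res <- tryCatch({
      tr <- integrate_model(p, spec$variant, grid, output_times = out_times,
                            rtol = spec$rtol, atol = spec$atol)
      ob <- observables(tr)
      data.frame(varied_name = spec$varied_name, level = ci$level,
                 varied_value = ci$varied_value,
                 D = ci$D, b = ci$b,
                 front_speed = ob$front_speed,
                 infiltration_width = ob$infiltration_width,
                 D_eff = ob$D_eff, b_eff = ob$b_eff,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(varied_name = spec$varied_name, level = ci$level,
                 varied_value = ci$varied_value,
                 D = ci$D, b = ci$b,
                 front_speed = NA_real_, infiltration_width = NA_real_,
                 D_eff = NA_real_, b_eff = NA_real_,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    if (progress)
      message(sprintf("[%d/%d] %s=%.3g D=%.3g b=%.3g -> %s",
                      i, nrow(cells), spec$varied_name, ci$varied_value,
                      ci$D, ci$b, res$status))
    res
  })
  map <- do.call(rbind, rows)
  structure(list(map = map, diff = sweep_diff_maps(map), spec = spec),
            class = "sweep_result")
}

# Differences of every observable between consecutive varied levels,
# cell-wise over the (D, b) grid.
sweep_diff_maps <- function(map) {
  if (is.null(map$level)) map$level <- match(map$varied_value, sort(unique(map$varied_value)))
  lv <- sort(unique(map$level))
  if (length(lv) < 2) return(NULL)
  obs <- c("front_speed", "infiltration_width", "D_eff", "b_eff")
  out <- lapply(seq_len(length(lv) - 1), function(k) {
    lo <- map[map$level == lv[k], ]
    hi <- map[map$level == lv[k + 1], ]
    key <- c("D", "b")
    m <- merge(lo, hi, by = key, suffixes = c("_lo", "_hi"))
    d <- m[key]
    d$level_lo <- m$varied_value_lo; d$level_hi <- m$varied_value_hi
    for (o in obs) d[[paste0("d_", o)]] <- m[[paste0(o, "_hi")]] - m[[paste0(o, "_lo")]]
    d$base_front_speed <- m$front_speed_lo
    d$base_infiltration_width <- m$infiltration_width_lo
    d
  })
  do.call(rbind, out)
}

#' Signed change of an observable between the extreme varied levels
#'
#' For each (D, b) cell, the change of the observable from the lowest to the
#' highest level of the varied parameter, classified into sign {-1, 0, +1}.
#' Changes smaller than \code{dead_zone} times the cell's base value count as
#' "no change", absorbing numerical error in the regime classification.
#'
#' @param result a \code{\link{run_sweep}} result.
#' @param observable one of \code{"front_speed"}, \code{"infiltration_width"},
#'   \code{"D_eff"}, \code{"b_eff"}.
#' @param dead_zone relative no-change band (default 0.5\%).
#' @return data.frame with \code{D}, \code{b}, \code{delta}, \code{base},
#'   \code{sign}.
#' @export
diff_sign_map <- function(result, observable = "front_speed", dead_zone = 0.005) {
  stopifnot(inherits(result, "sweep_result"))
  map <- result$map
  if (is.null(map$level)) map$level <- match(map$varied_value, sort(unique(map$varied_value)))
  lo <- map[map$level == min(map$level), ]
  hi <- map[map$level == max(map$level), ]
  m <- merge(lo, hi, by = c("D", "b"), suffixes = c("_lo", "_hi"))
  delta <- m[[paste0(observable, "_hi")]] - m[[paste0(observable, "_lo")]]
  base <- m[[paste0(observable, "_lo")]]
  sgn <- ifelse(is.na(delta), NA_integer_,
                ifelse(abs(delta) < dead_zone * abs(base), 0L, as.integer(sign(delta))))
  data.frame(D = m$D, b = m$b, delta = delta, base = base, sign = sgn)
}

#' Critical proliferation rate under oxygen-consumption modulation
#'
#' Variations in the glioma oxygen-consumption rate h2 affect the front speed
#' in opposite directions on the two sides of a critical intrinsic
#' proliferation rate b*: slowly proliferating tumours (b < b*) invade faster
#' at higher h2, rapidly proliferating ones (b > b*) slow down. This
#' estimator locates, in each D column of the sweep, the sign change of the
#' front-speed difference along increasing b by bracketing between adjacent
#' grid values, and reports the median bracket across columns with its
#' min/max spread.
#'
#' @param result a \code{\link{run_sweep}} result from an h2 sweep with at
#'   least 2 levels.
#' @param observable observable whose sign change is tracked (front speed).
#' @param dead_zone see \code{\link{diff_sign_map}}.
#' @return A list: \code{b_star} (geometric mid of the median bracket),
#'   \code{bracket} (median lower/upper bound across columns), \code{spread}
#'   (min/max over columns), \code{per_column} data.frame, \code{no_crossing}
#'   flag, \code{ambiguous} flag (multiple crossings in some column).
#' @export
estimate_critical_b <- function(result, observable = "front_speed",
                                dead_zone = 0.005) {
  sm <- diff_sign_map(result, observable, dead_zone)
  Ds <- sort(unique(sm$D))
  per <- lapply(Ds, function(Di) {
    col <- sm[sm$D == Di, ]
    col <- col[order(col$b), ]
    s <- col$sign
    nz <- which(s != 0 & !is.na(s))
    if (length(nz) < 2) return(NULL)
    # crossings: consecutive nonzero signs that differ (+ -> - expected)
    br <- list(); amb <- FALSE
    for (k in seq_len(length(nz) - 1)) {
      i1 <- nz[k]; i2 <- nz[k + 1]
      if (s[i1] > 0 && s[i2] < 0)
        br[[length(br) + 1]] <- c(col$b[i1], col$b[i2])
      else if (s[i1] < 0 && s[i2] > 0)
        amb <- TRUE
    }
    if (!length(br)) return(NULL)
    if (length(br) > 1) amb <- TRUE
    data.frame(D = Di, b_lo = br[[1]][1], b_hi = br[[1]][2],
               n_brackets = length(br), ambiguous = amb)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per) || !nrow(per))
    return(list(b_star = NA_real_, bracket = c(NA_real_, NA_real_),
                spread = c(NA_real_, NA_real_), per_column = NULL,
                no_crossing = TRUE, ambiguous = FALSE))
  bracket <- c(stats::median(per$b_lo), stats::median(per$b_hi))
  list(b_star = sqrt(bracket[1] * bracket[2]),
       bracket = bracket,
       spread = c(min(per$b_lo), max(per$b_hi)),
       per_column = per,
       no_crossing = FALSE,
       ambiguous = any(per$ambiguous) || any(per$n_brackets > 1))
}

#' Critical proliferation rate and proliferation/diffusion ratio under
#' vaso-occlusion modulation
#'
#' Under increasing vaso-occlusion rate g2 (Model III), the front speed
#' increases only inside a region of the (D, b) plane delimited from below by
#' a critical proliferation rate b+ (tumours with b < b+ never reach the
#' densities that occlude vessels) and laterally by an approximately linear
#' boundary b = Lambda+ * D: speed-up occurs for proliferation/diffusion
#' ratios b/D below Lambda+, where the occlusion-triggered migratory response
#' outruns the loss of proliferation. This estimator classifies each cell by
#' the sign of the front-speed change, takes b+ as the smallest b whose row
#' contains a speed-up cell, collects the sign-boundary midpoints along D
#' (last slow-down to first speed-up cell) in every row with b >= b+, and
#' fits the through-origin line b = Lambda+ * D to them by least squares.
#'
#' @param result a \code{\link{run_sweep}} result from a g2 sweep with at
#'   least 2 levels.
#' @param dead_zone see \code{\link{diff_sign_map}}.
#' @return A list: \code{b_plus}, \code{b_plus_bracket} (the b grid value
#'   below the first speed-up row, and that row's b), \code{lambda_plus}
#'   (1/mm^2), \code{boundary} data.frame of midpoints, \code{residuals} of
#'   the linear fit (in b units), \code{no_region} flag.
#' @export
estimate_lambda_plus <- function(result, dead_zone = 0.005) {
  sm <- diff_sign_map(result, "front_speed", dead_zone)
  bs <- sort(unique(sm$b))
  pos_rows <- vapply(bs, function(bi) any(sm$sign[sm$b == bi] > 0, na.rm = TRUE),
                     logical(1))
  if (!any(pos_rows))
    return(list(b_plus = NA_real_, b_plus_bracket = c(NA_real_, NA_real_),
                lambda_plus = NA_real_, boundary = NULL, residuals = NULL,
                no_region = TRUE))
  k <- which(pos_rows)[1]
  b_plus <- bs[k]
  b_plus_bracket <- c(if (k > 1) bs[k - 1] else NA_real_, bs[k])
  boundary <- lapply(bs[pos_rows], function(bi) {
    row <- sm[sm$b == bi, ]
    row <- row[order(row$D), ]
    pos <- which(row$sign > 0)
    if (!length(pos)) return(NULL)
    jmin <- min(pos)   # speed-up occupies the high-D (low b/D) side of the row
    if (jmin == 1) return(NULL)  # positive region extends past the grid
    data.frame(b = bi, D_mid = sqrt(row$D[jmin - 1] * row$D[jmin]))
  })
  boundary <- do.call(rbind, boundary[!vapply(boundary, is.null, logical(1))])
  if (is.null(boundary) || nrow(boundary) < 3)
    stop(structure(class = c("gliovasc_resolution_error", "error", "condition"),
                   list(message = "fewer than 3 sign-boundary points: sweep grid too coarse to fit Lambda+",
                        call = NULL)))
  lambda_plus <- sum(boundary$b * boundary$D_mid) / sum(boundary$D_mid^2)
  res <- boundary$b - lambda_plus * boundary$D_mid
  list(b_plus = b_plus, b_plus_bracket = b_plus_bracket,
       lambda_plus = lambda_plus, boundary = boundary, residuals = res,
       no_region = FALSE)
}

#' @export
print.sweep_result <- function(x, ...) {
  m <- x$map
  cat(sprintf("<sweep_result> variant %s, %d x %d (D, b) cells, %s in {%s}\n",
              x$spec$variant, length(x$spec$D_values), length(x$spec$b_values),
              x$spec$varied_name,
              paste(signif(x$spec$varied_values, 3), collapse = ", ")))
  cat(sprintf("  %d/%d cells ok\n", sum(m$status == "ok"), nrow(m)))
  invisible(x)
}
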