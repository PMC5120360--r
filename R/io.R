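#' Load a run configuration
#'
#' Reads a YAML configuration describing one run (or sweep) of the
#' simulator. Recognised top-level keys: \code{variant} ("I"/"II"/"III"),
#' \code{nx}, \code{output_every} (days), \code{outdir}, \code{log_level},
#' \code{params} (a map of \code{\link{glioma_params}} fields) and
#' \code{sweep} (a map with \code{D_values}, \code{b_values},
#' \code{varied_name}, \code{varied_values}, optional \code{nx},
#' \code{output_every}). Missing keys take the package defaults; unknown keys
#' are rejected. All validation violations are reported together, not only
#' the first. An empty file yields the full-default configuration
#' (variant III, baseline parameters).
#'
#' @param path path to a YAML file.
#' @return A \code{run_config}: list with \code{params}
#'   (\code{glioma_params}), \code{variant}, \code{nx}, \code{output_every},
#'   \code{outdir}, \code{log_level}, \code{sweep} (or \code{NULL}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw, src = path)
}

build_config <- function(raw, src = "<config>") {
  errs <- character(0)
  known_top <- c("variant", "nx", "output_every", "outdir", "log_level",
                 "params", "sweep")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level key(s): ", paste(unknown, collapse = ", ")))

  par_fields <- names(formals(glioma_params))
  praw <- raw$params
  if (!is.null(praw)) {
    unknown_p <- setdiff(names(praw), par_fields)
    if (length(unknown_p))
      errs <- c(errs, paste0("unknown params key(s): ", paste(unknown_p, collapse = ", ")))
    praw <- praw[intersect(names(praw), par_fields)]
  }
  params <- tryCatch(do.call(glioma_params, as.list(praw)),
                     error = function(e) {
                       errs <<- c(errs, conditionMessage(e))
                       NULL
                     })
  variant <- raw$variant %||% "III"
  if (!variant %in% c("I", "II", "III"))
    errs <- c(errs, paste0("variant must be one of I, II, III (got ", variant, ")"))
  nx <- raw$nx %||% 2001
  if (!is.numeric(nx) || nx < 16)
    errs <- c(errs, "nx must be an integer >= 16")
  output_every <- raw$output_every %||% 10
  if (!is.numeric(output_every) || output_every <= 0)
    errs <- c(errs, "output_every must be positive")

  sweep <- NULL
  if (!is.null(raw$sweep)) {
    known_sw <- c("D_values", "b_values", "varied_name", "varied_values",
                  "L", "T_f", "dx", "output_every", "variant")
    unknown_s <- setdiff(names(raw$sweep), known_sw)
    if (length(unknown_s))
      errs <- c(errs, paste0("unknown sweep key(s): ", paste(unknown_s, collapse = ", ")))
    sweep <- raw$sweep[intersect(names(raw$sweep), known_sw)]
  }
  if (length(errs))
    stop(structure(class = c("gliovasc_config_error", "error", "condition"),
                   list(message = paste0("invalid configuration (", src, "):\n  - ",
                                         paste(errs, collapse = "\n  - ")),
                        call = NULL)))
  structure(list(params = params, variant = variant, nx = as.integer(nx),
                 output_every = output_every,
                 outdir = raw$outdir %||% ".",
                 log_level = raw$log_level %||% "info",
                 sweep = sweep),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' The written file round-trips: \code{load_config(write_config(cfg, f))}
#' reproduces \code{cfg}.
#'
#' @param cfg a \code{run_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(variant = cfg$variant, nx = cfg$nx,
              output_every = cfg$output_every, outdir = cfg$outdir,
              log_level = cfg$log_level,
              params = unclass(cfg$params))
  if (!is.null(cfg$sweep)) out$sweep <- cfg$sweep
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Persist a trajectory to a self-describing directory
#'
#' Writes plain-text artefacts sufficient to reproduce and re-analyse a run:
#' \code{fields.csv} (long format: t, x, rho, v, sigma), \code{front.csv}
#' (per-output-time front position), \code{config.yaml} (full parameter
#' echo) and \code{meta.json} (grid, solver settings, package version).
#'
#' @param trajectory a \code{glioma_trajectory}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "glioma_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- trajectory$grid
  fields <- do.call(rbind, lapply(trajectory$states, function(s)
    data.frame(t = s$t, x = g$x, rho = s$rho, v = s$v, sigma = s$sigma)))
  utils::write.csv(fields, file.path(dir, "fields.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trajectory$times,
                              front_position = trajectory$front_positions),
                   file.path(dir, "front.csv"), row.names = FALSE)
  cfg <- structure(list(params = trajectory$params, variant = trajectory$variant,
                        nx = g$nx, output_every = if (length(trajectory$times) > 1)
                          diff(trajectory$times)[1] else trajectory$params$T_f,
                        outdir = dir, log_level = "info", sweep = NULL),
                   class = "run_config")
  write_config(cfg, file.path(dir, "config.yaml"))
  meta <- list(package = "gliovasc",
               version = as.character(utils::packageVersion("gliovasc")),
               variant = trajectory$variant,
               grid = list(L = g$L, nx = g$nx, dx = g$dx),
               solver = trajectory$solver,
               times = trajectory$times)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a persisted trajectory
#'
#' @param dir a directory written by \code{\link{write_trajectory}}.
#' @return A \code{glioma_trajectory}.
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- load_config(file.path(dir, "config.yaml"))
  grid <- build_grid(meta$grid$L, meta$grid$nx)
  fields <- utils::read.csv(file.path(dir, "fields.csv"))
  front <- utils::read.csv(file.path(dir, "front.csv"))
  states <- lapply(split(fields, fields$t), function(df) {
    df <- df[order(df$x), ]
    structure(list(t = df$t[1], rho = df$rho, v = df$v, sigma = df$sigma),
              class = "sim_state")
  })
  states <- unname(states[order(vapply(states, `[[`, numeric(1), "t"))])
  structure(list(times = unname(vapply(states, `[[`, numeric(1), "t")),
                 states = states,
                 front_positions = front$front_position[order(front$t)],
                 grid = grid, params = cfg$params, variant = meta$variant,
                 solver = meta$solver, diagnostics = NULL),
            class = "glioma_trajectory")
}

#' Persist a sweep result
#'
#' Writes the tidy per-cell map (\code{sweep.csv}), the consecutive-level
#' difference maps (\code{diff.csv}) and a JSON sidecar
#' (\code{thresholds.json}) holding the estimated critical thresholds and
#' fit diagnostics (b* for h2 sweeps; b+ and Lambda+ for g2 sweeps).
#'
#' @param result a \code{\link{run_sweep}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$map, file.path(dir, "sweep.csv"), row.names = FALSE)
  if (!is.null(result$diff))
    utils::write.csv(result$diff, file.path(dir, "diff.csv"), row.names = FALSE)
  thr <- list(varied_name = result$spec$varied_name)
  if (length(result$spec$varied_values) >= 2) {
    if (result$spec$varied_name == "h2") {
      est <- tryCatch(estimate_critical_b(result), error = function(e)
        list(error = conditionMessage(e)))
      thr$b_star <- est
    } else {
      est <- tryCatch(estimate_lambda_plus(result), error = function(e)
        list(error = conditionMessage(e)))
      thr$lambda_plus <- est
    }
  }
  jsonlite::write_json(thr, file.path(dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Read a persisted sweep map
#'
#' @param dir a directory written by \code{\link{write_sweep_result}}.
#' @return A \code{sweep_result} (with a reconstructed minimal spec).
#' @export
read_sweep_result <- function(dir) {
  map <- utils::read.csv(file.path(dir, "sweep.csv"), stringsAsFactors = FALSE)
  spec <- list(varied_name = map$varied_name[1],
               varied_values = sort(unique(map$varied_value)),
               D_values = sort(unique(map$D)),
               b_values = sort(unique(map$b)))
  structure(list(map = map, diff = sweep_diff_maps(map), spec = spec),
            class = "sweep_result")
}
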