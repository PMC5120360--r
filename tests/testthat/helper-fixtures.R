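# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# A state with a tanh front: rho(x) = amp * (1 - tanh((x - centre)/w)) / 2.
tanh_state <- function(grid, centre, w, amp = 100) {
  structure(list(t = 0,
                 rho = amp * (1 - tanh((grid$x - centre) / w)) / 2,
                 v = rep(0.5, grid$nx),
                 sigma = rep(1, grid$nx)),
            class = "sim_state")
}

# A minimal trajectory whose front positions follow a prescribed function of
# time; the states carry a matching translated tanh profile.
synthetic_trajectory <- function(times, position_fun, grid, params) {
  states <- lapply(times, function(t)
    tanh_state(grid, centre = position_fun(t), w = 5, amp = params$N))
  structure(list(times = times, states = states,
                 front_positions = vapply(times, position_fun, numeric(1)),
                 grid = grid, params = params, variant = "I",
                 solver = list(), diagnostics = NULL),
            class = "glioma_trajectory")
}

# Hand-build a sweep_result from a cell-wise front-speed difference rule,
# for exercising the threshold estimators on known geometry.
synthetic_sweep_result <- function(D_values, b_values, delta_fun,
                                   base_speed = 0.1, varied_name = "g2",
                                   varied_values = c(1e-13, 1e-11)) {
  cells <- expand.grid(b = b_values, D = D_values, KEEP.OUT.ATTRS = FALSE)
  mk <- function(level, varied_value, speed) {
    data.frame(varied_name = varied_name, level = level,
               varied_value = varied_value, D = cells$D, b = cells$b,
               front_speed = speed,
               infiltration_width = 10, D_eff = cells$D, b_eff = cells$b,
               status = "ok", stringsAsFactors = FALSE)
  }
  delta <- mapply(delta_fun, cells$D, cells$b)
  map <- rbind(mk(1L, varied_values[1], base_speed),
               mk(2L, varied_values[2], base_speed + delta))
  structure(list(map = map, diff = gliovasc:::sweep_diff_maps(map),
                 spec = list(varied_name = varied_name,
                             varied_values = varied_values,
                             D_values = D_values, b_values = b_values)),
            class = "sweep_result")
}

# Small default parameter set for fast integration tests.
fast_params <- function(...) {
  glioma_params(L = 100, T_f = 100, ...)
}
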