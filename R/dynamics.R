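#' Integrate the deterministic model
#'
#' Solves the model ODEs with an adaptive, implicit-capable integrator
#' (`deSolve::lsoda`); tight default tolerances keep the stiff fast-conjugate
#' regime accurate. Tiny negative solver excursions are clipped to zero and
#' counted in the `n_clipped` attribute.
#'
#' @param p a [conjugate_params()] or [reduced_params()] object.
#' @param init initial [system_state()]; `C` defaults to 0 for the conjugate
#'   model if absent.
#' @param t_max time horizon (days), > 0.
#' @param dt output grid spacing (days).
#' @param rtol,atol relative/absolute solver tolerances.
#' @return A tibble with columns `time`, `E`, `T` (and `C` for the
#'   conjugate model), class `conj_trajectory`, with the model tag and
#'   parameters as attributes.
#' @examples
#' p <- conjugate_params(0.15, 0.3, 0.1, 0.01, 0.9, 0.1)
#' traj <- integrate_model(p, system_state(E = 100, T = 500, C = 0),
#'                         t_max = 100)
#' @export
integrate_model <- function(p, init, t_max, dt = 0.2,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_max > 0, dt > 0)
  model <- model_of(p)
  y0 <- as_state_vector(init, model)
  if (any(y0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  times <- seq(0, t_max, by = dt)
  if (times[length(times)] < t_max) times <- c(times, t_max)
  # tiny negative solver excursions are clamped before evaluating the rates:
  # near-extinction abundances otherwise feed exponential blow-up
  deriv <- if (model == "conjugate") {
    function(t, y, parms) list(unname(rhs_conjugate(pmax(y, 0), p)))
  } else {
    function(t, y, parms) list(unname(rhs_reduced(pmax(y, 0), p)))
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed; last valid time = ",
         format(max(sol[, "time"], na.rm = TRUE)), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  vars <- setdiff(names(out), "time")
  n_clipped <- sum(vapply(out[vars], function(v) sum(v < 0), 0L))
  out[vars] <- lapply(out[vars], function(v) pmax(v, 0))
  attr(out, "model") <- model
  attr(out, "params") <- p
  attr(out, "n_clipped") <- n_clipped
  class(out) <- c("conj_trajectory", class(out))
  out
}

#' Convergence criterion specification
#'
#' Settings for the time-to-steady-state metric: the first time the squared
#' Euclidean distance to the coexistence point in the (E, T) plane,
#' \eqn{(E-E^*)^2 + (T-T^*)^2}, drops to `epsilon` or below and stays below
#' at the next check point (a debounce against transient crossings of the
#' epsilon-ball during damped oscillations). The conjugate coordinate C is
#' excluded from the distance.
#'
#' @param epsilon squared-distance threshold (cells^2), > 0.
#' @param reference `"analytic"` uses the closed-form coexistence point;
#'   `"horizon"` uses the integrated state at `ref_time` as the reference,
#'   mimicking reading the steady state off a long run.
#' @param ref_time reference time (days) for `reference = "horizon"`.
#' @param max_time integration horizon (days); a trajectory that never
#'   satisfies the criterion reports `max_time` with `converged = FALSE`.
#' @param dt check resolution (days).
#' @return A `convergence_spec` list.
#' @export
convergence_spec <- function(epsilon = 0.01,
                             reference = c("analytic", "horizon"),
                             ref_time = 800, max_time = 2000, dt = 0.2) {
  stopifnot(epsilon > 0, max_time > 0, dt > 0, ref_time > 0)
  structure(list(epsilon = epsilon, reference = match.arg(reference),
                 ref_time = ref_time, max_time = max_time, dt = dt),
            class = "convergence_spec")
}

#' Time to converge to the coexistence steady state
#'
#' Integrates the model from `init` and returns the first time the
#' (E, T)-plane squared distance to the coexistence point falls to
#' `spec$epsilon` and remains below at the following check point.
#'
#' @param p a parameter object whose coexistence point is feasible.
#' @param init initial [system_state()].
#' @param spec a [convergence_spec()].
#' @param rtol,atol solver tolerances passed to [integrate_model()].
#' @return Convergence time (days), with attribute `converged`; a run that
#'   never meets the criterion returns `spec$max_time` with
#'   `converged = FALSE`.
#' @export
convergence_time <- function(p, init, spec = convergence_spec(),
                             rtol = 1e-8, atol = 1e-10) {
  fp <- coexistence_fixed_point(p)
  traj <- integrate_model(p, init, t_max = spec$max_time, dt = spec$dt,
                          rtol = rtol, atol = atol)
  ref <- if (spec$reference == "analytic") {
    fp$coordinates[c("E", "T")]
  } else {
    i <- which.min(abs(traj$time - spec$ref_time))
    c(E = traj$E[i], T = traj$T[i])
  }
  d2 <- (traj$E - ref[["E"]])^2 + (traj$T - ref[["T"]])^2
  below <- d2 <= spec$epsilon
  n <- length(below)
  # debounce: require the criterion to hold at the next check point too
  hit <- which(below & c(below[-1], TRUE))
  if (length(hit) == 0) {
    return(structure(spec$max_time, converged = FALSE))
  }
  structure(traj$time[hit[1]], converged = TRUE)
}

#' Convergence-time sweep over a parameter pair
#'
#' Evaluates [convergence_time()] on a rectangular grid of two named
#' parameters, holding the rest at their values in `p_base`. Grid cells
#' whose coexistence point is infeasible are flagged, not errored.
#'
#' @param p_base base parameter object.
#' @param param_x,param_y names of the swept fields (e.g. `"r"`, `"d"`,
#'   `"beta1"`).
#' @param grid_x,grid_y numeric grids for the two fields.
#' @param init initial [system_state()].
#' @param spec a [convergence_spec()].
#' @return A tibble with columns `param_x`, `param_y` (named after the
#'   swept fields), `time_days`, `converged`, `feasible`.
#' @export
convergence_sweep <- function(p_base, param_x, grid_x, param_y, grid_y,
                              init, spec = convergence_spec()) {
  stopifnot(param_x %in% names(p_base), param_y %in% names(p_base))
  grid <- tidyr::expand_grid(x = grid_x, y = grid_y)
  res <- purrr::pmap(grid, function(x, y) {
    p <- set_param(set_param(p_base, param_x, x), param_y, y)
    if (!feasibility_condition(p)) {
      return(tibble::tibble(time_days = NA_real_, converged = FALSE,
                            feasible = FALSE))
    }
    tt <- convergence_time(p, init, spec)
    tibble::tibble(time_days = as.numeric(tt),
                   converged = attr(tt, "converged"), feasible = TRUE)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  names(out)[1:2] <- c(param_x, param_y)
  out
}

set_param <- function(p, name, value) {
  stopifnot(name %in% names(p))
  cls <- class(p)
  p <- unclass(p)
  p[[name]] <- value
  validate_params(p, cls[1])
  structure(p, class = cls)
}
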