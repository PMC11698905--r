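#' Parameters of the conjugate (three-compartment) model
#'
#' Constructs the rate set of the effector/tumor/conjugate system
#'
#' \deqn{dE/dt = sT - \gamma ET + \alpha_1 C - dE}
#' \deqn{dT/dt = rT - \gamma ET + \alpha_2 C}
#' \deqn{dC/dt = \gamma ET - (\alpha_1 + \alpha_2) C}
#'
#' Effector T cells (E) are recruited in proportion to tumor load (`s * T`),
#' die or emigrate at rate `d`, and bind tumor cells (T) into conjugates (C)
#' at rate `gamma`. A conjugate resolves either by tumor lysis (rate
#' `alpha1`, returning the effector) or by effector exhaustion (rate
#' `alpha2`, releasing the tumor cell). Tumor cells grow exponentially at
#' rate `r`.
#'
#' @param s effector influx coefficient (day^-1); the product of the naive
#'   pool size and its differentiation rate.
#' @param r tumor growth rate (day^-1).
#' @param d effector removal rate (day^-1); must be positive for
#'   non-dimensionalization.
#' @param gamma conjugation (binding) rate (day^-1 cell^-1, volume v = 1).
#' @param alpha1 tumor-lysis rate of a conjugate (day^-1).
#' @param alpha2 effector-inactivation (exhaustion) rate of a conjugate
#'   (day^-1).
#' @return An object of class `conjugate_params`.
#' @examples
#' conjugate_params(s = 0.15, r = 0.3, d = 0.1,
#'                  gamma = 0.01, alpha1 = 0.9, alpha2 = 0.1)
#' @export
conjugate_params <- function(s, r, d, gamma, alpha1, alpha2) {
  p <- list(s = s, r = r, d = d, gamma = gamma,
            alpha1 = alpha1, alpha2 = alpha2)
  validate_params(p, "conjugate_params")
  structure(p, class = c("conjugate_params", "model_params"))
}

#' Parameters of the reduced (two-compartment) model
#'
#' Constructs the rate set of the quasi-steady-state reduction
#'
#' \deqn{dE/dt = sT - \beta_2 ET - dE}
#' \deqn{dT/dt = rT - \beta_1 ET}
#'
#' obtained from the conjugate model by assuming conjugates equilibrate
#' instantaneously; `beta1` and `beta2` are the effective killing and
#' exhaustion rates (see [reduce_params()]).
#'
#' @inheritParams conjugate_params
#' @param beta1 effective tumor-killing rate (day^-1 cell^-1).
#' @param beta2 effective effector-inactivation rate (day^-1 cell^-1).
#' @return An object of class `reduced_params`.
#' @examples
#' reduced_params(s = 0.15, r = 0.3, d = 0.1, beta1 = 0.009, beta2 = 0.001)
#' @export
reduced_params <- function(s, r, d, beta1, beta2) {
  p <- list(s = s, r = r, d = d, beta1 = beta1, beta2 = beta2)
  validate_params(p, "reduced_params")
  structure(p, class = c("reduced_params", "model_params"))
}

validate_params <- function(p, what) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(what, ": field '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    if (v < 0) stop(what, ": field '", nm, "' must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  tag <- if (inherits(x, "conjugate_params")) "conjugate (3-compartment)"
         else "reduced (2-compartment)"
  cat("<", tag, " model parameters>\n", sep = "")
  cat(paste0("  ", names(x), " = ", format(unlist(x), digits = 6),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Model tag of a parameter set
#' @param p a `conjugate_params` or `reduced_params` object.
#' @return `"conjugate"` or `"reduced"`.
#' @export
model_of <- function(p) {
  if (inherits(p, "conjugate_params")) return("conjugate")
  if (inherits(p, "reduced_params")) return("reduced")
  stop("not a model parameter object", call. = FALSE)
}

#' System state (cell abundances)
#'
#' A named abundance vector over the model compartments: effector T cells
#' `E`, tumor cells `T`, and (conjugate model only) conjugates `C`.
#' Deterministic work uses continuous abundances; the stochastic simulator
#' requires integer counts (`discrete = TRUE`).
#'
#' @param E effector T cell count (cells), >= 0.
#' @param T tumor cell count (cells), >= 0.
#' @param C conjugate count (cells), >= 0, or `NULL` for the reduced model.
#' @param discrete flag that the abundances are integer counts (stochastic
#'   use); checked, not coerced.
#' @return A named numeric vector with class `system_state`.
#' @examples
#' system_state(E = 100, T = 500, C = 0)
#' @export
system_state <- function(E, T, C = NULL, discrete = FALSE) {
  x <- c(E = E, T = T)
  if (!is.null(C)) x <- c(x, C = C)
  if (any(!is.finite(x))) stop("invalid state: non-finite abundance", call. = FALSE)
  if (any(x < 0)) stop("invalid state: negative abundance", call. = FALSE)
  if (discrete && any(x != round(x))) {
    stop("invalid state: discrete state requires integer counts", call. = FALSE)
  }
  structure(x, discrete = discrete, class = c("system_state", "numeric"))
}

as_state_vector <- function(state, model) {
  x <- unclass(state)
  if (any(!is.finite(x))) stop("invalid state: non-finite abundance", call. = FALSE)
  if (model == "conjugate") {
    if (!all(c("E", "T") %in% names(x))) {
      stop("state must carry named E and T components", call. = FALSE)
    }
    c(E = unname(x["E"]), T = unname(x["T"]),
      C = if ("C" %in% names(x)) unname(x["C"]) else 0)
  } else {
    c(E = unname(x["E"]), T = unname(x["T"]))
  }
}

#' Right-hand side of the conjugate model
#'
#' Evaluates the time derivatives of (E, T, C) at a state, in cells/day.
#'
#' @param state a [system_state()] (or named numeric vector) with components
#'   `E`, `T` and `C` (a missing `C` is taken as 0).
#' @param p a [conjugate_params()] object.
#' @return Named numeric vector `c(dE, dT, dC)`.
#' @examples
#' p <- conjugate_params(0.15, 0.3, 0.1, 0.01, 0.9, 0.1)
#' rhs_conjugate(system_state(E = 0, T = 1, C = 0), p)
#' @export
rhs_conjugate <- function(state, p) {
  stopifnot(inherits(p, "conjugate_params"))
  x <- as_state_vector(state, "conjugate")
  E <- x[["E"]]; T <- x[["T"]]; C <- x[["C"]]
  c(dE = p$s * T - p$gamma * E * T + p$alpha1 * C - p$d * E,
    dT = p$r * T - p$gamma * E * T + p$alpha2 * C,
    dC = p$gamma * E * T - (p$alpha1 + p$alpha2) * C)
}

#' Right-hand side of the reduced model
#'
#' Evaluates the time derivatives of (E, T) at a state, in cells/day.
#'
#' @param state a [system_state()] (or named numeric vector) with components
#'   `E` and `T`.
#' @param p a [reduced_params()] object.
#' @return Named numeric vector `c(dE, dT)`.
#' @export
rhs_reduced <- function(state, p) {
  stopifnot(inherits(p, "reduced_params"))
  x <- as_state_vector(state, "reduced")
  E <- x[["E"]]; T <- x[["T"]]
  c(dE = p$s * T - p$beta2 * E * T - p$d * E,
    dT = p$r * T - p$beta1 * E * T)
}

#' Quasi-steady-state conjugate abundance
#'
#' The conjugate compartment equilibrates at \eqn{C = \gamma ET /
#' (\alpha_1+\alpha_2)} when its dynamics are much faster than those of E
#' and T; this is the algebraic elimination that produces the reduced model.
#'
#' @param E,T effector and tumor abundances (cells).
#' @param p a [conjugate_params()] object with `alpha1 + alpha2 > 0`.
#' @return Conjugate abundance (cells).
#' @export
qss_conjugate <- function(E, T, p) {
  stopifnot(inherits(p, "conjugate_params"))
  denom <- p$alpha1 + p$alpha2
  if (denom == 0) {
    stop("qss_conjugate: alpha1 + alpha2 = 0, conjugate resolution rate ",
         "vanishes (division by zero)", call. = FALSE)
  }
  p$gamma * E * T / denom
}

#' Map conjugate-model rates to effective reduced-model rates
#'
#' Under the quasi-steady-state elimination of the conjugate, the effective
#' killing and exhaustion rates are
#' \deqn{\beta_1 = \gamma\,\alpha_1/(\alpha_1+\alpha_2), \qquad
#'       \beta_2 = \gamma\,\alpha_2/(\alpha_1+\alpha_2),}
#' so that \eqn{\beta_1 + \beta_2 = \gamma}; `s`, `r`, `d` carry over.
#'
#' @param p a [conjugate_params()] object with `alpha1 + alpha2 > 0`.
#' @return A [reduced_params()] object.
#' @examples
#' reduce_params(conjugate_params(0.15, 0.3, 0.1, 0.01, 0.9, 0.1))
#' @export
reduce_params <- function(p) {
  stopifnot(inherits(p, "conjugate_params"))
  denom <- p$alpha1 + p$alpha2
  if (denom == 0) {
    stop("reduce_params: alpha1 + alpha2 = 0, reduction undefined",
         call. = FALSE)
  }
  reduced_params(s = p$s, r = p$r, d = p$d,
                 beta1 = p$gamma * p$alpha1 / denom,
                 beta2 = p$gamma * p$alpha2 / denom)
}

#' Non-dimensionalize a parameter set
#'
#' Rescales time by the effector removal rate (\eqn{\tau = d\,t}) and
#' reports every other rate as its ratio to `d`, which acts as the common
#' denominator of all rescaled parameters. State variables are left
#' unscaled.
#'
#' @param p a [conjugate_params()] or [reduced_params()] object with
#'   `d > 0`.
#' @return An object of class `rescaled_params`: the dimensionless ratios,
#'   the time scale `d`, and the model tag. Invert with [unscale_params()].
#' @examples
#' rp <- nondimensionalize(conjugate_params(0.15, 0.3, 0.1, 0.01, 0.9, 0.1))
#' unscale_params(rp)
#' @export
nondimensionalize <- function(p) {
  if (p$d == 0) stop("nondimensionalize: d = 0, time rescaling undefined",
                     call. = FALSE)
  ratios <- lapply(p[setdiff(names(p), "d")], function(v) v / p$d)
  structure(list(ratios = ratios, d = p$d, model = model_of(p)),
            class = "rescaled_params")
}

#' Undo a non-dimensional rescaling
#' @param rp a `rescaled_params` object from [nondimensionalize()].
#' @return The original parameter object.
#' @export
unscale_params <- function(rp) {
  stopifnot(inherits(rp, "rescaled_params"))
  vals <- lapply(rp$ratios, function(v) v * rp$d)
  if (rp$model == "conjugate") {
    conjugate_params(s = vals$s, r = vals$r, d = rp$d, gamma = vals$gamma,
                     alpha1 = vals$alpha1, alpha2 = vals$alpha2)
  } else {
    reduced_params(s = vals$s, r = vals$r, d = rp$d,
                   beta1 = vals$beta1, beta2 = vals$beta2)
  }
}

#' @export
print.rescaled_params <- function(x, ...) {
  cat("<non-dimensionalized ", x$model, " parameters; tau = d*t, d = ",
      format(x$d), ">\n", sep = "")
  cat(paste0("  ", names(x$ratios), "/d = ",
             format(unlist(x$ratios), digits = 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a parameter set to a flat key-value config file
#'
#' @param p a parameter object.
#' @param path output path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  x <- c(list(model = model_of(p)), unclass(p))
  write_kv_config(x, path)
  invisible(path)
}

#' Read a parameter set from a flat key-value config file
#'
#' @param path a JSON or YAML file with a `model` tag (`"conjugate"` or
#'   `"reduced"`) and the rate fields `s, r, d` plus `gamma, alpha1, alpha2`
#'   or `beta1, beta2`. Rates are per day; `gamma`, `beta1`, `beta2` are per
#'   day per cell at unit volume.
#' @return A parameter object.
#' @export
read_params <- function(path) {
  x <- read_kv_config(path)
  params_from_list(x)
}

params_from_list <- function(x) {
  model <- x$model
  if (is.null(model)) {
    model <- if (!is.null(x$gamma)) "conjugate" else "reduced"
  }
  if (identical(model, "conjugate")) {
    need <- c("s", "r", "d", "gamma", "alpha1", "alpha2")
  } else if (identical(model, "reduced")) {
    need <- c("s", "r", "d", "beta1", "beta2")
  } else {
    stop("unknown model tag: ", model, call. = FALSE)
  }
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("parameter config missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(if (model == "conjugate") conjugate_params else reduced_params,
          lapply(x[need], as.numeric))
}

write_kv_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop("unsupported config extension: .", ext, " (use .json or .yaml)",
         call. = FALSE)
  }
  invisible(path)
}

read_kv_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: .", ext, " (use .json or .yaml)",
         call. = FALSE)
  }
}
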