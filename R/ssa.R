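#' Build the stochastic reaction system for either model
#'
#' Defines the continuous-time Markov jump process whose mean field is the
#' corresponding ODE system. Species are `E`, `T`, `C` plus the cumulative
#' bookkeeping counters `Ed` (exhausted effectors) and `Td` (lysed tumor
#' cells), which never feed back into any propensity.
#'
#' The conjugate model has six reactions: effector death `E -> 0` (rate
#' `d*E`), tumor-driven effector influx `T -> T + E` (`s*T`), tumor division
#' `T -> 2T` (`r*T`), binding `E + T -> C` (`gamma*E*T/v`), lysis
#' `C -> Td + E` (`alpha1*C`, the effector is returned) and exhaustion
#' `C -> T + Ed` (`alpha2*C`, the tumor cell survives). The reduced model
#' collapses the last three into killing `E + T -> Td + E` (`beta1*E*T/v`)
#' and exhaustion `E + T -> T + Ed` (`beta2*E*T/v`). When `mu > 0` a
#' mutation pseudo-reaction is appended; it has no stoichiometric effect but
#' terminates a run as tumor escape. Its timing follows the `mutation_mode`
#' of the [ssa_config()]: by default each tumor division carries probability
#' `mu` of producing an escaping mutant; the alternative is a first-order
#' channel with propensity `mu*T` per day (the propensity evaluator reports
#' the latter form).
#'
#' @param model `"conjugate"` or `"reduced"` (inferred from `p` by default).
#' @param p a [conjugate_params()] or [reduced_params()] object.
#' @param mu mutation (escape) rate per tumor cell per day.
#' @param v system volume scaling the bimolecular propensities (default 1).
#' @return A `reaction_system`: reaction table (name, propensity label),
#'   stoichiometry matrix (species x reactions), and a propensity evaluator.
#' @examples
#' sys <- build_reactions(p = reduced_params(0.05, 0.15, 0.1, 0.018, 0.002))
#' propensities(sys, c(E = 30, T = 50))
#' @export
build_reactions <- function(model = model_of(p), p, mu = 0, v = 1) {
  stopifnot(mu >= 0, v > 0)
  if (!model %in% c("conjugate", "reduced")) {
    stop("unknown model tag: ", model, call. = FALSE)
  }
  if (model != model_of(p)) {
    stop("model tag '", model, "' does not match the parameter object",
         call. = FALSE)
  }
  species <- c("E", "T", "C", "Ed", "Td")
  if (model == "conjugate") {
    names_rxn <- c("effector_death", "effector_influx", "tumor_division",
                   "binding", "lysis", "exhaustion")
    labels <- c("d*E", "s*T", "r*T", "gamma*E*T/v", "alpha1*C", "alpha2*C")
    stoich <- cbind(
      effector_death  = c(-1, 0, 0, 0, 0),
      effector_influx = c( 1, 0, 0, 0, 0),
      tumor_division  = c( 0, 1, 0, 0, 0),
      binding         = c(-1, -1, 1, 0, 0),
      lysis           = c( 1, 0, -1, 0, 1),
      exhaustion      = c( 0, 1, -1, 1, 0))
    prop_fun <- function(state) {
      E <- state[["E"]]; T <- state[["T"]]
      C <- if ("C" %in% names(state)) state[["C"]] else 0
      c(effector_death = p$d * E, effector_influx = p$s * T,
        tumor_division = p$r * T, binding = p$gamma * E * T / v,
        lysis = p$alpha1 * C, exhaustion = p$alpha2 * C)
    }
    rates <- c(p$s, p$r, p$d, p$gamma, p$alpha1, p$alpha2)
  } else {
    names_rxn <- c("effector_death", "effector_influx", "tumor_division",
                   "killing", "exhaustion")
    labels <- c("d*E", "s*T", "r*T", "beta1*E*T/v", "beta2*E*T/v")
    stoich <- cbind(
      effector_death  = c(-1, 0, 0, 0, 0),
      effector_influx = c( 1, 0, 0, 0, 0),
      tumor_division  = c( 0, 1, 0, 0, 0),
      killing         = c( 0, -1, 0, 0, 1),
      exhaustion      = c(-1, 0, 0, 1, 0))
    prop_fun <- function(state) {
      E <- state[["E"]]; T <- state[["T"]]
      c(effector_death = p$d * E, effector_influx = p$s * T,
        tumor_division = p$r * T, killing = p$beta1 * E * T / v,
        exhaustion = p$beta2 * E * T / v)
    }
    rates <- c(p$s, p$r, p$d, p$beta1, p$beta2)
  }
  rownames(stoich) <- species
  if (mu > 0) {
    names_rxn <- c(names_rxn, "mutation")
    labels <- c(labels, "mu*T")
    stoich <- cbind(stoich, mutation = rep(0, 5))
    base_prop <- prop_fun
    prop_fun <- function(state) c(base_prop(state),
                                  mutation = mu * state[["T"]])
  }
  structure(list(model = model, params = p, mu = mu, v = v,
                 reactions = tibble::tibble(reaction = names_rxn,
                                            propensity = labels),
                 stoichiometry = stoich, prop_fun = prop_fun,
                 rates = rates),
            class = "reaction_system")
}

#' Evaluate all reaction propensities at a state
#' @param sys a `reaction_system` from [build_reactions()].
#' @param state named abundance vector (`E`, `T`, and `C` for the conjugate
#'   model).
#' @return Named numeric vector of propensities (events/day).
#' @export
propensities <- function(sys, state) {
  stopifnot(inherits(sys, "reaction_system"))
  sys$prop_fun(state)
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction system, ", x$model, " model, v = ", x$v,
      ", mu = ", format(x$mu), ">\n", sep = "")
  print(x$reactions, n = Inf)
  invisible(x)
}

#' Stochastic run configuration
#'
#' @param t_max time horizon (days); default 50000, long enough to exceed a
#'   human lifetime.
#' @param mu mutation (escape) rate; default 1e-6. Under
#'   `mutation_mode = "per_division"` it is the probability that a tumor
#'   division produces an escaping mutant; under `"per_cell"` it is a
#'   propensity `mu*T` per day.
#' @param mutation_mode `"per_division"` (default: mutations arise at DNA
#'   replication, so escape is a thinned division channel) or `"per_cell"`
#'   (a first-order escape reaction with propensity `mu*T`).
#' @param seed integer RNG seed for a single run.
#' @param record_mode `"outcome"` (no trajectory), `"full"` (every event),
#'   or `"thinned"` (state sampled every `record_dt` days).
#' @param record_dt sampling interval (days) for `record_mode = "thinned"`.
#' @param max_events event-count guard; a run that exceeds it is censored at
#'   the current time.
#' @return An `ssa_config` list.
#' @export
ssa_config <- function(t_max = 50000, mu = 1e-6,
                       mutation_mode = c("per_division", "per_cell"),
                       seed = 1L,
                       record_mode = c("outcome", "full", "thinned"),
                       record_dt = 1, max_events = 5e8) {
  stopifnot(t_max > 0, mu >= 0, record_dt > 0, max_events > 0)
  structure(list(t_max = t_max, mu = mu,
                 mutation_mode = match.arg(mutation_mode),
                 seed = as.integer(seed),
                 record_mode = match.arg(record_mode),
                 record_dt = record_dt, max_events = max_events),
            class = "ssa_config")
}

#' Run one exact stochastic simulation
#'
#' Gillespie's direct method: exponential waiting times from the total
#' propensity, reaction chosen with probability proportional to its
#' propensity. A run terminates at the first of tumor extinction (`T = 0`,
#' and `C = 0` for the conjugate model, since a conjugate can still release
#' a live tumor cell), a mutation event (tumor escape), the time horizon
#' (censored), or total propensity zero.
#'
#' @param sys a `reaction_system`, or a parameter object (then a system is
#'   built with `cfg$mu`).
#' @param init initial [system_state()] with integer counts.
#' @param cfg an [ssa_config()].
#' @return An `ssa_result`: `outcome` (`"extinct"`, `"escaped"`,
#'   `"censored"`), `extinction_time` (days, `NA` unless extinct),
#'   `end_time`, `final_state`, `n_events`, `seed`, and (per `record_mode`)
#'   a trajectory tibble `log` with columns `time`, `reaction`, `E`, `T`,
#'   `C`, `Ed`, `Td`.
#' @examples
#' p <- reduced_params(0.05, 0.15, 0.1, 0.018, 0.002)
#' simulate_ssa(p, system_state(E = 30, T = 50, discrete = TRUE),
#'              ssa_config(t_max = 100, seed = 7))
#' @export
simulate_ssa <- function(sys, init, cfg = ssa_config()) {
  if (inherits(sys, "model_params")) {
    sys <- build_reactions(p = sys, mu = cfg$mu, v = 1)
  }
  stopifnot(inherits(sys, "reaction_system"), inherits(cfg, "ssa_config"))
  y0 <- as_state_vector(init, sys$model)
  if (any(y0 != round(y0))) {
    stop("stochastic simulation requires integer initial counts",
         call. = FALSE)
  }
  model_code <- if (sys$model == "conjugate") 1L else 2L
  rec_code <- match(cfg$record_mode, c("outcome", "full", "thinned")) - 1L
  mu <- if (sys$mu > 0) sys$mu else cfg$mu
  mut_code <- if (identical(cfg$mutation_mode, "per_cell")) 0L else 1L
  set.seed(cfg$seed)
  raw <- .ssa_run(model_code, sys$rates, unname(y0), cfg$t_max, mu, sys$v,
                  mut_code, rec_code, cfg$record_dt, cfg$max_events)
  outcome <- c("extinct", "escaped", "censored")[raw$outcome + 1L]
  log <- NULL
  if (rec_code > 0L) {
    log <- tibble::as_tibble(as.data.frame(raw$log))
    rxn_names <- unique(c(sys$reactions$reaction, "mutation"))
    idx <- raw$log[, "reaction"] + 1L
    log$reaction <- ifelse(idx < 1L, NA_character_, rxn_names[pmax(idx, 1L)])
  }
  structure(list(outcome = outcome,
                 extinction_time = if (outcome == "extinct") raw$end_time
                                   else NA_real_,
                 end_time = raw$end_time,
                 final_state = raw$final_state,
                 n_events = raw$n_events,
                 seed = cfg$seed,
                 model = sys$model,
                 log = log),
            class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat("<SSA run, ", x$model, " model> outcome = ", x$outcome, sep = "")
  if (x$outcome == "extinct") {
    cat(", extinction at ", format(x$extinction_time, digits = 6), " days",
        sep = "")
  }
  cat("\n  events = ", format(x$n_events, big.mark = ","), ", seed = ",
      x$seed, "\n  final state: ",
      paste0(names(x$final_state), "=", x$final_state, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Run an ensemble of independent stochastic replicates
#'
#' Replicate `i` uses seed `seed_base + i - 1` (collision-free, documented,
#' reproducible); aggregation is order-independent.
#'
#' @param sys a `reaction_system` or parameter object.
#' @param init initial [system_state()] with integer counts.
#' @param cfg an [ssa_config()]; its `seed` is ignored in favor of the
#'   per-replicate scheme.
#' @param n_reps number of replicates, >= 1.
#' @param seed_base first replicate's seed.
#' @return A tibble of class `ssa_ensemble` with one row per replicate:
#'   `replicate`, `seed`, `outcome`, `extinction_time`, `end_time`,
#'   `n_events`, `final_E`, `final_T`, `final_C`.
#' @export
run_ensemble <- function(sys, init, cfg = ssa_config(), n_reps,
                         seed_base = 1L) {
  stopifnot(n_reps >= 1)
  if (inherits(sys, "model_params")) {
    sys <- build_reactions(p = sys, mu = cfg$mu, v = 1)
  }
  rows <- purrr::map(seq_len(n_reps), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed_base + i - 1L)
    cfg_i$record_mode <- "outcome"
    res <- simulate_ssa(sys, init, cfg_i)
    tibble::tibble(replicate = i, seed = cfg_i$seed, outcome = res$outcome,
                   extinction_time = res$extinction_time,
                   end_time = res$end_time, n_events = res$n_events,
                   final_E = res$final_state[["E"]],
                   final_T = res$final_state[["T"]],
                   final_C = res$final_state[["C"]])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model") <- sys$model
  attr(out, "params") <- sys$params
  attr(out, "mu") <- if (sys$mu > 0) sys$mu else cfg$mu
  attr(out, "t_max") <- cfg$t_max
  attr(out, "init") <- as_state_vector(init, sys$model)
  attr(out, "seed_base") <- seed_base
  class(out) <- c("ssa_ensemble", class(out))
  out
}
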