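#' Summarize an ensemble of stochastic runs
#'
#' Counts outcomes, estimates the tumor-extinction probability with an
#' exact binomial confidence interval, and summarizes the extinction-time
#' distribution over the extinct replicates. Censored and escaped runs are
#' reported in the counts; with `censoring_mode = "exclude"` (default,
#' matching the convention that time distributions are drawn over extinct
#' runs only) they contribute no time, while `"censor"` additionally
#' includes them at the horizon as right-censored times in the quantile
#' summary.
#'
#' @param e an `ssa_ensemble` tibble from [run_ensemble()].
#' @param censoring_mode `"exclude"` or `"censor"`.
#' @param conf_level confidence level for the binomial interval.
#' @return A one-row tibble: `n_total`, `n_extinct`, `n_escaped`,
#'   `n_censored`, `p_extinct`, `p_lo`, `p_hi`, `min_time`, `median_time`,
#'   `max_time`, and list-column `times` holding the sorted extinction-time
#'   sample.
#' @export
summarize_ensemble <- function(e, censoring_mode = c("exclude", "censor"),
                               conf_level = 0.95) {
  censoring_mode <- match.arg(censoring_mode)
  if (!is.data.frame(e) || nrow(e) == 0) {
    stop("empty or invalid ensemble", call. = FALSE)
  }
  n_total <- nrow(e)
  n_extinct <- sum(e$outcome == "extinct")
  n_escaped <- sum(e$outcome == "escaped")
  n_censored <- sum(e$outcome == "censored")
  bt <- stats::binom.test(n_extinct, n_total, conf.level = conf_level)
  times <- sort(e$extinction_time[e$outcome == "extinct"])
  tsample <- if (censoring_mode == "censor") {
    sort(c(times, e$end_time[e$outcome != "extinct"]))
  } else {
    times
  }
  qs <- if (length(tsample) > 0) {
    c(min(tsample), stats::median(tsample), max(tsample))
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  tibble::tibble(n_total = n_total, n_extinct = n_extinct,
                 n_escaped = n_escaped, n_censored = n_censored,
                 p_extinct = n_extinct / n_total,
                 p_lo = bt$conf.int[1], p_hi = bt$conf.int[2],
                 min_time = qs[1], median_time = qs[2], max_time = qs[3],
                 times = list(times))
}

#' Sweep a parameter and summarize extinction behavior at each value
#'
#' Runs an ensemble at each grid value of one rate and returns one summary
#' row per value. The special name `"beta_total"` (reduced model only)
#' sweeps the sum `beta1 + beta2` while holding the ratio `beta2/beta1`
#' fixed, the natural axis for the extinction-probability trend.
#'
#' @param p base parameter object.
#' @param param field name to sweep, or `"beta_total"`.
#' @param grid numeric grid of values.
#' @param init initial [system_state()] (integer counts).
#' @param cfg an [ssa_config()].
#' @param n_reps replicates per grid value.
#' @param seed_base seed for the first replicate of the first grid value;
#'   successive grid values advance by `n_reps` so no stream is reused.
#' @param censoring_mode passed to [summarize_ensemble()].
#' @return A tibble with `param`, `value`, and the summary columns.
#' @export
sweep_extinction <- function(p, param, grid, init, cfg = ssa_config(),
                             n_reps = 1000, seed_base = 1L,
                             censoring_mode = "exclude") {
  rows <- purrr::imap(as.list(grid), function(val, i) {
    p_i <- if (identical(param, "beta_total")) {
      stopifnot(inherits(p, "reduced_params"))
      ratio <- p$beta2 / p$beta1
      reduced_params(p$s, p$r, p$d,
                     beta1 = val / (1 + ratio),
                     beta2 = val * ratio / (1 + ratio))
    } else {
      set_param(p, param, val)
    }
    e <- run_ensemble(p_i, init, cfg, n_reps = n_reps,
                      seed_base = seed_base + (i - 1L) * n_reps)
    dplyr::bind_cols(tibble::tibble(param = param, value = val),
                     summarize_ensemble(e, censoring_mode = censoring_mode))
  })
  dplyr::bind_rows(rows)
}

#' Trajectory plot
#'
#' @param object a `conj_trajectory` from [integrate_model()].
#' @param ... unused.
#' @return A ggplot of abundances over time, one line per compartment.
#' @method autoplot conj_trajectory
#' @export
autoplot.conj_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "compartment",
                              values_to = "cells")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cells,
                                     color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "cells",
                  title = paste0(attr(object, "model"), " model dynamics"))
}

#' Extinction-time distribution plot
#'
#' Violin of the extinction-time sample over extinct replicates, with the
#' minimum, median and maximum marked.
#'
#' @param object an `ssa_ensemble` from [run_ensemble()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ssa_ensemble
#' @export
autoplot.ssa_ensemble <- function(object, ...) {
  ext <- dplyr::filter(tibble::as_tibble(object),
                       .data$outcome == "extinct")
  if (nrow(ext) == 0) stop("no extinct replicates to plot", call. = FALSE)
  qs <- stats::quantile(ext$extinction_time, c(0, 0.5, 1))
  ggplot2::ggplot(ext, ggplot2::aes(x = "", y = .data$extinction_time)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::annotate("point", x = 1, y = qs, shape = 3) +
    ggplot2::labs(x = NULL, y = "extinction time (days)",
                  title = paste0(attr(object, "model"),
                                 " model tumor extinction times"))
}

#' Stability-map plot
#'
#' @param object a `stability_map` tibble from [stability_map()].
#' @param ... unused.
#' @return A ggplot tiling the (alpha1, alpha2) grid by stability class.
#' @method autoplot stability_map
#' @export
autoplot.stability_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- ifelse(df$feasible, df$class, "infeasible")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha1, y = .data$alpha2,
                                   fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "tumor-killing rate alpha1 (1/day)",
                  y = "exhaustion rate alpha2 (1/day)",
                  fill = "coexistence point")
}

#' Convergence-time sweep plot
#'
#' @param sweep a tibble from [convergence_sweep()]; the first two columns
#'   are the swept parameters.
#' @return A ggplot heat map of convergence time.
#' @export
plot_convergence_sweep <- function(sweep) {
  nx <- names(sweep)[1]; ny <- names(sweep)[2]
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data[[nx]], y = .data[[ny]],
                               fill = .data$time_days)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "time to converge (days)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
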