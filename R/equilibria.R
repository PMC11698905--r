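#' Feasibility of the coexistence steady state
#'
#' Both models admit a nontrivial (tumor-control) steady state only when
#' \eqn{\alpha_1 s - \alpha_2 r > 0} (strict); otherwise a coexistence
#' coordinate would be negative or infinite. For reduced parameters the
#' equivalent condition \eqn{\beta_1 s - \beta_2 r > 0} is used (the two
#' differ by the positive factor \eqn{\gamma/(\alpha_1+\alpha_2)}).
#'
#' @param p a [conjugate_params()] or [reduced_params()] object.
#' @return `TRUE` iff the coexistence point is feasible.
#' @export
feasibility_condition <- function(p) {
  if (inherits(p, "conjugate_params")) {
    p$alpha1 * p$s - p$alpha2 * p$r > 0
  } else if (inherits(p, "reduced_params")) {
    p$beta1 * p$s - p$beta2 * p$r > 0
  } else {
    stop("not a model parameter object", call. = FALSE)
  }
}

#' Fixed points of either model
#'
#' `extinction_fixed_point()` is the trivial steady state (all compartments
#' zero); it always exists and is a saddle in both models. `coexistence_
#' fixed_point()` is the tumor-control steady state; in closed form,
#' for the conjugate model
#' \deqn{E^* = \frac{r}{\gamma}\frac{\alpha_1+\alpha_2}{\alpha_1},\quad
#'       T^* = \frac{dr}{\gamma}\frac{\alpha_1+\alpha_2}{\alpha_1 s-\alpha_2 r},\quad
#'       C^* = \frac{dr^2}{\gamma\alpha_1}\frac{\alpha_1+\alpha_2}{\alpha_1 s-\alpha_2 r},}
#' and for the reduced model \eqn{E^* = r/\beta_1}, \eqn{T^* =
#' dr/(\beta_1 s - \beta_2 r)} — the same (E*, T*) once the rates are
#' mapped by [reduce_params()].
#'
#' @param p a [conjugate_params()] or [reduced_params()] object.
#' @param tol stability classification tolerance (day^-1), see
#'   [classify_stability()].
#' @return A `fixed_point` object: coordinates, Jacobian eigenvalues,
#'   feasibility flag and stability class. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] for tibble views.
#' @examples
#' p <- conjugate_params(0.15, 0.3, 0.1, 0.01, 0.9, 0.1)
#' coexistence_fixed_point(p)
#' @export
coexistence_fixed_point <- function(p, tol = 1e-9) {
  if (!feasibility_condition(p)) {
    if (inherits(p, "conjugate_params")) {
      stop("coexistence point infeasible: requires alpha1*s - alpha2*r > 0 ",
           "(got ", format(p$alpha1 * p$s - p$alpha2 * p$r), ")",
           call. = FALSE)
    }
    stop("coexistence point infeasible: requires beta1*s - beta2*r > 0 ",
         "(got ", format(p$beta1 * p$s - p$beta2 * p$r), ")", call. = FALSE)
  }
  if (inherits(p, "conjugate_params")) {
    if (p$gamma <= 0 || p$alpha1 <= 0) {
      stop("coexistence point requires gamma > 0 and alpha1 > 0",
           call. = FALSE)
    }
    asum <- p$alpha1 + p$alpha2
    denom <- p$alpha1 * p$s - p$alpha2 * p$r
    coords <- c(E = p$r / p$gamma * asum / p$alpha1,
                T = p$d * p$r / p$gamma * asum / denom,
                C = p$d * p$r^2 / (p$gamma * p$alpha1) * asum / denom)
  } else {
    if (p$beta1 <= 0) {
      stop("coexistence point requires beta1 > 0", call. = FALSE)
    }
    coords <- c(E = p$r / p$beta1,
                T = p$d * p$r / (p$beta1 * p$s - p$beta2 * p$r))
  }
  new_fixed_point(coords, p, tol = tol)
}

#' @rdname coexistence_fixed_point
#' @export
extinction_fixed_point <- function(p, tol = 1e-9) {
  coords <- if (inherits(p, "conjugate_params")) c(E = 0, T = 0, C = 0)
            else c(E = 0, T = 0)
  new_fixed_point(coords, p, tol = tol)
}

new_fixed_point <- function(coords, p, tol = 1e-9) {
  J <- jacobian(p, coords)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  feasible <- all(is.finite(coords)) && all(coords >= 0)
  fp <- structure(
    list(coordinates = coords, jacobian = J, eigenvalues = ev,
         feasible = feasible, stability_class = NA_character_,
         model = model_of(p), params = p, tol = tol),
    class = "fixed_point")
  fp$stability_class <- classify_stability(fp, tol = tol)
  fp
}

#' Jacobian of the model right-hand side
#'
#' Analytic matrix of partial derivatives of the ODE right-hand side,
#' evaluated at a state; eigenvalues of this matrix at a fixed point
#' determine its linear stability.
#'
#' @param p a [conjugate_params()] or [reduced_params()] object.
#' @param at state at which to evaluate (named vector with `E`, `T` and,
#'   for the conjugate model, `C`).
#' @return A 3x3 (conjugate) or 2x2 (reduced) numeric matrix, day^-1.
#' @export
jacobian <- function(p, at) {
  if (inherits(p, "conjugate_params")) {
    x <- as_state_vector(at, "conjugate")
    E <- x[["E"]]; T <- x[["T"]]
    matrix(c(-p$gamma * T - p$d, p$s - p$gamma * E, p$alpha1,
             -p$gamma * T,       p$r - p$gamma * E, p$alpha2,
             p$gamma * T,        p$gamma * E,       -(p$alpha1 + p$alpha2)),
           nrow = 3, byrow = TRUE,
           dimnames = list(c("dE", "dT", "dC"), c("E", "T", "C")))
  } else if (inherits(p, "reduced_params")) {
    x <- as_state_vector(at, "reduced")
    E <- x[["E"]]; T <- x[["T"]]
    matrix(c(-p$beta2 * T - p$d, p$s - p$beta2 * E,
             -p$beta1 * T,       p$r - p$beta1 * E),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("dE", "dT"), c("E", "T")))
  } else {
    stop("not a model parameter object", call. = FALSE)
  }
}

#' Classify linear stability from Jacobian eigenvalues
#'
#' @param fp a `fixed_point` object (or anything with an `eigenvalues`
#'   element).
#' @param tol tolerance (day^-1) below which a real part is treated as zero.
#' @return One of `"saddle"`, `"stable_node"`, `"stable_spiral"`,
#'   `"unstable"`, `"marginal"`: a saddle has real eigenvalues of both
#'   signs (monotone escape along an unstable direction, as at the
#'   extinction point); any other spectrum with a real part above `tol`
#'   (e.g. a complex pair spiralling outward) is unstable; a stable node
#'   has all eigenvalues real and negative; a stable spiral has a complex
#'   pair with negative real parts; a dominant real part within `tol` of
#'   zero is reported as marginal rather than guessed.
#' @export
classify_stability <- function(fp, tol = 1e-9) {
  ev <- if (is.list(fp)) fp$eigenvalues else fp
  re <- Re(ev)
  if (max(abs(re)) <= tol) return("marginal")
  if (any(re > tol)) {
    all_real <- all(abs(Im(ev)) <= tol)
    if (all_real && any(re < -tol)) return("saddle")
    return("unstable")
  }
  if (max(re) >= -tol) return("marginal")
  # all real parts negative: node vs spiral by a complex pair among the
  # dominant (slowest-decaying) eigenvalues
  dominant <- ev[abs(re - max(re)) <= tol + 1e-12 * abs(max(re))]
  if (any(abs(Im(dominant)) > tol)) "stable_spiral" else "stable_node"
}

#' Damping rate at the coexistence steady state
#'
#' The damping rate of the oscillatory approach to tumor control is the
#' largest real part among the Jacobian eigenvalues at the coexistence
#' point (negative when the point is stable; its absolute value is the
#' decay rate of the oscillation envelope). It is independent of the
#' binding rate `gamma` in the conjugate model.
#'
#' @param p a [conjugate_params()] or [reduced_params()] object with a
#'   feasible coexistence point.
#' @return Largest eigenvalue real part (day^-1).
#' @export
damping_rate <- function(p) {
  fp <- coexistence_fixed_point(p)
  max(Re(fp$eigenvalues))
}

#' Stability map of the coexistence point over an (alpha1, alpha2) grid
#'
#' Classifies the conjugate-model coexistence fixed point on a rectangular
#' grid of tumor-killing and effector-exhaustion rates, holding the other
#' rates at their values in `p`. Infeasible cells (violating
#' \eqn{\alpha_1 s - \alpha_2 r > 0}) are flagged rather than classified.
#'
#' @param p a [conjugate_params()] object supplying `s`, `r`, `d`, `gamma`.
#' @param alpha1_grid,alpha2_grid finite positive numeric grids.
#' @param tol classification tolerance passed to [classify_stability()].
#' @return A tibble with columns `alpha1`, `alpha2`, `feasible`, `class`,
#'   `max_real_eig`, one row per grid cell.
#' @export
stability_map <- function(p, alpha1_grid, alpha2_grid, tol = 1e-9) {
  stopifnot(inherits(p, "conjugate_params"),
            all(is.finite(alpha1_grid)), all(is.finite(alpha2_grid)),
            all(alpha1_grid > 0), all(alpha2_grid > 0))
  grid <- tidyr::expand_grid(alpha1 = alpha1_grid, alpha2 = alpha2_grid)
  res <- purrr::pmap(grid, function(alpha1, alpha2) {
    pc <- conjugate_params(p$s, p$r, p$d, p$gamma, alpha1, alpha2)
    if (!feasibility_condition(pc)) {
      return(tibble::tibble(feasible = FALSE, class = NA_character_,
                            max_real_eig = NA_real_))
    }
    fp <- coexistence_fixed_point(pc, tol = tol)
    tibble::tibble(feasible = TRUE, class = fp$stability_class,
                   max_real_eig = max(Re(fp$eigenvalues)))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("stability_map", class(out))
  out
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed point, ", x$model, " model>\n", sep = "")
  cat("  coordinates:",
      paste0(names(x$coordinates), "* = ",
             format(x$coordinates, digits = 6), collapse = ", "), "\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  cat("  feasible:", x$feasible, " class:", x$stability_class, "\n")
  invisible(x)
}

#' Tidy a fixed point into one row per coordinate
#'
#' @param x a `fixed_point` object.
#' @param ... unused.
#' @return A tibble with columns `compartment`, `value`.
#' @method tidy fixed_point
#' @export
tidy.fixed_point <- function(x, ...) {
  tibble::tibble(compartment = names(x$coordinates),
                 value = unname(x$coordinates))
}

#' One-row summary of a fixed point
#'
#' @param x a `fixed_point` object.
#' @param ... unused.
#' @return A tibble with feasibility, stability class, dominant eigenvalue
#'   real part (the damping rate when the point is the stable coexistence
#'   state) and dominant oscillation frequency.
#' @export
glance.fixed_point <- function(x, ...) {
  tibble::tibble(model = x$model,
                 feasible = x$feasible,
                 stability_class = x$stability_class,
                 max_real_eig = max(Re(x$eigenvalues)),
                 dominant_freq = max(abs(Im(x$eigenvalues))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
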