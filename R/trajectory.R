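#' Closed-form solution for the peaceful density
#'
#' The reduced ODE factors as `beta * (p1 - sigma_P) * (p2 - sigma_P)`, a
#' Riccati (logistic-type) equation whose solution between the roots is
#' \deqn{\sigma_P(t) = p_2 + \frac{p_1 - p_2}
#'   {1 - \frac{\sigma_P(0) - p_1}{\sigma_P(0) - p_2}
#'        e^{\beta (p_1 - p_2) t}}.}
#' When the roots coincide (`p1 = p2 = p`, the marginal threshold case) the
#' double-root form `sigma_P(t) = p + u0 / (1 - beta * u0 * t)` with
#' `u0 = sigma_P(0) - p` applies; in the physical domain `u0 <= 0`, so the
#' denominator never vanishes for `t >= 0` and the equilibrium is approached
#' algebraically (power law) instead of exponentially.
#'
#' For large `beta * (p1 - p2) * t` the exponential limit is taken
#' analytically, never evaluated as an overflowing number. A start exactly
#' on a root stays there. Output is clipped to `[0, 1 - sigma_I]` only to
#' absorb last-bit rounding.
#'
#' @param params A [model_params] object with `beta > 0`.
#' @param sigma_P0 Initial peaceful fraction, in `[0, 1 - sigma_I]`.
#' @param t Time or vector of times, `>= 0`.
#' @return `sigma_P(t)`, vectorized over `t`.
#' @examples
#' p <- model_params(0.1, 22, 2)
#' closed_form_sigma_P(p, 0.5, c(0, 1, 10)) # tends to p1 = 0.9
#' @export
closed_form_sigma_P <- function(params, sigma_P0, t) {
  params <- as_model_params(params)
  if (params$beta <= 0)
    stop("closed form requires beta > 0 (at beta = 0 the opponent fraction ",
         "decays exponentially at rate alpha * sigma_I)", call. = FALSE)
  hi <- 1 - params$sigma_I
  if (sigma_P0 < -params$tol || sigma_P0 > hi + params$tol)
    stop(sprintf("sigma_P0 must lie in [0, %g]", hi), call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  sigma_P0 <- min(max(sigma_P0, 0), hi)

  roots <- equilibrium_roots(params)
  p1 <- roots$p1; p2 <- roots$p2

  if (abs(p1 - p2) <= params$tol) {          # double root: algebraic decay
    u0 <- sigma_P0 - p1
    out <- p1 + u0 / (1 - params$beta * u0 * t)
  } else if (abs(sigma_P0 - p1) <= .Machine$double.eps) {
    out <- rep(p1, length(t))                # fixed point
  } else if (abs(sigma_P0 - p2) <= .Machine$double.eps) {
    out <- rep(p2, length(t))                # fixed point
  } else {
    s0 <- (sigma_P0 - p1) / (sigma_P0 - p2)
    ex <- params$beta * (p1 - p2) * t
    out <- ifelse(ex > 700,                  # exp would overflow: limit is p2
                  p2,
                  p2 + (p1 - p2) / (1 - s0 * exp(ex)))
  }
  pmin(pmax(out, 0), hi)
}

#' Integrate the mean-field dynamics numerically
#'
#' Solves the reduced one-dimensional ODE with `deSolve` and derives the
#' opponent fraction pointwise from the conservation constraint
#' `sigma_O(t) = 1 - sigma_I - sigma_P(t)`, so the three fractions sum to
#' one at every output time by construction. The default horizon is scaled
#' to the relaxation rate of the stable equilibrium, `t_max = 20 / |lambda|`,
#' so the equilibrium is resolved; in the marginal double-root case (where
#' `lambda = 0` and the approach is a power law) the default is `200 / beta`.
#'
#' @param params A [model_params] object.
#' @param sigma_O0 Initial opponent fraction; the initial peaceful fraction
#'   is `1 - sigma_I - sigma_O0`.
#' @param t_max Integration horizon (`> 0`); `NULL` for the scaled default.
#' @param n_out Number of evenly spaced output times on `[0, t_max]`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method `deSolve` integration method.
#' @return A `trajectory`: a data frame with columns `t`, `sigma_I`,
#'   `sigma_P`, `sigma_O`, carrying the parameters and a provenance tag
#'   (`"numeric"`) as attributes.
#' @examples
#' traj <- integrate_trajectory(model_params(0.3, 1, 1), sigma_O0 = 0.3)
#' tail(traj, 2) # converges to sigma_P = 0.3, sigma_O = 0.4
#' @export
integrate_trajectory <- function(params, sigma_O0, t_max = NULL,
                                 n_out = 512, rtol = 1e-12, atol = 1e-12,
                                 method = "lsoda") {
  params <- as_model_params(params)
  hi <- 1 - params$sigma_I
  if (sigma_O0 < -params$tol || sigma_O0 > hi + params$tol)
    stop(sprintf("sigma_O0 must lie in [0, %g]", hi), call. = FALSE)
  sigma_O0 <- min(max(sigma_O0, 0), hi)
  sigma_P0 <- hi - sigma_O0
  if (is.null(t_max)) t_max <- default_horizon(params)
  if (t_max <= 0) stop("'t_max' must be > 0", call. = FALSE)
  if (n_out < 2) stop("'n_out' must be >= 2", call. = FALSE)

  times <- seq(0, t_max, length.out = n_out)
  deriv <- function(t, y, parms) {
    sO <- hi - y[1]
    list(params$alpha * params$sigma_I * sO - params$beta * sO * y[1])
  }
  sol <- deSolve::ode(y = c(sigma_P = sigma_P0), times = times,
                      func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(sol) < n_out || abs(sol[nrow(sol), "time"] - t_max) > 1e-10)
    stop("integrator step control failed before reaching t_max", call. = FALSE)

  sigma_P <- pmin(pmax(unname(sol[, "sigma_P"]), 0), hi)
  new_trajectory(
    data.frame(t = times, sigma_I = params$sigma_I,
               sigma_P = sigma_P, sigma_O = hi - sigma_P),
    params = params, provenance = "numeric"
  )
}

#' Trajectory from the closed-form solution
#'
#' Same output grid and columns as [integrate_trajectory()], but every point
#' is evaluated from the analytic solution.
#'
#' @inheritParams integrate_trajectory
#' @return A `trajectory` with provenance `"closed_form"`.
#' @export
closed_form_trajectory <- function(params, sigma_O0, t_max = NULL,
                                   n_out = 512) {
  params <- as_model_params(params)
  hi <- 1 - params$sigma_I
  if (sigma_O0 < -params$tol || sigma_O0 > hi + params$tol)
    stop(sprintf("sigma_O0 must lie in [0, %g]", hi), call. = FALSE)
  sigma_O0 <- min(max(sigma_O0, 0), hi)
  if (is.null(t_max)) t_max <- default_horizon(params)
  times <- seq(0, t_max, length.out = n_out)
  sigma_P <- closed_form_sigma_P(params, hi - sigma_O0, times)
  new_trajectory(
    data.frame(t = times, sigma_I = params$sigma_I,
               sigma_P = sigma_P, sigma_O = hi - sigma_P),
    params = params, provenance = "closed_form"
  )
}

new_trajectory <- function(df, params, provenance) {
  structure(df, params = params, provenance = provenance,
            class = c("trajectory", "data.frame"))
}

# Horizon scaled so the stable equilibrium is resolved.
default_horizon <- function(params) {
  rep <- stability(params)
  if (rep$degenerate) {
    rate <- params$alpha * params$sigma_I
    return(if (rate > 0) 20 / rate else 1)
  }
  if (rep$marginal) return(200 / params$beta)
  20 / abs(rep$lambda1)
}

#' Detect the equilibrium reached by a trajectory
#'
#' Declares convergence when the ODE right-hand side at the final state is
#' below `tol` in absolute value. The values are reported either way, with
#' `converged = FALSE` signalling that the horizon was too short.
#'
#' @param traj A `trajectory` from [integrate_trajectory()] or
#'   [closed_form_trajectory()].
#' @param tol Convergence tolerance on `|d sigma_P / dt|` at the final state.
#' @return A list with `sigma_P_eq`, `sigma_O_eq` and `converged`.
#' @export
equilibrium_from_trajectory <- function(traj, tol = 1e-8) {
  if (!inherits(traj, "trajectory") || nrow(traj) == 0)
    stop("'traj' must be a non-empty trajectory", call. = FALSE)
  params <- attr(traj, "params")
  final <- traj[nrow(traj), ]
  rate <- rhs(params, final$sigma_P)
  list(sigma_P_eq = final$sigma_P, sigma_O_eq = final$sigma_O,
       converged = abs(rate) < tol)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s), %d samples on [0, %g]\n",
              attr(x, "provenance"), nrow(x), x$t[nrow(x)]))
  NextMethod()
}
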