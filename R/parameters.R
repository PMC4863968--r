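#' Model parameters for the three-compartment radicalization model
#'
#' The population is split into a constant fraction `sigma_I` of inflexible
#' core agents and a sensitive remainder `1 - sigma_I` that moves between a
#' peaceful and an opponent (radicalized) state. `alpha` is the per-unit-time
#' rate at which encounters with inflexible agents turn opponents peaceful;
#' `beta` is the rate at which opponents convert peaceful agents. Time units
#' are arbitrary: the rates set the scale.
#'
#' @param sigma_I Inflexible (core) population fraction, in `[0, 1]`.
#' @param alpha Opponent-to-peaceful conversion rate per unit time, `>= 0`.
#' @param beta Peaceful-to-opponent conversion rate per unit time, `>= 0`.
#' @param tol Absolute tolerance used for floating-point comparisons by
#'   downstream routines (equality of roots, domain checks).
#'
#' @return An object of class `model_params`: a list with fields `sigma_I`,
#'   `alpha`, `beta` and `tol`.
#' @examples
#' model_params(sigma_I = 0.1, alpha = 22, beta = 2)
#' @export
model_params <- function(sigma_I, alpha, beta, tol = 1e-9) {
  check_scalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  check_scalar(sigma_I, "sigma_I")
  check_scalar(alpha, "alpha")
  check_scalar(beta, "beta")
  check_scalar(tol, "tol")
  if (sigma_I < 0 || sigma_I > 1)
    stop("'sigma_I' must lie in [0, 1]", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  structure(
    list(sigma_I = sigma_I, alpha = alpha, beta = beta, tol = tol),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Radicalization model parameters\n")
  cat(sprintf("  sigma_I = %g (inflexible fraction)\n", x$sigma_I))
  cat(sprintf("  alpha   = %g (opponent -> peaceful rate)\n", x$alpha))
  cat(sprintf("  beta    = %g (peaceful -> opponent rate)\n", x$beta))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x) && all(c("sigma_I", "alpha", "beta") %in% names(x)))
    return(model_params(x$sigma_I, x$alpha, x$beta,
                        tol = if (is.null(x$tol)) 1e-9 else x$tol))
  stop("cannot interpret input as model parameters", call. = FALSE)
}

#' Population state at a given time
#'
#' A state records the peaceful and opponent fractions at time `t`; the
#' inflexible fraction is constant and carried by the parameters. The three
#' fractions must sum to one.
#'
#' @param t Time, `>= 0`.
#' @param sigma_P Peaceful fraction, `>= 0`.
#' @param sigma_O Opponent fraction, `>= 0`.
#' @param sigma_I Inflexible fraction the state is checked against.
#' @param tol Tolerance for the conservation check.
#'
#' @return An object of class `population_state`.
#' @examples
#' population_state(0, sigma_P = 0.4, sigma_O = 0.3, sigma_I = 0.3)
#' @export
population_state <- function(t, sigma_P, sigma_O, sigma_I, tol = 1e-9) {
  if (!is.finite(t) || t < 0) stop("'t' must be >= 0", call. = FALSE)
  if (!is.finite(sigma_P) || sigma_P < -tol)
    stop("'sigma_P' must be >= 0", call. = FALSE)
  if (!is.finite(sigma_O) || sigma_O < -tol)
    stop("'sigma_O' must be >= 0", call. = FALSE)
  if (abs(sigma_I + sigma_P + sigma_O - 1) > tol)
    stop("fractions must satisfy sigma_I + sigma_P + sigma_O = 1",
         call. = FALSE)
  structure(
    list(t = t, sigma_P = max(sigma_P, 0), sigma_O = max(sigma_O, 0),
         sigma_I = sigma_I),
    class = "population_state"
  )
}
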