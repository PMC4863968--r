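#' Right-hand side of the reduced peaceful-density ODE
#'
#' Eliminating the opponent fraction through the conservation constraint
#' `sigma_O = 1 - sigma_I - sigma_P` reduces the dynamics to one equation,
#' \deqn{d\sigma_P/dt = \alpha \sigma_I (1 - \sigma_I - \sigma_P)
#'                      - \beta (1 - \sigma_I - \sigma_P)\, \sigma_P,}
#' which factors as `beta * (p1 - sigma_P) * (p2 - sigma_P)` with the two
#' equilibrium roots `p1 = 1 - sigma_I` and `p2 = (alpha/beta) * sigma_I`.
#'
#' @param params A [model_params] object.
#' @param sigma_P Peaceful fraction(s), each in the physical domain
#'   `[0, 1 - sigma_I]`.
#' @return The rate of change of `sigma_P`, per unit time (vectorized).
#' @examples
#' p <- model_params(0.3, 1, 1)
#' rhs(p, 0.4) # -0.03
#' @export
rhs <- function(params, sigma_P) {
  params <- as_model_params(params)
  hi <- 1 - params$sigma_I
  if (any(sigma_P < -params$tol | sigma_P > hi + params$tol))
    stop(sprintf("sigma_P must lie in the physical domain [0, %g]", hi),
         call. = FALSE)
  sigma_O <- hi - sigma_P
  params$alpha * params$sigma_I * sigma_O - params$beta * sigma_O * sigma_P
}

#' Equilibrium roots of the peaceful density
#'
#' The equilibrium condition is a quadratic in `sigma_P` with the two roots
#' `p1 = 1 - sigma_I` (opponent-free state) and `p2 = (alpha/beta) * sigma_I`
#' (coexistence state; `p2` may exceed 1, in which case it is unphysical and
#' `p1` is the attractor). At `beta = 0` the coexistence root is undefined:
#' the dynamics degenerate to pure decay of the opponent fraction and only
#' `p1` is reported, with `p2 = NA` and `degenerate = TRUE`.
#'
#' @param params A [model_params] object.
#' @return A list with `p1`, `p2` and a logical `degenerate` flag.
#' @examples
#' equilibrium_roots(model_params(0.1, 22, 2)) # p1 = 0.9, p2 = 1.1
#' @export
equilibrium_roots <- function(params) {
  params <- as_model_params(params)
  p1 <- 1 - params$sigma_I
  if (params$beta == 0)
    return(list(p1 = p1, p2 = NA_real_, degenerate = TRUE))
  list(p1 = p1, p2 = (params$alpha / params$beta) * params$sigma_I,
       degenerate = FALSE)
}

#' Critical inflexible fraction
#'
#' The threshold `I_c = beta / (alpha + beta)`: when the inflexible fraction
#' reaches or exceeds it, the opponent compartment is driven extinct at
#' equilibrium (radicalization is thwarted).
#'
#' @param params A [model_params] object.
#' @return The critical fraction, in `[0, 1]`.
#' @examples
#' critical_threshold(model_params(0.1, 22, 2)) # 1/12
#' @export
critical_threshold <- function(params) {
  params <- as_model_params(params)
  if (params$alpha + params$beta == 0)
    stop("critical threshold undefined when alpha = beta = 0", call. = FALSE)
  params$beta / (params$alpha + params$beta)
}

#' Minimum core engagement needed to extinguish the opponents
#'
#' Given the inflexible fraction and the opponents' conversion rate `beta`,
#' returns the engagement level `alpha* = (1/sigma_I - 1) * beta`. Any
#' `alpha >= alpha*` makes the opponent fraction vanish at equilibrium (the
#' equality case is marginal: extinction is approached algebraically rather
#' than exponentially). Setting `alpha = alpha*` makes `sigma_I` exactly
#' equal to the critical fraction [critical_threshold()].
#'
#' @param sigma_I Inflexible fraction, in `(0, 1]`.
#' @param beta Peaceful-to-opponent conversion rate, `>= 0`.
#' @return The threshold rate `alpha*`.
#' @examples
#' min_core_engagement(0.5, 2)  # 2: equal engagement suffices at parity
#' min_core_engagement(0.25, 1) # 3
#' @export
min_core_engagement <- function(sigma_I, beta) {
  if (!is.numeric(sigma_I) || any(!is.finite(sigma_I)) ||
      any(sigma_I <= 0) || any(sigma_I > 1))
    stop("'sigma_I' must lie in (0, 1]", call. = FALSE)
  if (any(beta < 0)) stop("'beta' must be >= 0", call. = FALSE)
  (1 / sigma_I - 1) * beta
}

#' Equilibrium and linear stability report
#'
#' Linearizing the reduced ODE about each root gives the eigenvalues
#' `lambda1 = beta * (p1 - p2)` at `p1` and `lambda2 = -lambda1` at `p2`;
#' the smaller root is always the stable one. Stability of the opponent-free
#' root `p1` is equivalent to `sigma_I >= I_c`. The report carries the
#' selected equilibrium, both eigenvalues, the critical fraction and the
#' regime classification from [classify_regime()].
#'
#' @param params A [model_params] object.
#' @return An object of class `equilibrium_report`: a list with fields
#'   `p1`, `p2`, `lambda1`, `lambda2`, `stable_root` (`"p1"`, `"p2"` or
#'   `"marginal"`), `sigma_P_eq`, `sigma_O_eq`, `I_c`, `regime`, `thwarted`,
#'   `marginal` and `degenerate` (`TRUE` for the `beta = 0` limit).
#' @examples
#' stability(model_params(0.1, 22, 2)) # p1 stable, opponents extinct
#' stability(model_params(0.1, 12, 2)) # coexistence, sigma_O_eq = 0.3
#' @export
stability <- function(params) {
  params <- as_model_params(params)
  roots <- equilibrium_roots(params)
  regime <- classify_regime(params)
  I_c <- if (params$alpha + params$beta > 0) critical_threshold(params)
         else NA_real_

  if (roots$degenerate) {
    # beta = 0: pure exponential decay of sigma_O at rate alpha * sigma_I
    rep <- list(
      p1 = roots$p1, p2 = NA_real_,
      lambda1 = -params$alpha * params$sigma_I, lambda2 = NA_real_,
      stable_root = "p1",
      sigma_P_eq = roots$p1, sigma_O_eq = 0,
      I_c = I_c, regime = regime$case, thwarted = TRUE,
      marginal = FALSE, degenerate = TRUE
    )
    class(rep) <- "equilibrium_report"
    return(rep)
  }

  lambda1 <- params$beta * (roots$p1 - roots$p2)
  marginal <- abs(roots$p1 - roots$p2) <= params$tol
  if (marginal) {
    stable_root <- "marginal"
    sigma_P_eq <- roots$p1
    sigma_O_eq <- 0
  } else if (roots$p1 < roots$p2) {
    stable_root <- "p1"
    sigma_P_eq <- roots$p1
    sigma_O_eq <- 0
  } else {
    stable_root <- "p2"
    sigma_P_eq <- roots$p2
    sigma_O_eq <- 1 - ((params$alpha + params$beta) / params$beta) *
      params$sigma_I
  }

  rep <- list(
    p1 = roots$p1, p2 = roots$p2,
    lambda1 = lambda1, lambda2 = -lambda1,
    stable_root = stable_root,
    sigma_P_eq = sigma_P_eq, sigma_O_eq = sigma_O_eq,
    I_c = I_c, regime = regime$case, thwarted = regime$thwarted,
    marginal = marginal, degenerate = FALSE
  )
  class(rep) <- "equilibrium_report"
  rep
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibrium report\n")
  cat(sprintf("  roots:       p1 = %g, p2 = %s\n", x$p1,
              if (is.na(x$p2)) "NA (beta = 0)" else format(x$p2)))
  cat(sprintf("  eigenvalues: lambda1 = %g, lambda2 = %s\n", x$lambda1,
              if (is.na(x$lambda2)) "NA" else format(x$lambda2)))
  cat(sprintf("  stable root: %s\n", x$stable_root))
  cat(sprintf("  equilibrium: sigma_P = %g, sigma_O = %g\n",
              x$sigma_P_eq, x$sigma_O_eq))
  cat(sprintf("  I_c = %s; regime = %s; thwarted = %s%s\n",
              if (is.na(x$I_c)) "NA" else format(x$I_c),
              x$regime, x$thwarted,
              if (isTRUE(x$marginal)) " (marginal)" else ""))
  invisible(x)
}

#' Classify the core-majority regime and the fate of radicalization
#'
#' Two independent labels: the case depends only on whether the inflexible
#' core is a majority (`case1`: `sigma_I > 1/2`), exactly half (`case2`) or
#' a minority (`case3`); the `thwarted` flag records whether the opponents
#' go extinct at equilibrium, i.e. `sigma_I >= I_c`, equivalently
#' `alpha/beta >= 1/sigma_I - 1`. The labels are deliberately not merged: a
#' core majority can still face permanent radicalization when the opponent
#' rate `beta` is large enough, and a small core can thwart it with enough
#' engagement.
#'
#' @param params A [model_params] object.
#' @return A list with `case` (`"case1"`, `"case2"` or `"case3"`),
#'   `thwarted` and `marginal` (exactly on the threshold, within tolerance).
#' @examples
#' classify_regime(model_params(0.6, 0.5, 2))  # majority core, not thwarted
#' classify_regime(model_params(0.28, 0.5, 0.5)) # minority, coexistence
#' @export
classify_regime <- function(params) {
  params <- as_model_params(params)
  case <- if (params$sigma_I > 0.5) "case1"
          else if (params$sigma_I == 0.5) "case2"
          else "case3"
  if (params$alpha + params$beta == 0)
    return(list(case = case, thwarted = NA, marginal = FALSE))
  I_c <- params$beta / (params$alpha + params$beta)
  marginal <- abs(params$sigma_I - I_c) <= params$tol
  list(case = case, thwarted = params$sigma_I >= I_c - params$tol,
       marginal = marginal)
}
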