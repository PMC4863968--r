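#' Degree-of-radicalization indices
#'
#' Two complementary indices of how radicalized a population is:
#' `zeta = sigma_O / (1 - sigma_I)`, the opponents' share of the flexible
#' (sensitive) subpopulation, always in `[0, 1]`; and
#' `eta = sigma_O / sigma_I`, opponents per inflexible agent, unbounded
#' above. `zeta = 0` means no opponents; `zeta = 1` means every flexible
#' agent is an opponent. `eta > 1` means opponents outnumber the core.
#'
#' Edge cases: with `sigma_I = 1` (no flexible agents) `zeta` is defined as
#' 0; with `sigma_I = 0`, `eta` is reported as `Inf` with the
#' `eta_infinite` flag set rather than raising an error.
#'
#' @param sigma_I Inflexible fraction.
#' @param sigma_O Opponent fraction, with `sigma_I + sigma_O <= 1`.
#' @return An object of class `radicalization_metrics`: a list with `zeta`,
#'   `eta` and `eta_infinite`.
#' @examples
#' radicalization_degree(0.1, 0.4) # zeta = 4/9, eta = 4
#' @export
radicalization_degree <- function(sigma_I, sigma_O) {
  if (any(sigma_I < 0 | sigma_I > 1)) stop("'sigma_I' must lie in [0, 1]",
                                           call. = FALSE)
  if (any(sigma_O < 0)) stop("'sigma_O' must be >= 0", call. = FALSE)
  if (any(sigma_I + sigma_O > 1 + 1e-9))
    stop("'sigma_I + sigma_O' must not exceed 1", call. = FALSE)
  zeta <- ifelse(sigma_I == 1, 0, sigma_O / (1 - sigma_I))
  eta <- ifelse(sigma_I == 0, Inf, sigma_O / sigma_I)
  structure(list(zeta = zeta, eta = eta, eta_infinite = sigma_I == 0),
            class = "radicalization_metrics")
}

#' @export
print.radicalization_metrics <- function(x, ...) {
  cat(sprintf("zeta = %s, eta = %s%s\n",
              format(x$zeta), format(x$eta),
              if (any(x$eta_infinite)) " (eta unbounded: sigma_I = 0)" else ""))
  invisible(x)
}

#' Radicalization indices along a trajectory
#'
#' Applies [radicalization_degree()] pointwise, returning the trajectory
#' with `zeta` and `eta` columns appended (same time grid and length).
#'
#' @param traj A `trajectory`.
#' @return The trajectory with columns `zeta` and `eta` added.
#' @export
metrics_series <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("'traj' must be a trajectory",
                                          call. = FALSE)
  m <- radicalization_degree(traj$sigma_I, traj$sigma_O)
  traj$zeta <- m$zeta
  traj$eta <- m$eta
  traj
}

#' Qualitative reading of the radicalization indices
#'
#' Maps the two indices onto an advisory label. The numeric cutoffs have no
#' counterpart in the underlying theory; they are configurable defaults
#' that encode the qualitative grid: low `zeta` with `eta` above 1
#' (opponents outnumbering the core) is `"alarming"`; `zeta` near 1 in a
#' core-majority population is a `"latent-warning"` (weak counter-strategy
#' but few opponents overall); `zeta` near 1 otherwise is
#' `"fully-radicalized"`; low `zeta` with modest `eta` is `"contained"`.
#' Labels are advisory output only and are never used in computation.
#'
#' @param metrics A `radicalization_metrics` object (scalar fields).
#' @param sigma_I Inflexible fraction of the population assessed.
#' @param zeta_low,zeta_high Cutoffs for "close to 0" / "close to 1".
#' @param eta_high Cutoff above which opponents are deemed to overpower the
#'   core (default 1: opponents outnumber inflexibles).
#' @return One of `"contained"`, `"latent-warning"`, `"alarming"`,
#'   `"fully-radicalized"`.
#' @examples
#' interpret_radicalization(radicalization_degree(0.3, 0), 0.3) # contained
#' @export
interpret_radicalization <- function(metrics, sigma_I,
                                     zeta_low = 0.25, zeta_high = 0.75,
                                     eta_high = 1) {
  if (!inherits(metrics, "radicalization_metrics"))
    stop("'metrics' must come from radicalization_degree()", call. = FALSE)
  zeta <- metrics$zeta[1]
  eta <- metrics$eta[1]
  if (zeta >= zeta_high) {
    if (sigma_I > 0.5) "latent-warning" else "fully-radicalized"
  } else if (eta > eta_high) {
    "alarming"
  } else {
    "contained"
  }
}
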