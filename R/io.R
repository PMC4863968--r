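#' Write a trajectory to CSV
#'
#' Emits the columns `t,sigma_I,sigma_P,sigma_O,zeta,eta` (comma-separated,
#' `.` decimal, header row, UTF-8), computing the radicalization indices if
#' the trajectory does not carry them yet.
#'
#' @param traj A `trajectory`.
#' @param path Output file path, or `""` for standard output.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path = "") {
  if (!inherits(traj, "trajectory"))
    stop("'traj' must be a trajectory", call. = FALSE)
  if (!all(c("zeta", "eta") %in% names(traj))) traj <- metrics_series(traj)
  cols <- c("t", "sigma_I", "sigma_P", "sigma_O", "zeta", "eta")
  utils::write.csv(as.data.frame(traj)[, cols], file = path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Equilibrium summary of a trajectory
#'
#' Combines the numerically detected equilibrium with the closed-form
#' analysis of the same parameters: roots, eigenvalues, critical fraction,
#' regime, and the radicalization indices at the detected equilibrium.
#'
#' @param traj A `trajectory`.
#' @param tol Convergence tolerance, as in [equilibrium_from_trajectory()].
#' @return A named list, ready for JSON serialization.
#' @export
trajectory_summary <- function(traj, tol = 1e-8) {
  params <- attr(traj, "params")
  eq <- equilibrium_from_trajectory(traj, tol = tol)
  rep <- stability(params)
  m <- radicalization_degree(params$sigma_I, eq$sigma_O_eq)
  list(
    sigma_I = params$sigma_I, alpha = params$alpha, beta = params$beta,
    sigma_P_eq = eq$sigma_P_eq, sigma_O_eq = eq$sigma_O_eq,
    converged = eq$converged,
    p1 = rep$p1, p2 = rep$p2, lambda1 = rep$lambda1, lambda2 = rep$lambda2,
    stable_root = rep$stable_root, I_c = rep$I_c,
    regime = rep$regime, thwarted = rep$thwarted,
    zeta_eq = m$zeta, eta_eq = m$eta
  )
}

#' Write a summary as JSON
#'
#' Numbers are emitted at full double precision.
#'
#' @param x A named list.
#' @param path Output path, or `""` for standard output.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path = "") {
  if (identical(path, "")) {
    cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null"), "\n")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

# 32-bit FNV-1a hash of a character string; used for config provenance.
# Arithmetic is done in doubles, split so no intermediate exceeds 2^53.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)  # xor touches low byte only
    h <- ((h %/% 65536 * prime) %% 65536) * 65536 + (h %% 65536) * prime
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}

#' Provenance block for a run
#'
#' Every CLI run embeds this block in its JSON output: tool name and
#' version, a hash of the resolved configuration, and the seed (when the
#' run is stochastic).
#'
#' @param config A named list of resolved settings.
#' @param seed Integer seed or `NULL` for deterministic runs.
#' @return A named list.
#' @export
provenance_block <- function(config, seed = NULL) {
  cfg <- config[order(names(config))]
  serialized <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  list(
    tool = "radcon",
    version = as.character(utils::packageVersion("radcon")),
    config_hash = fnv1a32(serialized),
    seed = seed
  )
}
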