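#' Nine benchmark scenarios spanning the model's regimes
#'
#' A fixed set of nine named scenarios (keys `a` to `i`) covering the
#' qualitative behaviors of the model: symmetric rates with coexistence,
#' opponent-dominated dynamics under large `beta`, and core fractions above
#' the critical threshold where opponents go extinct. Each row gives the
#' inflexible fraction, the initial opponent fraction (the initial peaceful
#' fraction is `1 - sigma_I - sigma_O0`) and the two rates.
#'
#' @return A data frame with columns `name`, `sigma_I`, `sigma_O0`,
#'   `alpha`, `beta`, one scenario per row.
#' @examples
#' worked_scenarios()
#' @export
worked_scenarios <- function() {
  data.frame(
    name = letters[1:9],
    sigma_I = c(0.3, 0.3, 0.3, 0.28, 0.3, 0.1, 0.1, 0.1, 0.28),
    sigma_O0 = c(0.3, 0.3, 0.3, 0.02, 0.3, 0.4, 0.4, 0.4, 0.7),
    alpha = c(1, 1, 4, 0.5, 1, 4, 12, 22, 0.5),
    beta = c(1, 2, 2, 0.5, 5, 2, 2, 2, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration
#'
#' Bundles everything one run needs: model parameters, the initial opponent
#' fraction, integration settings, stochastic-simulation settings and a
#' seed. Round-trips losslessly through YAML via
#' [write_scenario_config()] / [read_scenario_config()].
#'
#' @param sigma_I,alpha,beta Model parameters, as in [model_params()].
#' @param sigma_O0 Initial opponent fraction.
#' @param t_max Integration horizon (`NULL` for the scaled default).
#' @param n_out Output grid size for trajectories.
#' @param n_agents Population size for the stochastic simulator.
#' @param replicates Stochastic replicates.
#' @param seed RNG seed for stochastic runs.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(sigma_I, alpha, beta, sigma_O0,
                            t_max = NULL, n_out = 512,
                            n_agents = 10000L, replicates = 1L,
                            seed = NULL) {
  params <- model_params(sigma_I, alpha, beta)  # validates
  if (sigma_O0 < 0 || sigma_O0 > 1 - sigma_I)
    stop("'sigma_O0' must lie in [0, 1 - sigma_I]", call. = FALSE)
  structure(
    list(sigma_I = sigma_I, alpha = alpha, beta = beta,
         sigma_O0 = sigma_O0, t_max = t_max, n_out = as.integer(n_out),
         n_agents = as.integer(n_agents), replicates = as.integer(replicates),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "scenario_config"
  )
}

#' Look up one benchmark scenario as a configuration
#'
#' @param name One of the scenario keys `"a"` to `"i"`.
#' @param ... Further settings passed to [scenario_config()].
#' @return A `scenario_config`.
#' @examples
#' worked_scenario("h") # core above threshold: opponents go extinct
#' @export
worked_scenario <- function(name, ...) {
  sc <- worked_scenarios()
  row <- sc[sc$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown scenario '", name, "'; available: ",
         paste(sc$name, collapse = ", "), call. = FALSE)
  scenario_config(sigma_I = row$sigma_I, alpha = row$alpha, beta = row$beta,
                  sigma_O0 = row$sigma_O0, ...)
}

#' @rdname scenario_config
#' @param path File path for the YAML configuration.
#' @export
write_scenario_config <- function(x, path) {
  if (!inherits(x, "scenario_config"))
    stop("'x' must be a scenario_config", call. = FALSE)
  fields <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname scenario_config
#' @param x A `scenario_config` (for writing).
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, raw)
}
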