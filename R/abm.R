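#' Configuration for the stochastic contact-process simulator
#'
#' Describes a finite population of `N = n_I + n_P + n_O` agents evolving by
#' pairwise contacts: opponents turn peaceful at total rate
#' `alpha * (n_I / N) * n_O` and peaceful agents turn opponent at total rate
#' `beta * (n_O / N) * n_P`. The per-capita hazards are normalized by `N` so
#' the large-`N` limit reproduces the mean-field ODE with the same rates.
#' The population is well mixed (no interaction topology).
#'
#' @param n_I,n_P,n_O Initial counts of inflexible, peaceful and opponent
#'   agents (non-negative, summing to `N > 0`).
#' @param alpha,beta Conversion rates, as in [model_params()].
#' @param t_max Simulated time horizon; `NULL` for the relaxation-scaled
#'   default used by [integrate_trajectory()].
#' @param seed RNG seed (required for reproducibility; auto-generated and
#'   reported via a message when omitted).
#' @param replicates Number of independent runs.
#' @return An object of class `abm_config`.
#' @examples
#' abm_config(n_I = 100, n_P = 500, n_O = 400, alpha = 12, beta = 2,
#'            seed = 42)
#' @export
abm_config <- function(n_I, n_P, n_O, alpha, beta, t_max = NULL,
                       seed = NULL, replicates = 1L) {
  counts <- c(n_I = n_I, n_P = n_P, n_O = n_O)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("agent counts must be non-negative integers", call. = FALSE)
  N <- sum(counts)
  if (N == 0) stop("total population N must be positive", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("rates must be >= 0", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  params <- model_params(n_I / N, alpha, beta)
  if (is.null(t_max)) t_max <- default_horizon(params)
  if (t_max <= 0) stop("'t_max' must be > 0", call. = FALSE)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("abm_config: no seed supplied; using auto-generated seed ", seed)
  }
  structure(
    list(N = as.integer(N), n_I = as.integer(n_I), n_P = as.integer(n_P),
         n_O = as.integer(n_O), alpha = alpha, beta = beta,
         t_max = t_max, seed = as.integer(seed),
         replicates = as.integer(replicates)),
    class = "abm_config"
  )
}

#' Run the stochastic contact process
#'
#' Exact continuous-time simulation (Gillespie direct method) over the two
#' aggregate reaction channels, run independently `replicates` times from
#' one seeding of R's RNG. Identical configurations (including the seed)
#' yield bit-identical event series. A replicate stops at `t_max` or at
#' absorption (no enabled channel: `n_O = 0`, or a frozen state when the
#' remaining inflow rate is zero).
#'
#' @param config An [abm_config] object.
#' @return An object of class `abm_result`: a list with `series` (one
#'   data frame `t, n_P, n_O` per replicate), `final` (one row per
#'   replicate: final time, counts, densities, absorbed flag) and the
#'   `config` (seed included).
#' @examples
#' cfg <- abm_config(n_I = 50, n_P = 250, n_O = 200, alpha = 12, beta = 2,
#'                   t_max = 5, seed = 1, replicates = 2)
#' res <- run_abm(cfg)
#' res$final
#' @export
run_abm <- function(config) {
  if (!inherits(config, "abm_config"))
    stop("'config' must come from abm_config()", call. = FALSE)
  if (config$alpha == 0 && config$beta == 0)
    warning("both rates are zero: the system is frozen", call. = FALSE)
  set.seed(config$seed)
  series <- vector("list", config$replicates)
  final <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    run <- gillespie_run_cpp(config$n_I, config$n_P, config$n_O,
                             config$alpha, config$beta, config$t_max)
    series[[r]] <- data.frame(t = run$t, n_P = run$n_P, n_O = run$n_O)
    k <- length(run$t)
    final[[r]] <- data.frame(
      replicate = r, t_final = run$t[k],
      n_P = run$n_P[k], n_O = run$n_O[k],
      sigma_P = run$n_P[k] / config$N, sigma_O = run$n_O[k] / config$N,
      absorbed = run$absorbed
    )
  }
  structure(
    list(series = series, final = do.call(rbind, final), config = config),
    class = "abm_result"
  )
}

#' Cross-replicate summary of final states
#'
#' Summary statistics over the final state of each replicate: mean,
#' standard error, minimum and maximum of the final peaceful and opponent
#' densities, and the fraction of replicates that reached absorption. With
#' a single replicate the standard errors are `NA` (flagged, not an error).
#'
#' @param result An `abm_result` from [run_abm()].
#' @return A list with `n_replicates`, `mean_sigma_P`, `mean_sigma_O`,
#'   `se_sigma_P`, `se_sigma_O`, `min_sigma_O`, `max_sigma_O`,
#'   `min_sigma_P`, `max_sigma_P` and `fraction_absorbed`.
#' @export
summarize_replicates <- function(result) {
  if (!inherits(result, "abm_result"))
    stop("'result' must come from run_abm()", call. = FALSE)
  fin <- result$final
  n <- nrow(fin)
  se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  list(
    n_replicates = n,
    mean_sigma_P = mean(fin$sigma_P), mean_sigma_O = mean(fin$sigma_O),
    se_sigma_P = se(fin$sigma_P), se_sigma_O = se(fin$sigma_O),
    min_sigma_P = min(fin$sigma_P), max_sigma_P = max(fin$sigma_P),
    min_sigma_O = min(fin$sigma_O), max_sigma_O = max(fin$sigma_O),
    fraction_absorbed = mean(fin$absorbed)
  )
}

#' @export
print.abm_result <- function(x, ...) {
  cat(sprintf("Contact-process simulation: N = %d, %d replicate(s), seed %d\n",
              x$config$N, x$config$replicates, x$config$seed))
  print(x$final, ...)
  invisible(x)
}
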