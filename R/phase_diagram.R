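#' Thwarted/permanent regime map over parameter space
#'
#' The fate of radicalization depends on the parameters only through the
#' inflexible fraction and the rate ratio `alpha/beta`: opponents go
#' extinct exactly when the ratio reaches the curve `1/sigma_I - 1`.
#' This builds the full grid classification, attaching the curve value, the
#' equilibrium opponent density and the equilibrium radicalization indices
#' to every cell. Boundary cells (equality within `tol`) carry a distinct
#' `marginal` flag so renderers can draw the critical curve.
#'
#' @param sigma_I Grid of inflexible fractions, strictly inside `(0, 1)`.
#'   Default: 99 evenly spaced points on `[0.01, 0.99]`.
#' @param ratio Grid of rate ratios `alpha/beta`, `>= 0`. Default: 100
#'   log-spaced points on `[0.01, 100]` (the critical curve diverges as
#'   `sigma_I` approaches 0, so log spacing resolves it).
#' @param tol Tolerance for boundary detection.
#' @return An object of class `phase_grid`: a data frame with columns
#'   `sigma_I`, `ratio`, `curve` (`1/sigma_I - 1`), `thwarted`, `marginal`,
#'   `sigma_O_eq`, `zeta_eq`, `eta_eq`.
#' @examples
#' g <- classify_grid(sigma_I = c(0.1, 0.5, 0.9), ratio = c(0.2, 1, 6))
#' subset(g, !thwarted)
#' @export
classify_grid <- function(sigma_I = seq(0.01, 0.99, length.out = 99),
                          ratio = exp(seq(log(0.01), log(100),
                                          length.out = 100)),
                          tol = 1e-9) {
  if (length(sigma_I) == 0 || length(ratio) == 0)
    stop("grids must be non-empty", call. = FALSE)
  if (any(sigma_I <= 0 | sigma_I >= 1))
    stop("'sigma_I' grid values must lie strictly inside (0, 1)",
         call. = FALSE)
  if (any(ratio < 0)) stop("'ratio' values must be >= 0", call. = FALSE)

  grid <- expand.grid(sigma_I = sigma_I, ratio = ratio,
                      KEEP.OUT.ATTRS = FALSE)
  grid$curve <- 1 / grid$sigma_I - 1
  grid$marginal <- abs(grid$ratio - grid$curve) <= tol
  grid$thwarted <- grid$ratio >= grid$curve - tol
  # Coexistence branch: sigma_O_eq = 1 - (ratio + 1) * sigma_I; zero on and
  # above the curve (both branches vanish at the boundary).
  grid$sigma_O_eq <- ifelse(grid$thwarted, 0,
                            1 - (grid$ratio + 1) * grid$sigma_I)
  m <- radicalization_degree(grid$sigma_I, grid$sigma_O_eq)
  grid$zeta_eq <- m$zeta
  grid$eta_eq <- m$eta
  structure(grid, class = c("phase_grid", "data.frame"))
}

#' Equilibrium surfaces over an explicit parameter grid
#'
#' Evaluates the stable equilibrium (peaceful and opponent densities and the
#' radicalization indices at equilibrium) for each row of a parameter grid.
#' The opponent surface is continuous across the critical boundary: both
#' branches give `sigma_O_eq = 0` there.
#'
#' @param grid A data frame with columns `sigma_I`, `alpha`, `beta`
#'   (`beta > 0` on all cells), one scenario per row.
#' @return The grid with columns `sigma_P_eq`, `sigma_O_eq`, `zeta_eq`,
#'   `eta_eq` appended.
#' @examples
#' equilibrium_surface(data.frame(sigma_I = 0.1, alpha = 12, beta = 2))
#' @export
equilibrium_surface <- function(grid) {
  req <- c("sigma_I", "alpha", "beta")
  if (!is.data.frame(grid) || !all(req %in% names(grid)))
    stop("'grid' must be a data frame with columns sigma_I, alpha, beta",
         call. = FALSE)
  if (any(grid$beta <= 0)) stop("'beta' must be > 0 on all cells",
                                call. = FALSE)
  eq <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- stability(model_params(grid$sigma_I[i], grid$alpha[i],
                                  grid$beta[i]))
    c(sigma_P_eq = rep$sigma_P_eq, sigma_O_eq = rep$sigma_O_eq)
  })
  eq <- do.call(rbind, eq)
  grid$sigma_P_eq <- eq[, "sigma_P_eq"]
  grid$sigma_O_eq <- eq[, "sigma_O_eq"]
  m <- radicalization_degree(grid$sigma_I, grid$sigma_O_eq)
  grid$zeta_eq <- m$zeta
  grid$eta_eq <- m$eta
  grid
}

#' Plot a phase grid
#'
#' Renders the thwarted/permanent regions with the critical curve
#' `1/sigma_I - 1` overlaid. The tabular grid is the tested artifact; this
#' figure is cosmetic. Requires `ggplot2`.
#'
#' @param grid A `phase_grid` from [classify_grid()].
#' @return A `ggplot` object.
#' @export
plot_phase_diagram <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package 'ggplot2' is required for plotting", call. = FALSE)
  if (!inherits(grid, "phase_grid"))
    stop("'grid' must come from classify_grid()", call. = FALSE)
  curve_df <- data.frame(sigma_I = sort(unique(grid$sigma_I)))
  curve_df$ratio <- 1 / curve_df$sigma_I - 1
  ggplot2::ggplot(grid, ggplot2::aes(x = sigma_I, y = ratio)) +
    ggplot2::geom_raster(ggplot2::aes(fill = thwarted)) +
    ggplot2::geom_line(data = curve_df, linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#ffd54f", `FALSE` = "#1a4f8b"),
      labels = c(`TRUE` = "thwarted", `FALSE` = "permanent"),
      name = NULL
    ) +
    ggplot2::labs(x = expression(sigma[I]), y = expression(alpha / beta))
}
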