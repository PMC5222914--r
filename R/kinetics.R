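#' Parametric release model
#'
#' A simple release law used both as the forward model of the synthetic
#' study generator and as the object recovered by [fit_power_law()]. The
#' power law \eqn{M_t/M_\infty = k t^n} (Korsmeyer--Peppas) is the
#' canonical choice for hydrophilic matrix tablets: its exponent n
#' operationalises the diffusion-vs-erosion release axis, with small n
#' indicating Fickian diffusion through the swollen gel layer and n near 1
#' indicating erosion-controlled (case-II) release.
#'
#' @param law One of `"power_law"`, `"first_order"`, `"zero_order"`.
#' @param k Rate coefficient (> 0). For the power law its units are
#'   % per min^n.
#' @param n Release exponent, power law only; must lie in (0, 1.2].
#' @param plateau Maximum cumulative release in percent (default 100,
#'   at most 110).
#' @return An object of class `release_model`.
#' @examples
#' release_model("power_law", k = 5, n = 0.5)
#' @export
release_model <- function(law = c("power_law", "first_order", "zero_order"),
                          k, n = NULL, plateau = 100) {
  law <- match.arg(law)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    dk_domain_error("k must be a single finite value > 0, got %s", k)
  if (law == "power_law") {
    if (is.null(n) || !is.finite(n) || n <= 0 || n > 1.2)
      dk_domain_error("power-law exponent n must lie in (0, 1.2], got %s",
                      if (is.null(n)) "NULL" else n)
  } else {
    n <- NA_real_
  }
  if (!is.finite(plateau) || plateau <= 0 || plateau > 110)
    dk_domain_error("plateau must lie in (0, 110] %%, got %s", plateau)
  structure(list(law = law, k = k, n = n, plateau = plateau),
            class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  par <- switch(x$law,
    power_law = sprintf("k = %.4g %%/min^%.3g, n = %.3g", x$k, x$n, x$n),
    first_order = sprintf("k = %.4g /min", x$k),
    zero_order = sprintf("k = %.4g %%/min", x$k))
  cat(sprintf("<release_model> %s: %s, plateau %g%%\n", x$law, par, x$plateau))
  invisible(x)
}

#' Simulate a noiseless release profile from a model
#'
#' Evaluates the release law on a sampling grid, capping at the plateau.
#' All laws give y(0) = 0.
#'
#' @param model A [release_model()].
#' @param grid Sampling times in minutes (strictly increasing, >= 0).
#' @param arm Optional [study_arm()] metadata to attach.
#' @param replicate_id Replicate label for the resulting profile.
#' @return A [dissolution_profile()].
#' @examples
#' m <- release_model("power_law", k = 5, n = 0.5)
#' simulate_release(m, c(0, 36, 144))$release  # 0 30 60
#' @export
simulate_release <- function(model, grid, arm = NULL, replicate_id = 1L) {
  stopifnot(inherits(model, "release_model"))
  grid <- as.numeric(grid)
  if (any(grid < 0) || any(diff(grid) <= 0))
    dk_domain_error("grid must be non-negative and strictly increasing")
  y <- switch(model$law,
    power_law  = pmin(model$plateau, model$k * grid^model$n),
    first_order = model$plateau * (1 - exp(-model$k * grid)),
    zero_order = pmin(model$plateau, model$k * grid))
  y[grid == 0] <- 0
  dissolution_profile(grid, y, arm = arm, replicate_id = replicate_id)
}

#' Fit the power law to a release profile
#'
#' Ordinary least squares of log(release) on log(time) over the points in
#' the power-law validity window (release at most `fit_cap`, conventionally
#' 60%). Returns the estimated rate coefficient and exponent plus a
#' mechanism label from the standard cylindrical-geometry thresholds on the
#' exponent: n <= 0.45 Fickian diffusion, 0.45 < n < 0.89 anomalous
#' transport, n >= 0.89 case-II (erosion-controlled) release.
#'
#' @param profile A [dissolution_profile()].
#' @param fit_cap Upper release bound (%) of the fitting window (default 60).
#' @return A `fit_result` list: `k_hat`, `n_hat`, `r_squared`,
#'   `n_points_fit`, `mechanism_label`.
#' @examples
#' m <- release_model("power_law", k = 5, n = 0.5)
#' fit_power_law(simulate_release(m, default_grid()))
#' @export
fit_power_law <- function(profile, fit_cap = 60) {
  stopifnot(inherits(profile, "dissolution_profile"))
  eligible <- profile$times > 0 & profile$release <= fit_cap
  t <- profile$times[eligible]
  y <- profile$release[eligible]
  if (any(y <= 0))
    dk_domain_error("non-positive release within the fitting window at t = %g min",
                    t[which(y <= 0)[1]])
  if (length(y) < 3)
    dk_insufficient_points(
      "only %d point(s) in (0, %g%%] fitting window; need at least 3",
      length(y), fit_cap)
  fit <- stats::lm(log(y) ~ log(t))
  n_hat <- unname(stats::coef(fit)[2])
  k_hat <- exp(unname(stats::coef(fit)[1]))
  # noiseless inputs fit exactly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(k_hat = k_hat, n_hat = n_hat,
                 r_squared = min(1, max(0, r2)),
                 n_points_fit = length(y),
                 mechanism_label = mechanism_from_exponent(n_hat)),
            class = "fit_result")
}

mechanism_from_exponent <- function(n) {
  if (n <= 0.45) "Fickian_diffusion"
  else if (n < 0.89) "anomalous"
  else "case_II_erosion"
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> k = %.4g, n = %.3f (R2 = %.4f, %d points): %s\n",
              x$k_hat, x$n_hat, x$r_squared, x$n_points_fit,
              x$mechanism_label))
  invisible(x)
}
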