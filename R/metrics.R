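#' Dissolution efficiency (DE)
#'
#' DE is the area under the cumulative release curve up to `t_end`,
#' expressed as a percentage of the area of the rectangle corresponding to
#' 100% release over the same interval:
#'
#' \deqn{DE = \frac{\int_0^{T} y\,dt}{100\,T} \times 100\%}
#'
#' The integral is evaluated by the trapezoidal rule on the observed grid,
#' with a (0, 0) origin prepended when absent and the release at `t_end`
#' obtained by linear interpolation when `t_end` falls between samples.
#'
#' @param profile A monotone [dissolution_profile()] (see
#'   [validate_and_repair()]).
#' @param t_end Integration horizon in minutes (default 720, i.e. DE over
#'   the full 12-h run).
#' @return DE in percent.
#' @examples
#' p <- dissolution_profile(c(0, 60, 120, 240), c(0, 60, 90, 100))
#' compute_de(p, t_end = 240)  # 73.75
#' @export
compute_de <- function(profile, t_end = 720) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (t_end <= 0) dk_domain_error("t_end must be > 0 min, got %g", t_end)
  profile <- prepend_origin(profile)
  t <- profile$times
  y <- profile$release
  if (t_end > t[length(t)])
    dk_extrapolation_error("t_end = %g min exceeds last sampled time %g min",
                           t_end, t[length(t)])
  keep <- t <= t_end
  tt <- t[keep]
  yy <- y[keep]
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end)
    yy <- c(yy, stats::approx(t, y, xout = t_end)$y)
  }
  100 * pracma::trapz(tt, yy) / (100 * t_end)
}

#' Mean dissolution time (MDT)
#'
#' The release-increment-weighted mean of interval midpoints: with
#' \eqn{\Delta M_j} the release over the j-th sampling interval and
#' \eqn{\bar t_j} the interval's midpoint,
#'
#' \deqn{MDT = \frac{\sum_j \bar t_j \,\Delta M_j}{\sum_j \Delta M_j}}
#'
#' MDT is the expected time for a drug molecule to dissolve under the in
#' vitro conditions. Computed in minutes on the observed grid (with origin
#' prepended) and reported in hours.
#'
#' @param profile A monotone [dissolution_profile()] with non-zero total
#'   release.
#' @return MDT in hours.
#' @examples
#' p <- dissolution_profile(c(0, 60, 120, 240), c(0, 60, 90, 100))
#' compute_mdt(p)  # 1.05
#' @export
compute_mdt <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  profile <- prepend_origin(profile)
  t <- profile$times
  y <- profile$release
  dM <- diff(y)
  if (sum(dM) <= 0)
    dk_undefined_statistic("total release is zero; MDT undefined")
  mid <- (t[-1] + t[-length(t)]) / 2
  sum(mid * dM) / sum(dM) / 60
}

#' Bundle DE and MDT for one profile
#'
#' @inheritParams compute_de
#' @return A `metrics_result` list: `de` (%), `mdt` (hours), `t_end`
#'   (minutes), `n_points`.
#' @export
compute_metrics <- function(profile, t_end = 720) {
  structure(list(de = compute_de(profile, t_end),
                 mdt = compute_mdt(profile),
                 t_end = t_end,
                 n_points = length(profile$times)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("<metrics_result> DE(%g min) = %.2f%%, MDT = %.2f h (%d points)\n",
              x$t_end, x$de, x$mdt, x$n_points))
  invisible(x)
}

#' Select the shared time points used by the similarity factor
#'
#' f2 compares the two curves at common sampling times. The origin is
#' excluded (both curves are 0 there by definition, which would only dilute
#' the statistic), and per regulatory convention at most one point is kept
#' once both profiles have reached 85% release -- beyond that the curves are
#' essentially complete and extra points would mask earlier differences.
#'
#' @param reference,test [dissolution_profile()] objects.
#' @param cap Release level (%) beyond which at most one shared point is
#'   retained (default 85).
#' @return A list with `times`, `reference`, `test` (aligned release
#'   values), `n_used` and `n_dropped`.
#' @export
select_f2_points <- function(reference, test, cap = 85) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  shared <- intersect(reference$times, test$times)
  shared <- sort(shared[shared > 0])
  total <- length(shared)
  r <- reference$release[match(shared, reference$times)]
  s <- test$release[match(shared, test$times)]
  over <- which(r >= cap & s >= cap)
  if (length(over) > 0) {
    keep <- seq_len(over[1])  # first point past the cap is retained
    r <- r[keep]; s <- s[keep]; shared <- shared[keep]
  }
  if (length(shared) < 3)
    dk_insufficient_points(
      "only %d shared time point(s) after selection; f2 needs at least 3",
      length(shared))
  list(times = shared, reference = r, test = s,
       n_used = length(shared), n_dropped = total - length(shared))
}

#' Similarity factor (f2) between two dissolution profiles
#'
#' The regulatory similarity factor over the n selected shared time points:
#'
#' \deqn{f_2 = 50 \log_{10}\!\left\{\left[1 + \tfrac{1}{n}\sum_t (R_t - T_t)^2
#'   \right]^{-0.5} \times 100\right\}}
#'
#' Identical profiles give exactly 100; a uniform 10% gap gives
#' approximately 49.9. Values in [50, 100] are conventionally declared
#' similar. Point selection follows [select_f2_points()].
#'
#' @param reference Reference profile (conventionally the fresh arm).
#' @param test Test profile (e.g. an aged arm).
#' @param cap Passed to [select_f2_points()].
#' @return A `similarity_result` list: `f2`, `n_points_used`,
#'   `points_dropped`, `verdict`.
#' @examples
#' grid <- default_grid()
#' a <- dissolution_profile(grid, pmin(100, grid / 10))
#' compute_f2(a, a)$f2  # 100
#' @export
compute_f2 <- function(reference, test, cap = 85) {
  sel <- select_f2_points(reference, test, cap = cap)
  msd <- mean((sel$reference - sel$test)^2)
  f2 <- 50 * log10((1 + msd)^(-0.5) * 100)
  structure(list(f2 = f2,
                 n_points_used = sel$n_used,
                 points_dropped = sel$n_dropped,
                 verdict = classify_similarity(f2)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> f2 = %.1f (%s; %d points used, %d dropped)\n",
              x$f2, x$verdict, x$n_points_used, x$points_dropped))
  invisible(x)
}

#' Similarity verdict from an f2 value
#'
#' An f2 between 50 and 100 (inclusive) declares the two release profiles
#' similar; smaller values declare them dissimilar. Values above 90 are
#' additionally flagged near-identical (informational only, via the
#' `near_identical` attribute).
#'
#' @param f2 A finite f2 value.
#' @return `"similar"` or `"dissimilar"`, with attribute `near_identical`.
#' @examples
#' classify_similarity(76.3)  # similar
#' classify_similarity(45.5)  # dissimilar
#' @export
classify_similarity <- function(f2) {
  stopifnot(is.numeric(f2), is.finite(f2))
  verdict <- ifelse(f2 >= 50 & f2 <= 100, "similar", "dissimilar")
  attr(verdict, "near_identical") <- f2 > 90
  verdict
}
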