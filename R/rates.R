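#' Stage timings of petal development
#'
#' Named vector of stage onset times in hours, from the staging of petal
#' development used throughout: S0a 1 h through S5 416 h. Used to place
#' staged summaries on a common time axis for rate estimation.
#'
#' @param hours Named numeric vector of stage times (hours), strictly
#'   increasing.
#' @return Object of class `stage_timing` (named numeric, hours).
#' @export
stage_timing <- function(hours = c(S0a = 1, S0b = 31, S0c = 62, S1 = 93,
                                   S2E = 152, S2L = 211, S3 = 309,
                                   S4 = 404, S5 = 416)) {
  if (is.null(names(hours)) || any(!nzchar(names(hours)))) {
    stop("stage times must be named", call. = FALSE)
  }
  if (is.unsorted(hours, strictly = TRUE)) {
    stop("stage times must be strictly increasing", call. = FALSE)
  }
  structure(hours, class = c("stage_timing", "numeric"))
}

#' Exponential rate between two staged measurements
#'
#' Cell counts (and, effectively, cell sizes) are approximated as increasing
#' exponentially between consecutive stages, so the per-interval rate is
#' `k = (ln v_next - ln v_prev) / dt`. Times are supplied in hours and the
#' returned rate is per day. For measured lengths the estimate is an
#' *effective* growth rate: it conflates true expansion with division (which
#' halves lengths), and is closest to the basal expansion rate in the last
#' interval, when divisions have essentially stopped.
#'
#' @param v_prev,v_next Positive values (counts or median lengths) at the
#'   earlier and later stage.
#' @param t_prev,t_next Stage times in hours, `t_next > t_prev`.
#' @return List with `k` (per day), `interval_hours`.
#' @examples
#' estimate_rate(10, 20, 0, 24)$k  # log(2) per day
#' @export
estimate_rate <- function(v_prev, v_next, t_prev, t_next) {
  if (v_prev <= 0 || v_next <= 0) {
    stop("values must be strictly positive", call. = FALSE)
  }
  if (t_next <= t_prev) stop("t_next must exceed t_prev", call. = FALSE)
  dt_days <- (t_next - t_prev) / 24
  list(k = (log(v_next) - log(v_prev)) / dt_days,
       interval_hours = c(t_prev, t_next))
}

#' Interval rates along a staged series
#'
#' Applies [estimate_rate()] to every consecutive pair of stages. No rate is
#' computed into the first stage.
#'
#' @param values Positive values per stage (same order as `timing`).
#' @param timing A [stage_timing()] vector (hours) matching `values`.
#' @return data.frame with `stage` (interval end), `k` (per day) and the
#'   interval bounds in hours.
#' @export
stage_rates <- function(values, timing) {
  stopifnot(length(values) == length(timing), length(values) >= 2L)
  i <- seq_len(length(values) - 1L)
  data.frame(
    stage = names(timing)[i + 1L],
    t_from = as.numeric(timing[i]), t_to = as.numeric(timing[i + 1L]),
    k = vapply(i, function(j) {
      estimate_rate(values[j], values[j + 1L], timing[j], timing[j + 1L])$k
    }, numeric(1))
  )
}

#' Fit the exponential decay of division rates with tissue length
#'
#' Division rates estimated per stage interval decline with the length of
#' the tissue; fitting `k = r_d * exp(-L / L0)` recovers the basal division
#' rate and the decay length scale. The fit is linear least squares on
#' `log(k)` against `L`.
#'
#' @param L Tissue lengths (um) at which rates were estimated.
#' @param k Positive estimated rates (per day).
#' @return List with `r_d_hat`, `L0_hat`, `fit` (the `lm` object) and
#'   `residual_sd` on the log scale.
#' @examples
#' L <- c(5, 30, 60, 120, 240)
#' k <- 1.1 * exp(-L / 30)
#' fit_division_decay(L, k)[c("r_d_hat", "L0_hat")]
#' @export
fit_division_decay <- function(L, k) {
  if (length(L) != length(k) || length(L) < 3L) {
    stop("need at least 3 (L, k) points", call. = FALSE)
  }
  if (any(k <= 0)) stop("rates must be strictly positive", call. = FALSE)
  if (stats::sd(L) == 0) stop("degenerate design: all L equal", call. = FALSE)
  if (anyDuplicated(L)) {
    warning("duplicated L values: high-leverage fit", call. = FALSE)
  }
  fit <- stats::lm(log(k) ~ L)
  slope <- stats::coef(fit)[["L"]]
  if (slope >= 0) {
    warning("fitted rates do not decay with length (slope >= 0)",
            call. = FALSE)
  }
  # summary.lm warns on exact (noise-free) fits; exactness is expected here
  res_sd <- suppressWarnings(summary(fit)$sigma)
  list(r_d_hat = exp(stats::coef(fit)[["(Intercept)"]]),
       L0_hat = -1 / slope,
       fit = fit,
       residual_sd = res_sd)
}

#' Moment-based mean and variance of a ratio of random variables
#'
#' For independent X and Y the comparisons between genotypes use
#' `E(X/Y) = E(X) E(1/Y)` and
#' `Var(X/Y) = E(X^2) E(1/Y^2) - E(X)^2 E(1/Y)^2`; reported error bars are
#' `sqrt(Var(X/Y))`.
#'
#' @param mean_x `E(X)`.
#' @param mean_x2 `E(X^2)`.
#' @param mean_invy `E(1/Y)`.
#' @param mean_invy2 `E(1/Y^2)`.
#' @return List with `mean_ratio`, `var_ratio`, `sd_ratio`.
#' @examples
#' # X ~ anything with E(X)=2, E(X^2)=5; Y = 2 constant
#' ratio_stats(2, 5, 1/2, 1/4)
#' @export
ratio_stats <- function(mean_x, mean_x2, mean_invy, mean_invy2) {
  for (v in list(mean_x, mean_x2, mean_invy, mean_invy2)) {
    if (!is.finite(v)) stop("moments must be finite", call. = FALSE)
  }
  if (mean_x2 < mean_x^2) {
    stop("inconsistent moments: E(X^2) < E(X)^2", call. = FALSE)
  }
  m <- mean_x * mean_invy
  v <- mean_x2 * mean_invy2 - mean_x^2 * mean_invy^2
  if (v < -sqrt(.Machine$double.eps)) {
    stop("numerically inconsistent inputs: negative ratio variance",
         call. = FALSE)
  }
  v <- max(v, 0)
  list(mean_ratio = m, var_ratio = v, sd_ratio = sqrt(v))
}

#' Ratio statistics from samples
#'
#' Convenience wrapper computing the sample moments of independent samples
#' `x` and `y` and passing them to [ratio_stats()].
#'
#' @param x,y Numeric samples; `y` must be bounded away from zero.
#' @return As [ratio_stats()].
#' @export
ratio_stats_sample <- function(x, y) {
  if (any(y == 0)) stop("Y must be bounded away from zero", call. = FALSE)
  ratio_stats(mean(x), mean(x^2), mean(1 / y), mean(1 / y^2))
}
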