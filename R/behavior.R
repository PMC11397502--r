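#' Area fraction of an artificial bullseye disc
#'
#' Bi-colored test discs carry an inner pigmented circle on a white disc;
#' the fraction of the disc surface it occupies is `100 * (inner/outer)^2`.
#' The three designs used with bumblebees (1.2, 2.4 and 3.6 cm inner circles
#' on 6 cm discs) give 4, 16 and 36%.
#'
#' @param inner Inner (pigmented) circle diameter, same unit as `outer`.
#' @param outer Disc diameter, `> inner`.
#' @return Percentage of the disc area, in (0, 100).
#' @examples
#' disc_area_fraction(2.4, 6)  # 16
#' @export
disc_area_fraction <- function(inner, outer) {
  if (any(inner <= 0) || any(outer <= 0) || any(inner >= outer)) {
    stop("diameters must satisfy 0 < inner < outer", call. = FALSE)
  }
  100 * (inner / outer)^2
}

#' Two-sided preference test on first-choice counts
#'
#' Given counts of first landings on two equally rewarding disc types,
#' reports the observed proportion for the first type and an exact two-sided
#' binomial p-value against the no-preference null of 0.5.
#'
#' @param a,b Non-negative first-choice counts for the two disc types,
#'   `a + b >= 1`.
#' @return List with `proportion`, `p_value`, `n`.
#' @examples
#' preference_test(23, 7)  # strong preference for the first type
#' @export
preference_test <- function(a, b) {
  if (a < 0 || b < 0 || a + b < 1) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  ht <- stats::binom.test(a, a + b, p = 0.5, alternative = "two.sided")
  list(proportion = a / (a + b), p_value = ht$p.value, n = a + b)
}

#' Fit a pooled learning curve to choice sequences
#'
#' Pools all bees and fits a binomial regression with logit link of the
#' correct/incorrect outcome on the visit index, the standard description of
#' a conditioning learning curve. Returns fitted success probabilities with
#' pointwise 95% Wald bands (computed on the link scale and mapped back) and
#' the likelihood-ratio chi-square against the intercept-only model, which
#' tests whether foragers learn at all.
#'
#' @param choices data.frame with columns `visit` (1..N) and `correct`
#'   (0/1), e.g. from [gen_choices()]; at least two distinct visit indices.
#' @return List of class `learning_curve`: `fit` (the `glm`), `curve`
#'   (data.frame `visit`, `p`, `lower`, `upper`), `lr_chisq`, `df`,
#'   `p_value`, `slope`, `separation` (TRUE when the fit is degenerate).
#' @export
learning_curve <- function(choices) {
  stopifnot(all(c("visit", "correct") %in% names(choices)))
  if (length(unique(choices$visit)) < 2L) {
    stop("need at least two distinct visit indices", call. = FALSE)
  }
  # glm.fit warns on separated data; separation is detected and flagged below
  fit <- suppressWarnings(stats::glm(correct ~ visit,
                                     family = stats::binomial(),
                                     data = choices))
  separation <- !fit$converged ||
    any(abs(stats::predict(fit, type = "link")) > 15)
  if (separation) {
    warning("possible complete separation: fitted probabilities are extreme",
            call. = FALSE)
  }
  vis <- sort(unique(choices$visit))
  pred <- stats::predict(fit, newdata = data.frame(visit = vis),
                         type = "link", se.fit = TRUE)
  z <- stats::qnorm(0.975)
  curve <- data.frame(
    visit = vis,
    p = stats::plogis(pred$fit),
    lower = stats::plogis(pred$fit - z * pred$se.fit),
    upper = stats::plogis(pred$fit + z * pred$se.fit)
  )
  lr <- fit$null.deviance - fit$deviance
  structure(list(fit = fit, curve = curve,
                 lr_chisq = lr, df = 1L,
                 p_value = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
                 slope = stats::coef(fit)[["visit"]],
                 separation = separation),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("learning curve: p(visit %d) = %.3f -> p(visit %d) = %.3f; LR chi-square(%d) = %.2f, p = %.3g\n",
              x$curve$visit[1L], x$curve$p[1L], x$curve$visit[n], x$curve$p[n],
              x$df, x$lr_chisq, x$p_value))
  invisible(x)
}
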