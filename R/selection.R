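#' Aneuploidy risk model on the logit scale
#'
#' Per-embryo aneuploidy risk as a logistic function of maternal age with
#' a quadratic term and an additive per-allele genotype effect:
#' `p_g(a) = logistic(b0 + b1 a + b2 a^2 + bg g)`.
#'
#' @param b0,b1,b2 intercept, per-year and per-year-squared coefficients.
#' @param bg per-allele genotype coefficient.
#' @return list of class `risk_model`.
#' @export
risk_model <- function(b0, b1 = 0, b2 = 0, bg = 0) {
  stopifnot(is.finite(b0), is.finite(b1), is.finite(b2), is.finite(bg))
  structure(list(b0 = b0, b1 = b1, b2 = b2, bg = bg), class = "risk_model")
}

#' Aneuploidy risk at an age and genotype
#'
#' @param model a [risk_model()].
#' @param a maternal age (years), vectorized.
#' @param g risk-allele count.
#' @return list with `p` (risk) and `delta` (per-allele marginal risk
#'   increase `p_{g+1}(a) - p_g(a)`).
#' @export
risk_at_age <- function(model, a, g = 0) {
  eta <- model$b0 + model$b1 * a + model$b2 * a^2
  p <- plogis(eta + model$bg * g)
  list(p = p, delta = plogis(eta + model$bg * (g + 1)) - p)
}

#' Selection-model parameters
#'
#' Reproductive window, age-weight function, effective population size and
#' the scaling factor relating the fitness proxy to realized fitness.
#'
#' @param a0,a1 reproductive window bounds (years), `a1 > a0`.
#' @param f optional weight function of age on \[a0, a1\] (need not be
#'   normalized; default uniform).
#' @param Ne effective population size.
#' @param alpha scaling factor in (0, 1\].
#' @return list of class `selection_params`.
#' @export
selection_params <- function(a0 = 18, a1 = 35, f = NULL, Ne = 1e4,
                             alpha = 1) {
  if (a1 <= a0) stop("reproductive window requires a1 > a0")
  stopifnot(Ne > 0, alpha > 0, alpha <= 1)
  structure(list(a0 = a0, a1 = a1, f = f, Ne = Ne, alpha = alpha),
            class = "selection_params")
}

#' Lifetime euploid-embryo output for a genotype
#'
#' `W(g) = integral over [a0, a1] of f(a) (1 - p_g(a)) da` with f
#' normalized to integrate to 1, evaluated by composite Simpson quadrature
#' on a uniform grid of step about `step` years.
#'
#' @param model a [risk_model()].
#' @param params a [selection_params()].
#' @param g risk-allele count.
#' @param step integration step (years).
#' @return scalar W in (0, 1\].
#' @export
lifetime_fitness_proxy <- function(model, params, g = 0, step = 0.05) {
  span <- params$a1 - params$a0
  n <- max(2L, 2L * ceiling(span / step / 2))  # even interval count
  a <- seq(params$a0, params$a1, length.out = n + 1L)
  h <- span / n
  sw <- h / 3 * c(1, rep(c(4, 2), length.out = n - 1), 1)
  w <- if (is.null(params$f)) rep(1, length(a)) else params$f(a)
  if (any(w < 0)) stop("age weights must be non-negative")
  Zw <- sum(sw * w)
  if (Zw <= 0) stop("age weight function integrates to zero")
  p <- risk_at_age(model, a, g)$p
  sum(sw * w * (1 - p)) / Zw
}

#' Selection-coefficient proxy from lifetime euploid output
#'
#' Contrasts carriers (g = `g1`) with non-carriers (g = `g0`):
#' `s_proxy = 1 - W(g1) / W(g0)`. The neutrality threshold in the scaling
#' factor is `alpha* = 1 / (2 Ne s_proxy)`; the allele is effectively
#' neutral when `alpha * s_proxy < 1 / (2 Ne)`.
#'
#' @param model a [risk_model()].
#' @param params a [selection_params()].
#' @param g0,g1 genotypes contrasted (default 0 vs 1, per-allele).
#' @param step integration step.
#' @return list of class `selection_result` with `W0`, `W1`, `s_proxy`,
#'   `alpha_threshold` (NA when `s_proxy <= 0`), `neutral`.
#' @export
selection_proxy <- function(model, params, g0 = 0, g1 = 1, step = 0.05) {
  W0 <- lifetime_fitness_proxy(model, params, g = g0, step = step)
  W1 <- lifetime_fitness_proxy(model, params, g = g1, step = step)
  if (W0 <= 0) stop("W0 must be positive")
  s <- 1 - W1 / W0
  at <- if (s > 0) alpha_threshold(s, params$Ne) else NA_real_
  structure(list(W0 = W0, W1 = W1, s_proxy = s,
                 alpha_threshold = at,
                 neutral = params$alpha * s < 1 / (2 * params$Ne),
                 Ne = params$Ne, alpha = params$alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selection proxy: W0 = ", signif(x$W0, 6), ", W1 = ",
      signif(x$W1, 6), "\n  s_proxy = ", signif(x$s_proxy, 4),
      "; alpha* = ", signif(x$alpha_threshold, 4),
      " (Ne = ", format(x$Ne, big.mark = ","), "); ",
      if (x$neutral) "effectively neutral" else "selected",
      " at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Neutrality threshold for the fitness-proxy scaling factor
#'
#' @param s_proxy selection-coefficient proxy, > 0.
#' @param Ne effective population size.
#' @return `alpha* = 1 / (2 Ne s_proxy)`.
#' @export
alpha_threshold <- function(s_proxy, Ne) {
  if (s_proxy <= 0) stop("alpha threshold undefined for s_proxy <= 0")
  1 / (2 * Ne * s_proxy)
}

#' Sweep the fitness-proxy scaling factor
#'
#' Evaluates `alpha * s_proxy` against the drift threshold over a grid of
#' alpha values.
#'
#' @param model a [risk_model()].
#' @param params a [selection_params()].
#' @param alpha_grid alpha values.
#' @return data frame with `alpha`, `s_scaled`, `neutral`.
#' @export
selection_alpha_sweep <- function(model, params,
                                  alpha_grid = 10^seq(-4, 0, by = 0.25)) {
  res <- selection_proxy(model, params)
  data.frame(alpha = alpha_grid,
             s_scaled = alpha_grid * res$s_proxy,
             neutral = alpha_grid * res$s_proxy < 1 / (2 * params$Ne))
}
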