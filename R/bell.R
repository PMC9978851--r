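#' Evaluate the bell curve a * exp(-0.5 * ((x - b) / c)^2)
#'
#' The three-parameter Gaussian-shaped curve used throughout the package to
#' describe unimodal seasonal signals: `a` is the peak height, `b` the center
#' and `c` the width.
#'
#' @param x Numeric vector.
#' @param a,b,c Curve parameters (`a > 0`, `c > 0`).
#' @return Numeric vector of curve values.
#' @export
bell_curve <- function(x, a, b, c) a * exp(-0.5 * ((x - b) / c)^2)

#' Least-squares fit of a bell curve
#'
#' Fits `y = a * exp(-0.5 * ((x - b) / c)^2)` by Levenberg-Marquardt
#' nonlinear least squares, started from moment estimates (peak height, mass
#' center and mass spread of `y`). If the local fit fails to converge, a
#' coarse grid search over `(b, c)` with `a` profiled out in closed form
#' supplies the best-found parameters and the result is flagged
#' `converged = FALSE`.
#'
#' @param x Numeric predictor (at least 3 distinct values).
#' @param y Non-negative response with `max(y) > 0`.
#' @return A `bell_fit` object with elements `a`, `b`, `c`, `converged`,
#'   `rss`, and the data; supports `coef()`, `predict()`, `tidy()` and
#'   `glance()`.
#' @examples
#' x <- seq(150, 180, by = 2)
#' f <- fit_bell(x, bell_curve(x, 2, 160, 8))
#' coef(f)
#' @export
fit_bell <- function(x, y) {
  if (length(x) != length(y))
    abort_parameter("`x` and `y` must have equal length.")
  if (length(unique(x)) < 3)
    abort_validation("Bell fit needs at least 3 distinct x values.")
  if (any(y < 0) || !any(y > 0))
    abort_validation("Bell fit needs a non-negative y with a positive maximum.")

  b0 <- sum(x * y) / sum(y)
  c0 <- sqrt(sum(y * (x - b0)^2) / sum(y))
  if (!is.finite(c0) || c0 <= 0) c0 <- max(diff(range(x)) / 6, 0.5)
  a0 <- max(y)

  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-0.5 * ((x - b) / c)^2),
      data = df, start = list(a = a0, b = b0, c = c0),
      lower = c(a = 1e-12, b = -Inf, c = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (!is.null(fit)) {
    cf <- coef(fit)
    out <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = abs(unname(cf["c"])),
                converged = isTRUE(fit$convInfo$isConv),
                rss = sum(stats::resid(fit)^2), x = x, y = y)
  } else {
    out <- c(bell_grid_fit(x, y), list(x = x, y = y))
  }
  structure(out, class = "bell_fit")
}

# Profile-a grid search over (b, c): for fixed shape g = exp(...), the
# optimal a is sum(y*g)/sum(g^2).
bell_grid_fit <- function(x, y, n = 50) {
  bs <- seq(min(x), max(x), length.out = n)
  span <- max(diff(range(x)), 1)
  cs <- seq(span / (2 * n), span, length.out = n)
  best <- list(a = max(y), b = bs[1], c = cs[1], rss = Inf)
  for (b in bs) {
    for (cc in cs) {
      g <- exp(-0.5 * ((x - b) / cc)^2)
      a <- sum(y * g) / sum(g^2)
      if (!is.finite(a) || a <= 0) next
      rss <- sum((y - a * g)^2)
      if (rss < best$rss) best <- list(a = a, b = b, c = cc, rss = rss)
    }
  }
  best$converged <- FALSE
  best
}

#' @export
coef.bell_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
predict.bell_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.data.frame(newdata)) newdata$x
       else newdata
  bell_curve(x, object$a, object$b, object$c)
}

#' @export
print.bell_fit <- function(x, ...) {
  cat("<bell_fit> y = a * exp(-0.5*((x-b)/c)^2)\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g  (converged: %s, RSS = %.4g)\n",
              x$a, x$b, x$c, x$converged, x$rss))
  invisible(x)
}

#' @method tidy bell_fit
#' @export
tidy.bell_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @method glance bell_fit
#' @export
glance.bell_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n = length(x$x))
}
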