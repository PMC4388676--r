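#' Fit a first-order serum-decay model
#'
#' Fits the intact fraction f(t) = exp(-k t) by nonlinear least squares,
#' initialized from the log-linear regression of the positive fractions. The
#' half-life is t_half = ln(2)/k. A series that never drops below 1 within
#' noise (no measurable decay) returns an infinite half-life flag rather
#' than an error; fitted negative rates (systematically increasing "decay"
#' data) are an error.
#'
#' @param series A data frame with columns `time_min` (non-negative, strictly
#'   increasing) and `fraction` (intact fraction, in \[0, 1.05\] allowing
#'   small noise overshoot).
#' @return An object of class `halflife_fit` with elements `k` (1/min),
#'   `t_half` (min), `k_se`, `t_half_se` (delta method), `residual_norm`,
#'   `no_decay` flag, and the input `series`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' tp <- c(0, 60, 120, 180, 360, 900)
#' fit <- fit_half_life(data.frame(time_min = tp,
#'                                 fraction = exp(-log(2) * tp / 420)))
#' fit$t_half   # 420
#' @export
fit_half_life <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_min", "fraction") %in% names(series)))
  t <- series$time_min
  f <- series$fraction
  if (length(t) < 3) abort("need at least 3 timepoints")
  if (any(t < 0) || any(diff(t) <= 0)) abort("timepoints must be non-negative and strictly increasing")
  if (any(f < 0) || any(f > 1.05)) abort("fractions must lie in [0, 1.05]")
  out <- structure(
    list(k = NA_real_, t_half = Inf, k_se = NA_real_, t_half_se = NA_real_,
         residual_norm = NA_real_, no_decay = TRUE, series = as_tibble(series)),
    class = "halflife_fit"
  )
  # no measurable decay: everything within noise of 1
  if (all(f > 0.95)) {
    lm0 <- stats::lm(log(pmax(f, 1e-12)) ~ 0 + t)
    if (stats::coef(lm0)[[1]] > -1e-5) return(out)
  }
  pos <- f > 0
  if (sum(pos) < 2) abort("too few positive fractions to initialize the fit")
  # systematically increasing data are not first-order decay
  trend <- stats::coef(stats::lm(log(f[pos]) ~ t[pos]))[[2]]
  if (trend >= 0) abort("fitted rate is not positive: data do not show first-order decay")
  k0 <- -stats::coef(stats::lm(log(f[pos]) ~ 0 + t[pos]))[[1]]
  fit <- minpack.lm::nlsLM(
    f ~ exp(-k * t), start = list(k = k0),
    lower = -1, upper = 10,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  k <- stats::coef(fit)[["k"]]
  if (k <= 0) abort("fitted rate is not positive: data do not show first-order decay")
  k_se <- summary(fit)$coefficients["k", "Std. Error"]
  out$k <- k
  out$t_half <- log(2) / k
  out$k_se <- k_se
  out$t_half_se <- log(2) / k^2 * k_se
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$no_decay <- FALSE
  out
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat("<halflife_fit>\n")
  if (x$no_decay) {
    cat("  no measurable decay: t_half = Inf\n")
  } else {
    cat(sprintf("  k = %.5g 1/min (SE %.3g)\n", x$k, x$k_se))
    cat(sprintf("  t_half = %.4g min (%.3g h; SE %.3g min)\n",
                x$t_half, x$t_half / 60, x$t_half_se))
  }
  invisible(x)
}

#' @export
tidy.halflife_fit <- function(x, ...) {
  tibble(
    term = c("k", "t_half"),
    estimate = c(x$k, x$t_half),
    std.error = c(x$k_se, x$t_half_se)
  )
}

#' @export
glance.halflife_fit <- function(x, ...) {
  tibble(t_half = x$t_half, k = x$k, residual_norm = x$residual_norm,
         no_decay = x$no_decay, n = nrow(x$series))
}

#' @export
autoplot.halflife_fit <- function(object, ...) {
  df <- object$series
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "intact fraction")
  if (!object$no_decay) {
    grid <- tibble(time_min = seq(min(df$time_min), max(df$time_min), length.out = 200))
    grid$fraction <- exp(-object$k * grid$time_min)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
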