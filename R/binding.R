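#' Fit the one-site fluorescence-polarization binding model
#'
#' Fits FP = FP0 + Bmax * R / (KD + R), where R is the added receptor
#' concentration (monomer convention) and FP is in millipolarization units.
#' The added concentration is treated as free ligand (no depletion
#' correction); an optional quadratic depletion model accounting for the
#' probe concentration is available with `depletion = TRUE`.
#'
#' K_D is initialized from a log-spaced grid between the smallest and
#' largest positive concentrations (linear least squares for Bmax/FP0 at
#' each grid point), then refined by Levenberg-Marquardt. If the best
#' hyperbolic fit does not improve on the flat model, a `no_binding` flag is
#' returned instead of an arbitrary K_D.
#'
#' @param series Data frame with columns `conc_M` (molar, increasing within
#'   replicate) and `fp` (mP); an optional `replicate` column is allowed.
#' @param probe_conc_M Probe concentration (molar), used only by the
#'   depletion model.
#' @param depletion Use the quadratic ligand-depletion binding model.
#' @return An object of class `fp_fit`: `kd`, `bmax`, `fp0`, standard
#'   errors, `ci` (95% profile-free Wald intervals), `residual_norm`,
#'   `converged`, `no_binding`, `at_bound`, and the input series. Supports
#'   `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' s <- simulate_fp(kd = 305e-9, bmax = 100, fp0 = 50, noise_sd = 0, seed = 1)
#' fit_fp(s)$kd
#' @export
fit_fp <- function(series, probe_conc_M = NULL, depletion = FALSE) {
  stopifnot(is.data.frame(series), all(c("conc_M", "fp") %in% names(series)))
  x <- series$conc_M
  y <- series$fp
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (length(x) < 5) abort("need at least 5 titration points")
  if (!all(is.finite(y))) abort("responses must be finite")
  if (depletion && is.null(probe_conc_M)) abort("depletion model needs probe_conc_M")

  model_fp <- function(R, kd, bmax, fp0) {
    if (depletion) {
      P <- probe_conc_M
      b <- kd + R + P
      frac <- (b - sqrt(pmax(b^2 - 4 * R * P, 0))) / (2 * P)
      fp0 + bmax * frac
    } else {
      fp0 + bmax * R / (kd + R)
    }
  }
  # grid initialization: linear LS in (bmax, fp0) for each trial kd
  pos <- x[x > 0]
  grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10), length.out = 40))
  rss_at <- function(kd) {
    h <- x / (kd + x)
    fit <- stats::lm(y ~ h)
    sum(stats::resid(fit)^2)
  }
  rss <- vapply(grid, rss_at, numeric(1))
  kd0 <- grid[which.min(rss)]
  h0 <- x / (kd0 + x)
  lin <- stats::coef(stats::lm(y ~ h0))
  flat_rss <- sum((y - mean(y))^2)

  out <- structure(
    list(kd = NA_real_, bmax = NA_real_, fp0 = mean(y),
         kd_se = NA_real_, bmax_se = NA_real_, fp0_se = NA_real_,
         ci = NULL, residual_norm = sqrt(flat_rss), converged = FALSE,
         no_binding = TRUE, at_bound = FALSE, depletion = depletion,
         series = as_tibble(series), model = model_fp),
    class = "fp_fit"
  )
  if (min(rss) >= flat_rss * (1 - 1e-9) || lin[[2]] <= 0) {
    return(out)
  }
  # require the hyperbola to improve significantly on the flat model
  n <- length(y)
  fstat <- ((flat_rss - min(rss)) / 2) / (min(rss) / max(n - 3, 1))
  if (min(rss) > 0 && stats::pf(fstat, 2, n - 3, lower.tail = FALSE) > 0.05) {
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ model_fp(x, kd, bmax, fp0),
      start = list(kd = kd0, bmax = max(lin[[2]], 1e-9), fp0 = lin[[1]]),
      lower = c(kd = min(pos) / 1e4, bmax = 0, fp0 = -Inf),
      upper = c(kd = max(pos) * 1e4, bmax = Inf, fp0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  dfree <- length(y) - 3
  tq <- stats::qt(0.975, dfree)
  out$kd <- cf[["kd"]]; out$bmax <- cf[["bmax"]]; out$fp0 <- cf[["fp0"]]
  out$kd_se <- se[["kd"]]; out$bmax_se <- se[["bmax"]]; out$fp0_se <- se[["fp0"]]
  out$ci <- tibble(
    term = c("kd", "bmax", "fp0"),
    estimate = c(cf[["kd"]], cf[["bmax"]], cf[["fp0"]]),
    conf.low = c(cf[["kd"]] - tq * se[["kd"]], cf[["bmax"]] - tq * se[["bmax"]],
                 cf[["fp0"]] - tq * se[["fp0"]]),
    conf.high = c(cf[["kd"]] + tq * se[["kd"]], cf[["bmax"]] + tq * se[["bmax"]],
                  cf[["fp0"]] + tq * se[["fp0"]])
  )
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$converged <- TRUE
  out$no_binding <- FALSE
  out$at_bound <- cf[["kd"]] <= min(pos) / 1e4 * 1.01 || cf[["kd"]] >= max(pos) * 1e4 * 0.99
  out
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit>\n")
  if (x$no_binding) {
    cat("  no binding detected (hyperbola does not improve on flat model)\n")
  } else {
    cat(sprintf("  K_D  = %.4g M (SE %.3g)\n", x$kd, x$kd_se))
    cat(sprintf("  Bmax = %.4g mP (SE %.3g)\n", x$bmax, x$bmax_se))
    cat(sprintf("  FP0  = %.4g mP (SE %.3g)\n", x$fp0, x$fp0_se))
    if (x$at_bound) cat("  warning: K_D at search bound\n")
  }
  invisible(x)
}

#' @export
tidy.fp_fit <- function(x, ...) {
  if (x$no_binding) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric(), conf.low = numeric(),
                  conf.high = numeric()))
  }
  dplyr::mutate(x$ci, std.error = c(x$kd_se, x$bmax_se, x$fp0_se),
                .after = "estimate")
}

#' @export
glance.fp_fit <- function(x, ...) {
  tibble(kd = x$kd, bmax = x$bmax, fp0 = x$fp0,
         residual_norm = x$residual_norm, converged = x$converged,
         no_binding = x$no_binding, at_bound = x$at_bound,
         n = nrow(x$series))
}

#' @export
autoplot.fp_fit <- function(object, ...) {
  df <- object$series
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_M, y = .data$fp)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[receptor] (M, monomer)", y = "FP (mP)")
  if (!object$no_binding) {
    pos <- df$conc_M[df$conc_M > 0]
    grid <- tibble(conc_M = exp(seq(log(min(pos)), log(max(pos)), length.out = 200)))
    grid$fp <- object$model(grid$conc_M, object$kd, object$bmax, object$fp0)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Normalize an ELISA series against its negative control
#'
#' Subtracts the matched negative-control response at each concentration and
#' floors at zero; optionally rescales to the per-series maximum.
#'
#' @param series,negative_control Data frames with `conc_M` and `response`
#'   on identical concentration grids.
#' @param scale_max Rescale so the maximum is 1 (default `FALSE`).
#' @return A tibble with `conc_M` and `response` (control-subtracted).
#' @export
normalize_elisa <- function(series, negative_control, scale_max = FALSE) {
  if (!isTRUE(all.equal(sort(series$conc_M), sort(negative_control$conc_M)))) {
    abort("series and control concentration grids differ")
  }
  s <- series[order(series$conc_M), ]
  ctl <- negative_control[order(negative_control$conc_M), ]
  r <- s$response - ctl$response
  if (any(r < 0)) warn("negative control exceeds signal at some points; clamped to 0")
  r <- pmax(r, 0)
  if (scale_max && max(r) > 0) r <- r / max(r)
  tibble(conc_M = s$conc_M, response = r)
}

#' Rank binders by ELISA area under the curve
#'
#' Orders normalized series by trapezoidal area under the response curve on
#' the common concentration grid; reports the plateau response (mean of the
#' two highest concentrations). Ties are broken by name for a stable order.
#'
#' @param series_list Named list of normalized series (`conc_M`,
#'   `response`).
#' @return A tibble `name`, `auc`, `plateau`, `rank` in descending AUC.
#' @export
rank_binders <- function(series_list) {
  stopifnot(length(series_list) >= 1, !is.null(names(series_list)))
  purrr::imap_dfr(series_list, function(s, nm) {
    s <- s[order(s$conc_M), ]
    auc <- sum(diff(s$conc_M) * (utils::head(s$response, -1) +
                                   utils::tail(s$response, -1)) / 2)
    tibble(name = nm, auc = auc,
           plateau = mean(utils::tail(s$response, 2)))
  }) |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$name) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Fit a four-parameter logistic competition curve
#'
#' FP = floor + (ceiling - floor) / (1 + (x / IC50)^hill). Used as a
#' qualitative control that an unlabeled competitor displaces the probe; a
#' series in which FP does not decrease with competitor yields a
#' `no_competition` flag.
#'
#' @param series Data frame with `conc_M` (competitor) and `fp`.
#' @return A list with `ic50`, `floor`, `ceiling`, `hill`, standard errors,
#'   `no_competition`, `residual_norm`.
#' @export
fit_competition <- function(series) {
  x <- series$conc_M; y <- series$fp
  if (length(x) < 5) abort("need at least 5 points")
  out <- list(ic50 = NA_real_, floor = NA_real_, ceiling = NA_real_,
              hill = NA_real_, se = NULL, no_competition = TRUE,
              residual_norm = sqrt(sum((y - mean(y))^2)))
  slope <- stats::coef(stats::lm(y ~ log10(pmax(x, min(x[x > 0]) / 10))))[[2]]
  if (slope >= 0) return(out)
  pos <- x[x > 0]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) / (1 + (x / ic50)^h),
      start = list(fl = min(y), ce = max(y),
                   ic50 = exp(mean(log(range(pos)))), h = 1),
      lower = c(fl = -Inf, ce = -Inf, ic50 = min(pos) / 1e4, h = 0.1),
      upper = c(fl = Inf, ce = Inf, ic50 = max(pos) * 1e4, h = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$ic50 <- cf[["ic50"]]; out$floor <- cf[["fl"]]
  out$ceiling <- cf[["ce"]]; out$hill <- cf[["h"]]
  out$se <- summary(fit)$coefficients[, "Std. Error"]
  out$no_competition <- FALSE
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out
}
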