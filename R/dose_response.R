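# Dose-response calibration: four-parameter Hill fits on growth-inhibition
# data and closed-form GI20 extraction. x is log10(concentration in
# ug/uL); y is percent growth relative to untreated cells.

#' Construct a dose-response curve
#'
#' @param x log10 concentration values (concentration in ug/uL).
#' @param y response, percent growth versus untreated (%). Values outside
#'   \[-50, 150\]% trigger a warning (kept, not clipped).
#' @param log10_x set to `FALSE` if `x` is on the raw concentration scale;
#'   it is then log10-transformed on construction.
#' @return A `dose_response_curve` object.
#' @export
dose_response_curve <- function(x, y, log10_x = TRUE) {
  if (!log10_x) {
    if (any(x <= 0)) stop("raw concentrations must be positive")
    x <- log10(x)
  }
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x))) stop("non-finite concentration values")
  if (any(y < -50 | y > 150, na.rm = TRUE))
    warning("responses outside [-50, 150]% present; check units")
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "dose_response_curve")
}

#' Evaluate the four-parameter Hill equation
#'
#' y = Bottom + (Top - Bottom) / (1 + 10^((logGI50 - x) * h))
#'
#' @param x log10 concentration.
#' @param bottom,top asymptotes (%); `top > bottom`.
#' @param loggi50 log10 concentration of half-maximal response.
#' @param h Hill slope (negative for growth-inhibition curves).
#' @return Predicted response (%).
#' @export
hill_eq <- function(x, bottom, top, loggi50, h) {
  bottom + (top - bottom) / (1 + 10^((loggi50 - x) * h))
}

#' Fit a dose-response curve to the Hill equation
#'
#' Nonlinear least squares with data-driven starts (top = max y, bottom =
#' min y, logGI50 = x nearest the response midpoint, h = -1) and a
#' Nelder-Mead polish as fallback when the Gauss-Newton path fails to
#' converge.
#'
#' @param curve a [dose_response_curve()] with at least 4 distinct doses.
#' @return A `hill_fit` list: `bottom`, `top`, `loggi50`, `h`, `r2`,
#'   `converged`, `fitted`.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  x <- curve$x; y <- curve$y
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("Hill fit needs at least 4 distinct doses")
  if (stats::var(y) < 1e-10)
    stop("degenerate fit: response is constant across doses")

  top0 <- max(y); bottom0 <- min(y)
  mid <- (top0 + bottom0) / 2
  loggi0 <- x[which.min(abs(y - mid))]
  start <- c(bottom = bottom0, top = top0, loggi50 = loggi0, h = -1)

  sse <- function(p) {
    pred <- hill_eq(x, p[1], p[2], p[3], p[4])
    sum((y - pred)^2)
  }

  fit <- NULL
  converged <- FALSE
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ hill_eq(x, bottom, top, loggi50, h), data = df,
                 start = as.list(start),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    converged <- fit$convInfo$isConv
  } else {
    p <- start
  }
  # polish (or rescue) with Nelder-Mead on the SSE surface
  opt <- stats::optim(p, sse, control = list(maxit = 2000, reltol = 1e-12))
  if (opt$value < sse(p)) {
    p <- opt$par
    converged <- converged || opt$convergence == 0
  }
  p <- as.numeric(p); names(p) <- c("bottom", "top", "loggi50", "h")
  if (p["top"] < p["bottom"]) {  # canonical orientation: flip both h and asymptotes
    p[c("bottom", "top")] <- p[c("top", "bottom")]
    p["h"] <- -p["h"]
  }
  fitted_y <- hill_eq(x, p["bottom"], p["top"], p["loggi50"], p["h"])
  r2 <- 1 - sum((y - fitted_y)^2) / sum((y - mean(y))^2)
  structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                 loggi50 = unname(p["loggi50"]), h = unname(p["h"]),
                 r2 = r2, converged = converged,
                 fitted = fitted_y, x = x, y = y),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("<hill_fit> Bottom=%.3f Top=%.3f logGI50=%.3f ",
                     "h=%.3f R2=%.4f%s\n"),
              x$bottom, x$top, x$loggi50, x$h, x$r2,
              if (x$converged) "" else " (non-converged)"))
  invisible(x)
}

#' Invert a Hill fit at a target response (GI20 by default)
#'
#' Closed form: x* = logGI50 - log10((Top-Bottom)/(y-Bottom) - 1) / h, and
#' the concentration returned is 10^x*. The default target y = 80%
#' corresponds to 20% growth inhibition (GI20).
#'
#' @param fit a `hill_fit` (or any list with bottom/top/loggi50/h).
#' @param y_target target response (%), strictly between bottom and top.
#' @return Concentration in ug/uL at which the fitted response equals
#'   `y_target`.
#' @export
gi20_from_fit <- function(fit, y_target = 80) {
  b <- fit$bottom; t <- fit$top
  if (y_target >= t || y_target <= b)
    stop(sprintf(paste0("no GI20 in range: target %.1f%% outside fitted ",
                        "asymptotes (%.1f%%, %.1f%%)"), y_target, b, t))
  xstar <- fit$loggi50 - log10((t - b) / (y_target - b) - 1) / fit$h
  10^xstar
}
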