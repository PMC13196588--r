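## Local maxima of a density grid with a prominence filter.
## Prominence of a peak = height minus the higher of the two minima separating
## it from the nearest higher point (or grid edge) on each side.
find_density_peaks <- function(y, min_prominence) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  # plateaus: rising then flat then falling
  if (!length(is_max)) {
    d <- diff(y)
    up <- which(d > 0); dn <- which(d < 0)
    if (length(up) && length(dn) && min(dn) > max(up)) {
      is_max <- max(up) + 1L
    }
  }
  if (!length(is_max)) return(integer(0))
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- if (i > 1L) {
      higher <- which(y[seq_len(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(i - 1L)])
    } else h
    right <- if (i < n) {
      seg <- y[(i + 1L):n]
      higher <- which(seg > h)
      hi <- if (length(higher)) i + min(higher) - 1L else n
      min(y[(i + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  is_max[prom >= min_prominence]
}

#' Calibrate sensitivity/resistance thresholds from the RBG distribution
#'
#' Fits a Gaussian kernel density (Silverman-type rule-of-thumb bandwidth) on
#' a regular grid spanning the observed range, locates the two most prominent
#' modes, and takes the density minimum strictly between them as the
#' resistance threshold (the "valley"). The valley's sampling stability is
#' assessed by bootstrap resampling; the percentile 95% confidence interval,
#' rounded outward to two decimals, gives the class bounds
#' `(sensitive_max, resistant_min)` used by [classify_resistance()].
#'
#' @param rbg_values Numeric vector of mean RBG values (>= 50).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param bw Bandwidth rule or value passed to [stats::density()]
#'   (default `"nrd0"`).
#' @param grid_n Density grid size (default 512).
#' @param prominence_frac Minimum peak prominence as a fraction of the maximum
#'   density (default 0.01).
#'
#' @return An `rbg_calibration` with fields `peak_low`, `peak_high`, `valley`,
#'   `ci_low`, `ci_high`, `class_bounds`, `n_boot`, `bandwidth`, `seed` and
#'   `density` (the fitted grid).
#' @export
rbg_calibrate <- function(rbg_values, n_boot = 1000L, seed = 1L, bw = "nrd0",
                          grid_n = 512L, prominence_frac = 0.01) {
  x <- as.numeric(rbg_values)
  if (length(x) < 50L) stop("need at least 50 RBG values to calibrate")
  if (any(!is.finite(x)) || any(x < 0)) stop("RBG values must be finite and >= 0")

  fit_valley <- function(xx) {
    d <- stats::density(xx, bw = bw, n = grid_n, from = min(xx), to = max(xx))
    pk <- find_density_peaks(d$y, prominence_frac * max(d$y))
    if (length(pk) < 2L) return(NULL)
    top2 <- sort(pk[order(d$y[pk], decreasing = TRUE)][1:2])
    between <- (top2[1L] + 1L):(top2[2L] - 1L)
    if (!length(between)) return(NULL)
    ymin <- min(d$y[between])
    argmin <- between[d$y[between] == ymin]
    list(peaks = d$x[top2], valley = mean(range(d$x[argmin])), density = d)
  }

  fit <- fit_valley(x)
  if (is.null(fit)) {
    stop("fewer than two density modes detected: distribution not bimodal, ",
         "no thresholds issued")
  }

  if (n_boot > 0L) {
    boot_valleys <- rep(NA_real_, n_boot)
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      f <- fit_valley(sample(x, replace = TRUE))
      if (!is.null(f)) boot_valleys[b] <- f$valley
    }
    ok <- boot_valleys[!is.na(boot_valleys)]
    if (length(ok) < max(2L, 0.5 * n_boot)) {
      stop("bootstrap valley undefined in most resamples: degenerate distribution")
    }
    ci <- unname(stats::quantile(ok, c(0.025, 0.975), type = 7))
    bounds <- c(sensitive_max = floor(ci[1L] * 100) / 100,
                resistant_min = ceiling(ci[2L] * 100) / 100)
  } else {
    # no bootstrap requested: point estimate only, no class bounds issued
    ok <- numeric(0)
    ci <- c(NA_real_, NA_real_)
    bounds <- c(sensitive_max = NA_real_, resistant_min = NA_real_)
  }

  structure(list(peak_low = fit$peaks[1L], peak_high = fit$peaks[2L],
                 valley = fit$valley, ci_low = ci[1L], ci_high = ci[2L],
                 class_bounds = bounds, n_boot = as.integer(n_boot),
                 bandwidth = fit$density$bw, seed = as.integer(seed),
                 n = length(x), density = fit$density,
                 boot_valleys = ok),
            class = "rbg_calibration")
}

#' @export
print.rbg_calibration <- function(x, ...) {
  cat("<rbg_calibration>\n")
  cat(sprintf("  modes: %.3f / %.3f   valley: %.3f\n",
              x$peak_low, x$peak_high, x$valley))
  cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f]  (%d resamples)\n",
              x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  class bounds: sensitive <= %.2f < intermediate < %.2f <= resistant\n",
              x$class_bounds[1L], x$class_bounds[2L]))
  invisible(x)
}

#' @export
summary.rbg_calibration <- function(object, ...) {
  out <- c(peak_low = object$peak_low, peak_high = object$peak_high,
           valley = object$valley, ci_low = object$ci_low,
           ci_high = object$ci_high, object$class_bounds,
           bandwidth = object$bandwidth, n = object$n,
           n_boot = object$n_boot)
  class(out) <- "summary.rbg_calibration"
  out
}

#' @export
print.summary.rbg_calibration <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Predict resistance classes from a calibration
#'
#' @param object An `rbg_calibration`.
#' @param newdata Numeric vector of RBG values.
#' @param ... Unused.
#' @return Ordered factor of classes (see [classify_resistance()]).
#' @export
predict.rbg_calibration <- function(object, newdata, ...) {
  classify_resistance(newdata, object)
}

#' Plot a calibrated RBG density with modes, valley and class bounds
#'
#' @param x An `rbg_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rbg_calibration <- function(x, ...) {
  d <- x$density
  graphics::plot(d$x, d$y, type = "l", xlab = "mean RBG", ylab = "density",
                 main = "RBG threshold calibration", ...)
  graphics::abline(v = c(x$peak_low, x$peak_high), lty = 3)
  graphics::abline(v = x$valley, col = 2)
  graphics::abline(v = x$class_bounds, col = 4, lty = 2)
  invisible(x)
}

#' Write calibration results to JSON
#'
#' @param cal An `rbg_calibration`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(
    list(peak_low = cal$peak_low, peak_high = cal$peak_high,
         valley = cal$valley, ci_low = cal$ci_low, ci_high = cal$ci_high,
         sensitive_max = unname(cal$class_bounds[1L]),
         resistant_min = unname(cal$class_bounds[2L]),
         n_boot = cal$n_boot, bandwidth = cal$bandwidth, seed = cal$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
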