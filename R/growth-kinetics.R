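#' Read a long-format plate-reader growth table
#'
#' Parses a CSV/TSV of OD600 time series into a list of growth curves, one per
#' (sample, phage treatment, replicate) well, each sorted by time. Rows with a
#' missing OD reading are dropped (a message reports how many).
#'
#' @param path Path to a delimited file with one row per reading.
#' @param schema Named character vector mapping canonical column names
#'   (`sample`, `time`, `od`, and optionally `strain`, `phage`, `replicate`)
#'   to the column headers actually present in the file. Unmapped canonical
#'   names fall back to common defaults (`sample`, `strain`, `phage`,
#'   `replicate`, `time_h`, `od600`).
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#'
#' @return A list of `growth_curve` objects. Each has fields `sample_id`,
#'   `strain_id`, `phage_treatment` (`NA` for untreated controls),
#'   `replicate`, `times` (hours) and `od`.
#' @export
read_growth_table <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop("growth table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- c(sample = "sample", strain = "strain", phage = "phage",
                replicate = "replicate", time = "time_h", od = "od600")
  cols <- defaults
  if (!is.null(schema)) cols[names(schema)] <- unname(schema)

  for (need in c("sample", "time", "od")) {
    if (!cols[[need]] %in% names(df)) {
      stop("required column '", need, "' (mapped to '", cols[[need]],
           "') not present in ", path)
    }
  }
  tvals <- suppressWarnings(as.numeric(df[[cols[["time"]]]]))
  if (anyNA(tvals) && !anyNA(df[[cols[["time"]]]])) {
    bad <- which(is.na(tvals))[1L]
    stop("non-numeric time value at row ", bad)
  }
  ovals <- suppressWarnings(as.numeric(df[[cols[["od"]]]]))
  nonnum <- which(is.na(ovals) & !is.na(df[[cols[["od"]]]]) &
                    df[[cols[["od"]]]] != "")
  if (length(nonnum)) stop("non-numeric OD value at row ", nonnum[1L])

  drop <- is.na(ovals) | is.na(tvals)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing OD/time dropped")
    df <- df[!drop, , drop = FALSE]
    tvals <- tvals[!drop]; ovals <- ovals[!drop]
  }

  getcol <- function(key, default) {
    if (cols[[key]] %in% names(df)) df[[cols[[key]]]] else rep(default, nrow(df))
  }
  strain <- getcol("strain", NA_character_)
  phage  <- getcol("phage", NA_character_)
  phage[!is.na(phage) & phage %in% c("", "none", "NA")] <- NA_character_
  repl <- getcol("replicate", 1L)

  key <- paste(df[[cols[["sample"]]]], phage, repl, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx <- idx[order(tvals[idx])]
    growth_curve(sample_id = df[[cols[["sample"]]]][idx[1L]],
                 strain_id = strain[idx[1L]],
                 phage_treatment = phage[idx[1L]],
                 replicate = as.integer(repl[idx[1L]]),
                 times = tvals[idx], od = ovals[idx])
  })
}

#' Construct a growth curve
#'
#' @param sample_id,strain_id,phage_treatment,replicate Well metadata;
#'   `phage_treatment` is `NA` for no-phage controls.
#' @param times Strictly increasing sampling times in hours.
#' @param od OD600 readings, same length as `times`.
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(sample_id, strain_id = NA_character_,
                         phage_treatment = NA_character_, replicate = 1L,
                         times, od) {
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < 3L) stop("a growth curve needs at least 3 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(od))) stop("od values must be finite")
  structure(list(sample_id = sample_id, strain_id = strain_id,
                 phage_treatment = phage_treatment,
                 replicate = as.integer(replicate),
                 times = as.numeric(times), od = as.numeric(od)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s%s, %d points over %.1f-%.1f h\n",
              x$sample_id,
              if (is.na(x$phage_treatment)) "" else paste0(" + ", x$phage_treatment),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

## rolling log-linear slopes over windows of `w` consecutive points; windows
## containing a reading below min_od (after blank correction) are skipped
window_slopes <- function(times, y, ok, w) {
  n <- length(times)
  nw <- n - w + 1L
  slopes <- rep(NA_real_, nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + w - 1L)
    if (!all(ok[idx])) next
    tt <- times[idx]
    slopes[i] <- stats::cov(tt, y[idx]) / stats::var(tt)
  }
  slopes
}

#' Per-curve kinetic summary: maximum growth rate, AUC, endpoint change
#'
#' The maximum specific growth rate is the largest least-squares slope of
#' log blank-corrected OD against time over sliding windows of
#' `window_points` consecutive readings. Windows containing a reading below
#' the detection floor `min_od` (above blank) are excluded, so the rate is
#' estimated where the optical signal is trustworthy. The area under the
#' curve is the trapezoidal integral of blank-corrected OD with negative
#' values clamped to zero; the endpoint change is computed on the raw series
#' over `[window_start, window_end]` hours.
#'
#' @param curve A `growth_curve`.
#' @param blank Blank OD offset subtracted before the log fit and the AUC
#'   (default 0: no correction).
#' @param window_points Number of consecutive readings per regression window
#'   (default 5; must be between 3 and the curve length).
#' @param min_od Detection floor in blank-corrected OD units; windows with any
#'   reading below it are skipped (default 0.02).
#' @param window_start,window_end Assay window in hours for the endpoint
#'   change (defaults 0 and 8; use 16 for slow growers).
#' @param eps Floor applied to blank-corrected OD before taking logs.
#'
#' @return A `kinetic_summary` with fields `mu_max` (per hour), `auc`
#'   (OD x hours), `endpoint_delta`, `window_used` and `flags`.
#' @export
summarize_kinetics <- function(curve, blank = 0, window_points = 5L,
                               min_od = 0.02, window_start = 0,
                               window_end = 8, eps = 1e-6) {
  stopifnot(inherits(curve, "growth_curve"))
  if (blank < 0) stop("blank must be >= 0")
  n <- length(curve$times)
  if (window_points < 3L) stop("window_points must be >= 3")
  if (window_points > n) stop("curve shorter than the regression window")

  oc <- curve$od - blank
  flags <- character(0)
  if (all(oc <= 0)) {
    mu <- 0
    flags <- c(flags, "all_od_below_blank")
  } else {
    ok <- oc >= min_od
    y <- log(pmax(oc, eps))
    slopes <- window_slopes(curve$times, y, ok, as.integer(window_points))
    mu <- if (all(is.na(slopes))) {
      flags <- c(flags, "no_window_above_floor")
      0
    } else max(0, slopes, na.rm = TRUE)
  }

  auc <- trapezoid_auc(curve$times, pmax(oc, 0))

  inwin <- curve$times >= window_start & curve$times <= window_end
  delta <- if (any(inwin)) {
    iw <- which(inwin)
    curve$od[iw[length(iw)]] - curve$od[iw[1L]]
  } else NA_real_

  structure(list(mu_max = mu, auc = auc, endpoint_delta = delta,
                 window_used = c(start_h = window_start, end_h = window_end),
                 window_points = as.integer(window_points),
                 blank = blank, min_od = min_od, flags = flags,
                 sample_id = curve$sample_id),
            class = "kinetic_summary")
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("<kinetic_summary> mu_max = %.4f /h, AUC = %.3f OD*h, delta[%g-%g h] = %.3f\n",
              x$mu_max, x$auc, x$window_used[1L], x$window_used[2L],
              x$endpoint_delta))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kinetic_summary <- function(object, ...) {
  c(mu_max = object$mu_max, auc = object$auc,
    endpoint_delta = object$endpoint_delta)
}

#' Relative growth rate of a mutant versus its ancestor
#'
#' The fitness of a resistant mutant expressed as its maximum growth rate
#' divided by the wild-type maximum growth rate.
#'
#' @param mutant,wildtype `kinetic_summary` objects.
#' @return The ratio `mutant$mu_max / wildtype$mu_max`.
#' @export
relative_growth_rate <- function(mutant, wildtype) {
  stopifnot(inherits(mutant, "kinetic_summary"),
            inherits(wildtype, "kinetic_summary"))
  if (wildtype$mu_max <= 0) stop("wild-type mu_max is zero: ratio undefined")
  mutant$mu_max / wildtype$mu_max
}

#' Pairwise Welch comparison of per-well AUC values across treatments
#'
#' For every ordered pair of treatment groups, reports the difference in mean
#' AUC and a two-sided Welch t-test p-value. P-values are reported raw; set
#' `bh = TRUE` to append Benjamini-Hochberg adjusted values.
#'
#' @param groups Named list mapping treatment name to a numeric vector of AUC
#'   values (each of length >= 2).
#' @param bh Append a BH-adjusted `q` column (default `FALSE`).
#' @return A data.frame with columns `group_a`, `group_b`, `mean_diff`,
#'   `p_value` (and `q_value` if requested).
#' @export
compare_groups_auc <- function(groups, bh = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(groups)[sizes < 2L], collapse = ", "))
  }
  nm <- names(groups)
  pairs <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xa <- groups[[pairs$a[i]]]; xb <- groups[[pairs$b[i]]]
    d <- mean(xa) - mean(xb)
    se <- sqrt(stats::var(xa) / length(xa) + stats::var(xb) / length(xb))
    p <- if (se == 0) {
      if (d == 0) 1 else 0   # degenerate: both groups constant
    } else {
      stats::t.test(xa, xb, var.equal = FALSE)$p.value
    }
    data.frame(group_a = pairs$a[i], group_b = pairs$b[i],
               mean_diff = d, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (bh) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Write per-sample kinetic summaries to TSV
#'
#' @param summaries List of `kinetic_summary` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_kinetics_tsv <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample = s$sample_id, mu_max = s$mu_max, auc = s$auc,
               endpoint_delta = s$endpoint_delta,
               flags = paste(s$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
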