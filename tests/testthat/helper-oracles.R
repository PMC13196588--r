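# Independent reference implementations used to cross-check the package's
# optimized code paths. These deliberately use different machinery (explicit
# lm() loops, dense grids, from-definition formulas).

# brute-force mu_max: fit every sliding window with lm(), same window and
# detection-floor semantics as summarize_kinetics
mu_max_oracle <- function(curve, blank = 0, window_points = 5L,
                          min_od = 0.02, eps = 1e-6) {
  oc <- curve$od - blank
  if (all(oc <= 0)) return(0)
  y <- log(pmax(oc, eps))
  n <- length(curve$times)
  best <- 0
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    if (min(oc[idx]) < min_od) next
    sl <- unname(stats::coef(stats::lm(y[idx] ~ curve$times[idx]))[2L])
    if (sl > best) best <- sl
  }
  best
}

# dense-grid argmin of the fitted density between two mode locations
valley_dense_oracle <- function(x, bw, peak_low, peak_high, n_dense = 8192L) {
  d <- stats::density(x, bw = bw, n = n_dense, from = min(x), to = max(x))
  inside <- d$x > peak_low & d$x < peak_high
  d$x[inside][which.min(d$y[inside])]
}

# Benjamini-Hochberg from the definition: q_i = min over j >= rank(i) of
# p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

logistic_curve_od <- function(t, r, K = 1, N0 = 0.01) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

# small endpoint-absorbance table with planted resistance states
make_planted_measurements <- function(strains, selecting_phage, focal_phage,
                                      resistant, n_rep = 3L, seed = 1L) {
  set.seed(seed)
  selecting_phage <- rep(selecting_phage, length.out = length(strains))
  focal_phage <- rep(focal_phage, length.out = length(strains))
  resistant <- rep(resistant, length.out = length(strains))
  rows <- list()
  for (i in seq_along(strains)) {
    rbg <- if (resistant[i]) stats::rbeta(n_rep, 50, 2) else stats::rbeta(n_rep, 2, 50)
    rows[[i]] <- data.frame(
      strain = strains[i], selecting_phage = selecting_phage[i],
      focal_phage = focal_phage[i], replicate = seq_len(n_rep),
      a0_phage = 0.05, a8_phage = 0.05 + rbg * 0.8,
      a0_ctrl = 0.05, a8_ctrl = 0.85, endpoint_h = 8,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
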