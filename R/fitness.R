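#' Relative competitive fitness from a head-to-head co-culture assay
#'
#' Two strains (phage-resistant R and wild-type S) are co-cultured for one
#' growth cycle; the final composition is estimated by phenotyping sampled
#' colonies. Fitness is the ratio of realized Malthusian growth:
#' \deqn{W = \frac{\ln[T_R(24)/T_R(0)]}{\ln[T_S(24)/T_S(0)]}}
#' with final densities split from the total by the sampled resistant
#' proportion. When every sampled colony is of one type, a +0.5 continuity
#' correction on both colony counts avoids log(0) (enabled by default).
#'
#' @param t0_resistant,t0_wt Initial densities (CFU/ml) of each strain.
#' @param t24_total Total density at the end of the assay.
#' @param colonies_sampled Number of colonies phenotyped (e.g. 20).
#' @param colonies_wt Number of those identified as wild type (phage
#'   sensitive).
#' @param correction Apply the continuity correction on 0/n and n/n splits
#'   (default `TRUE`).
#' @return Numeric W with attribute `flags` (character vector; includes
#'   `"denominator_nonpositive"` with value `NA` when the wild type failed to
#'   grow, `"continuity_corrected"` when the correction fired).
#' @export
competition_fitness <- function(t0_resistant, t0_wt, t24_total,
                                colonies_sampled, colonies_wt,
                                correction = TRUE) {
  if (colonies_sampled <= 0) stop("colonies_sampled must be positive")
  if (colonies_wt < 0 || colonies_wt > colonies_sampled) {
    stop("colonies_wt must be between 0 and colonies_sampled")
  }
  if (t0_resistant <= 0 || t0_wt <= 0) stop("initial densities must be positive")
  if (t24_total <= 0) stop("t24_total must be positive")

  flags <- character(0)
  n <- colonies_sampled; k_wt <- colonies_wt; k_r <- n - colonies_wt
  if (k_wt == 0 || k_r == 0) {
    if (!correction) stop("all sampled colonies of one type with correction ",
                          "disabled: log of zero density")
    k_wt <- k_wt + 0.5; k_r <- k_r + 0.5
    flags <- c(flags, "continuity_corrected")
  }
  p <- k_r / (k_wt + k_r)
  tr24 <- p * t24_total
  ts24 <- (1 - p) * t24_total
  den <- log(ts24 / t0_wt)
  if (den <= 0) {
    flags <- c(flags, "denominator_nonpositive")
    return(structure(NA_real_, flags = flags))
  }
  structure(log(tr24 / t0_resistant) / den, flags = flags)
}

#' Efficiency of plating (EOP)
#'
#' Phage titer on a test strain divided by the titer on the reference
#' (wild-type) host. A test titer of zero (no plaques) gives EOP 0 with a
#' below-detection flag and, if a detection limit is supplied, an upper bound
#' `detection_limit / reference_titer`.
#'
#' @param test_titer,reference_titer Titers in PFU/ml.
#' @param detection_limit Assay detection limit in PFU/ml (optional).
#' @return Numeric EOP with attributes `below_detection` and `upper_bound`.
#' @export
efficiency_of_plating <- function(test_titer, reference_titer,
                                  detection_limit = NA_real_) {
  if (reference_titer <= 0) stop("reference titer must be positive: EOP undefined")
  if (test_titer < 0) stop("titers must be >= 0")
  below <- test_titer == 0
  structure(test_titer / reference_titer,
            below_detection = below,
            upper_bound = if (below && is.finite(detection_limit)) {
              detection_limit / reference_titer
            } else NA_real_)
}

#' Phage adsorption rate
#'
#' Fraction of input phage particles adsorbed to cells after a fixed
#' incubation: `(initial - free) / initial`, clamped to [0, 1]. A free titer
#' exceeding the initial titer (measurement noise) clamps to 0 with a
#' warning.
#'
#' @param initial_titer,free_titer Titers in PFU (or PFU/ml).
#' @return Adsorbed fraction in [0, 1].
#' @export
adsorption_rate <- function(initial_titer, free_titer) {
  if (initial_titer <= 0) stop("initial titer must be positive: rate undefined")
  if (free_titer < 0) stop("free titer must be >= 0")
  r <- (initial_titer - free_titer) / initial_titer
  if (r < 0) {
    warning("free titer exceeds initial titer (measurement noise); rate clamped to 0")
    r <- 0
  }
  min(r, 1)
}
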