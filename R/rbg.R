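#' Relative bacterial growth (RBG) of a strain under phage challenge
#'
#' RBG is the ratio of the absorbance gain of a phage-treated well to the gain
#' of the matching no-phage control over the same assay window:
#' \deqn{RBG = \frac{Abs_{600}(t_{end}) - Abs_{600}(t_0)\;[phage]}
#'                  {Abs_{600}(t_{end}) - Abs_{600}(t_0)\;[control]}}
#' A value of 1 means growth equal to the control (complete resistance); 0
#' means no growth under phage (complete sensitivity). A negative numerator
#' (lysis below the inoculum density) is clamped to 0 and flagged; values
#' above 1 are preserved.
#'
#' @param abs_start_phage,abs_end_phage OD600 of the phage-treated well at the
#'   start and end of the window.
#' @param abs_start_ctrl,abs_end_ctrl OD600 of the no-phage control well.
#' @return Numeric RBG value with attribute `clamped` (`TRUE` if a negative
#'   numerator was clamped to 0).
#' @export
compute_rbg <- function(abs_start_phage, abs_end_phage,
                        abs_start_ctrl, abs_end_ctrl) {
  vals <- c(abs_start_phage, abs_end_phage, abs_start_ctrl, abs_end_ctrl)
  if (!all(is.finite(vals))) stop("absorbances must be finite")
  den <- abs_end_ctrl - abs_start_ctrl
  if (den <= 0) stop("control growth is non-positive: RBG undefined")
  num <- abs_end_phage - abs_start_phage
  clamped <- num < 0
  structure(max(num, 0) / den, clamped = clamped)
}

#' Read an endpoint-absorbance interaction table
#'
#' One row per (strain, focal phage, replicate) with start/end absorbances of
#' the phage-treated and control wells. Expected columns: `strain`,
#' `selecting_phage`, `focal_phage`, `replicate`, `a0_phage`, `a8_phage`,
#' `a0_ctrl`, `a8_ctrl`, optionally `endpoint_h`.
#'
#' @param path CSV file path.
#' @return A data.frame of interaction measurements.
#' @export
read_interaction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "selecting_phage", "focal_phage", "replicate",
            "a0_phage", "a8_phage", "a0_ctrl", "a8_ctrl")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Build a strain x phage RBG matrix from replicate measurements
#'
#' Computes per-replicate RBG values and averages them per (strain, phage)
#' cell. Cells with no measurement are `NA` (absent, not zero).
#'
#' @param measurements Data.frame as returned by [read_interaction_table()].
#' @param receptor_map Named character vector mapping phage name to receptor
#'   class (e.g. `"core"`, `"O-antigen"`, `"BtuB"`); optional but required for
#'   [cross_resistance_summary()].
#' @return An `rbg_matrix`: list with `values` (mean RBG matrix, strains x
#'   phages), `replicates` (long data.frame of per-replicate RBG),
#'   `selecting_phage` (named by strain) and `receptor_of_phage`.
#' @export
build_rbg_matrix <- function(measurements, receptor_map = NULL) {
  m <- measurements
  dupkey <- paste(m$strain, m$focal_phage, m$replicate)
  if (anyDuplicated(dupkey)) {
    stop("duplicate (strain, phage, replicate) rows: ",
         dupkey[duplicated(dupkey)][1L])
  }
  m$rbg <- vapply(seq_len(nrow(m)), function(i) {
    as.numeric(compute_rbg(m$a0_phage[i], m$a8_phage[i],
                           m$a0_ctrl[i], m$a8_ctrl[i]))
  }, numeric(1))
  strains <- unique(m$strain)
  phages <- unique(m$focal_phage)
  values <- matrix(NA_real_, length(strains), length(phages),
                   dimnames = list(strains, phages))
  agg <- stats::aggregate(rbg ~ strain + focal_phage, data = m, FUN = mean)
  values[cbind(match(agg$strain, strains), match(agg$focal_phage, phages))] <-
    agg$rbg
  sel <- tapply(m$selecting_phage, m$strain, function(x) x[1L])
  structure(list(values = values,
                 replicates = m[, c("strain", "selecting_phage",
                                    "focal_phage", "replicate", "rbg")],
                 selecting_phage = sel[strains],
                 receptor_of_phage = receptor_map),
            class = "rbg_matrix")
}

#' @export
print.rbg_matrix <- function(x, ...) {
  cat(sprintf("<rbg_matrix> %d strains x %d phages (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Classify RBG values as sensitive, intermediate or resistant
#'
#' Uses the class bounds of a calibration: `rbg <= sensitive_max` is
#' sensitive, `rbg >= resistant_min` is resistant, anything strictly between
#' is intermediate.
#'
#' @param rbg Numeric vector of RBG values.
#' @param cal An `rbg_calibration`, or a numeric length-2 vector
#'   `c(sensitive_max, resistant_min)`.
#' @return Ordered factor with levels sensitive < intermediate < resistant.
#' @export
classify_resistance <- function(rbg, cal) {
  b <- if (inherits(cal, "rbg_calibration")) cal$class_bounds else as.numeric(cal)
  if (length(b) != 2L || b[1L] > b[2L]) stop("invalid class bounds")
  out <- ifelse(rbg <= b[1L], "sensitive",
                ifelse(rbg >= b[2L], "resistant", "intermediate"))
  factor(out, levels = c("sensitive", "intermediate", "resistant"),
         ordered = TRUE)
}

#' Cross-resistance rates between receptor groups
#'
#' For each ordered pair of receptor groups (source -> target), the
#' denominator is the number of strains that were selected by a phage of the
#' source group and are resistant to their own selecting (focal) phage; the
#' numerator counts those additionally resistant to the target group's
#' phages, under `group_rule = "all"` (resistant to every phage of the group)
#' or `"any"`. Intermediate calls are not counted as resistant.
#'
#' @param matrix An `rbg_matrix` with `receptor_of_phage` set.
#' @param cal Calibration or bounds for [classify_resistance()].
#' @param group_rule `"all"` (default) or `"any"`.
#' @return Data.frame with `from_group`, `to_group`, `numerator`,
#'   `denominator`, `percent` (1 decimal; `NA` when the denominator is empty,
#'   flagged in `undefined`).
#' @export
cross_resistance_summary <- function(matrix, cal, group_rule = c("all", "any")) {
  stopifnot(inherits(matrix, "rbg_matrix"))
  group_rule <- match.arg(group_rule)
  rmap <- matrix$receptor_of_phage
  if (is.null(rmap)) stop("rbg_matrix has no receptor_of_phage map")
  phages <- colnames(matrix$values)
  if (!all(phages %in% names(rmap))) {
    stop("receptor map does not cover phage(s): ",
         paste(setdiff(phages, names(rmap)), collapse = ", "))
  }
  cls <- matrix$values
  cls[] <- as.character(classify_resistance(as.vector(matrix$values), cal))
  groups <- unique(unname(rmap[phages]))
  sel_phage <- matrix$selecting_phage
  sel_group <- unname(rmap[sel_phage])

  resistant_to_group <- function(strain, grp) {
    ph <- phages[rmap[phages] == grp]
    calls <- cls[strain, ph] == "resistant"
    if (anyNA(calls)) calls[is.na(calls)] <- FALSE
    if (group_rule == "all") all(calls) else any(calls)
  }

  out <- list()
  for (g1 in groups) for (g2 in setdiff(groups, g1)) {
    idx <- which(sel_group == g1)
    focal_res <- vapply(idx, function(i) {
      isTRUE(cls[i, sel_phage[i]] == "resistant")
    }, logical(1))
    denom_strains <- rownames(cls)[idx[focal_res]]
    num <- sum(vapply(denom_strains, resistant_to_group, logical(1), grp = g2))
    den <- length(denom_strains)
    out[[length(out) + 1L]] <- data.frame(
      from_group = g1, to_group = g2, numerator = num, denominator = den,
      percent = if (den > 0) round(100 * num / den, 1) else NA_real_,
      undefined = den == 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Hierarchically cluster the strain rows of an RBG matrix
#'
#' Agglomerative clustering of strains by their cross-resistance profiles
#' (Euclidean distance, average linkage). Missing cells are imputed with the
#' per-phage column mean (flagged). The leaf ordering is deterministic given
#' the input row order.
#'
#' @param matrix An `rbg_matrix`.
#' @return List with `order` (row indices), `labels`, `hclust` (the tree;
#'   `NULL` for fewer than 2 rows), `imputed` flag and `newick` string.
#' @export
cluster_rbg_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "rbg_matrix"))
  v <- matrix$values
  if (nrow(v) < 2L) {
    return(list(order = seq_len(nrow(v)), labels = rownames(v),
                hclust = NULL, imputed = FALSE,
                note = "fewer than 2 rows: trivial ordering"))
  }
  imputed <- anyNA(v)
  if (imputed) {
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      if (any(nas)) v[nas, j] <- mean(v[, j], na.rm = TRUE)
    }
  }
  hc <- stats::hclust(stats::dist(v, method = "euclidean"), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(order = hc$order, labels = rownames(v)[hc$order], hclust = hc,
       imputed = imputed, newick = nwk)
}
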