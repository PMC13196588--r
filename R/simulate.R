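#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every knob of the generators with a single seed; identical configs
#' give bit-identical output. Defaults mirror the assay designs the analyses
#' expect: 24 h of 30-min OD600 readings, triplicate wells; a 180-strain x
#' 8-phage endpoint-absorbance panel (20 strains per selecting phage, 40 for
#' the single O-antigen phage) with a bimodal RBG mixture; logistic selective
#' sweeps sampled at 12 h and days 1/3/5/7 at 100x population depth; 24-h
#' competition assays phenotyping 20 colonies; and a 500-gene insertion
#' library with three infected and three control replicates.
#'
#' @param seed Integer master seed.
#' @param growth Growth-curve block: `r` (per hour), `K`, `N0`, `noise_sd`
#'   (additive OD noise), `t_max`, `dt` (hours), `n_replicates`,
#'   `strain_mu_ratios` (named vector of per-strain rate multipliers),
#'   `resistant` (named logical: phenotype under phage), `lysis` (sensitive
#'   wells decline instead of staying flat).
#' @param rbg RBG-panel block: `mode_low`, `mode_high` (Beta modes),
#'   `concentration`, `weight_resistant` (focal-phage resistance
#'   probability), `cross` (receptor-pair resistance probabilities),
#'   `n_per_phage`, `receptors`, `n_replicates`, `ctrl_gain`, `abs_noise`.
#' @param sweep Selective-sweep block: per-class `onset` (days), `s`
#'   (selection coefficient per day), `f0`, plus `timepoints`, `depth`,
#'   `n_replicates`, `genes`.
#' @param competition Block: `true_W`, `g_s_meanlog`, `g_s_sdlog`, `t0`,
#'   `n_colonies`.
#' @param tnseq Block: `n_genes`, `n_enriched`, `multiplier`, `library_size`,
#'   `n_replicates`.
#' @param moi Multiplicity of infection recorded with the config (10 for the
#'   resistance panel, 1 for co-culture designs).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       growth = list(),
                       rbg = list(),
                       sweep = list(),
                       competition = list(),
                       tnseq = list(),
                       moi = 10) {
  merge_block <- function(defaults, user) {
    stopifnot(is.list(user))
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) stop("unknown field(s): ", paste(unknown, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  growth <- merge_block(list(
    r = 0.8, K = 1.0, N0 = 0.01, noise_sd = 0.002,
    t_max = 24, dt = 0.5, n_replicates = 3L,
    strain_mu_ratios = c(WT = 1.0, MUT = 0.9),
    resistant = c(WT = FALSE, MUT = TRUE),
    lysis = FALSE), growth)
  rbg <- merge_block(list(
    mode_low = 0.034, mode_high = 0.977, concentration = 52,
    weight_resistant = 166 / 180,
    cross = c(core_to_O = 0.447, O_to_core = 0.216, lps_btub = 0.05),
    n_per_phage = c(20L, 20L, 20L, 20L, 40L, 20L, 20L, 20L),
    receptors = c(P1 = "core", P2 = "core", P3 = "core", P4 = "core",
                  P5 = "O-antigen", P6 = "BtuB", P7 = "BtuB", P8 = "BtuB"),
    n_replicates = 3L, ctrl_gain = 0.8, abs_noise = 0.005), rbg)
  sweep <- merge_block(list(
    classes = list(
      LPS = list(gene = "rfaJ", onset = 0, s = 2.5, f0 = 0.05),
      BtuB = list(gene = "btuB", onset = 3, s = 2.5, f0 = 0.05)),
    timepoints = c(0.5, 1, 3, 5, 7), depth = 100L, n_replicates = 3L), sweep)
  competition <- merge_block(list(
    true_W = 0.93, g_s_meanlog = log(1e4), g_s_sdlog = 0.15,
    t0 = 1e5, n_colonies = 20L), competition)
  tnseq <- merge_block(list(
    n_genes = 500L, n_enriched = 10L, multiplier = 2^12,
    library_size = 2e6, n_replicates = 3L), tnseq)

  stopifnot(growth$r > 0, growth$K > 0, growth$N0 > 0, growth$noise_sd >= 0,
            rbg$weight_resistant >= 0, rbg$weight_resistant <= 1,
            rbg$concentration > 2,
            competition$true_W > 0, competition$true_W < 2,
            tnseq$n_enriched <= tnseq$n_genes)
  structure(list(seed = as.integer(seed), growth = growth, rbg = rbg,
                 sweep = sweep, competition = competition, tnseq = tnseq,
                 moi = moi),
            class = "sim_config")
}

logistic_od <- function(t, r, K, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

beta_mode_params <- function(mode, concentration) {
  c(shape1 = mode * (concentration - 2) + 1,
    shape2 = (1 - mode) * (concentration - 2) + 1)
}

#' Generate paired control/phage-treated growth curves
#'
#' Control wells follow a logistic curve with additive Gaussian noise;
#' phage-treated wells of sensitive strains stay flat at the inoculum
#' density (or decline, in lysis mode) while resistant strains grow as the
#' control does.
#'
#' @param cfg A [sim_config()].
#' @return List of `growth_curve` objects (control and phage-treated, per
#'   strain and replicate).
#' @export
gen_growth_curves <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$growth
  set.seed(cfg$seed + 101L)
  t <- seq(0, g$t_max, by = g$dt)
  out <- list()
  for (strain in names(g$strain_mu_ratios)) {
    r_i <- g$r * g$strain_mu_ratios[[strain]]
    for (rep_i in seq_len(g$n_replicates)) {
      ctrl <- logistic_od(t, r_i, g$K, g$N0) +
        stats::rnorm(length(t), 0, g$noise_sd)
      out[[length(out) + 1L]] <- growth_curve(
        sample_id = sprintf("%s_ctrl_r%d", strain, rep_i),
        strain_id = strain, phage_treatment = NA_character_,
        replicate = rep_i, times = t, od = ctrl)
      treated <- if (isTRUE(g$resistant[[strain]])) {
        logistic_od(t, r_i, g$K, g$N0)
      } else if (g$lysis) {
        g$N0 * exp(-0.3 * t)
      } else {
        rep(g$N0, length(t))
      }
      out[[length(out) + 1L]] <- growth_curve(
        sample_id = sprintf("%s_phage_r%d", strain, rep_i),
        strain_id = strain, phage_treatment = "phage",
        replicate = rep_i, times = t,
        od = treated + stats::rnorm(length(t), 0, g$noise_sd))
    }
  }
  out
}

#' Generate an endpoint-absorbance interaction panel with known classes
#'
#' Each strain is labelled by its selecting phage; per (strain, phage) cell a
#' true resistance state is drawn (focal cells with probability
#' `weight_resistant`; off-focal cells by receptor-pair rules), then
#' replicate RBG values are drawn from a Beta centred on the resistant or
#' sensitive mode and converted to endpoint absorbances consistent with the
#' RBG definition.
#'
#' @param cfg A [sim_config()].
#' @return List with `measurements` (data.frame as consumed by
#'   [build_rbg_matrix()]), `truth` (strain, phage, resistant) and
#'   `receptor_map`.
#' @export
gen_interaction_rbg <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$rbg
  set.seed(cfg$seed + 202L)
  phages <- names(p$receptors)
  sel_phage <- rep(phages, p$n_per_phage)
  n_strain <- length(sel_phage)
  strains <- sprintf("S%03d", seq_len(n_strain))

  ## resistance is receptor-mediated: one Bernoulli per (strain, receptor
  ## group), shared by every phage of the group; the strain's own group uses
  ## the focal-resistance probability
  group_prob <- function(sel_receptor, target_receptor) {
    if (sel_receptor == target_receptor) return(p$weight_resistant)
    if (sel_receptor == "core" && target_receptor == "O-antigen") {
      return(p$cross[["core_to_O"]])
    }
    if (sel_receptor == "O-antigen" && target_receptor == "core") {
      return(p$cross[["O_to_core"]])
    }
    p$cross[["lps_btub"]]
  }

  bres <- beta_mode_params(p$mode_high, p$concentration)
  bsen <- beta_mode_params(p$mode_low, p$concentration)

  groups <- unique(unname(p$receptors))
  grp_state <- matrix(FALSE, n_strain, length(groups),
                      dimnames = list(strains, groups))
  for (i in seq_len(n_strain)) {
    rsel <- p$receptors[[sel_phage[i]]]
    for (g in groups) {
      grp_state[i, g] <- stats::runif(1L) < group_prob(rsel, g)
    }
  }
  truth <- expand.grid(strain = strains, phage = phages,
                       stringsAsFactors = FALSE)
  truth$selecting_phage <- sel_phage[match(truth$strain, strains)]
  truth$resistant <- grp_state[cbind(truth$strain,
                                     unname(p$receptors[truth$phage]))]

  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pars <- if (truth$resistant[i]) bres else bsen
    rbg_rep <- stats::rbeta(p$n_replicates, pars[1L], pars[2L])
    gain <- p$ctrl_gain + stats::rnorm(p$n_replicates, 0, 0.02)
    a8p <- 0.05 + rbg_rep * gain + stats::rnorm(p$n_replicates, 0, p$abs_noise)
    rows[[i]] <- data.frame(
      strain = truth$strain[i], selecting_phage = truth$selecting_phage[i],
      focal_phage = truth$phage[i], replicate = seq_len(p$n_replicates),
      a0_phage = 0.05, a8_phage = pmax(a8p, 0.05),
      a0_ctrl = 0.05, a8_ctrl = 0.05 + gain,
      endpoint_h = 8, stringsAsFactors = FALSE)
  }
  list(measurements = do.call(rbind, rows),
       truth = truth[, c("strain", "phage", "selecting_phage", "resistant")],
       receptor_map = p$receptors)
}

#' Generate population variant records with staggered selective sweeps
#'
#' Each resistance class sweeps logistically
#' \eqn{f(t) = f_0 e^{s(t - onset)} / (1 + f_0 (e^{s(t - onset)} - 1))} for
#' `t >= onset` (0 before), and the observed frequency at each sampled
#' timepoint is a binomial draw at the configured sequencing depth. Records
#' carry gene names from the default gene-class map, so the full trajectory
#' and acquisition-order machinery runs on them unchanged.
#'
#' @param cfg A [sim_config()].
#' @return Variant data.frame (population dialect, one row per replicate x
#'   timepoint x class with non-zero observed frequency).
#' @export
gen_variant_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- cfg$sweep
  set.seed(cfg$seed + 303L)
  sweep_freq <- function(t, onset, sel, f0) {
    ifelse(t < onset, 0,
           f0 * exp(sel * (t - onset)) / (1 + f0 * (exp(sel * (t - onset)) - 1)))
  }
  rows <- list()
  for (rep_i in seq_len(s$n_replicates)) {
    for (cls in names(s$classes)) {
      cc <- s$classes[[cls]]
      f <- sweep_freq(s$timepoints, cc$onset, cc$s, cc$f0)
      obs <- stats::rbinom(length(f), s$depth, f) / s$depth
      keep <- obs > 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("pop_r%d", rep_i),
        timepoint = s$timepoints[keep], gene = cc$gene,
        mutation_type = "frameshift",
        nt_change = paste0(cc$gene, "_allele1"),
        aa_change = NA_character_,
        frequency = obs[keep], indel_len = 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_variants())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate competition assays with known true fitness
#'
#' The wild type realizes a lognormal fold-growth \eqn{G_S}; the resistant
#' strain realizes \eqn{G_R = G_S^{W}}. The total 24-h density follows, and
#' the number of wild-type colonies among those sampled is binomial in the
#' true final proportion.
#'
#' @param cfg A [sim_config()].
#' @param n_assays Number of independent assays to simulate.
#' @return Data.frame (`t0_resistant`, `t0_wt`, `t24_total`,
#'   `colonies_sampled`, `colonies_wt`, `true_W`).
#' @export
gen_competition_assay <- function(cfg, n_assays = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  cp <- cfg$competition
  set.seed(cfg$seed + 404L)
  g_s <- stats::rlnorm(n_assays, cp$g_s_meanlog, cp$g_s_sdlog)
  g_r <- g_s^cp$true_W
  tr24 <- cp$t0 * g_r
  ts24 <- cp$t0 * g_s
  p_r <- tr24 / (tr24 + ts24)
  data.frame(t0_resistant = cp$t0, t0_wt = cp$t0,
             t24_total = tr24 + ts24,
             colonies_sampled = cp$n_colonies,
             colonies_wt = stats::rbinom(n_assays, cp$n_colonies, 1 - p_r),
             true_W = cp$true_W)
}

#' Generate an insertion-count table with planted enriched genes
#'
#' Control libraries are multinomial draws over genes with gamma-distributed
#' base weights; infected libraries reuse the same base weights with the
#' planted genes up-weighted by `multiplier`.
#'
#' @param cfg A [sim_config()].
#' @return List with `table` (an `insertion_count_table`) and
#'   `enriched_genes` (character vector of the planted genes).
#' @export
gen_tnseq_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tn <- cfg$tnseq
  set.seed(cfg$seed + 505L)
  genes <- sprintf("g%04d", seq_len(tn$n_genes))
  base_w <- stats::rgamma(tn$n_genes, shape = 5, rate = 1)
  enriched <- genes[seq_len(tn$n_enriched)]
  w_inf <- base_w
  w_inf[seq_len(tn$n_enriched)] <- w_inf[seq_len(tn$n_enriched)] * tn$multiplier
  n_rep <- tn$n_replicates
  counts <- matrix(0L, tn$n_genes, 2L * n_rep,
                   dimnames = list(genes, c(paste0("infected.", seq_len(n_rep)),
                                            paste0("control.", seq_len(n_rep)))))
  for (j in seq_len(n_rep)) {
    counts[, j] <- stats::rmultinom(1L, tn$library_size, w_inf)[, 1L]
    counts[, n_rep + j] <- stats::rmultinom(1L, tn$library_size, base_w)[, 1L]
  }
  list(table = insertion_count_table(counts,
                                     rep(c("infected", "control"), each = n_rep),
                                     rep(seq_len(n_rep), 2L)),
       enriched_genes = enriched)
}

#' Write every simulated input the analysis stages read
#'
#' Materializes the generator outputs as the flat files the readers consume:
#' long-format growth CSV, endpoint-absorbance interaction CSV, population
#' variant TSV, competition CSV, insertion-count TSV and a receptor-map YAML.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_inputs <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(growth = file.path(outdir, "growth.csv"),
             interactions = file.path(outdir, "interactions.csv"),
             variants = file.path(outdir, "variants.tsv"),
             competition = file.path(outdir, "competition.csv"),
             tnseq = file.path(outdir, "tnseq_counts.tsv"),
             receptors = file.path(outdir, "receptors.yaml"))

  curves <- gen_growth_curves(cfg)
  growth_df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample = cv$sample_id, strain = cv$strain_id,
               phage = ifelse(is.na(cv$phage_treatment), "", cv$phage_treatment),
               replicate = cv$replicate, time_h = cv$times, od600 = cv$od,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(growth_df, paths[["growth"]], row.names = FALSE)

  panel <- gen_interaction_rbg(cfg)
  utils::write.csv(panel$measurements, paths[["interactions"]],
                   row.names = FALSE)
  yaml::write_yaml(as.list(panel$receptor_map), paths[["receptors"]])

  vr <- gen_variant_timeseries(cfg)
  utils::write.table(
    stats::setNames(vr, c("sample", "timepoint", "gene", "mutation_type",
                          "nt_change", "aa_change", "frequency", "indel_len")),
    paths[["variants"]], sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.csv(gen_competition_assay(cfg, n_assays = 3L),
                   paths[["competition"]], row.names = FALSE)

  tn <- gen_tnseq_counts(cfg)
  long <- data.frame(
    gene = rep(rownames(tn$table$counts), ncol(tn$table$counts)),
    condition = rep(tn$table$condition, each = nrow(tn$table$counts)),
    replicate = rep(tn$table$replicate, each = nrow(tn$table$counts)),
    count = as.vector(tn$table$counts), stringsAsFactors = FALSE)
  utils::write.table(long, paths[["tnseq"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
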