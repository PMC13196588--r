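WORKFLOW_KEYS <- c("seed", "outdir", "simulate", "inputs", "rbg", "kinetics",
                   "mutations", "tnseq")

#' Validate a workflow configuration file
#'
#' Checks the YAML config against the documented schema and returns every
#' violation found, not just the first. Unknown top-level keys are rejected
#' (strict mode).
#'
#' @param config Path to a YAML config.
#' @return Character vector of violations; `character(0)` means the config is
#'   valid.
#' @export
validate_config <- function(config) {
  if (!file.exists(config)) stop("config file not readable: ", config)
  cf <- yaml::read_yaml(config)
  v <- character(0)
  unknown <- setdiff(names(cf), WORKFLOW_KEYS)
  if (length(unknown)) {
    v <- c(v, paste0("unknown top-level key(s): ",
                     paste(unknown, collapse = ", ")))
  }
  if (is.null(cf$outdir)) v <- c(v, "outdir: required")
  if (!is.null(cf$seed) &&
      (!is.numeric(cf$seed) || cf$seed != round(cf$seed))) {
    v <- c(v, "seed: must be an integer")
  }
  nb <- cf$rbg$n_boot
  if (!is.null(nb) && (!is.numeric(nb) || nb < 0)) {
    v <- c(v, "rbg.n_boot: must be a non-negative integer")
  }
  wp <- cf$kinetics$window_points
  if (!is.null(wp) && (!is.numeric(wp) || wp < 3)) {
    v <- c(v, "kinetics.window_points: must be >= 3")
  }
  mf <- cf$mutations$min_freq
  if (!is.null(mf) && (!is.numeric(mf) || mf < 0 || mf >= 1)) {
    v <- c(v, "mutations.min_freq: must be in [0, 1)")
  }
  th <- cf$mutations$threshold
  if (!is.null(th) && (!is.numeric(th) || th <= 0 || th >= 1)) {
    v <- c(v, "mutations.threshold: must be in (0, 1)")
  }
  pc <- cf$tnseq$pseudocount
  if (!is.null(pc) && (!is.numeric(pc) || pc <= 0)) {
    v <- c(v, "tnseq.pseudocount: must be positive")
  }
  if (isFALSE(cf$simulate) && is.null(cf$inputs)) {
    v <- c(v, "inputs: required when simulate is false")
  }
  v
}

wf_opt <- function(cf, path, default) {
  x <- cf
  for (k in path) {
    x <- x[[k]]
    if (is.null(x)) return(default)
  }
  x
}

#' Run the end-to-end resistance-analysis workflow
#'
#' Executes the pipeline stages in dependency order — simulate (optional),
#' RBG scoring, threshold calibration, classification, cross-resistance
#' tabulation, growth kinetics, competition fitness, mutation trajectories
#' and acquisition order, Tn-seq enrichment — each stage reading the config
#' block of the same name. Stages whose inputs are not configured are
#' skipped and noted. A stage failure aborts downstream stages but completed
#' outputs are preserved; the provenance manifest is written last either
#' way. All randomness derives from the single top-level `seed`. Progress is
#' logged to standard error.
#'
#' @param config Path to a YAML config (see [validate_config()]).
#' @return The run manifest (also written to `outdir/manifest.json`):
#'   config snapshot, input digests, seed, package version, per-stage output
#'   paths and digests, skipped stages, warnings, and `failed_stage` if any.
#' @export
run_workflow <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  }
  cf <- yaml::read_yaml(config)
  seed <- as.integer(wf_opt(cf, "seed", 1L))
  outdir <- cf$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    config = cf, seed = seed,
    package_version = as.character(utils::packageVersion("phageresist")),
    inputs = list(), outputs = list(), skipped = character(0),
    warnings = character(0))
  log_msg <- function(...) message("[phageresist] ", ...)
  note_output <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    stats::setNames(unname(tools::md5sum(path)), path))
  }

  inputs <- if (isTRUE(wf_opt(cf, "simulate", TRUE))) {
    log_msg("stage simulate: generating inputs")
    p <- write_simulated_inputs(sim_config(seed = seed),
                                file.path(outdir, "inputs"))
    as.list(p)
  } else {
    cf$inputs
  }
  for (nm in names(inputs)) {
    if (file.exists(inputs[[nm]])) {
      manifest$inputs[[nm]] <- unname(tools::md5sum(inputs[[nm]]))
    }
  }

  failed <- NULL
  run_stage <- function(name, fn) {
    if (!is.null(failed)) return(invisible(NULL))
    log_msg("stage ", name)
    tryCatch(fn(), error = function(e) {
      failed <<- name
      manifest$warnings <<- c(manifest$warnings,
                              paste0("stage ", name, " failed: ",
                                     conditionMessage(e)))
      log_msg("stage ", name, " FAILED: ", conditionMessage(e))
    })
  }
  skip_stage <- function(name, why) {
    manifest$skipped <<- c(manifest$skipped, paste0(name, ": ", why))
    log_msg("stage ", name, " skipped (", why, ")")
  }

  mat <- NULL; cal <- NULL
  if (!is.null(inputs$interactions)) {
    run_stage("score", function() {
      meas <- read_interaction_table(inputs$interactions)
      rmap <- if (!is.null(inputs$receptors)) {
        unlist(yaml::read_yaml(inputs$receptors))
      } else NULL
      mat <<- build_rbg_matrix(meas, receptor_map = rmap)
      path <- file.path(outdir, "rbg_matrix.tsv")
      utils::write.table(data.frame(strain = rownames(mat$values),
                                    mat$values, check.names = FALSE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      note_output("score", path)
    })
    run_stage("calibrate", function() {
      vals <- as.vector(mat$values)
      cal <<- rbg_calibrate(vals[!is.na(vals)],
                            n_boot = wf_opt(cf, c("rbg", "n_boot"), 1000L),
                            seed = seed)
      path <- file.path(outdir, "calibration.json")
      write_calibration_json(cal, path)
      note_output("calibrate", path)
    })
    run_stage("classify", function() {
      cls <- mat$values
      cls[] <- as.character(classify_resistance(as.vector(mat$values), cal))
      path <- file.path(outdir, "class_matrix.tsv")
      utils::write.table(data.frame(strain = rownames(cls), cls,
                                    check.names = FALSE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      note_output("classify", path)
    })
    run_stage("crosstab", function() {
      if (is.null(mat$receptor_of_phage)) {
        stop("no receptor map configured")
      }
      tab <- cross_resistance_summary(mat, cal)
      path <- file.path(outdir, "cross_resistance.tsv")
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_output("crosstab", path)
    })
  } else skip_stage("score", "no interaction input")

  if (!is.null(inputs$growth)) {
    run_stage("kinetics", function() {
      curves <- read_growth_table(inputs$growth)
      sums <- lapply(curves, summarize_kinetics,
                     blank = wf_opt(cf, c("kinetics", "blank"), 0),
                     window_points = wf_opt(cf, c("kinetics", "window_points"), 5L))
      path <- file.path(outdir, "kinetics.tsv")
      write_kinetics_tsv(sums, path)
      note_output("kinetics", path)
    })
  } else skip_stage("kinetics", "no growth input")

  if (!is.null(inputs$competition)) {
    run_stage("fitness", function() {
      d <- utils::read.csv(inputs$competition)
      d$W <- vapply(seq_len(nrow(d)), function(i) {
        as.numeric(competition_fitness(d$t0_resistant[i], d$t0_wt[i],
                                       d$t24_total[i], d$colonies_sampled[i],
                                       d$colonies_wt[i]))
      }, numeric(1))
      path <- file.path(outdir, "competition.tsv")
      utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
      note_output("fitness", path)
    })
  } else skip_stage("fitness", "no competition input")

  if (!is.null(inputs$variants)) {
    run_stage("mutations", function() {
      recs <- read_variant_table(inputs$variants, dialect = "tsv")
      recs <- filter_lof_variants(recs,
                                  min_freq = wf_opt(cf, c("mutations", "min_freq"), 0.05))
      traj <- build_trajectories(recs, aggregate = "category")
      path <- file.path(outdir, "trajectories.tsv")
      utils::write.table(as.data.frame(traj), path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note_output("mutations", path)
      ord <- detect_sequential_acquisition(
        traj, threshold = wf_opt(cf, c("mutations", "threshold"), 0.5))
      opath <- file.path(outdir, "acquisition_order.json")
      jsonlite::write_json(ord, opath, auto_unbox = TRUE, digits = NA)
      note_output("mutations", opath)
    })
  } else skip_stage("mutations", "no variant input")

  if (!is.null(inputs$tnseq)) {
    run_stage("tnseq", function() {
      tab <- read_insertion_counts(inputs$tnseq)
      enr <- compute_enrichment(tab,
                                pseudocount = wf_opt(cf, c("tnseq", "pseudocount"), 1))
      path <- file.path(outdir, "enrichment.tsv")
      utils::write.table(enr, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_output("tnseq", path)
    })
  } else skip_stage("tnseq", "no insertion-count input")

  manifest$failed_stage <- failed
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_msg("manifest written to ", mpath)
  invisible(manifest)
}
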