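LOF_TYPES <- c("nonsense", "missense", "frameshift", "large_indel")
MUTATION_TYPES <- c(LOF_TYPES, "synonymous", "intergenic", "other")

empty_variants <- function() {
  data.frame(sample_id = character(0), timepoint = numeric(0),
             gene = character(0), mutation_type = character(0),
             nt_change = character(0), aa_change = character(0),
             frequency = numeric(0), indel_len = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a variant table (breseq genome-diff or flat TSV)
#'
#' The GD dialect consumes breseq mutation lines (SNP/INS/DEL/MOB) and maps
#' them onto a closed mutation-type vocabulary: SNPs are classified from the
#' `snp_type` annotation (nonsynonymous -> missense, etc.); deletions and
#' insertions of at least `large_indel_min` bp become `large_indel`, shorter
#' coding indels with length not a multiple of 3 become `frameshift`;
#' mobile-element insertions in coding regions are treated as `large_indel`.
#' Lines whose type cannot be mapped are kept as `"other"` with a warning.
#' The TSV dialect is a direct column mapping (`sample`, `timepoint`, `gene`,
#' `mutation_type`, `nt_change`, `aa_change`, `frequency`, `indel_len`).
#'
#' @param path File path.
#' @param dialect `"gd"` or `"tsv"`.
#' @param sample_id Sample label for GD files (defaults to the file name).
#' @param large_indel_min Minimum deletion/insertion length in bp counted as
#'   a large indel (default 30).
#' @return A data.frame of variant records with columns `sample_id`,
#'   `timepoint`, `gene`, `mutation_type`, `nt_change`, `aa_change`,
#'   `frequency`, `indel_len`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "gd"),
                               sample_id = NULL, large_indel_min = 30L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene", "mutation_type", "frequency")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    out <- empty_variants()[seq_len(nrow(df)), ]
    out$sample_id <- if ("sample" %in% names(df)) as.character(df$sample) else
      rep(if (is.null(sample_id)) basename(path) else sample_id, nrow(df))
    out$timepoint <- if ("timepoint" %in% names(df)) as.numeric(df$timepoint) else NA_real_
    out$gene <- as.character(df$gene)
    out$mutation_type <- as.character(df$mutation_type)
    out$nt_change <- if ("nt_change" %in% names(df)) as.character(df$nt_change) else NA_character_
    out$aa_change <- if ("aa_change" %in% names(df)) as.character(df$aa_change) else NA_character_
    out$frequency <- as.numeric(df$frequency)
    out$indel_len <- if ("indel_len" %in% names(df)) as.numeric(df$indel_len) else NA_real_
    rownames(out) <- NULL
  } else {
    out <- parse_genome_diff(path,
                             if (is.null(sample_id)) basename(path) else sample_id,
                             large_indel_min)
  }
  bad <- !out$mutation_type %in% MUTATION_TYPES
  if (any(bad)) {
    warning(sum(bad), " record(s) with unmappable mutation type kept as 'other'")
    out$mutation_type[bad] <- "other"
  }
  if (any(out$frequency < 0 | out$frequency > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  out
}

parse_genome_diff <- function(path, sample_id, large_indel_min) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    type <- f[1L]
    if (!type %in% c("SNP", "INS", "DEL", "MOB", "SUB")) next  # evidence lines etc.
    kv <- f[grepl("=", f, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k, default = NA_character_) {
      i <- match(k, keys); if (is.na(i)) default else vals[i]
    }
    gene <- get("gene_name")
    gene_pos <- get("gene_position", "")
    intergenic <- grepl("intergenic", gene_pos, fixed = TRUE) ||
      (!is.na(gene) && grepl("/", gene, fixed = TRUE))
    freq <- suppressWarnings(as.numeric(get("frequency", "1")))
    if (is.na(freq)) freq <- 1
    pos <- f[5L]
    indel_len <- NA_real_
    if (type == "SNP") {
      mt <- switch(get("snp_type", "other"),
                   nonsynonymous = "missense", synonymous = "synonymous",
                   nonsense = "nonsense", intergenic = "intergenic",
                   "other")
      nt <- paste0(f[4L], ":", pos, ">", f[6L])
    } else if (type %in% c("DEL", "INS", "SUB", "MOB")) {
      size <- switch(type,
                     DEL = suppressWarnings(as.numeric(f[6L])),
                     INS = nchar(f[6L]),
                     SUB = suppressWarnings(as.numeric(f[6L])),
                     MOB = large_indel_min)  # element insertion: treat as large
      indel_len <- size
      nt <- switch(type,
                   DEL = paste0(pos, "del", size),
                   INS = paste0(pos, "ins", f[6L]),
                   SUB = paste0(pos, "sub", size),
                   MOB = paste0(pos, "mob", f[6L]))
      mt <- if (intergenic) "intergenic"
      else if (!is.na(size) && size >= large_indel_min) "large_indel"
      else if (!is.na(size) && size %% 3 != 0) "frameshift"
      else "other"
    }
    aa <- NA_character_
    if (!is.na(get("aa_position"))) {
      aa <- paste0(get("aa_ref_seq", ""), get("aa_position"),
                   get("aa_new_seq", ""))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      sample_id = sample_id,
      timepoint = suppressWarnings(as.numeric(get("timepoint"))),
      gene = gene, mutation_type = mt, nt_change = nt, aa_change = aa,
      frequency = freq, indel_len = indel_len, stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty_variants())
  do.call(rbind, recs)
}

#' Retain putative loss-of-function variants above a frequency floor
#'
#' Keeps nonsense, missense, frameshift and large-indel records with
#' frequency at or above `min_freq` (the polymorphism-detection floor;
#' default 5%). Records whose `indel_len` reaches `large_indel_min` are
#' promoted to `large_indel` first. Input order is preserved; the filter is
#' idempotent.
#'
#' @param records Variant data.frame (see [read_variant_table()]).
#' @param min_freq Minimum population frequency in [0, 1) (default 0.05).
#' @param large_indel_min Large-indel length threshold in bp (default 30).
#' @return The filtered data.frame.
#' @export
filter_lof_variants <- function(records, min_freq = 0.05,
                                large_indel_min = 30L) {
  if (min_freq < 0 || min_freq >= 1) stop("min_freq must be in [0, 1)")
  if (!nrow(records)) return(records)
  promote <- !is.na(records$indel_len) & records$indel_len >= large_indel_min &
    records$mutation_type %in% c("frameshift", "other")
  records$mutation_type[promote] <- "large_indel"
  keep <- records$mutation_type %in% LOF_TYPES &
    !is.na(records$frequency) & records$frequency >= min_freq
  records[keep, , drop = FALSE]
}

#' Remove ancestral background mutations
#'
#' Drops records matching an ancestor (wild-type) call on `(gene, nt_change)`
#' — mutations present before phage exposure are not responses to it.
#'
#' @param records,ancestor Variant data.frames in the same annotation
#'   convention.
#' @return `records` without background matches.
#' @export
subtract_background <- function(records, ancestor) {
  if (!nrow(records) || !nrow(ancestor)) return(records)
  key <- function(df) paste(df$gene, df$nt_change, sep = "\r")
  records[!key(records) %in% key(ancestor), , drop = FALSE]
}

#' Built-in gene-to-receptor-class map
#'
#' Maps receptor-pathway genes to the phenotype class of the resistance they
#' confer (`O-antigen-only`, `core-only`, `both-LPS`, `BtuB`, `other`) and a
#' pathway group (`rfb-cluster`, `rfc`, `rfa-cluster`, `LPS-regulator`,
#' `sugar-precursor`, `btuB`, `other`). Class is allele-dependent for rfaJ:
#' loss-of-function alleles truncate the core (and with it the O-antigen),
#' whereas the missense alleles A198V/L229P/A275E/D216E alter only the core —
#' these are carried in an allele-level override table. hldE is mapped to
#' sugar-precursor/core-only by pathway analogy (inferred, flagged).
#'
#' @return A `gene_class_map`: list with `genes` (data.frame gene, class,
#'   group, inferred) and `allele_overrides` (gene, aa_change, class, group).
#' @export
default_gene_class_map <- function() {
  genes <- data.frame(
    gene = c("rfbD", "rfbC", "rfbV", "rfbU", "rfbP", "rfc",
             "rfaI", "rfaJ", "rfaG", "rfaF", "rfaK", "rfaH",
             "rfaP", "pgm", "galE", "hldE", "btuB"),
    class = c(rep("O-antigen-only", 6L),
              rep("both-LPS", 6L),
              rep("core-only", 4L), "BtuB"),
    group = c(rep("rfb-cluster", 5L), "rfc",
              rep("rfa-cluster", 5L), "LPS-regulator",
              "rfa-cluster", "sugar-precursor", "sugar-precursor",
              "sugar-precursor", "btuB"),
    inferred = FALSE, stringsAsFactors = FALSE)
  genes$inferred[genes$gene %in% c("hldE", "rfaK")] <- TRUE
  overrides <- data.frame(
    gene = "rfaJ",
    aa_change = c("A198V", "L229P", "A275E", "D216E"),
    class = "core-only", group = "rfa-cluster", stringsAsFactors = FALSE)
  structure(list(genes = genes, allele_overrides = overrides),
            class = "gene_class_map")
}

#' Assign receptor class and pathway group to variant records
#'
#' @param records Variant data.frame.
#' @param map A `gene_class_map` (default [default_gene_class_map()]).
#' @return `records` with `class` and `group` columns appended; unmapped
#'   genes get `("other", "other")`.
#' @export
assign_receptor_class <- function(records, map = default_gene_class_map()) {
  stopifnot(inherits(map, "gene_class_map"))
  i <- match(records$gene, map$genes$gene)
  records$class <- ifelse(is.na(i), "other", map$genes$class[i])
  records$group <- ifelse(is.na(i), "other", map$genes$group[i])
  ov <- map$allele_overrides
  if (nrow(records) && nrow(ov)) {
    hit <- match(paste(records$gene, records$aa_change),
                 paste(ov$gene, ov$aa_change))
    sel <- !is.na(hit)
    records$class[sel] <- ov$class[hit[sel]]
    records$group[sel] <- ov$group[hit[sel]]
  }
  records
}

#' Mutation spectrum summaries
#'
#' Deterministic count tables over filtered variant records: records per
#' gene, per pathway group and per phenotype class, plus distinct-gene counts
#' per receptor-target category (all LPS-related classes pooled versus BtuB).
#'
#' @param records Variant data.frame (filtered).
#' @param map A `gene_class_map`.
#' @return List with `by_gene`, `by_group`, `by_class` (data.frames with
#'   `n_records` and `n_genes`) and `distinct_genes` (named vector with
#'   elements `LPS`, `BtuB`, `other`).
#' @export
mutation_spectrum <- function(records, map = default_gene_class_map()) {
  records <- assign_receptor_class(records, map)
  count_by <- function(key) {
    if (!nrow(records)) {
      return(data.frame(key = character(0), n_records = integer(0),
                        n_genes = integer(0), stringsAsFactors = FALSE))
    }
    split_idx <- split(seq_len(nrow(records)), records[[key]])
    data.frame(key = names(split_idx),
               n_records = vapply(split_idx, length, 1L),
               n_genes = vapply(split_idx, function(ii) {
                 length(unique(records$gene[ii]))
               }, 1L),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  lps_classes <- c("O-antigen-only", "core-only", "both-LPS")
  distinct <- c(
    LPS = length(unique(records$gene[records$class %in% lps_classes])),
    BtuB = length(unique(records$gene[records$class == "BtuB"])),
    other = length(unique(records$gene[records$class == "other"])))
  list(by_gene = stats::setNames(count_by("gene"),
                                 c("gene", "n_records", "n_genes")),
       by_group = stats::setNames(count_by("group"),
                                  c("group", "n_records", "n_genes")),
       by_class = stats::setNames(count_by("class"),
                                  c("class", "n_records", "n_genes")),
       distinct_genes = distinct)
}

#' Population allele-frequency trajectories
#'
#' Aggregates population variant records into per-replicate frequency series
#' over shared timepoints. Multiple alleles mapping to one key (gene, class
#' or receptor-target category) are combined by `max` (distinct alleles read
#' as alternative sweeps of the same target; default) or `sum_capped` (summed
#' and capped at 1). Timepoints at which a key was not observed get
#' frequency 0.
#'
#' @param records Population variant data.frame with `sample_id` (replicate),
#'   `timepoint` and `frequency`.
#' @param aggregate `"gene"`, `"class"` or `"category"` (LPS vs BtuB).
#' @param combine `"max"` or `"sum_capped"`.
#' @param map A `gene_class_map` (used for class/category aggregation).
#' @return A `trajectory_set`: long data.frame (`replicate`, `timepoint`,
#'   `key`, `frequency`) with attributes `timepoints` and `aggregate`.
#' @export
build_trajectories <- function(records,
                               aggregate = c("gene", "class", "category"),
                               combine = c("max", "sum_capped"),
                               map = default_gene_class_map()) {
  aggregate <- match.arg(aggregate)
  combine <- match.arg(combine)
  if (!nrow(records)) stop("no records to build trajectories from")
  if (anyNA(records$timepoint)) stop("population records must carry timepoints")
  records <- assign_receptor_class(records, map)
  records$key <- switch(aggregate,
                        gene = records$gene,
                        class = records$class,
                        category = ifelse(records$class == "BtuB", "BtuB",
                                          ifelse(records$class == "other",
                                                 "other", "LPS")))
  tps <- sort(unique(records$timepoint))
  grid <- expand.grid(replicate = unique(records$sample_id),
                      timepoint = tps, key = unique(records$key),
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(frequency ~ sample_id + timepoint + key,
                          data = records,
                          FUN = if (combine == "max") max else sum)
  if (combine == "sum_capped") agg$frequency <- pmin(agg$frequency, 1)
  i <- match(paste(grid$replicate, grid$timepoint, grid$key),
             paste(agg$sample_id, agg$timepoint, agg$key))
  grid$frequency <- ifelse(is.na(i), 0, agg$frequency[i])
  grid <- grid[order(grid$key, grid$replicate, grid$timepoint), ]
  rownames(grid) <- NULL
  structure(grid, class = c("trajectory_set", "data.frame"),
            timepoints = tps, aggregate = aggregate)
}

#' Order of resistance acquisition from frequency trajectories
#'
#' For each trajectory key, finds the earliest timepoint at which the
#' frequency reaches `threshold` ("dominance") in each replicate, summarizes
#' replicates by the median first-passage time, and orders keys by it. Keys
#' that never cross are omitted; simultaneous crossings are flagged as ties.
#'
#' @param traj A `trajectory_set` (class- or category-aggregated for
#'   receptor-level ordering).
#' @param threshold Dominance threshold in (0, 1) (default 0.5).
#' @return Data.frame (`key`, `first_passage`, `tie`) ordered by
#'   `first_passage`; zero rows if nothing crosses.
#' @export
detect_sequential_acquisition <- function(traj, threshold = 0.5) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!nrow(traj)) {
    return(data.frame(key = character(0), first_passage = numeric(0),
                      tie = logical(0), stringsAsFactors = FALSE))
  }
  fp_one <- function(d) {
    hit <- d$timepoint[d$frequency >= threshold]
    if (length(hit)) min(hit) else Inf
  }
  per_key <- lapply(split(as.data.frame(traj), traj$key), function(d) {
    stats::median(vapply(split(d, d$replicate), fp_one, numeric(1)))
  })
  fp <- unlist(per_key)
  fp <- fp[is.finite(fp)]
  if (!length(fp)) {
    return(data.frame(key = character(0), first_passage = numeric(0),
                      tie = logical(0), stringsAsFactors = FALSE))
  }
  ord <- order(fp, names(fp))
  out <- data.frame(key = names(fp)[ord], first_passage = unname(fp)[ord],
                    tie = FALSE, stringsAsFactors = FALSE)
  out$tie <- duplicated(out$first_passage) |
    duplicated(out$first_passage, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
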