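#' Construct a per-gene insertion-count table
#'
#' @param counts Numeric matrix, genes x libraries (columns are individual
#'   sequencing libraries).
#' @param condition Character vector, one of `"infected"`/`"control"` per
#'   column.
#' @param replicate Integer vector of replicate indices per column.
#' @return An `insertion_count_table` with `counts`, `condition`,
#'   `replicate` and `library_sizes` (column sums).
#' @export
insertion_count_table <- function(counts, condition, replicate) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts)) {
    stop("condition/replicate must have one entry per column")
  }
  if (!all(condition %in% c("infected", "control"))) {
    stop("condition must be 'infected' or 'control'")
  }
  structure(list(counts = counts, condition = condition,
                 replicate = as.integer(replicate),
                 library_sizes = colSums(counts)),
            class = "insertion_count_table")
}

#' Read a per-gene insertion-count TSV
#'
#' Long format with columns `gene`, `condition`, `replicate`, `count`.
#'
#' @param path TSV path.
#' @return An `insertion_count_table`.
#' @export
read_insertion_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lib <- paste(df$condition, df$replicate, sep = ".")
  genes <- unique(df$gene)
  libs <- unique(lib)
  m <- matrix(0, length(genes), length(libs),
              dimnames = list(genes, libs))
  m[cbind(match(df$gene, genes), match(lib, libs))] <- df$count
  meta <- do.call(rbind, strsplit(libs, ".", fixed = TRUE))
  insertion_count_table(m, meta[, 1L], as.integer(meta[, 2L]))
}

#' Library-size normalize insertion counts to reads per million
#'
#' @param table An `insertion_count_table`.
#' @return The table with a `normalized` matrix (counts per million) added.
#' @export
normalize_insertion_counts <- function(table) {
  stopifnot(inherits(table, "insertion_count_table"))
  if (any(table$library_sizes <= 0)) stop("zero library size")
  table$normalized <- sweep(table$counts, 2L, table$library_sizes, "/") * 1e6
  table
}

#' Per-gene enrichment of insertion mutants after phage challenge
#'
#' For each gene, the log2 fold change of mean normalized (per-million)
#' insertion abundance in the infected libraries over the uninfected
#' controls, with a pseudocount in per-million units; a two-sided test of
#' equal insertion proportions on pooled counts versus pooled library sizes;
#' and Benjamini-Hochberg q-values over all genes.
#'
#' @param table An `insertion_count_table`.
#' @param pseudocount Pseudocount in per-million units added inside the logs
#'   (default 1).
#' @return Data.frame (`gene`, `mean_cpm_infected`, `mean_cpm_control`,
#'   `log2fc`, `p_value`, `q_value`) in input gene order.
#' @export
compute_enrichment <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "insertion_count_table"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (!any(table$condition == "infected") ||
      !any(table$condition == "control")) {
    stop("need at least one replicate per condition")
  }
  table <- normalize_insertion_counts(table)
  inf <- table$condition == "infected"
  m_inf <- rowMeans(table$normalized[, inf, drop = FALSE])
  m_ctl <- rowMeans(table$normalized[, !inf, drop = FALSE])
  l2fc <- log2(m_inf + pseudocount) - log2(m_ctl + pseudocount)

  pooled_inf <- rowSums(table$counts[, inf, drop = FALSE])
  pooled_ctl <- rowSums(table$counts[, !inf, drop = FALSE])
  L_inf <- sum(table$library_sizes[inf])
  L_ctl <- sum(table$library_sizes[!inf])
  p <- vapply(seq_along(m_inf), function(i) {
    if (pooled_inf[i] + pooled_ctl[i] == 0) return(1)
    suppressWarnings(stats::prop.test(c(pooled_inf[i], pooled_ctl[i]),
                                      c(L_inf, L_ctl))$p.value)
  }, numeric(1))
  data.frame(gene = rownames(table$counts),
             mean_cpm_infected = m_inf, mean_cpm_control = m_ctl,
             log2fc = l2fc, p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
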