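write_gd_fixture <- function() {
  path <- tempfile(fileext = ".gd")
  writeLines(c(
    "#=GENOME_DIFF\t1.0",
    paste("SNP", "1", "10", "chr1", "12345", "A",
          "gene_name=rfaJ", "snp_type=nonsynonymous",
          "aa_position=198", "aa_ref_seq=A", "aa_new_seq=V", sep = "\t"),
    paste("SNP", "2", "11", "chr1", "22222", "T",
          "gene_name=pgm", "snp_type=nonsense", "frequency=0.095", sep = "\t"),
    paste("DEL", "3", "12", "chr1", "33333", "824",
          "gene_name=rfbU", sep = "\t"),
    paste("DEL", "4", "13", "chr1", "44444", "1",
          "gene_name=rfaG", sep = "\t"),
    paste("SNP", "5", "14", "chr1", "55555", "G",
          "gene_name=yjhB/yjhC", "snp_type=intergenic", sep = "\t"),
    paste("MOB", "6", "15", "chr1", "66666", "IS1", "1", "9",
          "gene_name=btuB", sep = "\t"),
    paste("RA", "7", ".", "chr1", "77777", "0", "A", "G", sep = "\t")
  ), path)
  path
}

test_that("genome-diff lines map onto the closed mutation vocabulary", {
  path <- write_gd_fixture()
  on.exit(unlink(path))
  recs <- read_variant_table(path, dialect = "gd", sample_id = "cl1")
  expect_equal(nrow(recs), 6)  # evidence (RA) line skipped

  rfaJ <- recs[recs$gene == "rfaJ", ]
  expect_equal(rfaJ$mutation_type, "missense")
  expect_equal(rfaJ$aa_change, "A198V")
  expect_equal(rfaJ$frequency, 1)

  pgm <- recs[recs$gene == "pgm", ]
  expect_equal(pgm$mutation_type, "nonsense")
  expect_equal(pgm$frequency, 0.095)

  expect_equal(recs$mutation_type[recs$gene == "rfbU"], "large_indel")
  expect_equal(recs$indel_len[recs$gene == "rfbU"], 824)
  expect_equal(recs$mutation_type[recs$gene == "rfaG"], "frameshift")
  expect_equal(recs$mutation_type[recs$gene == "yjhB/yjhC"], "intergenic")
  expect_equal(recs$mutation_type[recs$gene == "btuB"], "large_indel")
})

test_that("TSV dialect round-trips the flat columns", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  df <- data.frame(sample = "p1", timepoint = 1, gene = c("rfaJ", "glpK", "rfc"),
                   mutation_type = c("missense", "synonymous", "frameshift"),
                   nt_change = c("a", "b", "c"), aa_change = NA,
                   frequency = c(0.5, 1, 0.2), indel_len = c(NA, NA, 1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_variant_table(path, dialect = "tsv")
  expect_equal(recs$mutation_type, df$mutation_type)
  expect_equal(recs$frequency, df$frequency)
})

test_that("LOF filter keeps only the retained classes above the floor", {
  recs <- data.frame(
    sample_id = "s", timepoint = NA_real_,
    gene = c("a", "b", "c", "d", "e"),
    mutation_type = c("missense", "synonymous", "intergenic", "frameshift",
                      "nonsense"),
    nt_change = letters[1:5], aa_change = NA_character_,
    frequency = c(1, 1, 1, 0.04, 0.06), indel_len = NA_real_,
    stringsAsFactors = FALSE)
  out <- filter_lof_variants(recs, min_freq = 0.05)
  expect_equal(out$gene, c("a", "e"))  # synonymous/intergenic/0.04 dropped
  # subset of input, idempotent, empty-safe
  expect_true(all(out$nt_change %in% recs$nt_change))
  expect_equal(filter_lof_variants(out, min_freq = 0.05), out)
  expect_equal(nrow(filter_lof_variants(recs[0, ])), 0)
})

test_that("background subtraction matches on (gene, nt_change) only", {
  recs <- data.frame(gene = c("rfaJ", "rfaJ", "pgm"),
                     nt_change = c("x1", "x2", "y1"),
                     stringsAsFactors = FALSE)
  anc <- data.frame(gene = "rfaJ", nt_change = "x1", stringsAsFactors = FALSE)
  out <- subtract_background(recs, anc)
  expect_equal(out$nt_change, c("x2", "y1"))
  expect_equal(subtract_background(recs, anc[0, ]), recs)
})

test_that("receptor classes come from the map with rfaJ allele overrides", {
  recs <- data.frame(gene = c("rfbD", "btuB", "unknownX", "rfaJ", "rfaJ"),
                     aa_change = c(NA, NA, NA, "A198V", "F4L"),
                     stringsAsFactors = FALSE)
  out <- assign_receptor_class(recs)
  expect_equal(out$class, c("O-antigen-only", "BtuB", "other",
                            "core-only", "both-LPS"))
  expect_equal(out$group[1], "rfb-cluster")
  expect_equal(out$group[2], "btuB")
})

test_that("mutation spectrum counts the clone table's distinct genes", {
  path <- system.file("extdata", "receptor_mutations_clones.tsv",
                      package = "phageresist")
  recs <- filter_lof_variants(read_variant_table(path, dialect = "tsv"))
  sp <- mutation_spectrum(recs)
  expect_equal(unname(sp$distinct_genes["LPS"]), 14L)
  expect_equal(unname(sp$distinct_genes["BtuB"]), 1L)
  expect_true(all(sp$by_gene$n_genes <= sp$by_gene$n_records))
  # three records in one gene deduplicate to one distinct gene
  rfaI <- sp$by_gene[sp$by_gene$gene == "rfaI", ]
  expect_equal(rfaI$n_records, 3L)
  expect_equal(rfaI$n_genes, 1L)
  # empty input gives all-zero tables
  sp0 <- mutation_spectrum(recs[0, ])
  expect_equal(unname(sp0$distinct_genes), c(0L, 0L, 0L))
})

test_that("trajectory aggregation applies the allele-combine rules", {
  recs <- data.frame(
    sample_id = "r1", timepoint = c(1, 1, 3),
    gene = c("rfaJ", "rfaJ", "rfaJ"),
    mutation_type = "missense",
    nt_change = c("al1", "al2", "al1"), aa_change = NA_character_,
    frequency = c(0.4, 0.5, 0.9), indel_len = NA_real_,
    stringsAsFactors = FALSE)
  tmax <- build_trajectories(recs, aggregate = "gene", combine = "max")
  tsum <- build_trajectories(recs, aggregate = "gene", combine = "sum_capped")
  day1 <- function(tr) tr$frequency[tr$timepoint == 1]
  expect_equal(day1(tmax), 0.5)
  expect_equal(day1(tsum), 0.9)
  # frequencies in [0,1] under both rules; missing timepoints filled with 0
  expect_true(all(tmax$frequency >= 0 & tmax$frequency <= 1))
  expect_true(all(tsum$frequency >= 0 & tsum$frequency <= 1))
  big <- recs; big$frequency <- c(0.7, 0.8, 1.0)
  expect_true(all(build_trajectories(big, combine = "sum_capped")$frequency <= 1))
})

test_that("single-allele trajectories pass through unchanged", {
  recs <- data.frame(
    sample_id = "r1", timepoint = c(1, 2, 3), gene = "btuB",
    mutation_type = "frameshift", nt_change = "a", aa_change = NA_character_,
    frequency = c(0.1, 0.9, 1.0), indel_len = 1, stringsAsFactors = FALSE)
  tr <- build_trajectories(recs, aggregate = "gene")
  expect_equal(tr$frequency[order(tr$timepoint)], c(0.1, 0.9, 1.0))
})

test_that("acquisition ordering reports first passages and ties", {
  mk_traj <- function(freqs_by_key) {
    rows <- do.call(rbind, lapply(names(freqs_by_key), function(k) {
      data.frame(sample_id = "r1", timepoint = c(1, 3, 5),
                 gene = k, mutation_type = "frameshift",
                 nt_change = paste0(k, "_a"), aa_change = NA_character_,
                 frequency = freqs_by_key[[k]], indel_len = 1,
                 stringsAsFactors = FALSE)
    }))
    build_trajectories(rows, aggregate = "gene")
  }
  ord <- detect_sequential_acquisition(
    mk_traj(list(rfaJ = c(0.6, 1, 1), btuB = c(0, 0.2, 0.8))))
  expect_equal(ord$key, c("rfaJ", "btuB"))
  expect_equal(ord$first_passage, c(1, 5))
  expect_false(any(ord$tie))

  tie <- detect_sequential_acquisition(
    mk_traj(list(rfaJ = c(0, 0.6, 1), btuB = c(0, 0.7, 1))))
  expect_true(all(tie$tie))

  never <- detect_sequential_acquisition(
    mk_traj(list(rfaJ = c(0.1, 0.2, 0.3))))
  expect_equal(nrow(never), 0)
})

test_that("staggered sweeps are ordered correctly across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed)
    recs <- gen_variant_timeseries(cfg)
    traj <- build_trajectories(recs, aggregate = "category")
    ord <- detect_sequential_acquisition(traj, threshold = 0.5)
    lps_first <- nrow(ord) == 2 && ord$key[1] == "LPS" && !ord$tie[1]
    hits <- hits + as.integer(isTRUE(lps_first))
  }
  expect_gte(hits, 19L)
})

test_that("recovered sweep trajectories track the generating logistic", {
  cfg <- sim_config(seed = 77, sweep = list(depth = 400L))
  recs <- gen_variant_timeseries(cfg)
  traj <- build_trajectories(recs, aggregate = "category")
  sw <- cfg$sweep$classes$LPS
  tps <- attr(traj, "timepoints")
  f_true <- ifelse(tps < sw$onset, 0,
                   sw$f0 * exp(sw$s * (tps - sw$onset)) /
                     (1 + sw$f0 * (exp(sw$s * (tps - sw$onset)) - 1)))
  lps <- traj[traj$key == "LPS", ]
  obs <- tapply(lps$frequency, lps$timepoint, mean)[as.character(tps)]
  tol <- 3 * sqrt(f_true * (1 - f_true) / 400 / 3) + 1e-9
  expect_true(all(abs(obs - f_true) <= tol + 0.02))
})
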