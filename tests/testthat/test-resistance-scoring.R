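test_that("RBG endpoints have the intended semantics", {
  expect_equal(as.numeric(compute_rbg(0.05, 0.85, 0.05, 0.85)), 1.0)
  expect_equal(as.numeric(compute_rbg(0.05, 0.05, 0.05, 0.85)), 0.0)
  expect_equal(as.numeric(compute_rbg(0.10, 0.45, 0.10, 0.80)), 0.5)
  # negative numerator clamps to 0 with a flag; >1 preserved
  r <- compute_rbg(0.10, 0.05, 0.05, 0.85)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))
  expect_gt(as.numeric(compute_rbg(0.05, 0.95, 0.05, 0.85)), 1)
  expect_error(compute_rbg(0.05, 0.85, 0.85, 0.85), "non-positive")
})

test_that("RBG is invariant to scaling both growth deltas", {
  for (c_scale in c(0.5, 2, 10)) {
    base <- as.numeric(compute_rbg(0.05, 0.45, 0.05, 0.85))
    scaled <- as.numeric(compute_rbg(0.05, 0.05 + 0.40 * c_scale,
                                     0.05, 0.05 + 0.80 * c_scale))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("RBG matrix averages replicates and records absent cells as NA", {
  m <- make_planted_measurements(
    strains = c("s1", "s1", "s2", "s2"),
    selecting_phage = c("P1", "P1", "P2", "P2"),
    focal_phage = c("P1", "P2", "P1", "P2"),
    resistant = c(TRUE, FALSE, FALSE, TRUE), seed = 4)
  mat <- build_rbg_matrix(m)
  expect_equal(dim(mat$values), c(2L, 2L))
  s1p1 <- m[m$strain == "s1" & m$focal_phage == "P1", ]
  expect_equal(mat$values["s1", "P1"],
               mean((s1p1$a8_phage - s1p1$a0_phage) /
                      (s1p1$a8_ctrl - s1p1$a0_ctrl)))

  m_missing <- m[!(m$strain == "s2" & m$focal_phage == "P1"), ]
  mat2 <- build_rbg_matrix(m_missing)
  expect_true(is.na(mat2$values["s2", "P1"]))

  dup <- rbind(m, m[1, ])
  expect_error(build_rbg_matrix(dup), "duplicate")
})

test_that("matrix cell means recover generating values within noise", {
  cfg <- sim_config(seed = 17)
  panel <- gen_interaction_rbg(cfg)
  mat <- build_rbg_matrix(panel$measurements, panel$receptor_map)
  truth_res <- panel$truth$resistant[match(
    paste(rownames(mat$values)[row(mat$values)],
          colnames(mat$values)[col(mat$values)]),
    paste(panel$truth$strain, panel$truth$phage))]
  # Beta(mode 0.977 / 0.034, conc 52) means, absorbance noise ~0.005/0.8
  mu_res <- (0.977 * 50 + 1) / 52
  mu_sen <- (0.034 * 50 + 1) / 52
  means <- as.vector(mat$values)
  expect_lt(max(abs(means[truth_res] - mu_res)), 0.15)
  expect_lt(max(abs(means[!truth_res] - mu_sen)), 0.15)
  expect_lt(abs(mean(means[truth_res]) - mu_res), 0.01)
})

test_that("classification respects the published boundary semantics", {
  bounds <- c(0.49, 0.53)
  expect_equal(as.character(classify_resistance(0.49, bounds)), "sensitive")
  expect_equal(as.character(classify_resistance(0.51, bounds)), "intermediate")
  expect_equal(as.character(classify_resistance(0.53, bounds)), "resistant")
  # monotone non-decreasing in rbg
  x <- seq(0, 1.2, 0.01)
  cls <- classify_resistance(x, bounds)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("calibration finds two modes, a valley between them, and a CI", {
  set.seed(42)
  x <- c(rbeta(720, 2, 50), rbeta(720, 50, 2))
  cal <- rbg_calibrate(x, n_boot = 200, seed = 9)
  expect_s3_class(cal, "rbg_calibration")
  expect_lt(cal$peak_low, 0.15)
  expect_gt(cal$peak_high, 0.85)
  expect_true(cal$peak_low < cal$valley && cal$valley < cal$peak_high)
  expect_true(cal$ci_low <= cal$valley && cal$valley <= cal$ci_high)
  expect_lte(cal$class_bounds[1], cal$class_bounds[2])
  # dense-grid argmin oracle agrees to within the 512-grid spacing
  dense <- valley_dense_oracle(x, cal$bandwidth, cal$peak_low, cal$peak_high)
  expect_lt(abs(cal$valley - dense), diff(range(x)) / 511)
  # classes via predict
  expect_equal(as.character(predict(cal, c(0, 1))),
               c("sensitive", "resistant"))
})

test_that("calibration refuses unimodal samples", {
  set.seed(1)
  x <- abs(rnorm(200, 0.9, 0.02))  # everything near 0.9: one mode
  expect_error(rbg_calibrate(x, n_boot = 10, seed = 1), "bimodal|modes")
})

test_that("valley lies between the generating modes for every seed", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rbeta(400, 2, 50), rbeta(400, 50, 2))
    cal <- rbg_calibrate(x, n_boot = 0L, seed = seed)
    expect_gt(cal$valley, 0.034)
    expect_lt(cal$valley, 0.977)
  }
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- sapply(1:20, function(seed) {
    w <- sapply(c(200, 2000), function(n) {
      set.seed(seed)
      x <- c(rbeta(n / 2, 2, 50), rbeta(n / 2, 50, 2))
      cal <- rbg_calibrate(x, n_boot = 100, seed = seed)
      cal$ci_high - cal$ci_low
    })
    w
  })
  expect_lt(median(widths[2, ]), median(widths[1, ]))
})

test_that("cross-resistance tabulation reproduces planted group counts", {
  # 76 core-selected focal-resistant strains, 34 also resistant to the
  # O-antigen phage; 37 O-selected focal-resistant, 8 also core-resistant
  n_core <- 76; n_o <- 37
  strains <- c(sprintf("c%02d", 1:n_core), sprintf("o%02d", 1:n_o))
  sel <- c(rep("P1", n_core), rep("P5", n_o))
  rows <- list()
  for (i in seq_along(strains)) {
    cross <- if (startsWith(strains[i], "c")) i <= 34 else i - n_core <= 8
    focal <- sel[i]
    other <- if (focal == "P1") "P5" else "P1"
    rows[[i]] <- make_planted_measurements(
      strains = c(strains[i], strains[i]),
      selecting_phage = c(focal, focal),
      focal_phage = c(focal, other),
      resistant = c(TRUE, cross), seed = i)
  }
  mat <- build_rbg_matrix(do.call(rbind, rows),
                          receptor_map = c(P1 = "core", P5 = "O-antigen"))
  tab <- cross_resistance_summary(mat, c(0.49, 0.53))
  co <- tab[tab$from_group == "core" & tab$to_group == "O-antigen", ]
  oc <- tab[tab$from_group == "O-antigen" & tab$to_group == "core", ]
  expect_equal(co$numerator, 34); expect_equal(co$denominator, 76)
  expect_equal(co$percent, 44.7)
  expect_equal(oc$numerator, 8); expect_equal(oc$denominator, 37)
  expect_equal(oc$percent, 21.6)
  expect_true(all(tab$numerator <= tab$denominator))
  expect_true(all(tab$percent >= 0 & tab$percent <= 100, na.rm = TRUE))
})

test_that("cross-resistance saturates at 100 and empties at 0", {
  m <- make_planted_measurements(
    strains = rep(c("a", "b"), each = 2),
    selecting_phage = rep(c("P1", "P5"), each = 2),
    focal_phage = rep(c("P1", "P5"), 2),
    resistant = rep(TRUE, 4), seed = 2)
  rmap <- c(P1 = "core", P5 = "O-antigen")
  tab <- cross_resistance_summary(build_rbg_matrix(m, rmap), c(0.49, 0.53))
  expect_true(all(tab$percent == 100))

  m$a8_phage[m$focal_phage != m$selecting_phage] <- 0.05  # no cross growth
  tab0 <- cross_resistance_summary(build_rbg_matrix(m, rmap), c(0.49, 0.53))
  expect_true(all(tab0$percent == 0))
})

test_that("clustering groups identical rows and is permutation-invariant", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  fake <- structure(list(values = m, selecting_phage = NULL,
                         receptor_of_phage = NULL), class = "rbg_matrix")
  cl <- cluster_rbg_matrix(fake)
  pos <- match(c("a", "b"), cl$labels)
  expect_equal(abs(diff(pos)), 1)
  expect_true(grepl("^\\(", cl$newick))

  perm <- c(3, 1, 2)
  fake2 <- structure(list(values = m[perm, ], selecting_phage = NULL,
                          receptor_of_phage = NULL), class = "rbg_matrix")
  cl2 <- cluster_rbg_matrix(fake2)
  c1 <- as.matrix(stats::cophenetic(cl$hclust))
  c2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(c1[c("a", "b"), c("a", "c")], c2[c("a", "b"), c("a", "c")])
})

test_that("clustering recovers planted resistance archetypes", {
  set.seed(5)
  blocks <- rep(1:3, each = 6)
  arch <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0))
  v <- arch[blocks, ] + matrix(rnorm(18 * 4, 0, 0.05), 18, 4)
  rownames(v) <- sprintf("s%02d", 1:18)
  colnames(v) <- sprintf("P%d", 1:4)
  fake <- structure(list(values = v, selecting_phage = NULL,
                         receptor_of_phage = NULL), class = "rbg_matrix")
  cl <- cluster_rbg_matrix(fake)
  ord_blocks <- blocks[cl$order]
  expect_equal(sum(diff(ord_blocks) != 0), 2)  # contiguous blocks
})
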