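test_that("IBS identity and symmetry hold on random series", {
  set.seed(3)
  for (rep in 1:200) {
    m <- sample(1:2, 1)
    n <- sample((m + 2^m):30, 1)
    x <- random_series(n)
    y <- random_series(n)
    expect_identical(ibs_distance(x, x, m), 0)
    expect_equal(ibs_distance(x, y, m), ibs_distance(y, x, m), tolerance = 1e-14)
    d <- ibs_distance(x, y, m)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("IBS equals the brute-force oracle on 3-letter-alphabet series", {
  set.seed(4)
  # exhaustive over all pairs of length-4 series, m = 1
  s3 <- expand.grid(rep(list(1:3), 4))
  series <- lapply(seq_len(nrow(s3)), function(i) as.numeric(s3[i, ]))
  idx <- sample(length(series), 25)
  for (i in idx) {
    for (j in sample(length(series), 12)) {
      expect_equal(
        ibs_distance(series[[i]], series[[j]], 1),
        oracle_ibs(series[[i]], series[[j]], 1),
        tolerance = 1e-12
      )
    }
  }
  # random sample over lengths 6..12, m = 2
  for (rep in 1:300) {
    n <- sample(6:12, 1)
    x <- random_series(n, alphabet = 1:3)
    y <- random_series(n, alphabet = 1:3)
    expect_equal(ibs_distance(x, y, 2), oracle_ibs(x, y, 2), tolerance = 1e-12)
  }
})

test_that("alternating-vs-increasing distance matches exhaustive word counting", {
  x <- rep(c(1, 3), 6)[1:10] # strictly alternating
  y <- 1:10 # strictly increasing
  expect_equal(ibs_distance(x, y, 2), oracle_ibs(x, y, 2), tolerance = 1e-12)
  # hand enumeration: x increments 101010101 -> words 10,01 (4,4 of 8), ranks (3.5,1.5,1.5,3.5)
  # y increments all 1 -> word 11 (8 of 8), ranks (3,3,3,1)
  px <- c(0, 4, 4, 0) / 8
  py <- c(0, 0, 0, 8) / 8
  rx <- c(3.5, 1.5, 1.5, 3.5)
  ry <- c(3, 3, 3, 1)
  d_hand <- sum(abs(rx - ry) * (px + py) / 2) / 3
  expect_equal(ibs_distance(x, y, 2), d_hand, tolerance = 1e-12)
})

test_that("IBS is invariant under strictly monotone transforms", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    x <- random_series(n)
    y <- random_series(n)
    d <- ibs_distance(x, y, 2)
    expect_equal(ibs_distance(exp(3 * x), y, 2), d, tolerance = 1e-14)
    expect_equal(ibs_distance(x, rank(y), 2), d, tolerance = 1e-14)
    expect_equal(ibs_distance(x^3 + x, exp(y), 2), d, tolerance = 1e-14)
  }
})

test_that("IBS rejects inadmissible inputs", {
  expect_error(ibs_distance(1:10, 1:9, 2), "lengths")
  expect_error(ibs_distance(1:5, 5:1, 2), "too short")
  expect_error(ibs_distance(1:10, 10:1, 0), "positive integer")
  expect_error(ibs_config(word_length = 0), "word_length")
  expect_error(ibs_config(alpha = 2), "alpha")
})

test_that("permutation p equals the minimal attainable value for a shared pattern", {
  # monotone series: the probability that a permutation reproduces the
  # observed zero distance is ~1/n!, so the +1 pseudo-count is exact
  v <- rbind(x = (1:40) + 0, y = (1:40)^2)
  colnames(v) <- sprintf("s%02d", 1:40)
  em <- expression_matrix(v + 0.5)
  tab <- permutation_threshold(em, "x", ibs_config(n_permutations = 199, seed = 4))
  expect_equal(tab$ibs_distance, 0)
  expect_equal(tab$p_value, 1 / 200)
})

test_that("permutation p is approximately uniform under independence", {
  set.seed(20)
  ps <- replicate(100, {
    n <- 60
    v <- rbind(x = rexp(n), y = rnorm(n))
    colnames(v) <- sprintf("s%02d", 1:n)
    em <- expression_matrix(abs(v) + 0.01)
    permutation_threshold(
      em, "x",
      ibs_config(word_length = 2, n_permutations = 200, seed = sample.int(1e6, 1))
    )$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted pairs reach small permutation p at moderate noise", {
  wins <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(
      n_targets_per_tf = 1, n_background = 5,
      n_tumor = 50, n_control = 50, noise_sd = 0.05, seed = 1000 + r
    )
    sim <- simulate_expression(cfg)
    em <- sim$matrix[, sim$truth$progression_order]
    tab <- permutation_threshold(
      em, "MNDA",
      ibs_config(word_length = 2, n_permutations = 200, seed = r)
    )
    p_tg <- tab$p_value[tab$gene_a == "MNDA" & tab$gene_b == "MNDA.t01"]
    if (p_tg < 0.05) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("empty core and missing genes are rejected", {
  v <- matrix(1:20 + 0.5, 2, dimnames = list(c("a", "b"), sprintf("s%d", 1:10)))
  em <- expression_matrix(v)
  expect_error(permutation_threshold(em, character(0)), "empty core")
  expect_error(permutation_threshold(em, "zz"), "missing")
  expect_error(
    permutation_threshold(em, "a", ibs_config(word_length = 4)),
    "too few samples"
  )
})

test_that("network building respects alpha and annotates edges by precedence", {
  cfg <- synthetic_config(
    n_targets_per_tf = 2, n_background = 10,
    n_tumor = 30, n_control = 30, seed = 16
  )
  sim <- simulate_expression(cfg)
  em <- sim$matrix[, sim$truth$progression_order]
  ann <- make_annotations(cfg)
  cfg0 <- ibs_config(n_permutations = 100, alpha = 0, seed = 2)
  expect_equal(nrow(build_network(em, "MNDA", ann, cfg0)), 0)
  cfg1 <- ibs_config(n_permutations = 200, alpha = 0.05, seed = 2)
  net <- build_network(em, core_params()$gene_id, ann, cfg1)
  expect_s3_class(net, "edge_table")
  expect_true(all(net$gene_a < net$gene_b))
  expect_true(all(net$annotation_class %in%
    c("breast_cancer", "other_cancer", "metabolic", "other")))
  # core genes are breast-cancer annotated, so every core edge carries the
  # highest-precedence class
  expect_true(all(net$annotation_class[net$gene_a %in% core_params()$gene_id &
    net$gene_b %in% core_params()$gene_id] == "breast_cancer"))
})

test_that("edge selection at stricter alpha is a subset of looser alpha", {
  cfg <- synthetic_config(
    n_targets_per_tf = 2, n_background = 15,
    n_tumor = 25, n_control = 25, seed = 17
  )
  sim <- simulate_expression(cfg)
  em <- sim$matrix[, sim$truth$progression_order]
  ann <- make_annotations(cfg)
  core <- core_params()$gene_id
  strict <- build_network(em, core, ann, ibs_config(n_permutations = 150, alpha = 0.01, seed = 5))
  loose <- build_network(em, core, ann, ibs_config(n_permutations = 150, alpha = 0.2, seed = 5))
  expect_true(all(
    paste(strict$gene_a, strict$gene_b) %in% paste(loose$gene_a, loose$gene_b)
  ))
})

test_that("a target wired to two regulators yields both edges", {
  # co-regulation: construct a small matrix where gene "shared" follows the
  # same program as both MNDA and SMAD3 (identical series)
  set.seed(18)
  n <- 60
  base <- cumsum(c(0, rep(c(1, 1, 1, -1, -1, -1), length.out = n - 1))) + rnorm(n, 0, 0.02)
  v <- rbind(
    MNDA = 2^base, SMAD3 = 2^(base + 0.3), shared = 2^(2 * base),
    noise1 = rexp(n) + 0.1, noise2 = rexp(n) + 0.1
  )
  colnames(v) <- sprintf("s%02d", 1:n)
  em <- expression_matrix(v)
  ann <- annotation_table(data.frame(
    gene_id = rownames(v), is_tf = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    cancer_score = c(2L, 2L, 0L, 0L, 0L), is_metabolic = FALSE,
    has_thermo_params = FALSE
  ))
  net <- build_network(em, c("MNDA", "SMAD3"), ann, ibs_config(n_permutations = 300, seed = 6))
  keys <- paste(net$gene_a, net$gene_b)
  expect_true("MNDA shared" %in% keys)
  expect_true("SMAD3 shared" %in% keys)
})

test_that("degree summary counts degrees and shared partners", {
  edges <- data.frame(
    gene_a = c("A", "A", "B", "B", "A"),
    gene_b = c("x", "y", "x", "z", "B"),
    ibs_distance = 0.1, p_value = 0.001, q_value = 0.01,
    annotation_class = "other", stringsAsFactors = FALSE
  )
  class(edges) <- c("edge_table", "data.frame")
  ds <- degree_summary(edges, c("A", "B"))
  expect_equal(unname(ds$degree), c(3L, 3L))
  expect_equal(ds$co_regulation$shared, 1L) # only "x" shared, "B" is core
  # empty table gives all zeros
  ds0 <- degree_summary(edges[0, ], c("A", "B"))
  expect_equal(unname(ds0$degree), c(0L, 0L))
  expect_equal(ds0$co_regulation$shared, 0L)
})

test_that("planted out-degrees are recovered on an easy cohort", {
  cfg <- synthetic_config(
    n_targets_per_tf = 3, n_background = 10,
    n_tumor = 40, n_control = 40, noise_sd = 0.03, seed = 19
  )
  sim <- simulate_expression(cfg)
  em <- sim$matrix[, sim$truth$progression_order]
  ann <- make_annotations(cfg)
  core <- core_params()$gene_id
  net <- build_network(em, core, ann, ibs_config(
    word_length = 4,
    n_permutations = 400, seed = 7
  ))
  non_core <- net[!(net$gene_a %in% core & net$gene_b %in% core), ]
  ds <- degree_summary(non_core, core)
  expect_equal(unname(ds$degree[core]), rep(3L, 4))
})

test_that("network exports are loadable", {
  edges <- data.frame(
    gene_a = c("A", "B"), gene_b = c("x", "y"),
    ibs_distance = c(0.1, 0.2), p_value = c(0.001, 0.002),
    q_value = c(0.01, 0.02),
    annotation_class = c("breast_cancer", "other"), stringsAsFactors = FALSE
  )
  class(edges) <- c("edge_table", "data.frame")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(edges, sif)
  expect_equal(readLines(sif), c("A ibs x", "B ibs y"))
  attr_path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_attributes(edges, attr_path)
  expect_equal(nrow(read.delim(attr_path)), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(edges, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
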