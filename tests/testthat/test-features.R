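test_that("disease block: known associations are 1, others best-match Lin", {
  ont <- chain_ontology()
  ds <- mirna_dataset(list(
    mirna_record("m1", diseases = "b"),        # lin(b, c) = 0.5
    mirna_record("m2", diseases = c("b", "c")),
    mirna_record("m3")))                       # no associations
  md <- build_disease_matrix(ds, ont)
  V <- as.matrix(md$values)
  expect_equal(V["m1", "b"], 1)
  expect_equal(V["m1", "c"], 0.5)
  expect_equal(V["m2", c("b", "c")], c(b = 1, c = 1))
  expect_equal(unname(V["m3", ]), c(0, 0))
  expect_true(all(V >= 0 & V <= 1))

  # the sparsity floor drops small propagated values
  md2 <- build_disease_matrix(ds, ont, floor = 0.6)
  expect_equal(as.matrix(md2$values)["m1", "c"], 0)
  expect_equal(as.matrix(md2$values)["m1", "b"], 1)

  # mean aggregation is available and bounded by max
  mdm <- build_disease_matrix(ds, ont, aggregate = "mean")
  expect_true(all(as.matrix(mdm$values) <= V + 1e-12))
})

test_that("neighbor block follows the genomic-distance sigmoid", {
  p <- neighbor_params()
  # midpoint: exactly 0.5 for any steepness
  expect_identical(neighbor_weight(p$dist0, p), 0.5)
  expect_identical(neighbor_weight(1234, neighbor_params(dist0 = 1234, k = 1)),
                   0.5)
  # strict monotone decrease with distance
  d <- seq(0, 3e5, length.out = 50)
  expect_true(all(diff(neighbor_weight(d, p)) < 0))

  loc <- function(chrom, s, e)
    data.frame(chrom = chrom, strand = "+", start = s, end = e)
  ds <- mirna_dataset(list(
    mirna_record("m1", loc("chr1", 1000, 1100)),
    # gap to m1 = exactly dist0 bases between closest ends
    mirna_record("m2", loc("chr1", 1101 + p$dist0, 1200 + p$dist0)),
    mirna_record("m3", loc("chr1", 1050, 1500)),   # overlaps m1
    mirna_record("m4", loc("chr2", 1000, 1100)),   # other chromosome
    mirna_record("m5")))                           # no location
  expect_warning(mn <- build_neighbor_matrix(ds, p),
                 "without genomic location")
  V <- as.matrix(mn$values)
  expect_equal(V["m1", "m2"], 0.5)
  expect_equal(V["m1", "m3"], neighbor_weight(0, p))
  expect_gt(V["m1", "m3"], 0.99)
  expect_equal(V["m1", "m4"], 0)
  expect_equal(unname(V["m5", ]), rep(0, 5))
  expect_equal(unname(diag(V)), c(1, 1, 1, 1, 0))
  expect_true(isSymmetric(V))
})

test_that("multi-location miRNAs use the minimum gap over location pairs", {
  p <- neighbor_params()
  ds <- mirna_dataset(list(
    mirna_record("m1", data.frame(chrom = c("chr1", "chr3"),
                                  strand = "+",
                                  start = c(1000L, 900000L),
                                  end = c(1100L, 900100L))),
    mirna_record("m2", data.frame(chrom = c("chr1", "chr3"),
                                  strand = "+",
                                  start = c(500000L, 910101L),
                                  end = c(500100L, 910200L)))))
  # chr1 gap is huge; chr3 gap is 10 kb -> that one wins
  mn <- build_neighbor_matrix(ds, p)
  expect_equal(as.matrix(mn$values)["m1", "m2"],
               neighbor_weight(10000, p))
})

test_that("target projection reproduces the worked toy example", {
  res <- project_targets(fig3_fixture())
  # first step: b = alpha/2 + beta/3
  expect_equal(res$step1["b", "alpha"], 1 / 2)
  expect_equal(res$step1["b", "beta"], 1 / 3)
  # weight of alpha = 3/4 alpha + 1/6 beta; beta receives 1/4 from alpha
  expect_equal(res$W["alpha", "alpha"], 3 / 4)
  expect_equal(res$W["beta", "alpha"], 1 / 6)
  expect_equal(res$W["alpha", "beta"], 1 / 4)
  # existing edges keep positive weight; implied associations appear
  expect_gt(res$MT["a", "alpha"], 0)
  expect_gt(res$MT["a", "beta"], 0)      # new implied association
  expect_equal(sum(fig3_fixture()["a", ]), 1)

  # single edge degenerate case
  single <- project_targets(matrix(1, 1, 1))
  expect_equal(unname(single$W), matrix(1, 1, 1))
  expect_equal(unname(single$MT), matrix(1, 1, 1))
})

test_that("projection conserves resources and matches the diffusion oracle", {
  for (seed in 1:10) {
    M <- random_bipartite(sample(3:9, 1), sample(3:9, 1), 0.4, seed)
    res <- project_targets(M)
    expect_equal(unname(rowSums(res$W)), rep(1, ncol(M)), tolerance = 1e-12)
    expect_equal(res$W, oracle_diffusion(M), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(res$MT >= 0 & res$MT <= 1))
    expect_true(all(res$MT[M == 1] > 0))
  }
  expect_error(project_targets(matrix(2, 1, 1)), "binary")
})

test_that("word block is TF-IDF with L2-normalized rows", {
  ds <- mirna_dataset(list(
    mirna_record("m1", abstract_text = "apoptosis apoptosis pathway"),
    mirna_record("m2", abstract_text = "apoptosis cardiac"),
    mirna_record("m3", abstract_text = "")))
  mw <- build_word_matrix(ds)
  V <- as.matrix(mw$values)
  expect_equal(unname(V["m3", ]), rep(0, ncol(V)))
  norms <- sqrt(rowSums(V^2))
  expect_equal(unname(norms), c(1, 1, 0))
  # a word present in both documents has strictly smaller idf than a
  # document-specific one, visible after removing the tf difference
  m <- 3
  idf <- function(df) log((1 + m) / (1 + df)) + 1
  expect_lt(idf(2), idf(1))
  expect_equal(V["m2", "cardiac"] / V["m2", "apoptosis"], idf(1) / idf(2))

  # single miRNA, single word: normalized weight 1
  one <- build_word_matrix(mirna_dataset(list(
    mirna_record("m1", abstract_text = "apoptosis"))))
  expect_equal(as.numeric(one$values), 1)
})

test_that("family block is one-hot with zero rows for family-less miRNAs", {
  ds <- mirna_dataset(list(
    mirna_record("m1", family = "famX"),
    mirna_record("m2", family = "famX"),
    mirna_record("m3")))
  mf <- build_family_matrix(ds)
  V <- as.matrix(mf$values)
  expect_equal(unname(rowSums(V)), c(1, 1, 0))
  expect_equal(V["m1", ], V["m2", ])
})

test_that("concatenation is width-additive and validates row order", {
  env <- load_bundle_env(small_bundle(seed = 5))
  blocks <- list(build_disease_matrix(env$dataset, env$ontology),
                 build_neighbor_matrix(env$dataset),
                 build_target_matrix(env$dataset),
                 build_word_matrix(env$dataset),
                 build_family_matrix(env$dataset))
  cm <- concatenate_blocks(blocks)
  expect_equal(ncol(cm$X), sum(vapply(blocks, function(b) length(b$cols),
                                      integer(1))))
  expect_equal(unname(table(cm$col_blocks)[c("disease", "neighbor", "target",
                                             "word", "family")]),
               vapply(blocks, function(b) length(b$cols), integer(1)),
               ignore_attr = TRUE)
  # single block passes through
  cm1 <- concatenate_blocks(blocks[1])
  expect_equal(cm1$X, blocks[[1]]$values, ignore_attr = TRUE)
  # permuted rows in one block are rejected with the first differing row
  bad <- blocks[[5]]
  perm <- c(2, 1, seq_along(bad$rows)[-(1:2)])
  bad2 <- feature_matrix(bad$values[perm, ], bad$rows[perm], bad$cols,
                         "family")
  expect_error(concatenate_blocks(list(blocks[[1]], bad2)),
               "row ordering mismatch.*row 1")
  # MN block symmetry on generated data
  expect_true(Matrix::isSymmetric(blocks[[2]]$values, tol = 0))
})
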