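test_that("fold assignment is stratified, balanced and seed-deterministic", {
  mirnas <- sprintf("m%03d", 1:100)
  positives <- mirnas[1:20]
  f <- make_folds(mirnas, positives, n_folds = 5, seed = 3)
  expect_setequal(names(f), mirnas)
  for (k in 1:5) {
    expect_equal(sum(f[positives] == k), 4)
    expect_equal(sum(f[setdiff(mirnas, positives)] == k), 16)
  }
  expect_identical(make_folds(mirnas, positives, seed = 3), f)
  # different seeds give different partitions (checked over 10 seeds)
  alt <- vapply(1:10, function(s)
    identical(make_folds(mirnas, positives, seed = 100 + s), f), logical(1))
  expect_false(any(alt))
  # unbalanced strata still differ by at most one in total fold size
  f2 <- make_folds(mirnas, mirnas[1:22], n_folds = 5, seed = 1)
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(make_folds(mirnas, mirnas[1:3], n_folds = 5),
               "at least 20 miRNAs")
})

test_that("ROC/AUC matches hand counts and the concordance oracle", {
  # perfect separation
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # hand-counted example: 3 concordant pairs of 4
  expect_equal(roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "positive and one negative")
  # curve endpoints
  pts <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))

  # ties: grouped into a single sweep step, AUC = Mann-Whitney with 1/2
  for (seed in 1:10) {
    sl <- with_seed_test(seed, {
      n <- sample(5:40, 1)
      list(s = sample(seq(0, 1, 0.1), n, replace = TRUE),
           l = c(1, 0, rbinom(n - 2, 1, 0.5)))
    })
    expect_equal(roc_curve(sl$s, sl$l)$auc, oracle_auc(sl$s, sl$l),
                 tolerance = 1e-12)
  }

  # label-independent scores: AUC near 1/2
  big <- with_seed_test(99, list(s = runif(4000), l = rbinom(4000, 1, 0.4)))
  expect_lt(abs(roc_curve(big$s, big$l)$auc - 0.5), 0.05)
})

test_that("flagging uses strict rank-fraction thresholds", {
  mk <- function(ids, scores) {
    # build a ranked list directly from scores
    o <- order(-scores, ids)
    df <- data.frame(rank = seq_along(ids), mirna = ids[o],
                     score = scores[o], stringsAsFactors = FALSE)
    attr(df, "disease") <- "d"
    class(df) <- c("ranked_list", class(df))
    df
  }
  negs <- sprintf("n%03d", 1:100)
  # positive ranked below all 100 negatives: fraction 1, flagged
  r1 <- mk(c(negs, "pos1"), c(seq(1, 0.01, length.out = 100), 0.001))
  ff <- flag_putative_false(r1, "pos1")
  expect_equal(ff$mirna, "pos1")
  expect_equal(ff$fraction, 1)
  # positive ranked first: not flagged
  r2 <- mk(c("pos1", negs), c(2, seq(1, 0.01, length.out = 100)))
  expect_equal(nrow(flag_putative_false(r2, "pos1")), 0)
  # boundary: exactly 85 of 100 negatives above -> strict, not flagged;
  # 86 above -> flagged
  scores <- c(seq(2, 1.1, length.out = 85), 1.0, seq(0.9, 0.1, length.out = 15))
  r3 <- mk(c(negs[1:85], "pos1", negs[86:100]), scores)
  expect_equal(nrow(flag_putative_false(r3, "pos1")), 0)
  r4 <- mk(c(negs[1:86], "pos1", negs[87:100]),
           c(seq(2, 1.1, length.out = 86), 1.0, seq(0.9, 0.1, length.out = 14)))
  expect_equal(flag_putative_false(r4, "pos1")$fraction, 0.86)

  pos <- sprintf("p%03d", 1:100)
  # negative above all positives: fraction 1, flagged
  n1 <- mk(c("cand", pos), c(2, seq(1, 0.01, length.out = 100)))
  fn <- flag_novel(n1, pos)
  expect_equal(fn$mirna, "cand")
  expect_equal(fn$fraction, 1)
  # negative ranked last: not flagged
  n2 <- mk(c(pos, "cand"), c(seq(1, 0.01, length.out = 100), 0.001))
  expect_equal(nrow(flag_novel(n2, pos)), 0)
  # boundary at exactly 0.85: strict, not flagged
  n3 <- mk(c(pos[1:15], "cand", pos[16:100]),
           c(seq(2, 1.2, length.out = 15), 1.1, seq(1, 0.01, length.out = 85)))
  expect_equal(nrow(flag_novel(n3, pos)), 0)

  # monotone in the threshold: raising it never enlarges a flag list
  for (seed in 1:5) {
    sl <- with_seed_test(seed, list(ids = sprintf("x%02d", 1:40),
                                    s = runif(40),
                                    p = sample(sprintf("x%02d", 1:40), 12)))
    r <- mk(sl$ids, sl$s)
    for (th in c(0.5, 0.7, 0.85)) {
      expect_lte(nrow(flag_putative_false(r, sl$p, th + 0.1)),
                 nrow(flag_putative_false(r, sl$p, th)))
      expect_lte(nrow(flag_novel(r, sl$p, th + 0.1)),
                 nrow(flag_novel(r, sl$p, th)))
    }
  }
})

test_that("fold refits remove the held-out information", {
  env <- load_bundle_env(small_bundle(seed = 21))
  ctx <- cv_context(env$dataset, env$ontology)
  d <- env$dataset$diseases[1]
  ids <- names(env$dataset$mirnas)
  positives <- ids[vapply(env$dataset$mirnas,
                          function(r) d %in% r$diseases, logical(1))]
  folds <- make_folds(ids, positives, n_folds = 5, seed = 2)
  sc <- run_fold(ctx, d, folds, 1)
  expect_setequal(names(sc), names(folds)[folds == 1])
  # held-out positives lose their direct association: scores drop
  # relative to the full-data model
  full <- ls_query(ctx$full_fit, d)
  full_sc <- structure(full$score, names = full$mirna)
  held_pos <- intersect(names(sc), positives)
  expect_true(mean(sc[held_pos] < full_sc[held_pos]) > 0.8)

  # a miRNA whose only signal for d was the association + its abstract
  # scores near zero once both are removed
  ont <- chain_ontology()
  toy <- mirna_dataset(list(
    mirna_record("t1", diseases = "b", abstract_text = "alpha beta gamma"),
    mirna_record("t2", diseases = "b", abstract_text = "alpha beta"),
    mirna_record("t3", diseases = "b", abstract_text = "alpha gamma"),
    mirna_record("t4", diseases = "b", abstract_text = "beta gamma"),
    mirna_record("t5", diseases = "b", abstract_text = "alpha"),
    mirna_record("t6", diseases = "d", abstract_text = "delta")))
  tctx <- suppressWarnings(cv_context(toy, ont))  # toy records lack locations
  tf <- make_folds(names(toy$mirnas), paste0("t", 1:5), n_folds = 5, seed = 1)
  k <- tf[["t1"]]
  sc1 <- run_fold(tctx, "b", tf, k)
  expect_lt(abs(sc1[["t1"]]), 0.35)
})

test_that("cross-validation is deterministic and self-consistent", {
  env <- load_bundle_env(small_bundle(seed = 21))
  ctx <- cv_context(env$dataset, env$ontology)
  d <- env$dataset$diseases[2]
  cv1 <- run_cv(ctx, d, seed = 11)
  cv2 <- run_cv(ctx, d, seed = 11)
  expect_equal(cv1$fold_auc, cv2$fold_auc)
  expect_identical(cv1$ranking$mirna, cv2$ranking$mirna)
  expect_equal(cv1$auc, mean(cv1$fold_auc))
  expect_true(all(cv1$fold_auc >= 0 & cv1$fold_auc <= 1))
  # folds partition the miRNAs
  expect_setequal(names(cv1$folds), names(env$dataset$mirnas))
  # every miRNA appears exactly once in the flag ranking
  expect_setequal(cv1$ranking$mirna, names(env$dataset$mirnas))
  expect_true(all(diff(cv1$ranking$score) <= 0))
})
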