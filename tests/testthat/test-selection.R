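test_that("stratified folds partition indices with balanced class counts", {
  y <- rep(c("a", "b"), c(10, 5))
  folds <- stratified_folds(y, 5, seed = 0)
  expect_equal(sort(unlist(folds)), 1:15)
  for (f in folds) {
    expect_equal(sum(y[f] == "a"), 2)
    expect_equal(sum(y[f] == "b"), 1)
  }
  # pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  # determinism contract
  expect_identical(stratified_folds(y, 5, seed = 3),
                   stratified_folds(y, 5, seed = 3))
  expect_false(identical(stratified_folds(y, 5, seed = 3),
                         stratified_folds(y, 5, seed = 4)))
  expect_error(stratified_folds(rep(c("a", "b"), c(10, 3)), 5),
               "fewer members")
})

test_that("fold class proportions stay within one sample of global", {
  set.seed(77)
  y <- sample(c("a", "b", "c", "d"), 83, replace = TRUE,
              prob = c(0.5, 0.25, 0.15, 0.10))
  y <- c(y, rep(c("a", "b", "c", "d"), 5))  # ensure >= k members each
  folds <- stratified_folds(y, 5, seed = 1)
  for (cl in unique(y)) {
    per_fold <- vapply(folds, function(f) sum(y[f] == cl), numeric(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("inner search returns the grid maximiser with first-wins ties", {
  d <- make_two_block_data(n_per_class = c(x = 20, y = 20),
                           dims = c(INF = 10), delta = 3, seed = 2)
  cfg <- dcv_config(inner_folds = 3, seed = 0)
  # single grid point: returned as-is with its inner mean
  spec1 <- classifier_spec("SVM", grid = list(cost = 1, kernel = "linear"),
                           class_weights = "uniform")
  res1 <- inner_search(d$mats$INF, d$y, spec1, cfg, seed = 0)
  expect_equal(res1$hyper$cost, 1)
  expect_equal(res1$n_evaluated, 1L)
  expect_true(res1$score > 0.7)   # well above the 0.5 chance level

  # planted contrast: an absurdly tiny cost cannot learn, cost 1 can;
  # exhaustive evaluation oracle over the same folds
  spec2 <- classifier_spec("SVM",
                           grid = list(cost = c(1e-12, 1),
                                       kernel = "linear"),
                           class_weights = "uniform")
  res2 <- inner_search(d$mats$INF, d$y, spec2, cfg, seed = 0)
  scores <- vapply(c(1e-12, 1), function(cc) {
    s <- classifier_spec("SVM", grid = list(cost = cc, kernel = "linear"),
                         class_weights = "uniform")
    inner_search(d$mats$INF, d$y, s, cfg, seed = 0)$score
  }, numeric(1))
  expect_equal(res2$hyper$cost, c(1e-12, 1)[which.max(scores)])
  expect_equal(res2$score, max(scores))

  # exact tie between duplicated grid points keeps the earlier one
  spec3 <- classifier_spec("SVM", grid = list(cost = c(1, 1),
                                              kernel = "linear"),
                           class_weights = "uniform")
  res3 <- inner_search(d$mats$INF, d$y, spec3, cfg, seed = 0)
  expect_equal(res3$n_evaluated, 2L)
  expect_equal(res3$hyper$cost, 1)
  expect_error(
    inner_search(d$mats$INF, d$y,
                 structure(list(algorithm = "SVM", grid = list(),
                                class_weights = "uniform",
                                mode = "binary"),
                           class = "classifier_spec"),
                 cfg, seed = 0), "empty")
})

test_that("forward selection keeps the informative block and rejects noise", {
  d <- make_two_block_data(n_per_class = c(m = 50, n = 30),
                           dims = c(INF = 15, NOISE = 10),
                           delta = 3, seed = 0)
  cfg <- dcv_config(inner_folds = 3, seed = 0)
  spec <- small_svm_spec(weights = "uniform")
  fs <- forward_select(d$mats, d$y, spec, cfg, seed = 0)
  expect_s3_class(fs, "forward_selection_trace")
  expect_equal(fs$selected[1], "INF")
  # accepted scores strictly increase
  sc <- vapply(fs$steps, `[[`, numeric(1), "score")
  expect_true(all(diff(sc) > 0))
  # exhaustive subset oracle on the same folds/seed: the selected set
  # scores at least as well as every single block
  singles <- vapply(names(d$mats), function(b)
    inner_search(d$mats[[b]], d$y, spec, cfg, seed = 0)$score, numeric(1))
  expect_gte(fs$score, max(singles))
  if (fs$halted_reason == "worsened") expect_equal(fs$selected, "INF")
})

test_that("a single block is selected with halted_reason exhausted", {
  d <- make_two_block_data(n_per_class = c(m = 15, n = 15),
                           dims = c(ONLY = 8), delta = 2, seed = 5)
  cfg <- dcv_config(inner_folds = 3, seed = 1)
  fs <- forward_select(d$mats, d$y, small_svm_spec(weights = "uniform"),
                       cfg, seed = 1)
  expect_equal(fs$selected, "ONLY")
  expect_equal(fs$halted_reason, "exhausted")
})

test_that("complementary weak blocks are both selected", {
  # additive signal split across two blocks: each alone is weak, the
  # union carries sqrt(2) times the shift
  set.seed(10)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  shift <- ifelse(y == "b", 1.6, 0)
  A <- matrix(rnorm(n * 6), n, 6); A[, 1] <- A[, 1] + shift
  B <- matrix(rnorm(n * 6), n, 6); B[, 1] <- B[, 1] + shift
  cfg <- dcv_config(inner_folds = 3, seed = 0)
  spec <- small_svm_spec(weights = "uniform")
  fs <- forward_select(list(A = A, B = B), y, spec, cfg, seed = 0)
  expect_setequal(fs$selected, c("A", "B"))
  singles <- vapply(list(A, B), function(X)
    inner_search(X, y, spec, cfg, seed = 0)$score, numeric(1))
  expect_gt(fs$score, max(singles))
})

test_that("double cross-validation is leakage-free and partitions ids", {
  d <- make_two_block_data(n_per_class = c(m = 25, n = 15),
                           dims = c(INF = 10, NOISE = 5),
                           delta = 3, seed = 3)
  cfg <- dcv_config(outer_folds = 5, inner_folds = 2, seed = 0)
  res <- run_dcv(d$mats, d$y, small_svm_spec(), cfg,
                 ids = d$dataset$records$id)
  expect_length(res$per_fold, 5)
  all_val <- unlist(lapply(res$per_fold, `[[`, "val_ids"))
  expect_setequal(all_val, d$dataset$records$id)
  expect_false(anyDuplicated(all_val) > 0)
  for (pf in res$per_fold)
    expect_length(intersect(pf$cal_ids, pf$val_ids), 0)
})

test_that("perfectly separable data yields unit accuracy with zero spread", {
  d <- make_two_block_data(n_per_class = c(m = 25, n = 25),
                           dims = c(INF = 10), delta = 12, seed = 4)
  cfg <- dcv_config(outer_folds = 5, inner_folds = 2, seed = 0)
  res <- run_dcv(d$mats, d$y, small_svm_spec(weights = "uniform"), cfg)
  expect_equal(res$summary$ACC$mean, 1)
  expect_equal(res$summary$ACC$sd, 0)
  expect_equal(res$summary$MCC$mean, 1)
})

test_that("report table carries the five score columns plus summary rows", {
  d <- make_two_block_data(n_per_class = c(m = 12, n = 12),
                           dims = c(INF = 6), delta = 3, seed = 6)
  cfg <- dcv_config(outer_folds = 3, inner_folds = 2, seed = 0)
  res <- run_dcv(d$mats, d$y, small_svm_spec(weights = "uniform"), cfg)
  p <- tempfile(fileext = ".tsv")
  write_dcv_report(res, p)
  tab <- read.delim(p)
  expect_true(all(c("F1_inner", "F1_outer", "BACC", "MCC", "ACC")
                  %in% colnames(tab)))
  expect_equal(nrow(tab), 3 + 2)
  expect_equal(tab$fold[4:5], c("mean", "sd"))
})

test_that("four-compartment DCV reports macro metrics and per-class MCC", {
  sp <- synthetic_spec(n_per_class = c(I = 14, M = 14, O = 14, T = 14),
                       dims = c(EMB = 12), informative_blocks = "EMB",
                       delta = 4, seed = 0, length_range = c(20, 30))
  ds <- gen_sequences(sp)
  blocks <- gen_embeddings(ds$records$id, ds$labels, sp)
  spec <- classifier_spec("SVM", grid = list(cost = 1, kernel = "linear"),
                          class_weights = "uniform", mode = "multiclass")
  cfg <- dcv_config(outer_folds = 3, inner_folds = 2, seed = 0)
  res <- run_dcv(list(EMB = blocks$EMB$vectors), unname(ds$labels),
                 spec, cfg, ids = ds$records$id)
  expect_length(res$per_fold, 3)
  # classes are 4-sd separated in sequence (I at 0, T at 12): near-perfect
  expect_gte(res$summary$ACC$mean, 0.9)
  expect_gte(res$summary$MCC$mean, 0.85)
  # per-class one-vs-rest MCC on pooled outer predictions
  m <- fit_classifier(spec, blocks$EMB$vectors, unname(ds$labels),
                      hyper = list(cost = 1, kernel = "linear"))
  cmtab <- confusion_table(unname(ds$labels),
                           predict(m, blocks$EMB$vectors),
                           c("I", "M", "O", "T"))
  expect_true(all(per_class_mcc(cmtab) > 0.9))
})
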