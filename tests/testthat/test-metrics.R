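# independent oracle: metrics computed from raw prediction vectors,
# using stats::cor for MCC (MCC is the Pearson correlation of the two
# binary indicator vectors) and direct count arithmetic for the rest
oracle_from_vectors <- function(y_true, y_pred) {
  t1 <- as.numeric(y_true == 1); p1 <- as.numeric(y_pred == 1)
  acc <- mean(t1 == p1)
  ppv <- if (sum(p1) == 0) NA else sum(t1 * p1) / sum(p1)
  tpr <- if (sum(t1) == 0) NA else sum(t1 * p1) / sum(t1)
  tnr <- if (sum(1 - t1) == 0) NA else
    sum((1 - t1) * (1 - p1)) / sum(1 - t1)
  f1 <- if (is.na(ppv) || is.na(tpr) || ppv + tpr == 0) NA else
    2 * ppv * tpr / (ppv + tpr)
  bacc <- if (is.na(tpr) || is.na(tnr)) NA else (tpr + tnr) / 2
  mcc <- if (var(t1) == 0 || var(p1) == 0) NA else
    suppressWarnings(cor(t1, p1))
  list(ACC = acc, F1 = f1, BACC = bacc, MCC = mcc)
}

test_that("confusion counts enumerate the four outcomes", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1), positive = 1)
  expect_equal(cm[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  cm2 <- confusion(c(1, 0, 1), c(1, 0, 1), positive = 1)
  expect_equal(cm2$FP + cm2$FN, 0L)
  # swapping the positive label transposes the counts
  cm3 <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1), positive = 0)
  expect_equal(cm3[c("TP", "FP", "TN", "FN")],
               cm[c("TN", "FN", "TP", "FP")], ignore_attr = TRUE)
  expect_error(confusion(1:3, 1:2, positive = 1), "equal length")
})

test_that("metric formulas agree with a brute-force oracle on 1000 random confusion matrices", {
  set.seed(2024)
  for (i in 1:1000) {
    counts <- sample(0:100, 4, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    y_true <- rep(c(1, 0, 1, 0), counts)          # TP FP FN TN truth
    y_pred <- rep(c(1, 1, 0, 0), counts)
    cm <- confusion(y_true, y_pred, positive = 1)
    expect_identical(unlist(cm[c("TP", "FP", "FN", "TN")]),
                     setNames(as.integer(counts),
                              c("TP", "FP", "FN", "TN")))
    got <- compute_metrics(cm)
    want <- oracle_from_vectors(y_true, y_pred)
    for (mn in names(want)) {
      if (is.na(want[[mn]])) expect_true(is.na(got[[mn]]))
      else expect_equal(got[[mn]], want[[mn]], tolerance = 1e-12)
    }
  }
})

test_that("perfect prediction hits the metric boundaries", {
  m <- compute_metrics(structure(list(TP = 10L, FP = 0L, TN = 10L,
                                      FN = 0L, positive = "1"),
                                 class = "confusion_binary"))
  expect_equal(unlist(m[c("MCC", "F1", "ACC", "BACC")]),
               c(MCC = 1, F1 = 1, ACC = 1, BACC = 1))
  m2 <- compute_metrics(confusion(rep(c(1, 0), c(60, 40))[1:100],
                                  rep(c(1, 0, 1, 0), c(50, 10, 10, 30)),
                                  positive = 1))
  expect_equal(m2$ACC, 0.8)
})

test_that("degenerate all-positive predictor is flagged, not zeroed", {
  # balanced truth, constant positive prediction
  m <- compute_metrics(confusion(rep(c(1, 0), each = 10), rep(1, 20), 1))
  expect_equal(m$BACC, 0.5)
  expect_true(is.na(m$MCC))
  expect_true("MCC" %in% m$undefined)
})

test_that("MCC is invariant under swapping both truth and prediction", {
  set.seed(3)
  y <- sample(0:1, 40, replace = TRUE)
  p <- sample(0:1, 40, replace = TRUE)
  m1 <- compute_metrics(confusion(y, p, positive = 1))
  m2 <- compute_metrics(confusion(1 - y, 1 - p, positive = 1))
  expect_equal(m1$MCC, m2$MCC)
})

test_that("BACC equals ACC when class-wise recalls are equal", {
  # TPR = TNR = 0.8 by construction
  cm <- structure(list(TP = 8L, FN = 2L, TN = 40L, FP = 10L,
                       positive = "1"), class = "confusion_binary")
  m <- compute_metrics(cm)
  expect_equal(m$BACC, 0.8)
  expect_equal(m$ACC, 48 / 60)
  cm2 <- structure(list(TP = 8L, FN = 2L, TN = 8L, FP = 2L,
                        positive = "1"), class = "confusion_binary")
  m2 <- compute_metrics(cm2)
  expect_equal(m2$BACC, m2$ACC)
})

test_that("per-class one-vs-rest MCC matches brute-force binarisation", {
  labs <- c("O", "I", "T", "M")
  set.seed(8)
  y <- sample(labs, 60, replace = TRUE)
  p <- sample(labs, 60, replace = TRUE)
  cm <- confusion_table(y, p, labs)
  got <- per_class_mcc(cm)
  for (l in labs) {
    want <- compute_metrics(confusion(as.integer(y == l),
                                      as.integer(p == l), 1))$MCC
    expect_equal(got[[l]], want)
  }
  # perfect multiclass prediction
  expect_equal(unname(per_class_mcc(confusion_table(y, y, labs))),
               rep(1, 4))
})

test_that("per-class MCC of truth-independent predictions is near zero", {
  set.seed(0)
  labs <- c("O", "I", "T", "M")
  y <- sample(labs, 10000, replace = TRUE)
  p <- sample(labs, 10000, replace = TRUE)
  expect_true(all(abs(per_class_mcc(confusion_table(y, p, labs))) < 0.05))
})

test_that("collapsing classes reproduces binary MCC on merged labels", {
  labs <- c("O", "I", "T", "M")
  set.seed(12)
  y <- sample(labs, 50, replace = TRUE)
  p <- sample(labs, 50, replace = TRUE)
  ym <- ifelse(y %in% c("T", "M"), "TM", "rest")
  pm <- ifelse(p %in% c("T", "M"), "TM", "rest")
  merged <- compute_metrics(confusion(ym, pm, positive = "TM"))$MCC
  # brute force on the 4x4 table: collapse rows/cols then binary formula
  cm4 <- confusion_table(y, p, labs)
  grp <- ifelse(labs %in% c("T", "M"), "TM", "rest")
  cm2 <- rowsum(t(rowsum(cm4, grp)), grp)
  tp <- cm2["TM", "TM"]; fn <- cm2["TM", "rest"]
  fp <- cm2["rest", "TM"]; tn <- cm2["rest", "rest"]
  direct <- (tp * tn - fp * fn) /
    sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(merged, direct)
})

test_that("evaluate_predictions reports macro quantities and flags", {
  y <- c("a", "a", "b", "b"); p <- c("a", "b", "b", "a")
  ev <- evaluate_predictions(y, p)
  expect_equal(ev$ACC, 0.5)
  expect_equal(ev$BACC, 0.5)
  # macro F1: both classes have F1 = 0.5
  expect_equal(ev$F1, 0.5)
  ev2 <- evaluate_predictions(c("a", "a", "b"), c("a", "a", "a"))
  expect_equal(ev2$n_undefined, 2L)
})
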