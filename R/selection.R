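# Step-forward feature-block selection nested inside stratified double
# cross-validation.  The outer loop estimates unbiased performance on
# untouched validation folds; the inner loop, run on the calibration
# portion only, picks the feature-block combination, the hyperparameters
# and the class weights (metaparameters) by exhaustive grid search.

#' Double cross-validation configuration
#'
#' @param outer_folds,inner_folds fold counts (default 5 and 5).
#' @param stratified keep per-fold class proportions within one sample of
#'   the global proportions (default TRUE).
#' @param seed base RNG seed; repetition r uses `seed + r - 1`.
#' @param inner_metric metric ranking grid points and block sets in the
#'   inner loop: `"F1"` (macro, default), `"BACC"`, `"MCC"` or `"ACC"`.
#' @param repeats number of repeated double cross-validation runs with
#'   derived seeds (default 1).
#' @return a `dcv_config`.
#' @export
dcv_config <- function(outer_folds = 5L, inner_folds = 5L,
                       stratified = TRUE, seed = 0L,
                       inner_metric = c("F1", "BACC", "MCC", "ACC"),
                       repeats = 1L) {
  if (outer_folds < 2 || inner_folds < 2)
    stop("outer_folds and inner_folds must both be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed),
                 inner_metric = match.arg(inner_metric),
                 repeats = as.integer(repeats)),
            class = "dcv_config")
}

#' Stratified k-fold split
#'
#' Indices of each class are shuffled (seeded) and dealt round-robin, so
#' the folds partition all indices and per-fold class counts differ from
#' exact proportionality by at most one sample.
#'
#' @param y label vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified if `FALSE`, a plain shuffled split.
#' @return list of `k` disjoint integer index vectors covering
#'   `seq_along(y)`.
#' @export
stratified_folds <- function(y, k, seed = 0L, stratified = TRUE) {
  n <- length(y)
  if (k < 2) stop("need k >= 2 folds")
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  if (stratified) {
    counts <- table(y)
    if (any(counts < k))
      stop("class with fewer members than folds: minimum class count ",
           min(counts), " < k = ", k)
    for (cl in sort(names(counts))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (n < k) stop("fewer samples than folds")
    fold_of <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

inner_metric_value <- function(metrics, name) {
  v <- metrics[[name]]
  if (is.null(v) || is.na(v)) -Inf else v
}

expand_hyper_grid <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Inner-loop grid search over hyperparameters and class weights
#'
#' Exhaustive search over the Cartesian product of the spec's grid and its
#' class-weight candidates; for each point the mean inner metric across
#' the inner folds is computed and the maximising point returned.  Ties
#' keep the earlier point in iteration order (class-weight candidates
#' vary slowest, grid axes in `expand.grid` order fastest).
#'
#' @param X calibration feature matrix.
#' @param y calibration labels.
#' @param spec a `classifier_spec`.
#' @param cfg a `dcv_config`.
#' @param labels declared label set.
#' @param seed seed for the inner fold split and stochastic fits.
#' @return list with `hyper`, `weights` (the winning weight rule),
#'   `score` (its mean inner metric), `n_evaluated`.
#' @export
inner_search <- function(X, y, spec, cfg, labels = sort(unique(y)),
                         seed = cfg$seed) {
  X <- as.matrix(X)
  folds <- stratified_folds(y, cfg$inner_folds, seed = seed,
                            stratified = cfg$stratified)
  points <- expand_hyper_grid(spec$grid)
  if (!length(points)) stop("empty hyperparameter grid")
  wcands <- spec$class_weights
  if (is.numeric(wcands)) wcands <- list(wcands)
  best <- NULL
  n_eval <- 0L
  for (w in wcands) for (hp in points) {
    n_eval <- n_eval + 1L
    scores <- vapply(folds, function(test_idx) {
      tr <- setdiff(seq_along(y), test_idx)
      model <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr],
                              hyper = hp, weights = w, labels = labels,
                              seed = seed)
      pred <- predict(model, X[test_idx, , drop = FALSE])
      inner_metric_value(
        evaluate_predictions(y[test_idx], pred, labels), cfg$inner_metric)
    }, numeric(1))
    sc <- mean(scores)
    if (is.null(best) || sc > best$score)
      best <- list(hyper = hp, weights = w, score = sc)
  }
  best$n_evaluated <- n_eval
  best
}

#' Step-forward selection of feature blocks
#'
#' Starts by evaluating each block alone through [inner_search()], keeps
#' the best, then iteratively tries adding each not-yet-included block and
#' accepts the best addition only on strict improvement of the inner
#' score.  Halts when performance worsens (or no block is left).
#'
#' @param blocks named list of per-block feature matrices with aligned
#'   rows (one per sample).
#' @param y labels aligned with the block rows.
#' @param spec a `classifier_spec`.
#' @param cfg a `dcv_config`.
#' @param labels declared label set.
#' @param seed seed forwarded to [inner_search()].
#' @return a `forward_selection_trace`: list with `steps` (accepted steps:
#'   block set, inner score, hyper, weights), `selected`, `score`,
#'   `hyper`, `weights`, `halted_reason` (`"worsened"`/`"exhausted"`).
#' @export
forward_select <- function(blocks, y, spec, cfg,
                           labels = sort(unique(y)), seed = cfg$seed) {
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)),
            all(nzchar(names(blocks))))
  remaining <- names(blocks)
  current <- character(0)
  current_score <- -Inf
  steps <- list()
  hyper <- NULL; weights <- NULL
  halted <- "exhausted"
  while (length(remaining)) {
    round_best <- NULL
    for (b in remaining) {
      cand <- c(current, b)
      Xc <- do.call(cbind, blocks[cand])
      res <- inner_search(Xc, y, spec, cfg, labels = labels, seed = seed)
      if (is.null(round_best) || res$score > round_best$score)
        round_best <- c(res, list(set = cand, added = b))
    }
    if (round_best$score > current_score) {
      current <- round_best$set
      current_score <- round_best$score
      hyper <- round_best$hyper
      weights <- round_best$weights
      steps[[length(steps) + 1L]] <-
        list(set = current, score = current_score,
             hyper = hyper, weights = weights)
      remaining <- setdiff(remaining, round_best$added)
    } else {
      halted <- "worsened"
      break
    }
  }
  structure(list(steps = steps, selected = current, score = current_score,
                 hyper = hyper, weights = weights, halted_reason = halted),
            class = "forward_selection_trace")
}

#' Double cross-validation with nested forward selection
#'
#' For each outer fold, the calibration portion alone drives the forward
#' selection of blocks and the inner grid search; a model with the chosen
#' configuration is then fit on the full calibration set and scored on
#' the untouched validation fold.  The summary reports mean and standard
#' deviation of each outer metric across folds (and repetitions), with
#' undefined metric values skipped and counted.
#'
#' @param blocks named list of per-sample feature matrices (aligned rows).
#' @param y labels.
#' @param spec a `classifier_spec`.
#' @param cfg a `dcv_config`.
#' @param ids optional sample ids (default rownames of the first block or
#'   indices).
#' @return a `dcv_result`: `per_fold` (one entry per outer fold and
#'   repetition: selected blocks, hyper, weights, metrics, inner score,
#'   calibration/validation ids), `summary` (mean/sd/n_undefined per
#'   metric), `inner_summary`.
#' @export
run_dcv <- function(blocks, y, spec, cfg, ids = NULL) {
  stopifnot(inherits(cfg, "dcv_config"), inherits(spec, "classifier_spec"))
  y <- as.character(y)
  labels <- sort(unique(y))
  if (spec$mode == "binary" && length(labels) != 2)
    stop("binary mode requires exactly 2 classes, found ", length(labels))
  if (is.null(ids)) ids <- rownames(blocks[[1]]) %||% as.character(seq_along(y))
  per_fold <- list()
  for (r in seq_len(cfg$repeats)) {
    rep_seed <- cfg$seed + r - 1L
    outer <- stratified_folds(y, cfg$outer_folds, seed = rep_seed,
                              stratified = cfg$stratified)
    for (f in seq_along(outer)) {
      val <- outer[[f]]
      cal <- setdiff(seq_along(y), val)
      fold_seed <- rep_seed + 1000L * f
      cal_blocks <- lapply(blocks, function(B) B[cal, , drop = FALSE])
      fs <- forward_select(cal_blocks, y[cal], spec, cfg,
                           labels = labels, seed = fold_seed)
      X_cal <- do.call(cbind, cal_blocks[fs$selected])
      model <- fit_classifier(spec, X_cal, y[cal], hyper = fs$hyper,
                              weights = fs$weights, labels = labels,
                              seed = fold_seed)
      X_val <- do.call(cbind,
                       lapply(blocks[fs$selected],
                              function(B) B[val, , drop = FALSE]))
      pred <- predict(model, X_val)
      met <- evaluate_predictions(y[val], pred, labels)
      per_fold[[length(per_fold) + 1L]] <-
        list(rep = r, fold = f, selected = fs$selected,
             hyper = fs$hyper, weights = fs$weights,
             inner_score = fs$score, trace = fs, metrics = met,
             cal_ids = ids[cal], val_ids = ids[val])
    }
  }
  metric_names <- c("F1", "BACC", "MCC", "ACC")
  summary <- lapply(setNames(metric_names, metric_names), function(mn) {
    v <- vapply(per_fold, function(pf) pf$metrics[[mn]], numeric(1))
    list(mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
         sd = if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE),
         n_undefined = sum(is.na(v)))
  })
  inner_scores <- vapply(per_fold, `[[`, numeric(1), "inner_score")
  structure(list(per_fold = per_fold, summary = summary,
                 inner_summary = mean(inner_scores),
                 config = cfg, labels = labels),
            class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  cat("dcv_result:", length(x$per_fold), "outer folds;",
      "modal selection:",
      paste(modal_selection(x), collapse = " + "), "\n")
  cat(sprintf("  F1(inner) %.3f\n", x$inner_summary))
  for (mn in names(x$summary))
    cat(sprintf("  %s(outer) %.3f ± %.3f%s\n", mn,
                x$summary[[mn]]$mean,
                if (is.na(x$summary[[mn]]$sd)) 0 else x$summary[[mn]]$sd,
                if (x$summary[[mn]]$n_undefined)
                  sprintf("  (%d undefined fold(s) skipped)",
                          x$summary[[mn]]$n_undefined) else ""))
  invisible(x)
}

#' Modal block selection across outer folds
#'
#' The block set selected most often across outer folds (ties broken by
#' first occurrence) — the headline configuration of a DCV run.
#'
#' @param result a `dcv_result`.
#' @return character vector of block names.
#' @export
modal_selection <- function(result) {
  sets <- vapply(result$per_fold,
                 function(pf) paste(sort(pf$selected), collapse = "+"),
                 character(1))
  tab <- table(factor(sets, levels = unique(sets)))
  strsplit(names(tab)[which.max(tab)], "+", fixed = TRUE)[[1]]
}

#' Write a DCV report table
#'
#' One row per outer fold plus `mean` and `sd` summary rows; columns
#' `F1_inner`, `F1_outer`, `BACC`, `MCC`, `ACC` (and the selected blocks).
#'
#' @param result a `dcv_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dcv_report <- function(result, path) {
  rows <- lapply(result$per_fold, function(pf)
    data.frame(fold = sprintf("r%d.f%d", pf$rep, pf$fold),
               blocks = paste(pf$selected, collapse = "+"),
               F1_inner = pf$inner_score,
               F1_outer = pf$metrics$F1, BACC = pf$metrics$BACC,
               MCC = pf$metrics$MCC, ACC = pf$metrics$ACC))
  tab <- do.call(rbind, rows)
  s <- result$summary
  tab <- rbind(tab,
    data.frame(fold = "mean", blocks = "",
               F1_inner = result$inner_summary,
               F1_outer = s$F1$mean, BACC = s$BACC$mean,
               MCC = s$MCC$mean, ACC = s$ACC$mean),
    data.frame(fold = "sd", blocks = "", F1_inner = NA,
               F1_outer = s$F1$sd, BACC = s$BACC$sd,
               MCC = s$MCC$sd, ACC = s$ACC$sd))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
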