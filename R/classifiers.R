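# One fitting interface over the four classification algorithms: SVM
# (e1071/libsvm), random forest (ranger), penalised logistic regression
# (glmnet) and the package's own PLS-DA.  Hyperparameter grids are data:
# the stock grids ship as defaults and are fully overridable.

#' Stock hyperparameter grids
#'
#' The default search grids for the four algorithms: SVM — cost over 13
#' log-spaced values from 1e-2 to 1e10, gamma over 13 log-spaced values
#' from 1e-9 to 1e3, four kernels; RF — number of trees, maximum depth,
#' minimum node size, mtry rule; LR — L1/L2 penalty with 13 log-spaced
#' inverse strengths from 1e-3 to 1e9; PLS-DA — component counts 2 to 30.
#' The RF backend (ranger) splits on the Gini criterion only, so the
#' split-criterion axis is not part of the grid.
#'
#' @param algorithm one of `"SVM"`, `"RF"`, `"LR"`, `"PLSDA"`.
#' @return named list of candidate vectors.
#' @export
default_grid <- function(algorithm = c("SVM", "RF", "LR", "PLSDA")) {
  switch(match.arg(algorithm),
    SVM = list(cost = 10^seq(-2, 10), gamma = 10^seq(-9, 3),
               kernel = c("linear", "poly", "rbf", "sigmoid")),
    RF = list(n_estimators = c(15, 25, 50, 75, 100, 200, 300),
              max_depth = c(2, 5, 10, NA),
              min_samples_split = c(2, 4, 8, 10),
              max_features = c("sqrt", "log2")),
    LR = list(penalty = c("l1", "l2"), C = 10^seq(-3, 9)),
    PLSDA = list(k = c(2, 5, 10, 15, 20, 25, 30)))
}

#' Declare a classifier and its search space
#'
#' @param algorithm one of `"SVM"`, `"RF"`, `"LR"`, `"PLSDA"`.
#' @param grid named list of hyperparameter candidate vectors; defaults to
#'   [default_grid()].
#' @param class_weights either a single weighting rule (`"uniform"`,
#'   `"balanced"`, `"minority2"`, `"minority5"`, or a named numeric map
#'   label -> weight) or a character vector of candidate rules searched as
#'   metaparameters in the inner loop.
#' @param mode `"binary"` or `"multiclass"`; PLS-DA is binary-only.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("SVM", "RF", "LR", "PLSDA"),
                            grid = NULL,
                            class_weights = c("uniform", "balanced",
                                              "minority2", "minority5"),
                            mode = c("binary", "multiclass")) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (algorithm == "PLSDA" && mode == "multiclass")
    stop("PLS-DA is restricted to binary mode")
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid) || any(!vapply(grid, length, integer(1))))
    stop("hyperparameter grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid,
                 class_weights = class_weights, mode = mode),
            class = "classifier_spec")
}

#' Resolve a class-weight rule into a named per-label weight map
#'
#' `"balanced"` gives n / (C * n_c) per class (inverse-frequency);
#' `"minority2"`/`"minority5"` upweight the smallest class by 2/5.
#'
#' @param rule rule name or named numeric map.
#' @param y training labels.
#' @param labels declared label set.
#' @return named numeric vector of positive weights, one per label.
#' @export
resolve_class_weights <- function(rule, y, labels) {
  if (is.numeric(rule)) {
    if (!all(labels %in% names(rule)))
      stop("numeric class weights must name every label")
    return(rule[labels])
  }
  counts <- table(factor(y, labels))
  w <- setNames(rep(1, length(labels)), labels)
  if (rule == "uniform") {
  } else if (rule == "balanced") {
    w <- setNames(as.numeric(length(y) / (length(labels) * counts)), labels)
  } else if (rule %in% c("minority2", "minority5")) {
    w[names(which.min(counts))] <- as.numeric(sub("minority", "", rule))
  } else stop("unknown class-weight rule: ", rule)
  w
}

check_xy <- function(X, y, labels) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  if (nrow(X) != length(y)) stop("X rows and y length disagree")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  counts <- table(factor(y, labels))
  if (any(counts < 2))
    stop("need >= 2 training samples per class; got minimum ", min(counts))
  X
}

#' Fit one classifier at fixed hyperparameters
#'
#' @param spec a `classifier_spec`.
#' @param X n x D feature matrix.
#' @param y labels of length n.
#' @param hyper named list of one value per grid axis (e.g.
#'   `list(cost = 1, gamma = 0.01, kernel = "linear")`).
#' @param weights class-weight rule or map (see
#'   [resolve_class_weights()]); default `"uniform"`.
#' @param labels declared label set; defaults to sorted unique `y`.
#' @param seed RNG seed for stochastic fits (RF); default 0.
#' @return a `trained_model`.
#' @export
fit_classifier <- function(spec, X, y, hyper = NULL, weights = "uniform",
                           labels = NULL, seed = 0L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.character(y)
  if (is.null(labels)) labels <- sort(unique(y))
  X <- check_xy(X, y, labels)
  if (spec$mode == "binary" && length(labels) != 2)
    stop("binary mode requires exactly 2 labels")
  if (is.null(hyper)) hyper <- lapply(spec$grid, `[[`, 1)
  w <- resolve_class_weights(weights, y, labels)
  yf <- factor(y, levels = labels)
  set.seed(as.integer(seed))
  fit <- switch(spec$algorithm,
    SVM = {
      kern <- c(linear = "linear", poly = "polynomial", rbf = "radial",
                sigmoid = "sigmoid")[[hyper$kernel %||% "rbf"]]
      e1071::svm(x = X, y = yf, scale = FALSE, kernel = kern,
                 cost = hyper$cost %||% 1,
                 gamma = hyper$gamma %||% (1 / ncol(X)),
                 class.weights = w)
    },
    RF = {
      mtry <- switch(hyper$max_features %||% "sqrt",
                     sqrt = max(1L, floor(sqrt(ncol(X)))),
                     log2 = max(1L, floor(log2(ncol(X)))))
      md <- hyper$max_depth %||% NA
      ranger::ranger(x = as.data.frame(X), y = yf,
                     num.trees = hyper$n_estimators %||% 100,
                     mtry = min(mtry, ncol(X)),
                     max.depth = if (is.na(md)) 0 else md,
                     min.node.size = hyper$min_samples_split %||% 2,
                     class.weights = as.numeric(w[labels]),
                     seed = as.integer(seed), num.threads = 1)
    },
    LR = {
      fam <- if (length(labels) == 2) "binomial" else "multinomial"
      glmnet::glmnet(x = X, y = yf, family = fam,
                     alpha = if ((hyper$penalty %||% "l2") == "l1") 1 else 0,
                     lambda = 1 / ((hyper$C %||% 1) * nrow(X)),
                     weights = as.numeric(w[y]),
                     standardize = FALSE)
    },
    PLSDA = {
      k <- min(hyper$k %||% 2, nrow(X) - 1, ncol(X))
      pls_fit(X, as.integer(yf == labels[2]), k = k,
              weights = as.numeric(w[y]))
    })
  structure(list(spec = spec, algorithm = spec$algorithm, fit = fit,
                 hyper = hyper, weights = w, labels = labels,
                 width = ncol(X), block_order = attr(X, "block_order"),
                 seed = as.integer(seed)),
            class = "trained_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict labels with a trained model
#'
#' @param object a `trained_model`.
#' @param newdata m x D matrix; D must match the fit-time width.
#' @param ... unused.
#' @return character vector of m labels from the fit-time label set.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0) return(character(0))
  if (ncol(X) != object$width)
    stop("feature width ", ncol(X), " does not match the fitted width ",
         object$width)
  out <- switch(object$algorithm,
    SVM = as.character(predict(object$fit, X)),
    RF = as.character(predict(object$fit, data = as.data.frame(X),
                              num.threads = 1)$predictions),
    LR = {
      p <- predict(object$fit, newx = X, type = "class")
      as.character(p[, 1])
    },
    PLSDA = {
      s <- predict(object$fit, X)
      object$labels[1 + as.integer(s >= 0.5)]
    })
  unname(out)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$algorithm, "on", x$width, "features;",
      "labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a trained model archive
#'
#' The archive stores the spec snapshot, fitted parameters, block order
#' and label set in one file.
#'
#' @param model a `trained_model`.
#' @param path archive path.
#' @return `path` invisibly ([save_model()]); a `trained_model`
#'   ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model"))
    stop("not a sublocr model archive: ", path)
  model
}
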