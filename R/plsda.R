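# Partial least squares discriminant analysis: univariate-response PLS
# regression on a 0/1 dummy variable with the >= 0.5 decision rule.
# Implemented directly (NIPALS deflation) so that component extraction,
# weighting and the decision rule are under the package's control; at
# k = rank(X) the scores coincide with ordinary least squares on the
# dummy response.

#' Fit a PLS1 regression on a numeric response
#'
#' NIPALS-style extraction of `k` orthogonal score components; optional
#' non-negative observation weights enter through weighted centring and
#' weighted inner products (rows scaled by sqrt(w)).  Extraction stops
#' early, with a `degenerate` flag, if the residual predictor/response
#' covariance vanishes (e.g. constant X).
#'
#' @param X n x D numeric matrix.
#' @param y numeric response of length n.
#' @param k number of components, `1 <= k <= min(n - 1, D)`.
#' @param weights optional observation weights.
#' @return a `pls_fit`: list with `coef` (D-vector), `intercept`,
#'   `k_used`, `degenerate`.
#' @export
pls_fit <- function(X, y, k, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree")
  if (k < 1 || k > min(n - 1, D))
    stop("components k out of range: need 1 <= k <= min(n-1, D) = ",
         min(n - 1, D))
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) == 0) stop("invalid observation weights")
  wn <- w / sum(w)
  xbar <- colSums(X * wn)
  ybar <- sum(y * wn)
  sw <- sqrt(w)
  Xc <- sweep(X, 2, xbar) * sw
  yc <- (y - ybar) * sw
  W <- matrix(0, D, k); P <- matrix(0, D, k); q <- numeric(k)
  used <- 0L
  for (a in seq_len(k)) {
    wa <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(wa^2))
    if (nw < 1e-12) break
    wa <- wa / nw
    t_ <- Xc %*% wa
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xc, t_)[, 1] / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(pa)
    yc <- yc - qa * t_
    W[, a] <- wa; P[, a] <- pa; q[a] <- qa
    used <- a
  }
  if (used == 0L) {
    return(structure(list(coef = rep(0, D), intercept = ybar,
                          k_used = 0L, degenerate = TRUE),
                     class = "pls_fit"))
  }
  Wu <- W[, seq_len(used), drop = FALSE]
  Pu <- P[, seq_len(used), drop = FALSE]
  qu <- q[seq_len(used)]
  B <- Wu %*% solve(crossprod(Pu, Wu), qu)
  structure(list(coef = drop(B), intercept = ybar - sum(xbar * B),
                 k_used = used, degenerate = used < k),
            class = "pls_fit")
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coef) + object$intercept
}

#' PLS-DA: fit on a 0/1 dummy response and classify test rows
#'
#' Test rows with predicted score Y >= 0.5 are assigned class 1, class 0
#' otherwise (the boundary score 0.5 is class 1).
#'
#' @param X_train,X_test numeric matrices with equal column counts.
#' @param y_train binary response coded 0/1 (numeric, or a factor/character
#'   vector with exactly two levels — the second sorted level is class 1).
#' @param k number of PLS components.
#' @param weights optional observation weights for the training rows.
#' @return list with `labels` (0/1 integer per test row), `scores`
#'   (continuous Y), `fit` (the `pls_fit`), `degenerate` flag.
#' @export
plsda_fit_predict <- function(X_train, y_train, X_test, k, weights = NULL) {
  if (!is.numeric(y_train)) {
    lev <- sort(unique(as.character(y_train)))
    if (length(lev) != 2) stop("PLS-DA requires a binary response")
    y_train <- as.integer(as.character(y_train) == lev[2])
  }
  if (!all(y_train %in% c(0, 1)))
    stop("PLS-DA dummy response must be coded 0/1")
  if (ncol(as.matrix(X_test)) != ncol(as.matrix(X_train)))
    stop("train/test width mismatch")
  fit <- pls_fit(X_train, y_train, k, weights = weights)
  if (fit$k_used == 0L)
    warning("degenerate PLS-DA fit (constant predictors): ",
            "all scores equal the weighted class mean")
  scores <- predict(fit, X_test)
  list(labels = as.integer(scores >= 0.5), scores = scores, fit = fit,
       degenerate = fit$degenerate)
}
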