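#' Fit a PLS1 regression by NIPALS
#'
#' Classical NIPALS partial least squares for a single response: X and y
#' are column-centered; each component's weight vector is `X'y` normalized
#' (deterministic - no random initialization), scores are deflated from
#' both blocks, and regression coefficients for every truncation
#' `1..n_components` are recovered as `B_c = W_c (P_c' W_c)^{-1} q_c`.
#' Extraction stops early if the residual X block is exhausted (rank
#' deficiency), in which case `n_components` reflects the number actually
#' extracted.
#'
#' @param X numeric matrix (compounds x descriptor columns), or a
#'   `field_block` whose `$matrix` is used.
#' @param y numeric response vector (pIC50).
#' @param n_components number of latent components to extract.
#' @return object of class `pls_model`: `n_components`, `x_weights`,
#'   `x_loadings`, `y_loadings`, `coefficients` (columns = models with
#'   1..c components), `x_means`, `y_mean`, `scores`.
#' @export
fit_pls <- function(X, y, n_components) {
  if (inherits(X, "field_block")) X <- X$matrix
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (n < 3L) stop("need at least 3 samples")
  if (!all(is.finite(X))) stop("X must be finite")
  if (stats::sd(y) == 0) stop("y has zero variance")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop("n_components must be in 1..min(n_samples - 1, n_columns)")
  }
  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_means)
  f <- y - y_mean
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  qv <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  a <- 0L
  for (c in seq_len(n_components)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pl <- crossprod(E, t_) / tt
    qc <- sum(f * t_) / tt
    E <- E - t_ %*% t(pl)
    f <- f - qc * t_
    a <- c
    W[, c] <- w
    P[, c] <- pl
    qv[c] <- qc
    Tm[, c] <- t_
  }
  if (a == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  qv <- qv[seq_len(a)]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  # coefficients for each truncation c: B_c = W_c (P_c'W_c)^{-1} q_c.
  # P'W is upper triangular with unit-ish diagonal, so the solve is stable.
  B <- matrix(0, p, a)
  PW <- crossprod(P, W)
  for (c in seq_len(a)) {
    B[, c] <- W[, 1:c, drop = FALSE] %*%
      solve(PW[1:c, 1:c, drop = FALSE], qv[1:c])
  }
  structure(list(n_components = a, x_weights = W, x_loadings = P,
                 y_loadings = qv, coefficients = B, x_means = x_means,
                 y_mean = y_mean, scores = Tm),
            class = "pls_model")
}

#' Predict activities from a fitted PLS model
#'
#' `yhat = y_mean + (X_new - x_means) B_c`.
#'
#' @param object a `pls_model`.
#' @param newdata matrix (or `field_block`) with the model's column count.
#' @param ncomp number of components to use (default: all extracted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  if (inherits(newdata, "field_block")) newdata <- newdata$matrix
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_means))
  }
  if (is.null(ncomp)) ncomp <- object$n_components
  if (ncomp < 0L || ncomp > object$n_components) {
    stop("ncomp out of range")
  }
  if (ncomp == 0L) return(rep(object$y_mean, nrow(newdata)))
  b <- object$coefficients[, ncomp]
  as.numeric(object$y_mean + sweep(newdata, 2, object$x_means) %*% b)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %d descriptor columns>\n",
              x$n_components, nrow(x$coefficients)))
  invisible(x)
}

#' Leave-one-out cross-validation (q2 profile)
#'
#' For every sample, the model is refit on the remaining samples and the
#' held-out activity predicted, for each component count `1..max_components`.
#' PRESS_c is the sum of squared held-out residuals; TSS the squared
#' deviations of the activities from their mean over the cross-validated
#' set; `q2 = 1 - PRESS/TSS`. The optimal number of components (ONC) is
#' chosen by [select_onc()].
#'
#' @param X descriptor matrix or `field_block`.
#' @param y activity vector.
#' @param max_components largest component count to profile (clipped to
#'   what LOO sub-fits can support).
#' @param parsimony_tol tolerance passed to [select_onc()].
#' @return list of class `crossval_report`: `q2` (per component), `press`
#'   (per component), `tss`, `onc`, `q2_onc`, `predictions` (matrix of
#'   held-out predictions, samples x components).
#' @export
loo_q2 <- function(X, y, max_components = 10L, parsimony_tol = 0.05) {
  if (inherits(X, "field_block")) X <- X$matrix
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples for leave-one-out")
  if (stats::sd(y) == 0) stop("y is constant; TSS would be zero")
  cmax <- min(as.integer(max_components), n - 2L, ncol(X))
  if (cmax < 1L) stop("no admissible component count")
  preds <- matrix(NA_real_, n, cmax)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], cmax)
    for (c in seq_len(cmax)) {
      # rank-deficient sub-fits expose fewer components; reuse the largest
      cc <- min(c, fit$n_components)
      preds[i, c] <- predict(fit, X[i, , drop = FALSE], ncomp = cc)
    }
  }
  press <- colSums((preds - y)^2)
  tss <- sum((y - mean(y))^2)
  q2 <- 1 - press / tss
  onc <- select_onc(q2, parsimony_tol)
  structure(list(q2 = q2, press = press, tss = tss, onc = onc,
                 q2_onc = q2[onc], predictions = preds),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report: ONC %d, q2 %.3f (max %.3f at %d comp.)>\n",
              x$onc, x$q2_onc, max(x$q2), which.max(x$q2)))
  invisible(x)
}

#' Select the optimal number of components
#'
#' Parsimony rule: the smallest component count whose q2 reaches
#' `(1 - parsimony_tol)` of the maximum q2 in the profile; extra
#' components that buy less than that fraction are not worth their
#' overfitting risk. When the whole profile is negative, the argmax is
#' returned.
#'
#' @param q2_by_component numeric q2 profile (index = component count).
#' @param parsimony_tol fraction of the maximum q2 that may be sacrificed
#'   for a smaller model (default 0.05).
#' @return integer component count.
#' @export
select_onc <- function(q2_by_component, parsimony_tol = 0.05) {
  if (length(q2_by_component) == 0L) stop("empty q2 profile")
  m <- max(q2_by_component)
  thr <- (1 - parsimony_tol) * m
  ok <- which(q2_by_component >= thr - 1e-12)
  if (length(ok) == 0L) which.max(q2_by_component) else min(ok)
}

#' Non-cross-validated fit statistics
#'
#' `r2 = 1 - SSres/TSS`, `SEE = sqrt(SSres/(n - c - 1))` and
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))` with `c` the number of model
#' components; a perfect fit reports SEE 0 and `F = Inf`.
#'
#' @param model a `pls_model`.
#' @param X training descriptor matrix or `field_block`.
#' @param y training activities.
#' @param ncomp component count (default: the model's).
#' @return list with `r2`, `see`, `f_value`, `n`, `n_components`.
#' @export
fit_statistics <- function(model, X, y, ncomp = NULL) {
  if (inherits(X, "field_block")) X <- X$matrix
  if (is.null(ncomp)) ncomp <- model$n_components
  y <- as.numeric(y)
  n <- length(y)
  dof <- n - ncomp - 1L
  if (dof <= 0L) stop("non-positive degrees of freedom (n <= c + 1)")
  yhat <- predict(model, X, ncomp = ncomp)
  ssres <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / tss
  see <- sqrt(ssres / dof)
  f <- if (ssres == 0) Inf else f_statistic(r2, n, ncomp)
  list(r2 = r2, see = see, f_value = f, n = n, n_components = ncomp)
}

#' F statistic of a fitted regression from r2 alone
#'
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))`: the ratio of explained to
#' residual variance per degree of freedom. Useful for consistency checks
#' against reported model tables where only n, the component count and r2
#' are printed.
#'
#' @param r2 squared correlation of the fit.
#' @param n_samples training-set size.
#' @param n_components model component count.
#' @return the F value (`Inf` when `r2 = 1`).
#' @export
f_statistic <- function(r2, n_samples, n_components) {
  dof <- n_samples - n_components - 1
  if (dof <= 0) stop("non-positive degrees of freedom")
  if (r2 >= 1) return(Inf)
  (r2 / n_components) / ((1 - r2) / dof)
}

#' Per-field contributions of a PLS model
#'
#' SYBYL-style contribution of each field kind: the sum over its columns
#' of |coefficient| x column standard deviation (both in the scaled
#' descriptor space the model was fitted in), normalized across kinds to
#' sum to one.
#'
#' @param model a `pls_model` fitted on `block$matrix`.
#' @param block the `field_block` the model was fitted on.
#' @param ncomp component count (default: the model's).
#' @param rows optional compound indices over which column standard
#'   deviations are taken (typically the training set); default all.
#' @return named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, block, ncomp = NULL, rows = NULL) {
  if (is.null(ncomp)) ncomp <- model$n_components
  b <- model$coefficients[, ncomp]
  if (is.null(rows)) rows <- seq_len(nrow(block$matrix))
  sds <- apply(block$matrix[rows, , drop = FALSE], 2, stats::sd)
  contrib <- vapply(block$kinds, function(k) {
    j <- block$column_meta$kind == k
    if (!any(j)) stop("field kind absent from block: ", k)
    sum(abs(b[j]) * sds[j])
  }, numeric(1))
  total <- sum(contrib)
  if (total == 0) stop("all coefficients are zero; contributions undefined")
  contrib / total
}
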