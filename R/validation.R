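#' Predictive R2 for an external test set
#'
#' `Rpred2 = (SD - PRESS)/SD`, where PRESS is the sum of squared test-set
#' residuals and SD the sum of squared deviations of the test activities
#' from the training-set mean. Equal to 1 for perfect prediction and 0 for
#' a model no better than predicting the training mean.
#'
#' @param y_test experimental test activities.
#' @param y_pred predicted test activities.
#' @param y_train_mean mean activity of the training set.
#' @return Rpred2 (dimensionless).
#' @export
rpred2 <- function(y_test, y_pred, y_train_mean) {
  y_test <- as.numeric(y_test)
  y_pred <- as.numeric(y_pred)
  if (length(y_test) != length(y_pred) || length(y_test) < 2L) {
    stop("y_test and y_pred must have equal length >= 2")
  }
  sd_ <- sum((y_test - y_train_mean)^2)
  if (sd_ == 0) stop("SD is zero: test activities equal the training mean")
  press <- sum((y_pred - y_test)^2)
  (sd_ - press) / sd_
}

#' rm2 metric from R2 and the through-origin R02
#'
#' `rm2 = R2 (1 - sqrt(R2 - R02))`; the difference is clamped at zero
#' before the square root, since a through-origin fit can numerically beat
#' the centered fit. rm2 close to R2 indicates that predictions track
#' observations near the identity line, not merely correlate.
#'
#' @param r2 squared correlation between observed and predicted.
#' @param r02 through-origin coefficient of determination.
#' @return rm2 (dimensionless).
#' @export
rm_squared <- function(r2, r02) {
  r2 * (1 - sqrt(pmax(r2 - r02, 0)))
}

#' External validation battery (through-origin statistics)
#'
#' Computes the Golbraikh-Tropsha quantities for a test set: the squared
#' Pearson correlation R2 between experimental (`Ya`) and predicted (`Yp`)
#' activities; the through-origin slopes `k = sum(Ya Yp)/sum(Yp^2)` and
#' `k' = sum(Ya Yp)/sum(Ya^2)`; the through-origin determination
#' coefficients `R02 = 1 - sum((Ya - k Yp)^2)/sum((Ya - mean(Ya))^2)` and
#' its role-swapped counterpart `R0'2`; and `rm2` via [rm_squared()].
#'
#' @param Ya experimental test-set activities (pIC50).
#' @param Yp predicted test-set activities.
#' @return list of class `external_validation`: `r2`, `k`, `k_prime`,
#'   `r02`, `r02_prime`, `rm2`, `press`, plus the input vectors.
#' @export
external_battery <- function(Ya, Yp) {
  Ya <- as.numeric(Ya)
  Yp <- as.numeric(Yp)
  if (length(Ya) != length(Yp) || length(Ya) < 3L) {
    stop("Ya and Yp must have equal length >= 3")
  }
  if (stats::sd(Ya) == 0 || stats::sd(Yp) == 0) {
    stop("constant input vector; battery undefined")
  }
  r2 <- stats::cor(Ya, Yp)^2
  k <- sum(Ya * Yp) / sum(Yp^2)
  k_prime <- sum(Ya * Yp) / sum(Ya^2)
  r02 <- 1 - sum((Ya - k * Yp)^2) / sum((Ya - mean(Ya))^2)
  r02_prime <- 1 - sum((Yp - k_prime * Ya)^2) / sum((Yp - mean(Yp))^2)
  structure(list(r2 = r2, k = k, k_prime = k_prime, r02 = r02,
                 r02_prime = r02_prime, rm2 = rm_squared(r2, r02),
                 press = sum((Yp - Ya)^2), Ya = Ya, Yp = Yp),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf(paste0("<external_validation: R2 %.3f, k %.3f, k' %.3f, ",
                     "R02 %.3f, R0'2 %.3f, rm2 %.3f>\n"),
              x$r2, x$k, x$k_prime, x$r02, x$r02_prime, x$rm2))
  invisible(x)
}

#' Golbraikh-Tropsha condition table
#'
#' Evaluates the customary external-predictivity conditions (strict
#' inequalities): 1: `R2 > 0.6`; 3a: `0.85 < k < 1.15`; 3b:
#' `0.85 < k' < 1.15`; 4a: `(R2 - R02)/R2 < 0.1`; 4b:
#' `(R2 - R0'2)/R2 < 0.1`; 5: `|R02 - R0'2| < 0.3`; 6: `rm2 > 0.5`.
#' The overall verdict requires 1, (3a or 3b), (4a or 4b), 5 and 6.
#' (Conditions 2a/2b - R02 and R0'2 "close to" R2 - are qualitative;
#' 4a/4b quantify them.)
#'
#' @param report an `external_validation`, or a list providing `r2`, `k`,
#'   `k_prime`, `r02`, `r02_prime`, `rm2` (e.g. printed table values).
#' @param thresholds named list overriding `r2_min` (0.6), `k_lo` (0.85),
#'   `k_hi` (1.15), `rel_max` (0.1), `gap_max` (0.3), `rm2_min` (0.5).
#' @return list with `conditions` (named logical vector: `c1`, `c3a`,
#'   `c3b`, `c4a`, `c4b`, `c5`, `c6`), `values` (the quantities tested)
#'   and `overall` (logical).
#' @export
tropsha_conditions <- function(report, thresholds = list()) {
  th <- utils::modifyList(
    list(r2_min = 0.6, k_lo = 0.85, k_hi = 1.15,
         rel_max = 0.1, gap_max = 0.3, rm2_min = 0.5),
    thresholds
  )
  v <- list(
    r2 = report$r2, k = report$k, k_prime = report$k_prime,
    rel_a = (report$r2 - report$r02) / report$r2,
    rel_b = (report$r2 - report$r02_prime) / report$r2,
    gap = abs(report$r02 - report$r02_prime),
    rm2 = report$rm2
  )
  conditions <- c(
    c1 = v$r2 > th$r2_min,
    c3a = v$k > th$k_lo && v$k < th$k_hi,
    c3b = v$k_prime > th$k_lo && v$k_prime < th$k_hi,
    c4a = v$rel_a < th$rel_max,
    c4b = v$rel_b < th$rel_max,
    c5 = v$gap < th$gap_max,
    c6 = v$rm2 > th$rm2_min
  )
  overall <- conditions[["c1"]] &&
    (conditions[["c3a"]] || conditions[["c3b"]]) &&
    (conditions[["c4a"]] || conditions[["c4b"]]) &&
    conditions[["c5"]] && conditions[["c6"]]
  list(conditions = conditions, values = v, overall = overall)
}

#' Y-randomization (response scrambling) test
#'
#' Shuffles the activity vector `n_shuffles` times (uniform permutations
#' without replacement from a seeded generator), refits the model with the
#' supplied recipe - including re-selection of the component count - and
#' records each scrambled model's q2 and r2. Persistently high scrambled
#' statistics would indicate the real model rests on chance correlation.
#'
#' @param X descriptor matrix or `field_block`.
#' @param y activity vector.
#' @param fit_recipe function `(X, y) -> list(q2 = , r2 = )`; default
#'   runs [loo_q2()] for ONC selection, then [fit_pls()] +
#'   [fit_statistics()] at the ONC, with `max_components` and
#'   `parsimony_tol` below.
#' @param n_shuffles number of scrambles (default 10).
#' @param seed integer seed for the permutations.
#' @param max_components,parsimony_tol passed to the default recipe.
#' @return list of class `y_randomization`: `results` (data.frame shuffle
#'   / q2 / r2), `n_shuffles`, `seed`.
#' @export
y_randomization <- function(X, y, fit_recipe = NULL, n_shuffles = 10L,
                            seed = 1L, max_components = 10L,
                            parsimony_tol = 0.05) {
  if (inherits(X, "field_block")) X <- X$matrix
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (is.null(fit_recipe)) {
    fit_recipe <- function(X, y) {
      cv <- loo_q2(X, y, max_components = max_components,
                   parsimony_tol = parsimony_tol)
      fit <- fit_pls(X, y, cv$onc)
      st <- fit_statistics(fit, X, y)
      list(q2 = cv$q2_onc, r2 = st$r2)
    }
  }
  y <- as.numeric(y)
  perms <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) sample(length(y)))
  })
  rows <- lapply(seq_len(n_shuffles), function(i) {
    res <- tryCatch(fit_recipe(X, y[perms[[i]]]), error = function(e) {
      stop("shuffle ", i, ": ", conditionMessage(e))
    })
    data.frame(shuffle = i, q2 = res$q2, r2 = res$r2)
  })
  structure(list(results = do.call(rbind, rows), n_shuffles = n_shuffles,
                 seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("<y_randomization: %d shuffles, mean q2 %.3f, mean r2 %.3f>\n",
              x$n_shuffles, mean(x$results$q2), mean(x$results$r2)))
  invisible(x)
}
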