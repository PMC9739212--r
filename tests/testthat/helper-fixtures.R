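# Shared builders and independent oracles for the test suite.

# activity table fixture shipped with the package (printed compound series)
activities_path <- function() {
  system.file("extdata", "thq_activities.csv", package = "qsarfield")
}

# tiny rigid 4-atom molecule (non-planar, chiral enough to pin rotations)
toy_mol <- function(id = "toy", shift = c(0, 0, 0)) {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0.3, 0.4, 1.1))
  molecule(id, elements = c("C", "C", "N", "O"),
           coords = sweep(xyz, 2, -shift),
           bonds = rbind(c(1, 2), c(1, 3), c(1, 4)),
           skeleton = 1:4)
}

rotate_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# small correlated regression fixture with known planted structure
toy_xy <- function(n = 8, p = 5, seed = 42, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- 2 * X[, 1] - 1 * X[, 2] + noise * rnorm(n)
  list(X = X, y = y)
}

# ORACLE: leave-one-out PRESS by an explicit refit loop (independent of
# the loo_q2 internals' bookkeeping)
brute_force_loo_press <- function(X, y, ncomp) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    pred <- predict(fit, X[i, , drop = FALSE],
                    ncomp = min(ncomp, fit$n_components))
    press <- press + (pred - y[i])^2
  }
  press
}

# ORACLE: least-squares fitted values via the normal equations on
# centered data (what full-rank PLS must reproduce)
ls_fitted <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  b <- solve(crossprod(Xc), crossprod(Xc, yc))
  as.numeric(mean(y) + Xc %*% b)
}

# ORACLE: direct summation of the through-origin battery definitions
brute_force_battery <- function(Ya, Yp) {
  k <- sum(Ya * Yp) / sum(Yp^2)
  kp <- sum(Ya * Yp) / sum(Ya^2)
  r <- sum((Ya - mean(Ya)) * (Yp - mean(Yp))) /
    sqrt(sum((Ya - mean(Ya))^2) * sum((Yp - mean(Yp))^2))
  r02 <- 1 - sum((Ya - k * Yp)^2) / sum((Ya - mean(Ya))^2)
  r02p <- 1 - sum((Yp - kp * Ya)^2) / sum((Yp - mean(Yp))^2)
  r2 <- r^2
  list(r2 = r2, k = k, k_prime = kp, r02 = r02, r02_prime = r02p,
       rm2 = r2 * (1 - sqrt(max(r2 - r02, 0))))
}

# ORACLE: one hand-coded PEOE sweep sequence (re-derivation independent
# of assign_peoe_charges)
peoe_oracle <- function(elements, bonds, n_iter) {
  par <- list(H = c(7.17, 6.24, -0.56), C = c(7.98, 9.18, 1.88),
              N = c(11.54, 10.82, 1.36), O = c(14.18, 12.92, 1.39))
  q <- numeric(length(elements))
  for (k in seq_len(n_iter)) {
    chi <- vapply(seq_along(q), function(i) {
      p <- par[[elements[i]]]
      p[1] + p[2] * q[i] + p[3] * q[i]^2
    }, numeric(1))
    dvec <- numeric(length(q))
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      lo <- if (chi[i] <= chi[j]) i else j
      hi <- if (chi[i] <= chi[j]) j else i
      chip <- if (elements[lo] == "H") 20.02 else sum(par[[elements[lo]]])
      d <- (chi[hi] - chi[lo]) / chip * 0.5^k
      dvec[lo] <- dvec[lo] + d
      dvec[hi] <- dvec[hi] - d
    }
    q <- q + dvec
  }
  q
}

# ORACLE: contribution-mass contour level by an explicit accumulation loop
level_oracle <- function(values, fraction) {
  v <- sort(values[values != 0])
  total <- sum(abs(v))
  acc <- 0
  for (x in v) {
    acc <- acc + abs(x)
    if (acc / total >= fraction - 1e-12) return(x)
  }
  v[length(v)]
}

# default-condition synthetic set, cached across tests for speed
default_synth <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache) || cache$config$seed != seed) {
      cache <<- generate_set(synthetic_config(seed = seed))
    }
    cache
  }
})

default_fit <- local({
  cache <- NULL
  function(synth) {
    key <- synth$config$seed
    if (is.null(cache) || cache$key != key) {
      cache <<- list(key = key, rec = recovery_check(synth))
    }
    cache$rec
  }
})
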