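# Independent reference implementations used to cross-check the package.
# They deliberately use different algebra from the package code paths.

# PLS1 by the Dayal-MacGregor kernel algorithm: works entirely from X'X
# and X'y with no deflation of X (the package deflates X NIPALS-style).
kernel_pls1_predict <- function(X, y, A, Xnew) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  XtX <- crossprod(Xc)
  b <- as.vector(crossprod(Xc, yc))
  p_ <- ncol(X)
  R <- P <- matrix(0, p_, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- b / sqrt(sum(b^2))
    r <- w
    if (a > 1) for (j in seq_len(a - 1)) r <- r - sum(P[, j] * r) * R[, j]
    tt <- as.numeric(t(r) %*% XtX %*% r)
    p_a <- as.vector(XtX %*% r) / tt
    q_a <- sum(r * b) / tt
    b <- b - tt * q_a * p_a
    R[, a] <- r; P[, a] <- p_a; q[a] <- q_a
  }
  beta <- R %*% q
  ym + as.vector(sweep(Xnew, 2, xm) %*% beta)
}

# Strictly parallel reliability by direct numerical maximisation of the
# Gaussian likelihood (common mean, compound-symmetric covariance).
reliability_ml_oracle <- function(x1, x2) {
  X <- cbind(x1, x2)
  dnorm2 <- function(X, mu, S) {
    Si <- solve(S)
    ld <- as.numeric(determinant(S)$modulus)
    d <- sweep(X, 2, mu)
    -0.5 * (2 * log(2 * pi) + ld + rowSums((d %*% Si) * d))
  }
  nll <- function(par) {
    s2T <- exp(par[2]); s2e <- exp(par[3])
    S <- matrix(c(s2T + s2e, s2T, s2T, s2T + s2e), 2)
    -sum(dnorm2(X, par[1], S))
  }
  start <- c(mean(X), log(stats::var(as.vector(X))),
             log(stats::var(x1 - x2) / 2 + 1e-8))
  o <- stats::optim(start, nll, method = "Nelder-Mead",
                    control = list(maxit = 10000, reltol = 1e-15))
  o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                    control = list(maxit = 10000, reltol = 1e-15))
  s2T <- exp(o$par[2]); s2e <- exp(o$par[3])
  2 * s2T / (2 * s2T + s2e)
}

# small random spectra set on an arbitrary grid
random_spectra_set <- function(n = 4, p = 30, seed = 1,
                               grid = seq(1000, by = 2, length.out = p)) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p, mean = 0.5, sd = 0.1), n, p),
              grid, sprintf("r%02d", seq_len(n)))
}

# tolerance helper: agreement within k units of the value's last printed
# decimal digit (printed tables round their inputs, so exact equality of
# recomputed ratios is not attainable)
expect_printed <- function(computed, printed, digits, k = 1.05) {
  expect_true(all(abs(computed - printed) <= k * 10^(-digits)),
              label = paste0("computed ", paste(round(computed, digits + 2),
                                                collapse = ", "),
                             " vs printed ", paste(printed, collapse = ", ")))
}
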