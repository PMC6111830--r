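# Independent plain-R oracles, kept separate from the package's compiled
# PLS kernel so oracle-equivalence tests exercise two distinct routes.

# NIPALS PLS1 coefficient paths on mean-centered data: returns a p x nlv
# matrix whose column a holds the coefficients using a components, plus the
# centering means.
oracle_pls_path <- function(X, y, nlv) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xa <- sweep(X, 2, xm)
  ya <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, nlv)
  q <- numeric(nlv)
  B <- matrix(0, p, nlv)
  a_done <- 0
  for (a in seq_len(nlv)) {
    w <- drop(crossprod(Xa, ya))
    if (sqrt(sum(w^2)) < 1e-12) break
    w <- w / sqrt(sum(w^2))
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pa <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
    Xa <- Xa - tcrossprod(t, pa)
    ya <- ya - qa * t
    Wa <- W[, 1:a, drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), q[1:a])
    a_done <- a
  }
  if (a_done > 0 && a_done < nlv)
    for (j in (a_done + 1):nlv) B[, j] <- B[, a_done]
  list(beta = B, x_mean = xm, y_mean = ym)
}

# brute-force LOO: refit (oracle route) per left-out sample
oracle_loo_pred <- function(X, y, nlv) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    f <- oracle_pls_path(X[-i, , drop = FALSE], y[-i], nlv)
    pred[i] <- sum((X[i, ] - f$x_mean) * f$beta[, nlv]) + f$y_mean
  }
  pred
}

# brute-force final-NLV choice: enumerate candidates, rescale, arg min
oracle_final_nlv <- function(X, y, max_nlv) {
  k <- min(max_nlv, nrow(X) - 2, ncol(X))
  rmse <- vapply(seq_len(k), function(j)
    sqrt(mean((y - oracle_loo_pred(X, y, j))^2)), numeric(1))
  path <- oracle_pls_path(X, y, k)$beta
  J <- apply(path, 2, function(b) sum(diff(b)^2))
  r01 <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                     else (v - min(v)) / diff(range(v))
  which.min(r01(rmse) + r01(J))
}

# small noiseless synthetic campaign shared by recovery tests
noiseless_params <- function(seed = 11, ...) {
  synthetic_params(noise_sd_additive = 0, noise_sd_multiplicative = 0,
                   seed = seed, ...)
}

# flat-spectrum helper on an arbitrary uniform grid
flat_set <- function(value, wavelengths = 600:800, n = 4) {
  spectrum_set(wavelengths,
               matrix(value, n, length(wavelengths)), kind = "RL")
}
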