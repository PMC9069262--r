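# Independent oracle implementations used to cross-check the package.
# Deliberately written differently from the package code paths: scalar
# arithmetic from genotype category counts, exhaustive searches, naive loops.

# Weir-Cockerham (1984) variance components computed from per-group genotype
# category counts (n0, n1, n2), one plain scalar formula at a time.
oracle_wc_fst <- function(codes_by_group) {
  cnt <- lapply(codes_by_group, function(g) {
    g <- g[!is.na(g)]
    c(n0 = sum(g == 0), n1 = sum(g == 1), n2 = sum(g == 2))
  })
  r <- length(cnt)
  n <- sapply(cnt, sum)
  p <- sapply(cnt, function(x) (2 * x["n2"] + x["n1"]) / (2 * sum(x)))
  h <- sapply(cnt, function(x) x["n1"] / sum(x))
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NaN else a / (a + b + cc))
}

# Exact least-squares monotone (non-decreasing) fit by exhaustive enumeration
# of consecutive-block poolings -- independent of the PAVA routine.
oracle_monotone_fit <- function(y, w) {
  k <- length(y)
  if (k == 1) return(y)
  best <- NULL; best_sse <- Inf
  # enumerate all 2^(k-1) ways to cut the sequence into consecutive blocks
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)
    bounds <- c(0, cuts, k)
    fit <- numeric(k)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (all(diff(fit) >= -1e-12)) {
      sse <- sum(w * (y - fit)^2)
      if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
    }
  }
  best
}

# Brute-force alternating-least-squares ordinal PCA: same loss as
# fit_ordinal_pca but a separate implementation (eigen decomposition instead
# of svd, exhaustive monotone fit instead of PAVA, explicit loops).
oracle_ordinal_als <- function(codes, ndim = 2, tol = 1e-10, max_iter = 2000) {
  n <- nrow(codes); p <- ncol(codes)
  std <- function(x) { x <- x - mean(x); x / sqrt(mean(x^2)) }
  Q <- apply(codes, 2, std)
  lowrank <- function(Q) {
    e <- eigen(crossprod(Q) / n, symmetric = TRUE)
    V <- e$vectors[, 1:ndim, drop = FALSE]
    scores <- Q %*% V                       # n x ndim, var of col k = eig k
    list(eig = e$values, V = V, scores = scores,
         loss = (p - sum(e$values[1:ndim])) / p)
  }
  cur <- lowrank(Q)
  last <- Inf
  for (it in 1:max_iter) {
    Qhat <- cur$scores %*% t(cur$V)         # rank-ndim reconstruction
    for (j in 1:p) {
      cats <- sort(unique(codes[, j]))
      means <- sapply(cats, function(k) mean(Qhat[codes[, j] == k, j]))
      w <- sapply(cats, function(k) sum(codes[, j] == k))
      qc <- oracle_monotone_fit(means, w)
      qj <- qc[match(codes[, j], cats)]
      if (sd(qj) > 0) Q[, j] <- std(qj)
    }
    cur <- lowrank(Q)
    if (abs(last - cur$loss) < tol) break
    last <- cur$loss
  }
  list(eigenvalues = cur$eig[1:ndim], vaf = 100 * cur$eig[1:ndim] / p,
       loss = cur$loss)
}

# Gaussian log-likelihood of an OLS fit with MLE variance, from first
# principles (no logLik()).
oracle_ols_loglik <- function(y, X) {
  fit <- lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

rand_codes <- function(n, p = NULL, f = 0.5) {
  matrix(rbinom(n * (p %||% 1), 2, f), nrow = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
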