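#' Weighted isotonic regression (pool-adjacent-violators)
#'
#' Least-squares monotone non-decreasing fit to `y` with weights `w`.
#' Internal workhorse of the ordinal quantification step.
#'
#' @param y numeric values in category order.
#' @param w positive weights (category counts).
#' @return fitted non-decreasing vector, same length as `y`.
#' @keywords internal
pava <- function(y, w) {
  n <- length(y)
  if (n == 1) return(y)
  v <- y; ww <- w; cnt <- rep(1L, n)
  j <- 1L
  v[1] <- y[1]; ww[1] <- w[1]; cnt[1] <- 1L
  for (i in 2:n) {
    j <- j + 1L
    v[j] <- y[i]; ww[j] <- w[i]; cnt[j] <- 1L
    while (j > 1L && v[j - 1L] > v[j]) {
      v[j - 1L] <- (ww[j - 1L] * v[j - 1L] + ww[j] * v[j]) /
        (ww[j - 1L] + ww[j])
      ww[j - 1L] <- ww[j - 1L] + ww[j]
      cnt[j - 1L] <- cnt[j - 1L] + cnt[j]
      j <- j - 1L
    }
  }
  rep(v[seq_len(j)], cnt[seq_len(j)])
}

#' Ordinal (optimal-scaling) principal component analysis
#'
#' PRINCALS-style alternating least squares PCA for ordered categorical
#' variables, here genotype codes 0 < 1 < 2. Each locus's categories receive
#' numeric quantifications, constrained monotone non-decreasing in category
#' order and standardised to zero mean / unit variance over samples; object
#' scores and loadings come from the SVD of the quantified data. The
#' algorithm alternates (i) per-locus quantification — category means of the
#' current model prediction, projected onto the monotone cone by weighted
#' isotonic regression, then standardised — with (ii) an SVD update of the
#' low-rank model, until the loss (mean squared residual between the
#' quantified matrix and its rank-`n_dim` reconstruction) changes by less
#' than `tol`. With binary loci the monotone constraint is vacuous and the
#' fit coincides with classical PCA of the standardised codes.
#'
#' Missing genotypes are imputed to the locus modal category beforehand
#' (`missing = "modal"`), or samples above `drop_threshold` missingness are
#' removed first (`missing = "drop"`). Loci monomorphic after imputation are
#' dropped with a warning.
#'
#' @param gm a [genotype_matrix()] (or plain matrix of codes).
#' @param n_dim number of components (default 2).
#' @param tol convergence tolerance on the loss (default 1e-8).
#' @param max_iter maximum ALS iterations (default 500).
#' @param missing `"modal"` or `"drop"`.
#' @param drop_threshold per-sample missingness limit for `missing="drop"`.
#' @return object of class `ordinal_pca`: list with `quantifications` (per
#'   locus, named value per category), `object_scores` (samples x n_dim),
#'   `loadings` (loci x n_dim), `eigenvalues`, `vaf_percent`
#'   (eigenvalue / n_loci x 100), `loss_trace`, `n_iter`, `converged`,
#'   `n_loci` (active loci after drops), `dropped_loci`.
#' @export
fit_ordinal_pca <- function(gm, n_dim = 2, tol = 1e-8, max_iter = 500,
                            missing = c("modal", "drop"),
                            drop_threshold = 0.33) {
  missing <- match.arg(missing)
  codes <- if (inherits(gm, "genotype_matrix")) gm$codes else as.matrix(gm)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("L", seq_len(ncol(codes)))
  if (missing == "drop") {
    keep <- rowMeans(is.na(codes)) <= drop_threshold
    codes <- codes[keep, , drop = FALSE]
  }
  # modal imputation (remaining NAs in either policy); ties -> smaller code
  for (j in seq_len(ncol(codes))) {
    nas <- is.na(codes[, j])
    if (any(nas)) {
      tab <- table(codes[!nas, j])
      codes[nas, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  poly <- apply(codes, 2, function(x) length(unique(x)) > 1)
  dropped <- colnames(codes)[!poly]
  if (length(dropped))
    warning("dropping monomorphic locus/loci: ", paste(dropped, collapse = ", "))
  codes <- codes[, poly, drop = FALSE]
  n <- nrow(codes); p <- ncol(codes)
  if (p < 2) stop("need at least 2 polymorphic loci")
  if (n_dim >= p) stop("n_dim must be smaller than the number of loci")

  std <- function(x) {  # zero mean, unit variance with divisor n
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    if (s == 0) return(NULL)
    x / s
  }
  Q <- matrix(0, n, p, dimnames = dimnames(codes))
  for (j in seq_len(p)) Q[, j] <- std(codes[, j])

  rank1_loss <- function(Q) {
    sv <- svd(Q, nu = n_dim, nv = n_dim)
    eig <- sv$d^2 / n
    list(sv = sv, eig = eig,
         loss = (sum(sv$d^2) - sum(sv$d[seq_len(n_dim)]^2)) / (n * p))
  }
  cur <- rank1_loss(Q)
  loss_trace <- cur$loss
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    X <- sqrt(n) * cur$sv$u                      # object scores, X'X = n I
    A <- cur$sv$v %*% diag(cur$sv$d[seq_len(n_dim)] / sqrt(n), n_dim)
    for (j in seq_len(p)) {
      t_j <- X %*% A[j, ]                        # model prediction for locus j
      cats <- sort(unique(codes[, j]))
      means <- vapply(cats, function(k) mean(t_j[codes[, j] == k]), 0)
      w <- vapply(cats, function(k) sum(codes[, j] == k), 0)
      qcat <- pava(means, w)
      qj <- std(qcat[match(codes[, j], cats)])
      if (!is.null(qj)) Q[, j] <- qj             # degenerate: keep previous
    }
    cur <- rank1_loss(Q)
    loss_trace <- c(loss_trace, cur$loss)
    d <- loss_trace[iter] - loss_trace[iter + 1]
    if (abs(d) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  X <- sqrt(n) * cur$sv$u
  A <- cur$sv$v %*% diag(cur$sv$d[seq_len(n_dim)] / sqrt(n), n_dim)
  rownames(X) <- rownames(codes); colnames(X) <- paste0("PC", seq_len(n_dim))
  rownames(A) <- colnames(codes); colnames(A) <- paste0("PC", seq_len(n_dim))
  quants <- lapply(seq_len(p), function(j) {
    cats <- sort(unique(codes[, j]))
    q <- vapply(cats, function(k) Q[which(codes[, j] == k)[1], j], 0)
    stats::setNames(q, cats)
  })
  names(quants) <- colnames(codes)
  structure(list(quantifications = quants, object_scores = X, loadings = A,
                 eigenvalues = cur$eig[seq_len(n_dim)],
                 vaf_percent = 100 * cur$eig[seq_len(n_dim)] / p,
                 loss_trace = loss_trace, n_iter = iter,
                 converged = converged, n_loci = p, dropped_loci = dropped),
            class = "ordinal_pca")
}

#' @exportS3Method base::print
print.ordinal_pca <- function(x, ...) {
  cat(sprintf("ordinal PCA: %d loci, %d dims; VAF%%: %s; %d iter (%s)\n",
              x$n_loci, length(x$eigenvalues),
              paste(sprintf("%.1f", x$vaf_percent), collapse = ", "),
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fix component signs against an anchor locus
#'
#' Component signs are arbitrary under SVD; this flips each dimension so the
#' anchor locus loads positively, making scores comparable across runs and
#' across code polarity flips. If the anchor loads (numerically) zero on a
#' dimension, the locus with the largest absolute loading anchors that
#' dimension instead, with a message.
#'
#' @param fit an [fit_ordinal_pca()] result.
#' @param anchor_locus locus id to anchor on.
#' @return the fit with signs fixed (idempotent).
#' @export
fix_sign <- function(fit, anchor_locus) {
  stopifnot(inherits(fit, "ordinal_pca"))
  j <- match(anchor_locus, rownames(fit$loadings))
  if (is.na(j)) stop("anchor locus not in fit: ", anchor_locus)
  for (d in seq_len(ncol(fit$loadings))) {
    l <- fit$loadings[j, d]
    if (abs(l) < 1e-12) {
      jj <- which.max(abs(fit$loadings[, d]))
      message("anchor loading ~0 on dim ", d, "; anchoring on ",
              rownames(fit$loadings)[jj])
      l <- fit$loadings[jj, d]
    }
    if (l < 0) {
      fit$loadings[, d] <- -fit$loadings[, d]
      fit$object_scores[, d] <- -fit$object_scores[, d]
    }
  }
  fit
}
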