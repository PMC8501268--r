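# Symmetric (parallel-decorrelation) FastICA with the logcosh contrast.
#
# X is channels x samples (here: subjects x edges). Rows are centered,
# the channel covariance is eigendecomposed, the data are whitened down
# to n_comp dimensions, and the orthogonal unmixing matrix is iterated
# with the fixed-point update and symmetric orthogonalization until the
# rotation stabilizes.

sym_orth <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- e$values
  if (min(vals) <= 0) {
    rlang::abort("Unmixing matrix became singular during ICA iteration.")
  }
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

fastica_symm <- function(X, n_comp, seed, alpha = 1, tol = 1e-4,
                         max_iter = 1000) {
  S_ch <- nrow(X); m <- ncol(X)
  if (n_comp > min(S_ch, m)) {
    rlang::abort(sprintf(
      "n_comp = %d exceeds min(channels, samples) = %d.",
      n_comp, min(S_ch, m)))
  }
  Xc <- X - rowMeans(X)
  covm <- tcrossprod(Xc) / m
  e <- eigen(covm, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  if (sum(pos) < n_comp) {
    rlang::abort(sprintf(
      "Data are rank-deficient: only %d informative dimensions for %d requested components.",
      sum(pos), n_comp))
  }
  d <- e$values[seq_len(n_comp)]
  E <- e$vectors[, seq_len(n_comp), drop = FALSE]
  K <- diag(1 / sqrt(d), n_comp) %*% t(E)          # whitening, n_comp x S
  Z <- K %*% Xc                                    # n_comp x m, unit variance rows

  W <- withr::with_seed(seed,
                        matrix(rnorm(n_comp * n_comp), n_comp, n_comp))
  W <- sym_orth(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    WZ <- W %*% Z
    g <- tanh(alpha * WZ)
    gprime_mean <- alpha * rowMeans(1 - g^2)
    W1 <- (g %*% t(Z)) / m - diag(gprime_mean, n_comp) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  sources <- W %*% Z                               # n_comp x m
  mixing <- E %*% diag(sqrt(d), n_comp) %*% t(W)   # S x n_comp
  list(sources = sources, mixing = mixing, converged = converged,
       n_iter = iter)
}
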