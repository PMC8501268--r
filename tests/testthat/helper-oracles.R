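# Independent brute-force oracles, deliberately written without reusing
# any implementation path from the package.

# Benjamini-Hochberg step-up, straight from the definition: sort p,
# q_(i) = min_{j >= i} p_(j) * n / j, map back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) {
      q[i] <- min(q[i], q[i + 1])
    }
  }
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# connected components via explicit depth-first search over an edge list
dfs_components <- function(edges, nodes = sort(unique(c(edges$i, edges$j)))) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges$i[r]); b <- as.character(edges$j[r])
    adj[[a]] <- c(adj[[a]], edges$j[r])
    adj[[b]] <- c(adj[[b]], edges$i[r])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (v in nodes) {
    key <- as.character(v)
    if (seen[key]) next
    cid <- cid + 1L
    stack <- v
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ck <- as.character(cur)
      if (seen[ck]) next
      seen[ck] <- TRUE
      comp[ck] <- cid
      stack <- c(stack, adj[[ck]])
    }
  }
  comp
}

# OLS via the normal equations: beta = (X'X)^-1 X'y, with intercept
ols_oracle <- function(y, X) {
  Xd <- cbind(1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  res <- y - Xd %*% beta
  df <- length(y) - ncol(Xd)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tss <- sum((y - mean(y))^2)
  list(beta = as.numeric(beta), t = as.numeric(beta) / se,
       r_squared = 1 - sum(res^2) / tss, df = df)
}

# pooled-variance two-sample t, closed form
student_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}
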