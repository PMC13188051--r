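# shared helpers: independent oracles and random generators used across files

# brute-force all-pairs shortest paths (Floyd-Warshall) on an edge list;
# independent of the package's BFS implementation
oracle_wiener <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges[k, 1], edges[k, 2]] <- 1
    D[edges[k, 2], edges[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[!is.finite(D)] <- 0
  sum(D) / 2
}

# random connected-ish small graph: a random tree plus a few extra edges
random_graph <- function(n, extra = 1L) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  if (extra > 0L && n > 3L) {
    for (k in seq_len(extra)) {
      pair <- sample.int(n, 2L)
      edges <- rbind(edges, pair)
    }
    edges <- unique(t(apply(edges, 1, sort)))
  }
  edges
}

adjacency_from_edges <- function(n, edges) {
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# OLS via explicit normal equations + explicit hat matrix: the brute-force
# oracle for coefficients, residual SE and leverages
oracle_ols <- function(X, y) {
  Xt <- cbind(1, X)
  XtX <- t(Xt) %*% Xt
  beta <- solve(XtX, t(Xt) %*% y)
  H <- Xt %*% solve(XtX) %*% t(Xt)
  fitted <- drop(Xt %*% beta)
  resid <- y - fitted
  df <- nrow(X) - ncol(X) - 1L
  s <- sqrt(sum(resid^2) / df)
  list(beta = drop(beta), s = s, hat = diag(H), resid = resid, df = df,
       XtX_inv = solve(XtX))
}

oracle_halfwidth <- function(orc, x, alpha = 0.05) {
  xt <- c(1, x)
  h <- drop(t(xt) %*% orc$XtX_inv %*% xt)
  stats::qt(1 - alpha / 2, orc$df) * orc$s * sqrt(1 + h)
}

# descriptor values as a bare numeric vector (attributes stripped)
dval <- function(mol, names) {
  v <- compute_descriptors(mol, names)
  attributes(v) <- NULL
  v
}

random_binary_fp <- function(len = 64L, density = 0.3) {
  on <- which(stats::runif(len) < density) - 1L
  make_fingerprint("hashed_path", 1024L, if (length(on)) on else 0L)
}

# a small random MLR training set (returned as a data frame ready for fit)
random_mlr_data <- function(n = 20L, p = 3L, noise_sd = 0.5) {
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  beta <- c(stats::rnorm(1), stats::rnorm(p))
  y <- drop(cbind(1, X) %*% beta) + stats::rnorm(n, 0, noise_sd)
  list(data = data.frame(X, y = y), X = X, y = y, beta = beta,
       names = colnames(X))
}
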