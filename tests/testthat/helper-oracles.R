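# Independent oracles used to cross-check the package's own implementations.

# Brute-force pair enumeration of the inner-composition-alignment score.
iota_brute <- function(x_l, x_k) {
  M <- length(x_l)
  g <- x_k[order(x_l)]
  inv <- 0
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      if (g[i] > g[j]) inv <- inv + 1L
    }
  }
  1 - inv / (M * (M - 1) / 2)
}

# Accelerated proximal-gradient (FISTA) solver for
# 0.5*||y - X a - b||^2 + penalty*||a||_1 with unpenalised b.
# Independent of the coordinate-descent path it checks.
fista_lasso <- function(y, X, penalty, intercept = TRUE, iters = 20000L) {
  if (intercept) {
    my <- mean(y); mX <- colMeans(X)
    Xc <- sweep(X, 2L, mX); yc <- y - my
  } else {
    Xc <- X; yc <- y; mX <- numeric(ncol(X)); my <- 0
  }
  L <- max(eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) L <- 1
  a <- numeric(ncol(X)); v <- a; th <- 1
  for (i in seq_len(iters)) {
    g <- crossprod(Xc, Xc %*% v - yc)
    a_new <- sign(v - g / L) * pmax(abs(v - g / L) - penalty / L, 0)
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    v <- a_new + ((th - 1) / th_new) * (a_new - a)
    th <- th_new; a <- as.numeric(a_new)
  }
  b <- if (intercept) my - sum(mX * a) else 0
  list(a = a, b = b,
       obj = 0.5 * sum((y - X %*% a - b)^2) + penalty * sum(abs(a)))
}

lasso_objective <- function(y, X, a, b, penalty) {
  if (is.null(b)) b <- 0
  0.5 * sum((y - X %*% a - b)^2) + penalty * sum(abs(a))
}

# Pairwise enumeration AUROC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
auroc_brute <- function(score, truth) {
  off <- !diag(nrow(score))
  s <- score[off]; y <- truth[off]
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Threshold-sweep AUPR: walk distinct scores descending, precision at each
# recall increment (tied scores as one block).
aupr_brute <- function(score, truth) {
  off <- !diag(nrow(score))
  s <- score[off]; y <- truth[off]
  n_pos <- sum(y == 1)
  area <- 0; prev_recall <- 0
  for (thr in sort(unique(s), decreasing = TRUE)) {
    sel <- s >= thr
    precision <- sum(y[sel]) / sum(sel)
    recall <- sum(y[sel]) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Single-regime switching-AR series with a seeded random stable matrix.
single_regime_series <- function(n, T_len, seed, n_edges = n,
                                 noise_mean = 2, noise_var = 0.5,
                                 radius_cap = 0.9) {
  A <- make_random_sparse_stable_matrix(n, n_edges, seed = seed,
                                        radius_cap = radius_cap)
  model <- sar_model(list(A), integer(0), rep(noise_mean, n),
                     diag(noise_var, n))
  list(model = model,
       series = simulate_sar(model, T_len, rep(noise_mean, n),
                             seed = seed + 1000L))
}

# Whitened innovations of a full single-segment RLS pass.
collect_innovations <- function(series, sigma_w, p0 = 1e6, intercept = TRUE) {
  n <- n_genes(series)
  st <- parameter_state(n, intercept = intercept, p0 = p0)
  Z <- matrix(0, n_times(series) - 1L, n)
  for (t in 2:n_times(series)) {
    u <- rls_update(st, series$values[, t - 1L], series$values[, t], sigma_w)
    Z[t - 1L, ] <- u$innovation$z
    st <- u$state
  }
  list(Z = Z, state = st)
}
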