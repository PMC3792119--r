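# Static network inference on a segment, and ranking-based evaluation.
#
# Two per-segment scorers are provided: inner composition alignment (IOTA),
# a rank statistic suited to very short series, and per-target-gene
# L1-penalised autoregression giving signed sparse coefficient estimates.
# Edge rankings are compared against a gold standard by AUROC and AUPR.

#' Inner composition alignment score
#'
#' Directed dependence of `x_k` on `x_l` for short series: sort `x_l`
#' ascending (ties broken by time index, i.e. a stable sort) and reorder
#' `x_k` by the same permutation into `g`; then
#' `tau = 1 - (#inversions of g) / nu` with `nu = M(M-1)/2`, counting a pair
#' `i < j` as an inversion when `g_i > g_j` (exact ties are not crossings).
#' `tau = 1` when the two series are co-monotone, 0 when anti-monotone.
#' Implemented with unit weights; `nu` is the maximum possible number of
#' crossings.
#'
#' @param x_l candidate regulator series (length `M >= 2`).
#' @param x_k candidate target series (same length).
#' @return `tau` in `[0, 1]`.
#' @examples
#' iota_score(c(3, 1, 2), c(5, 7, 9))  # 1/3
#' @export
iota_score <- function(x_l, x_k) {
  M <- length(x_l)
  if (M < 2L) stop_arg("need at least 2 time points")
  if (length(x_k) != M) stop_arg("series lengths differ")
  g <- x_k[order(x_l)]                       # order() is a stable sort
  cmp <- outer(g, g, ">")
  inversions <- sum(cmp[upper.tri(cmp)])
  1 - inversions / (M * (M - 1) / 2)
}

# internal constructor for per-segment networks
new_segment_network <- function(interval, score, method, coefficients = NULL,
                                gene_ids = NULL) {
  if (!is.null(gene_ids)) {
    dimnames(score) <- list(regulator = gene_ids, target = gene_ids)
    if (!is.null(coefficients))
      dimnames(coefficients) <- list(target = gene_ids, regulator = gene_ids)
  }
  structure(
    list(interval = as.integer(interval), score = score, method = method,
         coefficients = coefficients, gene_ids = gene_ids),
    class = "segment_network"
  )
}

#' @export
print.segment_network <- function(x, ...) {
  cat("<segment_network> method =", x$method,
      "| interval [", x$interval[1L], ",", x$interval[2L], "] |",
      sum(x$score > 1e-8) , "scored edges\n")
  invisible(x)
}

#' IOTA network score of a segment
#'
#' Scores every ordered gene pair: entry `(l, k)` of the score matrix is
#' `iota_score(x_l, x_k)`, the evidence that gene `l` regulates gene `k`.
#' The diagonal is fixed at 0 (self-edges are excluded from ranking).
#'
#' @param segment an [expression_series()] of length at least 3.
#' @return a `segment_network` with `method = "iota"`.
#' @export
score_network_iota <- function(segment) {
  stopifnot(inherits(segment, "expression_series"))
  M <- n_times(segment)
  if (M < 3L) stop_arg("segment must have at least 3 time points")
  n <- n_genes(segment)
  X <- segment$values
  score <- matrix(0, n, n)
  for (l in seq_len(n)) {
    ord <- order(X[l, ])
    for (k in seq_len(n)) {
      if (k == l) next
      g <- X[k, ord]
      cmp <- outer(g, g, ">")
      score[l, k] <- 1 - sum(cmp[upper.tri(cmp)]) / (M * (M - 1) / 2)
    }
  }
  new_segment_network(range(segment$time_index), score, "iota",
                      gene_ids = segment$gene_ids)
}

soft_threshold <- function(u, lambda) sign(u) * pmax(abs(u) - lambda, 0)

#' L1-penalised regression for one target gene
#'
#' Minimises `0.5 * ||y - X a - b||^2 + penalty * ||a||_1` by cyclic
#' coordinate descent with soft-thresholding; the offset `b` (present iff
#' `intercept`) is unpenalised. Iteration stops when the largest coefficient
#' change in a sweep falls below `1e-8`, or after `10^4` sweeps.
#'
#' @param target response vector `y` (the target gene at times `2..M`).
#' @param design matrix `X` whose rows are the predecessor samples.
#' @param penalty nonnegative L1 penalty (Lagrangian form).
#' @param intercept fit an unpenalised offset?
#' @param init optional warm-start coefficient vector (length `ncol(design)`).
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep (default `1e-8`; cross-validation uses a looser internal value).
#' @return coefficient vector of length `ncol(design)`, with the fitted
#'   offset in attribute `"offset"`.
#' @export
lasso_fit_gene <- function(target, design, penalty, intercept = TRUE,
                           init = NULL, tol = 1e-8) {
  design <- as.matrix(design)
  if (penalty < 0) stop_arg("penalty must be >= 0")
  if (length(target) != nrow(design)) stop_arg("dimension mismatch")
  p <- ncol(design)
  a <- if (is.null(init)) numeric(p) else {
    if (length(init) != p) stop_arg("init must have length ", p)
    as.numeric(init)
  }
  # an unpenalised offset is equivalent to centring y and the columns of X;
  # centring also removes the dominant shared-mean direction, which keeps
  # the cyclic descent well conditioned on raw expression data
  if (intercept) {
    y_bar <- mean(target)
    x_bar <- colMeans(design)
    target <- target - y_bar
    design <- sweep(design, 2L, x_bar)
  }
  colsq <- colSums(design^2)
  r <- as.numeric(target - design %*% a)
  for (sweep in seq_len(10000L)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (colsq[j] == 0) next
      rho <- sum(design[, j] * r) + colsq[j] * a[j]
      a_new <- soft_threshold(rho, penalty) / colsq[j]
      if (a_new != a[j]) {
        r <- r - design[, j] * (a_new - a[j])
        delta <- max(delta, abs(a_new - a[j]))
        a[j] <- a_new
      }
    }
    if (delta < tol) break
  }
  structure(a, offset = if (intercept) y_bar - sum(x_bar * a) else NULL)
}

# per-segment penalty selection: 5-fold CV on the transition rows over a
# log-spaced grid, MSE pooled across all target genes
cv_lasso_penalty <- function(X_design, Y_targets, intercept,
                             n_folds = 5L, n_grid = 20L) {
  n_rows <- nrow(X_design)
  n_folds <- min(n_folds, n_rows)
  lam_max <- 0
  for (g in seq_len(ncol(Y_targets))) {
    y <- Y_targets[, g]
    lam_max <- max(lam_max, max(abs(crossprod(X_design, y - mean(y)))))
  }
  if (lam_max <= 0) return(0)
  grid <- exp(seq(log(lam_max), log(lam_max * 3e-3), length.out = n_grid))
  folds <- sample(rep_len(seq_len(n_folds), n_rows))
  errs <- matrix(0, n_grid, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    for (g in seq_len(ncol(Y_targets))) {
      a <- NULL
      for (i in seq_len(n_grid)) {
        a <- lasso_fit_gene(Y_targets[tr, g], X_design[tr, , drop = FALSE],
                            grid[i], intercept = intercept, init = a,
                            tol = 1e-5)
        b <- attr(a, "offset")
        pred <- X_design[!tr, , drop = FALSE] %*% a +
          if (is.null(b)) 0 else b
        errs[i, f] <- errs[i, f] + mean((Y_targets[!tr, g] - pred)^2)
      }
    }
  }
  grid[which.min(rowMeans(errs))]
}

#' Sparse autoregressive network of a segment
#'
#' For each target gene `g`, regresses `x_g(t+1)` on the full expression
#' vector `x(t)` over the segment's transitions with an L1 penalty
#' ([lasso_fit_gene()]); the rows of the coefficient matrix are the
#' independent per-gene solutions. The score for the directed edge
#' `l -> k` is `|coefficients[k, l]|`; signs are kept in `coefficients` to
#' report activation versus repression.
#'
#' @param segment an [expression_series()] of length at least 3.
#' @param penalty a nonnegative number, or `"cv"` to pick one penalty for
#'   the whole segment by 5-fold cross-validation over a log grid (uses the
#'   current RNG stream for fold assignment).
#' @param intercept fit unpenalised per-gene offsets?
#' @param warm_start optional `n x n` coefficient matrix (e.g. from the
#'   previous segment) used to initialise each row's coordinate descent.
#' @return a `segment_network` with `method = "lasso"`, carrying both the
#'   absolute `score` matrix and the signed `coefficients`.
#' @export
infer_network_lasso <- function(segment, penalty = "cv", intercept = TRUE,
                                warm_start = NULL) {
  stopifnot(inherits(segment, "expression_series"))
  M <- n_times(segment)
  if (M < 3L) stop_arg("segment must have at least 3 time points")
  n <- n_genes(segment)
  X <- segment$values
  X_design <- t(X[, seq_len(M - 1L), drop = FALSE])
  Y_targets <- t(X[, 2:M, drop = FALSE])
  if (identical(penalty, "cv")) {
    penalty <- cv_lasso_penalty(X_design, Y_targets, intercept)
  } else if (!is.numeric(penalty) || penalty < 0) {
    stop_arg("penalty must be a nonnegative number or \"cv\"")
  }
  coefs <- matrix(0, n, n)
  for (g in seq_len(n)) {
    init <- if (!is.null(warm_start)) warm_start[g, ] else NULL
    a <- lasso_fit_gene(Y_targets[, g], X_design, penalty,
                        intercept = intercept, init = init)
    coefs[g, ] <- as.numeric(a)
  }
  score <- t(abs(coefs))          # score[l, k] = |coef of regulator l on k|
  score[abs(score) < 1e-8] <- 0
  diag(score) <- 0
  net <- new_segment_network(range(segment$time_index), score, "lasso",
                             coefficients = coefs,
                             gene_ids = segment$gene_ids)
  net$penalty <- penalty
  net
}

# shared validation for the two ranking metrics
ranking_pairs <- function(score, truth) {
  score <- as.matrix(score)
  truth <- as.matrix(truth)
  if (!all(dim(score) == dim(truth)) || nrow(score) != ncol(score))
    stop_arg("score and truth must be square matrices of equal size")
  off <- !diag(nrow(score))
  s <- score[off]
  y <- truth[off]
  if (!all(y %in% c(0, 1))) stop_arg("truth must be binary")
  if (all(y == 1) || all(y == 0))
    stop_arg("truth must contain at least one positive and one negative ",
             "off-diagonal candidate")
  list(s = s, y = y)
}

#' Area under the ROC curve of an edge ranking
#'
#' Mann-Whitney form: the fraction of (true edge, non-edge) candidate pairs
#' in which the true edge scores higher, ties counting one half. Diagonal
#' entries are excluded from the candidate set.
#'
#' @param score `n x n` score matrix (higher = stronger edge evidence).
#' @param truth `n x n` binary gold-standard adjacency.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, truth) {
  pr <- ranking_pairs(score, truth)
  r <- rank(pr$s)                    # average ranks handle ties as 1/2
  n_pos <- sum(pr$y == 1)
  n_neg <- sum(pr$y == 0)
  (sum(r[pr$y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Steps through descending score thresholds, processing tied scores as one
#' block, and accumulates `precision * recall-increment` — the area under
#' the precision-recall step curve.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(score, truth) {
  pr <- ranking_pairs(score, truth)
  o <- order(pr$s, decreasing = TRUE)
  s <- pr$s[o]
  y <- pr$y[o]
  n_pos <- sum(y == 1)
  blocks <- cumsum(!duplicated(s))       # tied scores share a block id
  tp <- cumsum(y)
  count <- seq_along(y)
  last <- which(blocks != c(blocks[-1L], -1L))  # last index of each block
  recall <- tp[last] / n_pos
  precision <- tp[last] / count[last]
  sum(diff(c(0, recall)) * precision)
}
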