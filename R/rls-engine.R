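# RLS-as-Kalman parameter recursion and the innovation-whiteness machinery.
#
# A fixed-coefficient vector AR(1) model x(t+1) = A x(t) + w(t) is rewritten
# in state-space form with constant state theta = vec(A) (column-stacked)
# and observation matrix C(t) = x(t)' %x% I_n, so that C(t) theta = A x(t).
# Kalman filtering of this system coincides with recursive least squares,
# and its innovation sequence is white exactly when the data really are
# generated by a single fixed A.  Whitened innovations are standard normal
# under that null, so the cumulative sum of their squares is chi-square
# distributed — the statistic the change-point detector monitors.

#' Regressor matrix of the stacked-parameter form
#'
#' Builds `C = x' %x% I_n` so that `C %*% vec(A) = A %*% x` for any `n x n`
#' matrix `A` (columns stacked). With `intercept = TRUE` the columns
#' `1 %x% I_n` are appended, so the last `n` parameters act as an additive
#' offset vector; the offset absorbs a nonzero noise mean so that
#' innovations are zero-mean under the no-switch null.
#'
#' @param x numeric vector, the current expression sample (length `n`).
#' @param intercept logical; append the offset block?
#' @return numeric matrix `n x n*(n + b)` with `b = 0` or `1`.
#' @examples
#' build_regressor(c(1, 2), intercept = FALSE)
#' @export
build_regressor <- function(x, intercept = TRUE) {
  n <- length(x)
  if (n < 1L) stop_arg("x must be non-empty")
  C <- kronecker(t(x), diag(n))
  if (intercept) C <- cbind(C, diag(n))
  C
}

#' RLS/Kalman parameter state
#'
#' The running estimate `theta_hat` of the stacked AR coefficients (plus the
#' optional offset block) and its covariance `P`. The diffuse initialisation
#' `theta_hat = 0`, `P = p0 * I` with large `p0` makes the recursion
#' converge to batch least squares.
#'
#' @param n_genes number of genes `n`.
#' @param intercept logical; include the offset block?
#' @param p0 initial parameter variance (scalar), or a full initial
#'   covariance matrix of the correct dimension.
#' @return an object of class `parameter_state`.
#' @export
parameter_state <- function(n_genes, intercept = TRUE, p0 = 1e6) {
  d <- n_genes * (n_genes + as.integer(intercept))
  P <- if (is.matrix(p0)) {
    if (nrow(p0) != d || ncol(p0) != d)
      stop_arg("initial covariance must be ", d, "x", d)
    p0
  } else {
    if (p0 <= 0) stop_arg("p0 must be positive")
    diag(p0, d)
  }
  structure(
    list(theta_hat = numeric(d), P = P, n_updates = 0L,
         n_genes = as.integer(n_genes), intercept = isTRUE(intercept)),
    class = "parameter_state"
  )
}

#' Coefficient matrix held by a parameter state
#'
#' Unstacks `theta_hat` into the `n x n` matrix `A` and, when the state has
#' an intercept block, the offset vector.
#'
#' @param state a [parameter_state()].
#' @return list with elements `A` (matrix) and `offset` (vector or `NULL`).
#' @export
state_coefficients <- function(state) {
  n <- state$n_genes
  A <- matrix(state$theta_hat[seq_len(n * n)], n, n)
  offset <- if (state$intercept) state$theta_hat[n * n + seq_len(n)] else NULL
  list(A = A, offset = offset)
}

#' One RLS/Kalman update with innovation
#'
#' Performs the measurement update for the transition `x_t -> x_next`:
#' with `C = build_regressor(x_t)`,
#' `e = x_next - C theta`, `S = C P C' + Sigma_w`, `K = P C' S^{-1}`,
#' `theta' = theta + K e`, `P' = (I - K C) P` (re-symmetrised). The returned
#' innovation carries `e`, its predicted covariance `S`, and the whitened
#' innovation `z = L^{-1} e` (`L` the lower Cholesky factor of `S`) computed
#' from the pre-update state.
#'
#' @param state a [parameter_state()].
#' @param x_t regressor sample (length `n`).
#' @param x_next predicted sample (length `n`).
#' @param sigma_w noise covariance `Sigma_w`, symmetric PSD `n x n`.
#' @return list with elements `state` (updated [parameter_state()]) and
#'   `innovation` (fields `e`, `S`, `z`).
#' @export
rls_update <- function(state, x_t, x_next, sigma_w) {
  stopifnot(inherits(state, "parameter_state"))
  n <- state$n_genes
  if (length(x_t) != n || length(x_next) != n)
    stop_arg("samples must have length ", n)
  sigma_w <- as.matrix(sigma_w)
  if (nrow(sigma_w) != n || ncol(sigma_w) != n)
    stop_arg("sigma_w must be ", n, "x", n)
  C <- build_regressor(x_t, state$intercept)
  PCt <- state$P %*% t(C)
  S <- C %*% PCt + sigma_w
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(sum(diag(S)), .Machine$double.xmin))
    stop("innovation covariance numerically singular (min eigenvalue ",
         format(min(ev)), "); check for constant genes or supply a ridge",
         call. = FALSE)
  e <- as.numeric(x_next - C %*% state$theta_hat)
  R <- chol(S)
  z <- as.numeric(forwardsolve(t(R), e))
  K <- PCt %*% chol2inv(R)
  theta_new <- state$theta_hat + as.numeric(K %*% e)
  P_new <- state$P - K %*% t(PCt)
  P_new <- (P_new + t(P_new)) / 2
  state$theta_hat <- theta_new
  state$P <- P_new
  state$n_updates <- state$n_updates + 1L
  list(state = state,
       innovation = list(e = e, S = S, z = z))
}

#' Whiten an innovation
#'
#' `z = L^{-1} e` with `L` the lower Cholesky factor of `S`; under the
#' no-switch null `z` has zero mean and unit covariance, and
#' `z'z = e' S^{-1} e`.
#'
#' @param e innovation vector.
#' @param S its covariance, symmetric positive definite.
#' @return whitened innovation vector.
#' @export
normalize_innovation <- function(e, S) {
  S <- as.matrix(S)
  if (length(e) != nrow(S)) stop_arg("dimension mismatch")
  R <- tryCatch(chol(S),
                error = function(err) stop("S is not positive definite",
                                           call. = FALSE))
  as.numeric(forwardsolve(t(R), e))
}

#' Cumulative whiteness statistic
#'
#' `Q = sum_i z_i' z_i` over the whitened innovations collected since the
#' current segment start. Under the no-switch null each component of each
#' `z_i` is independent standard normal, so `Q` is chi-square with
#' `dof = n * m` degrees of freedom, `m` the number of innovations.
#'
#' @param z_list list of whitened-innovation vectors (all length `n`), or a
#'   `n x m` matrix with one innovation per column.
#' @return list with elements `Q` and `dof`.
#' @export
q_statistic <- function(z_list) {
  if (is.matrix(z_list)) z_list <- asplit(z_list, 2L)
  if (length(z_list) == 0L) stop_arg("z_list must be non-empty")
  n <- length(z_list[[1L]])
  Q <- sum(vapply(z_list, function(z) sum(z^2), numeric(1)))
  list(Q = Q, dof = n * length(z_list))
}

#' Chi-square detection threshold
#'
#' The `(1 - alpha)` quantile of the chi-square distribution: while the
#' cumulative statistic stays below it, the hypothesis that all data since
#' the segment start were generated by the same sub-network cannot be
#' rejected at confidence level `alpha`.
#'
#' @param alpha significance level in `(0, 1)`.
#' @param dof degrees of freedom, `>= 1`.
#' @return the threshold.
#' @export
chi2_threshold <- function(alpha, dof) {
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  if (any(dof < 1)) stop_arg("dof must be >= 1")
  stats::qchisq(1 - alpha, df = dof)
}

#' Noise-covariance estimation by forgetting-factor RLS
#'
#' Runs weighted recursive least squares over the whole series with
#' forgetting factor `lambda`:
#' `K = P C' (lambda I_n + C P C')^{-1}`, `theta' = theta + K r`,
#' `P' = (I - K C) P / lambda`, starting from `theta = 0`, `P = p0 I`.
#' The a-priori residuals `r(t) = x(t+1) - C(t) theta_hat(t-1)` for
#' `t > burn_in` are pooled and their centred sample covariance (divisor
#' `count - 1`) is returned as the estimate of `Sigma_w`. Exponential
#' forgetting lets the local linear fit track slow parameter drift, so the
#' residual covariance reflects the driving noise rather than regime
#' differences.
#'
#' @param series an [expression_series()].
#' @param lambda forgetting factor in `(0, 1]`; 0.95-0.99 is the usual
#'   range, default 0.98.
#' @param p0 initial parameter variance (large).
#' @param burn_in residuals with index `t <= burn_in` are excluded from the
#'   covariance (the diffuse start makes them meaningless).
#' @param intercept include the offset block in the regression?
#' @return object of class `noise_estimate` with fields `sigma_hat`,
#'   `residuals` (rows are `r(t)`, `t = burn_in+1 .. T-1`), `lambda`,
#'   `burn_in`.
#' @export
estimate_noise_covariance <- function(series, lambda = 0.98, p0 = 1e6,
                                      burn_in = 5L, intercept = TRUE) {
  stopifnot(inherits(series, "expression_series"))
  if (lambda <= 0 || lambda > 1) stop_arg("lambda must be in (0, 1]")
  n <- n_genes(series)
  T_len <- n_times(series)
  if (T_len < burn_in + 2L)
    stop_arg("series too short for burn_in = ", burn_in)
  n_resid <- T_len - 1L - burn_in
  if (n_resid < n + 2L)
    stop_arg("need at least ", n + 2L, " residuals after burn-in, have ",
             n_resid)
  X <- series$values
  state <- parameter_state(n, intercept = intercept, p0 = p0)
  resid <- matrix(NA_real_, T_len - 1L, n)
  I_n <- diag(n)
  for (t in seq_len(T_len - 1L)) {
    C <- build_regressor(X[, t], intercept)
    r_t <- as.numeric(X[, t + 1L] - C %*% state$theta_hat)
    resid[t, ] <- r_t
    PCt <- state$P %*% t(C)
    S_f <- lambda * I_n + C %*% PCt
    K <- PCt %*% solve((S_f + t(S_f)) / 2)
    state$theta_hat <- state$theta_hat + as.numeric(K %*% r_t)
    P_new <- (state$P - K %*% t(PCt)) / lambda
    state$P <- (P_new + t(P_new)) / 2
  }
  kept <- resid[(burn_in + 1L):(T_len - 1L), , drop = FALSE]
  sigma_hat <- stats::cov(kept)
  sigma_hat <- (sigma_hat + t(sigma_hat)) / 2
  structure(
    list(sigma_hat = sigma_hat, residuals = kept, lambda = lambda,
         burn_in = as.integer(burn_in), final_state = state),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat("<noise_estimate> lambda =", x$lambda, "| burn_in =", x$burn_in,
      "|", nrow(x$residuals), "residuals\n")
  print(signif(x$sigma_hat, 4))
  invisible(x)
}

#' Batch least-squares AR fit
#'
#' Ordinary least squares for `x(t+1) = A x(t) + b` over the transitions in
#' `[t_start, t_end]`, solved through the Moore-Penrose pseudo-inverse so an
#' underdetermined design yields the minimum-norm solution. Serves as the
#' offline counterpart of the RLS recursion (equal in the diffuse limit
#' `p0 -> Inf` with isotropic noise).
#'
#' @param series an [expression_series()].
#' @param t_start,t_end inclusive column range; `t_end - t_start >= 1`.
#' @param intercept include an offset column?
#' @return `n x (n + b)` matrix: the estimate of `A`, with the offset as a
#'   final column named `"(offset)"` when `intercept` is `TRUE`.
#' @export
batch_least_squares <- function(series, t_start = 1L,
                                t_end = n_times(series), intercept = TRUE) {
  stopifnot(inherits(series, "expression_series"))
  if (t_end - t_start < 1L) stop_arg("need at least one transition")
  if (t_start < 1L || t_end > n_times(series)) stop_arg("range out of bounds")
  X <- series$values
  D <- t(X[, t_start:(t_end - 1L), drop = FALSE])
  if (intercept) D <- cbind(D, 1)
  Y <- t(X[, (t_start + 1L):t_end, drop = FALSE])
  B <- MASS::ginv(D) %*% Y          # (n + b) x n
  est <- t(B)                       # n x (n + b)
  rownames(est) <- series$gene_ids
  colnames(est) <- c(series$gene_ids, if (intercept) "(offset)")
  est
}
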