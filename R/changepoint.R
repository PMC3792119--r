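# Sequential change-point detection by monitoring innovation whiteness.
#
# Monitoring starts at the current segment start with a fresh diffuse
# parameter state.  Every new sample is predicted by the RLS/Kalman
# recursion, the whitened innovation is accumulated, and once enough
# innovations exist the cumulative statistic Q is compared with the
# chi-square (1 - alpha) quantile at n*m degrees of freedom.  The first
# exceedance is recorded as a change point, monitoring restarts there, and
# the procedure continues until the data are exhausted.  Cost is linear in
# the series length and independent of how many change points are found.

#' Detection configuration
#'
#' @param alpha confidence parameter of the chi-square test, in `(0, 1)`.
#' @param p0 initial parameter variance of the diffuse RLS start.
#' @param min_innovations smallest number of whitened innovations before the
#'   statistic is tested; must be at least 3.
#' @param sigma_w either the known `n x n` noise covariance, or the string
#'   `"estimate"` to estimate it from the full series first (forgetting
#'   factor RLS, see [estimate_noise_covariance()]).
#' @param intercept include the additive offset block in the regression so a
#'   nonzero noise mean does not inflate the statistic (default `TRUE`).
#' @param ridge nonnegative scalar added as `ridge * I` to `sigma_w` for
#'   robustness against near-constant genes in real data; 0 for simulations.
#' @param noise_lambda,noise_burn_in forwarded to
#'   [estimate_noise_covariance()] when `sigma_w = "estimate"`.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.05, p0 = 1e6, min_innovations = 3L,
                             sigma_w = "estimate", intercept = TRUE,
                             ridge = 0, noise_lambda = 0.98,
                             noise_burn_in = 5L) {
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  if (p0 <= 0) stop_arg("p0 must be positive")
  if (min_innovations < 3L) stop_arg("min_innovations must be >= 3")
  if (ridge < 0) stop_arg("ridge must be >= 0")
  structure(
    list(alpha = alpha, p0 = p0, min_innovations = as.integer(min_innovations),
         sigma_w = sigma_w, intercept = isTRUE(intercept), ridge = ridge,
         noise_lambda = noise_lambda, noise_burn_in = as.integer(noise_burn_in)),
    class = "detection_config"
  )
}

#' Detect regime change points
#'
#' Sequential detection procedure: monitor the series from the current
#' segment start `t0` with a fresh diffuse parameter state; for each
#' predicted sample `t > t0` run one RLS/Kalman update against `sigma_w`,
#' whiten the innovation, and once at least `min_innovations` innovations
#' have accumulated compare `Q = sum z'z` with the chi-square
#' `(1 - alpha)` quantile at `n * m` degrees of freedom. When `Q` exceeds
#' the threshold, `t` is recorded as a change point and becomes the start of
#' the next monitoring window (the change sample is the new regime's first
#' sample). The reported change point is the raw first-exceedance index; no
#' retrospective refinement is applied.
#'
#' @param series an [expression_series()].
#' @param config a [detection_config()].
#' @return object of class `change_point_result`: fields `change_points`
#'   (integer vector), `q_trace` (data frame with columns `t`, `m`, `Q`,
#'   `dof`, `threshold`, `tested`, `exceeded`), `segments` (data frame with
#'   columns `start`, `end` partitioning `1..T`), `sigma_w` (the matrix
#'   actually used) and `config`.
#' @export
detect_change_points <- function(series, config = detection_config()) {
  stopifnot(inherits(series, "expression_series"),
            inherits(config, "detection_config"))
  n <- n_genes(series)
  T_len <- n_times(series)
  if (T_len < config$min_innovations + 2L)
    stop_arg("series has ", T_len, " samples; need at least ",
             config$min_innovations + 2L)
  sigma <- config$sigma_w
  if (is.character(sigma) && identical(sigma, "estimate")) {
    sigma <- estimate_noise_covariance(
      series, lambda = config$noise_lambda, p0 = config$p0,
      burn_in = config$noise_burn_in, intercept = config$intercept)$sigma_hat
  }
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != n || ncol(sigma) != n)
    stop_arg("sigma_w must be ", n, "x", n)
  if (config$ridge > 0) sigma <- sigma + diag(config$ridge, n)

  X <- series$values
  cps <- integer(0)
  trace_rows <- vector("list", T_len)
  t0 <- 1L
  state <- parameter_state(n, intercept = config$intercept, p0 = config$p0)
  z_sq <- numeric(0)                       # per-innovation z'z since t0
  t <- t0 + 1L
  while (t <= T_len) {
    upd <- rls_update(state, X[, t - 1L], X[, t], sigma)
    z_sq <- c(z_sq, sum(upd$innovation$z^2))
    m <- length(z_sq)
    Q <- sum(z_sq)
    dof <- n * m
    tested <- m >= config$min_innovations
    thr <- chi2_threshold(config$alpha, dof)
    exceeded <- tested && Q > thr
    trace_rows[[t]] <- data.frame(t = t, m = m, Q = Q, dof = dof,
                                  threshold = thr, tested = tested,
                                  exceeded = exceeded)
    if (exceeded) {
      cps <- c(cps, t)
      t0 <- t
      state <- parameter_state(n, intercept = config$intercept, p0 = config$p0)
      z_sq <- numeric(0)
      t <- t0 + 1L
    } else {
      state <- upd$state
      t <- t + 1L
    }
  }
  q_trace <- do.call(rbind, trace_rows[!vapply(trace_rows, is.null, TRUE)])
  rownames(q_trace) <- NULL
  structure(
    list(change_points = cps, q_trace = q_trace,
         segments = segments_from_change_points(cps, T_len),
         sigma_w = sigma, config = config),
    class = "change_point_result"
  )
}

segments_from_change_points <- function(change_points, T_len) {
  starts <- c(1L, as.integer(change_points))
  ends <- c(as.integer(change_points) - 1L, T_len)
  data.frame(start = starts, end = ends)
}

#' @export
print.change_point_result <- function(x, ...) {
  cat("<change_point_result>\n")
  if (length(x$change_points)) {
    cat("  change points:", paste(x$change_points, collapse = ", "), "\n")
  } else {
    cat("  no change points detected\n")
  }
  cat("  segments:\n")
  apply(x$segments, 1L, function(s)
    cat("    [", s[["start"]], ",", s[["end"]], "]\n"))
  invisible(x)
}

#' Split a series at change points
#'
#' Returns the `K + 1` sub-series over `[1, c1 - 1], [c1, c2 - 1], ...,
#' [cK, T]`: each change point starts its segment. Gene identifiers and the
#' original time labels are preserved, so concatenating the returned
#' segments reproduces the input series exactly.
#'
#' @param series an [expression_series()].
#' @param change_points strictly increasing integers in `(1, T]`; empty for
#'   a single segment.
#' @return list of `expression_series` segments.
#' @export
segment_series <- function(series, change_points) {
  stopifnot(inherits(series, "expression_series"))
  T_len <- n_times(series)
  change_points <- as.integer(change_points)
  if (length(change_points)) {
    if (any(diff(change_points) <= 0L))
      stop_arg("change points must be strictly increasing")
    if (min(change_points) < 2L || max(change_points) > T_len)
      stop_arg("change points must lie in (1, T]")
  }
  segs <- segments_from_change_points(change_points, T_len)
  lapply(seq_len(nrow(segs)), function(k) {
    idx <- segs$start[k]:segs$end[k]
    new_expression_series(series$values[, idx, drop = FALSE],
                          series$gene_ids, series$time_index[idx])
  })
}
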