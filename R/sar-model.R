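# Switching autoregressive (SAR) data model and synthetic benchmark designs.
#
# The observation model is a first-order vector autoregression whose
# coefficient matrix switches among a finite set A_1, ..., A_K at unknown
# change points:
#
#   x(t) = A_{r(t)} x(t-1) + w(t-1),   w ~ iid N(mu, Sigma_w),
#
# where r(t) is the regime governing sample t.  A change point is the first
# sample index generated under a new coefficient matrix; time indices are
# 1-based and inclusive throughout.

# internal constructor: skips the length check so segment views of an
# existing series (possibly short tails) keep the class
new_expression_series <- function(values, gene_ids, time_index) {
  rownames(values) <- gene_ids
  colnames(values) <- paste0("t", time_index)
  structure(
    list(gene_ids = gene_ids, values = values, time_index = time_index),
    class = "expression_series"
  )
}

#' Gene-expression time series
#'
#' Container for a genes-by-time numeric matrix with unique gene identifiers
#' and an ordered, 1-based time index. This is the universal input of the
#' package: the simulator produces it, the change-point detector and the
#' per-segment network inference consume it.
#'
#' @param values numeric matrix, `n_genes x T`, all entries finite.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the rownames of `values`, or `G1..Gn` when absent.
#' @return An object of class `expression_series` with fields `gene_ids`,
#'   `values` and `time_index`.
#' @examples
#' es <- expression_series(matrix(rnorm(12), 3, 4))
#' n_genes(es); n_times(es)
#' @export
expression_series <- function(values, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_arg("expression values must be numeric")
  n <- nrow(values)
  T_len <- ncol(values)
  if (n < 1L) stop_arg("need at least one gene")
  if (T_len < 3L) stop_arg("need at least 3 time points, got ", T_len)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_arg("non-finite expression value at gene row ", bad[1L],
             ", time column ", bad[2L])
  }
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(n))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n) stop_arg("gene_ids length must equal nrow(values)")
  if (anyDuplicated(gene_ids)) stop_arg("gene_ids must be unique")
  new_expression_series(values, gene_ids, seq_len(T_len))
}

#' @export
print.expression_series <- function(x, ...) {
  cat("<expression_series> ", n_genes(x), " genes x ", n_times(x),
      " time points [", x$time_index[1L], "..",
      x$time_index[n_times(x)], "]\n", sep = "")
  invisible(x)
}

#' @rdname expression_series
#' @param x an `expression_series`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_series
#' @export
n_times <- function(x) ncol(x$values)

#' Switching autoregressive model
#'
#' Ground-truth description of a piecewise-stationary vector AR(1) process:
#' an ordered list of `n x n` system matrices, the change points at which
#' the active matrix switches (each change point is the first sample index
#' generated under the new matrix), and the Gaussian noise mean and
#' covariance shared by all regimes.
#'
#' @param matrices list of `K` square numeric matrices, all `n x n`.
#' @param change_points strictly increasing integer vector of length `K - 1`,
#'   each in `(1, T]`.
#' @param noise_mean numeric vector of length `n`.
#' @param noise_cov symmetric positive-semidefinite `n x n` matrix.
#' @return An object of class `sar_model`.
#' @export
sar_model <- function(matrices, change_points, noise_mean, noise_cov) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop_arg("matrices must be a non-empty list")
  matrices <- lapply(matrices, as.matrix)
  n <- length(noise_mean)
  for (A in matrices) {
    if (nrow(A) != n || ncol(A) != n)
      stop_arg("every system matrix must be ", n, "x", n)
  }
  change_points <- as.integer(change_points)
  if (length(change_points) != length(matrices) - 1L)
    stop_arg("need one more matrix than change points")
  if (length(change_points) > 0L) {
    if (any(diff(change_points) <= 0L) || any(change_points < 2L))
      stop_arg("change points must be strictly increasing integers > 1")
  }
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != n || ncol(noise_cov) != n)
    stop_arg("noise_cov must be ", n, "x", n)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop_arg("noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop_arg("noise_cov must be positive semidefinite")
  structure(
    list(matrices = matrices, change_points = change_points,
         noise_mean = as.numeric(noise_mean), noise_cov = noise_cov),
    class = "sar_model"
  )
}

#' @export
print.sar_model <- function(x, ...) {
  cat("<sar_model> ", length(x$noise_mean), " genes, ",
      length(x$matrices), " regime(s)", sep = "")
  if (length(x$change_points))
    cat(", change points:", paste(x$change_points, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Regime label of each sample
#'
#' Regime `k + 1` begins at the `k`-th change point, so `r(t) = k` exactly
#' for `t` in `[c_{k-1}, c_k - 1]` with `c_0 = 1` and `c_K = T + 1`. The
#' labels partition `1..T` with no overlap.
#'
#' @param change_points strictly increasing integers in `(1, T]`.
#' @param T_len series length.
#' @return integer vector of length `T_len` with values in `1..K`.
#' @export
regime_index <- function(change_points, T_len) {
  bounds <- c(1L, as.integer(change_points), T_len + 1L)
  rep.int(seq_len(length(bounds) - 1L), diff(bounds))
}

#' Random sparse stable system matrix
#'
#' Draws exactly `n_edges` nonzero entries at uniformly chosen positions of
#' an `n x n` matrix, with values sampled from +/- Uniform(0.3, 1.0), then
#' rescales the matrix so its spectral radius equals
#' `min(original radius, radius_cap)`. Capping the radius below 1 keeps
#' simulated trajectories bounded without letting them die out over the
#' short horizons used in the benchmarks.
#'
#' @param n matrix dimension.
#' @param n_edges number of nonzero entries, in `1..n^2`.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @param radius_cap spectral-radius bound in `(0, 1)`.
#' @return an `n x n` numeric matrix.
#' @export
make_random_sparse_stable_matrix <- function(n, n_edges, seed = NULL,
                                             radius_cap = 0.95) {
  if (n < 1L) stop_arg("n must be >= 1")
  if (n_edges < 1L || n_edges > n * n)
    stop_arg("n_edges must be in 1..n^2 = ", n * n)
  if (radius_cap <= 0 || radius_cap >= 1)
    stop_arg("radius_cap must be in (0, 1)")
  with_seed(seed, {
    A <- matrix(0, n, n)
    pos <- sample.int(n * n, n_edges)
    A[pos] <- sample(c(-1, 1), n_edges, replace = TRUE) *
      stats::runif(n_edges, 0.3, 1.0)
    rho <- max(abs(eigen(A, only.values = TRUE)$values))
    if (rho > radius_cap) A <- A * (radius_cap / rho)
    A
  })
}

#' Simulate a switching AR series
#'
#' Generates `x(1) = x1` and, for `t >= 2`,
#' `x(t) = A_{r(t)} x(t-1) + w(t-1)` with `w ~ iid N(noise_mean, noise_cov)`
#' and `r(t)` the regime labels of [regime_index()]. The sample at a change
#' point is thus the first one produced by the new regime's dynamics applied
#' to the last sample of the old regime.
#'
#' @param model a [sar_model()].
#' @param T_len number of samples to generate; must be at least
#'   `max(change_points)`.
#' @param x1 initial state, length `n`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an [expression_series()].
#' @export
simulate_sar <- function(model, T_len, x1, seed = NULL) {
  stopifnot(inherits(model, "sar_model"))
  n <- length(model$noise_mean)
  if (length(x1) != n) stop_arg("x1 must have length ", n)
  if (length(model$change_points) && T_len < max(model$change_points))
    stop_arg("T_len must be >= max(change_points)")
  if (T_len < 3L) stop_arg("T_len must be >= 3")
  r <- regime_index(model$change_points, T_len)
  with_seed(seed, {
    W <- MASS::mvrnorm(T_len - 1L, mu = model$noise_mean,
                       Sigma = model$noise_cov)
    W <- matrix(W, nrow = T_len - 1L)   # mvrnorm drops to vector when n = 1
    X <- matrix(0, n, T_len)
    X[, 1L] <- x1
    for (t in 2:T_len) {
      X[, t] <- model$matrices[[r[t]]] %*% X[, t - 1L] + W[t - 1L, ]
    }
    expression_series(X, paste0("G", seq_len(n)))
  })
}

#' Benchmark design specification
#'
#' Parameters of the seeded synthetic benchmarks. The defaults reproduce the
#' 10-gene two-regime design: segments of 30 + 30 samples (switch at t = 31),
#' sub-networks with 10 and 18 directed interactions respectively, and
#' Gaussian noise with mean 2 and variance 0.5 per gene.
#'
#' @param n_genes number of genes.
#' @param segment_lengths integer vector of per-regime sample counts, each
#'   at least 3.
#' @param edges_per_matrix nonzero entries per system matrix; recycled
#'   across regimes.
#' @param spectral_radius_cap stability cap in `(0, 1)`.
#' @param noise_mean_value common noise mean per gene.
#' @param noise_variance common noise variance per gene (isotropic).
#' @param seed integer seed controlling both the random matrices and the
#'   simulated noise.
#' @return an object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_genes = 10L,
                           segment_lengths = c(30L, 30L),
                           edges_per_matrix = c(10L, 18L),
                           spectral_radius_cap = 0.95,
                           noise_mean_value = 2,
                           noise_variance = 0.5,
                           seed = 1L) {
  if (any(segment_lengths < 3L)) stop_arg("segment lengths must all be >= 3")
  if (spectral_radius_cap <= 0 || spectral_radius_cap >= 1)
    stop_arg("spectral_radius_cap must be in (0, 1)")
  if (noise_variance < 0) stop_arg("noise_variance must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes),
         segment_lengths = as.integer(segment_lengths),
         edges_per_matrix = as.integer(edges_per_matrix),
         spectral_radius_cap = spectral_radius_cap,
         noise_mean_value = noise_mean_value,
         noise_variance = noise_variance,
         seed = as.integer(seed)),
    class = "benchmark_spec"
  )
}

# shared machinery: one independent sparse stable matrix per segment,
# change points at the cumulative segment starts, x1 drawn from the noise
# distribution
build_benchmark <- function(spec) {
  n <- spec$n_genes
  K <- length(spec$segment_lengths)
  edges <- rep_len(spec$edges_per_matrix, K)
  T_len <- sum(spec$segment_lengths)
  cps <- if (K > 1L) 1L + cumsum(spec$segment_lengths)[seq_len(K - 1L)]
         else integer(0)
  with_seed(spec$seed, {
    mats <- lapply(edges, function(ne) {
      make_random_sparse_stable_matrix(n, ne, seed = NULL,
                                       radius_cap = spec$spectral_radius_cap)
    })
    model <- sar_model(mats, cps,
                       noise_mean = rep(spec$noise_mean_value, n),
                       noise_cov = diag(spec$noise_variance, n))
    x1 <- stats::rnorm(n, mean = spec$noise_mean_value,
                       sd = sqrt(spec$noise_variance))
    series <- simulate_sar(model, T_len, x1, seed = NULL)
    list(model = model, series = series)
  })
}

#' Two-regime switching benchmark
#'
#' The 10-gene calibration design: 60 samples with a single regime switch at
#' time instant 31, independent sparse stable matrices with different
#' supports for the two sub-networks, and iid Gaussian noise with mean 2 and
#' variance 0.5 per gene.
#'
#' @param spec a [benchmark_spec()] with exactly two segment lengths.
#' @return list with elements `model` (a [sar_model()]) and `series`
#'   (an [expression_series()]).
#' @export
make_benchmark_two_regime <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (length(spec$segment_lengths) != 2L)
    stop_arg("two-regime benchmark needs exactly 2 segment lengths")
  build_benchmark(spec)
}

#' Concatenated multi-network benchmark
#'
#' Emulates stitching together expression data generated by several distinct
#' static networks: by default 5 segments of 21 samples each (T = 105,
#' change points 22, 43, 64, 85), each driven by an independent sparse
#' stable matrix. At every boundary the state is carried over, i.e. the new
#' regime's dynamics are applied to the last sample of the previous segment.
#'
#' @param spec a [benchmark_spec()] with at least two segment lengths.
#' @return list with elements `model` and `series`, as in
#'   [make_benchmark_two_regime()].
#' @export
make_benchmark_concatenated <- function(spec = benchmark_spec(
                                          segment_lengths = rep(21L, 5L),
                                          edges_per_matrix = 15L)) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (length(spec$segment_lengths) < 2L)
    stop_arg("concatenated benchmark needs at least 2 segments")
  build_benchmark(spec)
}

#' True adjacency of a regime
#'
#' Binary edge matrix of one system matrix: entry `(l, k)` is 1 when gene
#' `l` regulates gene `k`, i.e. when `A[k, l] != 0`. The diagonal
#' (self-regulation) is dropped because ranking-based evaluation excludes
#' self-edges.
#'
#' @param model a [sar_model()].
#' @param regime regime number in `1..K`.
#' @return `n x n` binary matrix with zero diagonal.
#' @export
true_adjacency <- function(model, regime = 1L) {
  A <- model$matrices[[regime]]
  truth <- (t(A) != 0) * 1L
  diag(truth) <- 0L
  truth
}
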