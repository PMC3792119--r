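# End-to-end two-step strategy: detect change points, split the series, and
# infer one static directed network per segment.  Detection and inference
# are deliberately decoupled — running them separately on saved segments
# gives the same result as the one-shot pipeline.

#' Pipeline configuration
#'
#' @param detection a [detection_config()].
#' @param inference_method `"iota"`, `"lasso"`, or `"both"`.
#' @param lasso_penalty nonnegative number, or `"cv"` for per-segment
#'   5-fold cross-validation.
#' @param warm_start when inferring with the lasso, initialise each
#'   segment's coordinate descent from the previous segment's coefficients
#'   (joint learning across segments; useful when regulations are believed
#'   to persist).
#' @param standardize z-score each gene across the whole series before
#'   analysis (off by default; intended for real microarray inputs).
#' @param seed integer seed governing all pipeline randomness (currently
#'   the cross-validation fold assignment).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            inference_method = c("iota", "lasso", "both"),
                            lasso_penalty = "cv",
                            warm_start = FALSE,
                            standardize = FALSE,
                            seed = 1L) {
  inference_method <- match.arg(inference_method)
  if (is.numeric(lasso_penalty) && lasso_penalty < 0)
    stop_arg("lasso_penalty must be >= 0")
  structure(
    list(detection = detection, inference_method = inference_method,
         lasso_penalty = lasso_penalty, warm_start = isTRUE(warm_start),
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the two-step strategy
#'
#' Step 1: (optionally estimate the noise covariance from the full series
#' and) detect regime change points by innovation-whiteness monitoring.
#' Step 2: split the series at the detected change points and infer a
#' static directed network on every segment with the configured method(s).
#'
#' @param series an [expression_series()].
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: fields `change_points`
#'   (a `change_point_result`), `segments` (list of series), `networks`
#'   (one element per segment; each a named list of `segment_network`
#'   objects keyed by method) and `provenance`.
#' @export
run_two_step <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "expression_series"),
            inherits(config, "pipeline_config"))
  if (config$standardize) {
    v <- series$values
    v <- (v - rowMeans(v)) / apply(v, 1L, stats::sd)
    series <- expression_series(v, series$gene_ids)
  }
  with_seed(config$seed, {
    cp <- tryCatch(detect_change_points(series, config$detection),
                   error = function(err)
                     stop("change-point detection failed: ",
                          conditionMessage(err), call. = FALSE))
    segments <- segment_series(series, cp$change_points)
    methods <- switch(config$inference_method,
                      both = c("iota", "lasso"), config$inference_method)
    prev_coef <- NULL
    networks <- vector("list", length(segments))
    for (k in seq_along(segments)) {
      nets <- list()
      for (m in methods) {
        nets[[m]] <- tryCatch({
          if (m == "iota") {
            score_network_iota(segments[[k]])
          } else {
            net <- infer_network_lasso(
              segments[[k]], penalty = config$lasso_penalty,
              warm_start = if (config$warm_start) prev_coef else NULL)
            prev_coef <- net$coefficients
            net
          }
        }, error = function(err)
          stop("network inference (", m, ") failed on segment ", k, ": ",
               conditionMessage(err), call. = FALSE))
      }
      networks[[k]] <- nets
    }
    structure(
      list(change_points = cp, segments = segments, networks = networks,
           provenance = list(
             seed = config$seed,
             version = as.character(utils::packageVersion("tvgrn")),
             inference_method = config$inference_method,
             lasso_penalty = config$lasso_penalty,
             warm_start = config$warm_start,
             standardize = config$standardize,
             alpha = config$detection$alpha,
             sigma_w = if (is.character(config$detection$sigma_w))
               config$detection$sigma_w else "supplied")),
      class = "pipeline_result"
    )
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  change points:",
      if (length(x$change_points$change_points))
        paste(x$change_points$change_points, collapse = ", ")
      else "none", "\n")
  cat("  segments:", length(x$segments),
      "| methods:", paste(names(x$networks[[1L]]), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate segment networks against gold standards
#'
#' Computes per-segment (and per-method) AUROC and AUPR over off-diagonal
#' candidate edges.
#'
#' @param result a [run_two_step()] result.
#' @param truths one binary adjacency shared by all segments, or a list
#'   with one adjacency per segment.
#' @return data frame with columns `segment`, `start`, `end`, `method`,
#'   `auroc`, `aupr`, `n_edges_true`, `n_candidates`.
#' @export
evaluate_against_gold <- function(result, truths) {
  stopifnot(inherits(result, "pipeline_result"))
  K <- length(result$networks)
  if (is.matrix(truths)) truths <- rep(list(truths), K)
  if (length(truths) != K)
    stop_arg("need one gold standard per segment (", K, "), got ",
             length(truths))
  rows <- list()
  for (k in seq_len(K)) {
    truth <- as.matrix(truths[[k]])
    for (m in names(result$networks[[k]])) {
      net <- result$networks[[k]][[m]]
      off <- !diag(nrow(truth))
      rows[[length(rows) + 1L]] <- data.frame(
        segment = k,
        start = net$interval[1L], end = net$interval[2L], method = m,
        auroc = auroc(net$score, truth), aupr = aupr(net$score, truth),
        n_edges_true = sum(truth[off] == 1), n_candidates = sum(off))
    }
  }
  do.call(rbind, rows)
}

#' Write all pipeline outputs
#'
#' Writes, under `dir`: `change_points.json`, `q_trace.tsv`, one
#' `edges_<method>_segment<k>.tsv` per segment network, `provenance.json`,
#' and (when `evaluation` is given) `evaluation.tsv`. Outputs are
#' deterministic: the same configuration and seed produce byte-identical
#' files.
#'
#' @param result a [run_two_step()] result.
#' @param dir output directory (created if missing).
#' @param evaluation optional data frame from [evaluate_against_gold()].
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir, evaluation = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_change_point_summary(result$change_points,
                             file.path(dir, "change_points.json"))
  write_q_trace(result$change_points, file.path(dir, "q_trace.tsv"))
  for (k in seq_along(result$networks)) {
    for (m in names(result$networks[[k]])) {
      write_edge_list(result$networks[[k]][[m]],
                      file.path(dir, sprintf("edges_%s_segment%d.tsv", m, k)))
    }
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(evaluation)) {
    utils::write.table(evaluation, file.path(dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
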