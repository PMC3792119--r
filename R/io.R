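# Plain-text serialisation: expression TSV, DREAM gold-standard edge lists,
# SAR model JSON, and the pipeline's result files.  All tabular files are
# tab-separated with a header row.

#' Read an expression table
#'
#' TSV with a header row; first column is the gene identifier, remaining
#' columns are the ordered samples (taken as time `1..T` in file order).
#'
#' @param path file path.
#' @return an [expression_series()].
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 4L)
    stop_arg("expression table needs a gene column and >= 3 time columns")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop_arg("duplicate gene id '", gene_ids[duplicated(gene_ids)][1L],
             "' in ", path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | trimws(vals) == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_arg("non-numeric or missing value at row ", bad[1L, 1L],
             " (gene '", gene_ids[bad[1L, 1L]], "'), time column ",
             bad[1L, 2L], " of ", path)
  expression_series(num, gene_ids)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: header `gene<TAB>t1..tT`, one row
#' per gene, full-precision decimal values.
#'
#' @param series an [expression_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(series, path) {
  stopifnot(inherits(series, "expression_series"))
  tab <- data.frame(gene = series$gene_ids,
                    series$values, check.names = FALSE)
  colnames(tab) <- c("gene", paste0("t", series$time_index))
  utils::write.table(format(tab, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DREAM-format gold standard
#'
#' Tab-separated rows `regulator<TAB>target<TAB>label` with label 0 or 1
#' (with or without a header). Pairs absent from the file default to
#' negatives.
#'
#' @param path file path.
#' @param gene_ids character vector defining the adjacency order; any gene
#'   named in the file but missing here is an error.
#' @param default label assigned to unlisted pairs (0 by default).
#' @return `n x n` binary matrix, entry `(l, k)` = label of edge `l -> k`,
#'   zero diagonal.
#' @export
read_gold_standard <- function(path, gene_ids, default = 0L) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) != 3L)
    stop_arg("gold standard must have 3 tab-separated columns, found ",
             ncol(raw))
  if (identical(tolower(raw[1L, 3L]), "label") ||
      is.na(suppressWarnings(as.numeric(raw[1L, 3L]))) &&
      tolower(raw[1L, 1L]) %in% c("regulator", "source"))
    raw <- raw[-1L, , drop = FALSE]
  labels <- suppressWarnings(as.numeric(raw[[3L]]))
  if (any(is.na(labels)) || !all(labels %in% c(0, 1)))
    stop_arg("gold-standard labels must be 0 or 1")
  unknown <- setdiff(unique(c(raw[[1L]], raw[[2L]])), gene_ids)
  if (length(unknown))
    stop_arg("gold standard names unknown gene(s): ",
             paste(unknown, collapse = ", "))
  n <- length(gene_ids)
  truth <- matrix(as.integer(default), n, n,
                  dimnames = list(regulator = gene_ids, target = gene_ids))
  truth[cbind(match(raw[[1L]], gene_ids), match(raw[[2L]], gene_ids))] <-
    as.integer(labels)
  diag(truth) <- 0L
  truth
}

#' Write a DREAM-format gold standard
#'
#' One row per off-diagonal candidate pair: `regulator<TAB>target<TAB>label`,
#' no header (the dialect read back by [read_gold_standard()]).
#'
#' @param truth `n x n` binary adjacency, entry `(l, k)` = edge `l -> k`.
#' @param gene_ids gene identifiers in matrix order.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(truth, gene_ids, path) {
  n <- length(gene_ids)
  stopifnot(all(dim(truth) == n))
  rows <- expand.grid(reg = seq_len(n), tar = seq_len(n))
  rows <- rows[rows$reg != rows$tar, ]
  tab <- data.frame(regulator = gene_ids[rows$reg],
                    target = gene_ids[rows$tar],
                    label = as.integer(truth[cbind(rows$reg, rows$tar)] != 0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialise a SAR model to JSON
#'
#' Matrices as nested row-major lists, plus change points and the noise
#' mean/covariance; [read_sar_model()] restores the object.
#'
#' @param model a [sar_model()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sar_model <- function(model, path) {
  stopifnot(inherits(model, "sar_model"))
  payload <- list(
    matrices = lapply(model$matrices, function(A)
      lapply(seq_len(nrow(A)), function(i) A[i, ])),
    change_points = model$change_points,
    noise_mean = model$noise_mean,
    noise_cov = lapply(seq_len(nrow(model$noise_cov)),
                       function(i) model$noise_cov[i, ])
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_sar_model
#' @export
read_sar_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_matrix <- function(rows) {
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  sar_model(lapply(payload$matrices, to_matrix),
            as.integer(unlist(payload$change_points)),
            as.numeric(unlist(payload$noise_mean)),
            to_matrix(payload$noise_cov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the Q trace of a detection run
#'
#' @param result a `change_point_result`.
#' @param path file path for the tab-separated trace.
#' @return `path`, invisibly.
#' @export
write_q_trace <- function(result, path) {
  stopifnot(inherits(result, "change_point_result"))
  utils::write.table(result$q_trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a change-point summary as JSON
#'
#' Change points, segment intervals and an echo of the detection settings.
#'
#' @param result a `change_point_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_change_point_summary <- function(result, path) {
  stopifnot(inherits(result, "change_point_result"))
  cfg <- result$config
  payload <- list(
    change_points = result$change_points,
    segments = result$segments,
    config = list(alpha = cfg$alpha, p0 = cfg$p0,
                  min_innovations = cfg$min_innovations,
                  sigma_w = if (is.character(cfg$sigma_w)) cfg$sigma_w
                            else "supplied",
                  intercept = cfg$intercept, ridge = cfg$ridge)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Write a per-segment edge list
#'
#' Tab-separated columns: `regulator`, `target`, `score`, `sign`,
#' `segment_start`, `segment_end`. Only pairs with positive score are
#' listed, strongest first.
#'
#' @param network a `segment_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "segment_network"))
  n <- nrow(network$score)
  ids <- network$gene_ids %||% paste0("G", seq_len(n))
  rows <- which(network$score > 0 & !diag(n), arr.ind = TRUE)
  sgn <- if (!is.null(network$coefficients)) {
    sign(network$coefficients[cbind(rows[, 2L], rows[, 1L])])
  } else {
    rep(NA_integer_, nrow(rows))
  }
  tab <- data.frame(regulator = ids[rows[, 1L]], target = ids[rows[, 2L]],
                    score = network$score[rows], sign = sgn,
                    segment_start = network$interval[1L],
                    segment_end = network$interval[2L])
  tab <- tab[order(-tab$score, tab$regulator, tab$target), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
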