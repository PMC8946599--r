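#' Pearson correlation between two expression profiles
#'
#' @param expr_a,expr_b Numeric vectors of the same length (one sample each,
#'   over a shared probe set).
#' @return Pearson correlation in \[-1, 1\].
#' @export
pairwise_correlation <- function(expr_a, expr_b) {
  if (length(expr_a) != length(expr_b) || length(expr_a) < 2L) {
    stop("profiles must share a probe set of length >= 2", call. = FALSE)
  }
  if (sd(expr_a) == 0 || sd(expr_b) == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  cor(expr_a, expr_b)
}

#' Remove redundant samples across datasets by pairwise correlation
#'
#' When several public datasets share source cohorts, the same serum sample
#' can appear more than once.  This pass keeps a designated priority dataset
#' intact and removes, from the remaining datasets, every sample whose
#' Pearson correlation with any retained sample exceeds the threshold
#' (strictly).  Datasets are visited in the order given (priority first) and
#' samples within a dataset in lexicographic id order, so the result is
#' deterministic.
#'
#' @param expressions Named list of numeric matrices (shared probes x
#'   samples; normalized log2 expression over target probes), one per
#'   dataset.  `norm_expr` objects are accepted.
#' @param priority_dataset Name of the dataset whose samples are never
#'   removed.
#' @param threshold Correlation threshold (strict `>`); default 0.99.
#' @return A list of class `dedup_result`: `retained` (data.frame with
#'   `dataset`, `sample_id`), `removed` (data.frame with `dataset`,
#'   `sample_id`, `matched_dataset`, `matched_sample`, `correlation`), and
#'   `threshold`.
#' @export
remove_redundant <- function(expressions, priority_dataset,
                             threshold = 0.99) {
  if (is.null(names(expressions)) || any(names(expressions) == "")) {
    stop("expressions must be a named list of datasets", call. = FALSE)
  }
  if (!priority_dataset %in% names(expressions)) {
    stop("unknown priority dataset: ", priority_dataset, call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  mats <- lapply(expressions, as_expr_matrix)
  probes <- rownames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(rownames(m), probes),
                  logical(1)))) {
    stop("datasets must share an identical probe set", call. = FALSE)
  }

  order_ds <- c(priority_dataset,
                setdiff(names(mats), priority_dataset))
  ret_mat <- mats[[priority_dataset]]
  retained <- data.frame(
    dataset = rep(priority_dataset, ncol(ret_mat)),
    sample_id = colnames(ret_mat), stringsAsFactors = FALSE
  )
  removed <- data.frame(dataset = character(), sample_id = character(),
                        matched_dataset = character(),
                        matched_sample = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)

  for (ds in setdiff(order_ds, priority_dataset)) {
    m <- mats[[ds]]
    for (sid in sort(colnames(m))) {
      v <- m[, sid]
      r <- as.vector(cor(ret_mat, v))
      hit <- which(r > threshold)
      if (length(hit)) {
        best <- hit[which.max(r[hit])]
        removed <- rbind(removed, data.frame(
          dataset = ds, sample_id = sid,
          matched_dataset = retained$dataset[[best]],
          matched_sample = retained$sample_id[[best]],
          correlation = r[[best]], stringsAsFactors = FALSE
        ))
      } else {
        ret_mat <- cbind(ret_mat, v)
        colnames(ret_mat)[ncol(ret_mat)] <- sid
        retained <- rbind(retained, data.frame(
          dataset = ds, sample_id = sid, stringsAsFactors = FALSE
        ))
      }
    }
  }
  structure(list(retained = retained, removed = removed,
                 threshold = threshold),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("dedup_result: retained", nrow(x$retained), "samples, removed",
      nrow(x$removed), "at r >", x$threshold, "\n")
  invisible(x)
}
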