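#' Trimmed negative-control statistics
#'
#' Computes the mean and standard deviation of the negative-control signals
#' after removing the top and bottom 5% of values as ranked by intensity
#' (`floor(0.05 * k)` values from each end of `k` ranked values).  These
#' statistics define the presence threshold and the background level for a
#' single array.
#'
#' @param neg_signals Numeric vector of nonnegative negative-control signals
#'   (linear scale) from one sample.
#' @return A list of class `nc_stats`: `mean`, `sd` (n-1 denominator),
#'   `n_trimmed` (per end), `n_used`.
#' @export
trimmed_control_stats <- function(neg_signals) {
  stopifnot(is.numeric(neg_signals))
  k <- length(neg_signals)
  t <- floor(0.05 * k)
  kept <- sort(neg_signals)
  if (t > 0) kept <- kept[(t + 1):(k - t)]
  if (length(kept) < 2L) {
    stop("fewer than 2 negative-control values remain after trimming",
         call. = FALSE)
  }
  structure(list(mean = mean(kept), sd = sd(kept), n_trimmed = t,
                 n_used = length(kept)),
            class = "nc_stats")
}

#' Per-sample array quality control
#'
#' Applies the two low-quality-sample exclusion rules: a sample fails when
#' the coefficient of variation (sd/mean, untrimmed) of its negative-control
#' signals exceeds `cv_threshold`, or when its flagged-probe count (uneven
#' spot images reported by the scanner) exceeds `flag_threshold`.  Both
#' comparisons are strict.
#'
#' @param data A `raw_array`.
#' @param cv_threshold CV failure threshold (default 0.15).
#' @param flag_threshold Flagged-probe failure threshold (default 10).
#' @param cv_trimmed Compute the CV from trimmed control statistics instead
#'   of the raw control set (default `FALSE`; whether the original chip
#'   pipeline trimmed before the QC rule is not documented).
#' @return A data.frame of class `qc_report`: `sample_id`, `neg_cv`,
#'   `flagged`, `pass`, `reason` (`cv_fail`, `flag_fail`, or `pass`; a sample
#'   violating both rules is reported as `cv_fail`).
#' @export
sample_qc <- function(data, cv_threshold = 0.15, flag_threshold = 10,
                      cv_trimmed = FALSE) {
  stopifnot(inherits(data, "raw_array"))
  neg <- data$intensity[data$probes$class == "negative_control", ,
                        drop = FALSE]
  if (nrow(neg) < 2L) stop("negative-control probes missing", call. = FALSE)
  if (cv_trimmed) {
    st <- apply(neg, 2, trimmed_control_stats)
    m <- vapply(st, `[[`, numeric(1), "mean")
    s <- vapply(st, `[[`, numeric(1), "sd")
  } else {
    m <- colMeans(neg)
    s <- apply(neg, 2, sd)
  }
  if (any(m == 0)) {
    stop("zero mean negative-control signal in sample(s): ",
         paste(colnames(neg)[m == 0], collapse = ", "), call. = FALSE)
  }
  cv <- s / m
  flagged <- data$flagged[colnames(data$intensity)]
  reason <- ifelse(cv > cv_threshold, "cv_fail",
                   ifelse(flagged > flag_threshold, "flag_fail", "pass"))
  out <- data.frame(
    sample_id = colnames(data$intensity), neg_cv = unname(cv),
    flagged = unname(flagged), pass = reason == "pass", reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Presence call for a probe signal
#'
#' A miRNA is called present when its signal strictly exceeds the trimmed
#' negative-control mean plus two trimmed standard deviations.
#'
#' @param signal Numeric vector of linear-scale signals.
#' @param stats An `nc_stats` object from [trimmed_control_stats()].
#' @return Logical vector, `TRUE` where present.
#' @export
presence_call <- function(signal, stats) {
  stopifnot(inherits(stats, "nc_stats"))
  signal > stats$mean + 2 * stats$sd
}

#' Background subtraction
#'
#' Subtracts the trimmed negative-control mean from a signal, flooring the
#' result at a small positive constant so the subsequent log2 transform is
#' defined for every probe.
#'
#' @param signal Numeric vector of linear-scale signals.
#' @param stats An `nc_stats` object.
#' @param floor Lower bound on the subtracted signal (linear scale).
#' @return Numeric vector `pmax(signal - stats$mean, floor)`.
#' @export
background_subtract <- function(signal, stats, floor = 1) {
  stopifnot(inherits(stats, "nc_stats"), floor > 0)
  pmax(signal - stats$mean, floor)
}

#' Calibrate arrays by internal-control miRNAs
#'
#' Normalizes arrays against each other by an additive per-sample shift in
#' log2 space chosen so that the mean of the three internal-control miRNAs is
#' identical (equal to `reference_level`) in every sample.  This is the
#' log-scale equivalent of ratio scaling against stable endogenous controls
#' and removes array-level intensity effects.
#'
#' @param log2_matrix Numeric matrix (probes x samples, log2 scale) whose
#'   rownames include all three internal-control ids.
#' @param internal_control_ids Character vector of the three control probes.
#' @param reference_level Target level; defaults to the grand mean of the
#'   internal-control values across all samples.
#' @return A list of class `norm_expr` with elements `expr` (the calibrated
#'   matrix), `ref_level`, `shifts` (named per-sample additive shift), and
#'   `presence` (`NULL` here; filled by [preprocess_pipeline()]).
#' @export
normalize_internal_controls <- function(log2_matrix, internal_control_ids,
                                        reference_level = NULL) {
  stopifnot(is.matrix(log2_matrix))
  missing <- setdiff(internal_control_ids, rownames(log2_matrix))
  if (length(missing)) {
    stop("internal-control probe(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ic <- log2_matrix[internal_control_ids, , drop = FALSE]
  sample_means <- colMeans(ic)
  if (is.null(reference_level)) reference_level <- mean(ic)
  shifts <- reference_level - sample_means
  expr <- log2_matrix + rep(shifts, each = nrow(log2_matrix))
  structure(
    list(expr = expr, ref_level = reference_level,
         shifts = setNames(shifts, colnames(log2_matrix)), presence = NULL),
    class = "norm_expr"
  )
}

#' @export
print.norm_expr <- function(x, ...) {
  cat("norm_expr:", nrow(x$expr), "probes x", ncol(x$expr),
      "samples (log2, calibrated to", format(x$ref_level, digits = 4), ")\n")
  if (!is.null(x$presence)) {
    cat("  mean presence rate:",
        format(mean(x$presence), digits = 3), "\n")
  }
  invisible(x)
}

#' Full raw-array preprocessing pipeline
#'
#' Runs the preprocessing stages in order: sample QC and exclusion of
#' failing arrays, per-sample trimmed negative-control statistics, presence
#' calls on the raw signals, background subtraction with flooring, log2
#' transform, and internal-control calibration.  Only target probes are
#' carried into the output expression matrix.
#'
#' @param data A `raw_array`.
#' @param cv_threshold,flag_threshold QC thresholds; see [sample_qc()].
#' @param floor Linear-scale floor applied after background subtraction.
#' @param presence_filter Minimum fraction of samples in which a probe must
#'   be called present to be retained; 0 (default) keeps every probe.
#' @param reference_level Optional fixed calibration level; defaults to the
#'   grand mean of the internal controls in the passing samples.
#' @return A `norm_expr` object restricted to target probes, with `presence`
#'   (logical matrix of the same shape as `expr`), `qc` (the [sample_qc()]
#'   report for all input samples), and `samples` (metadata of retained
#'   samples) attached.
#' @export
preprocess_pipeline <- function(data, cv_threshold = 0.15,
                                flag_threshold = 10, floor = 1,
                                presence_filter = 0,
                                reference_level = NULL) {
  stopifnot(inherits(data, "raw_array"))
  qc <- sample_qc(data, cv_threshold, flag_threshold)
  keep <- qc$sample_id[qc$pass]
  if (length(keep) == 0L) {
    stop("all samples failed quality control", call. = FALSE)
  }
  neg <- data$intensity[data$probes$class == "negative_control", keep,
                        drop = FALSE]
  stats <- apply(neg, 2, trimmed_control_stats)
  bg_mean <- vapply(stats, `[[`, numeric(1), "mean")
  bg_sd <- vapply(stats, `[[`, numeric(1), "sd")

  target_ids <- data$probes$probe_id[data$probes$class == "target"]
  ic_ids <- data$probes$probe_id[data$probes$class == "internal_control"]
  sig <- data$intensity[c(target_ids, ic_ids), keep, drop = FALSE]
  npr <- nrow(sig)

  presence <- sig[target_ids, , drop = FALSE] >
    rep(bg_mean + 2 * bg_sd, each = length(target_ids))
  bg <- pmax(sig - rep(bg_mean, each = npr), floor)
  norm <- normalize_internal_controls(log2(bg), ic_ids, reference_level)

  norm$expr <- norm$expr[target_ids, , drop = FALSE]
  norm$presence <- presence
  if (presence_filter > 0) {
    keep_probes <- rowMeans(presence) >= presence_filter
    norm$expr <- norm$expr[keep_probes, , drop = FALSE]
    norm$presence <- presence[keep_probes, , drop = FALSE]
  }
  norm$qc <- qc
  if (!is.null(data$samples)) {
    norm$samples <- data$samples[match(keep, data$samples$sample_id), ,
                                 drop = FALSE]
    rownames(norm$samples) <- NULL
  }
  norm
}
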