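#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) estimator: the fraction of (case, control)
#' pairs in which the case scores higher, ties counted one half.  The curve
#' is built by thresholding at every distinct score.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Logical, `TRUE` for cases.
#' @return A list of class `roc_result`: `auc`, `curve` (data.frame of `fpr`,
#'   `tpr` from (0,0) to (1,1)), `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  tp <- cumsum(labels[o])
  fp <- cumsum(!labels[o])
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  curve <- data.frame(fpr = c(0, fp[last_of_tie] / n0),
                      tpr = c(0, tp[last_of_tie] / n1))
  structure(
    list(auc = auc_rank(scores, labels), curve = curve,
         n_case = n1, n_control = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC =", format(x$auc, digits = 4),
      sprintf("(%d cases, %d controls)\n", x$n_case, x$n_control))
  invisible(x)
}

#' Sensitivity and specificity at a cut-point
#'
#' Positive call at score `>=` cut-point: sensitivity is the detected
#' fraction of cases, specificity the fraction of controls strictly below
#' the cut-point.
#'
#' @inheritParams roc_auc
#' @param cutpoint Decision threshold.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(scores, labels, cutpoint) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  c(sensitivity = mean(scores[labels] >= cutpoint),
    specificity = mean(scores[!labels] < cutpoint))
}

#' Compare two paired AUCs by bootstrap
#'
#' Both score sets are measured on the same samples; bootstrap resamples are
#' drawn with replacement within each class (preserving class balance), the
#' AUC difference recomputed on each, and the observed difference divided by
#' the bootstrap standard deviation to give a standard-normal statistic.
#'
#' @param scores_a,scores_b Paired score vectors over the same samples.
#' @param labels Logical case labels.
#' @param n_boot Bootstrap replicates (default 2000; fewer than 100 draws a
#'   warning).
#' @param seed Integer seed.
#' @return A list of class `auc_comparison`: `auc_a`, `auc_b`, `D`
#'   (standardized difference), `p_value` (two-sided normal), `n_boot`.
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b, labels,
                                  n_boot = 2000, seed = 1L) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be paired over the same samples",
         call. = FALSE)
  }
  if (n_boot < 100) warning("n_boot < 100: unstable bootstrap variance")
  auc_a <- auc_rank(scores_a, labels)
  auc_b <- auc_rank(scores_b, labels)
  obs <- auc_a - auc_b
  case_idx <- which(labels)
  ctrl_idx <- which(!labels)
  lab_boot <- rep(c(TRUE, FALSE), c(length(case_idx), length(ctrl_idx)))
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(case_idx[sample.int(length(case_idx), replace = TRUE)],
               ctrl_idx[sample.int(length(ctrl_idx), replace = TRUE)])
      auc_rank(scores_a[idx], lab_boot) - auc_rank(scores_b[idx], lab_boot)
    }, numeric(1))
  })
  sdd <- sd(diffs)
  if (sdd == 0) {
    D <- if (obs == 0) 0 else sign(obs) * Inf
    p <- if (obs == 0) 1 else 0
  } else {
    D <- obs / sdd
    p <- 2 * pnorm(-abs(D))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, D = D, p_value = p,
                 n_boot = n_boot),
            class = "auc_comparison")
}

#' McNemar test for paired detection outcomes
#'
#' Compares the sensitivities of two tests applied to the same cases using
#' the discordant pairs: `b` detected only by test A, `c` only by test B.
#' For `b + c` below `exact_threshold` an exact two-sided binomial test is
#' used (`min(1, 2 * P(Binom(b + c, 1/2) <= min(b, c)))`); otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#' `b = c = 0` gives p = 1.
#'
#' @param detected_a,detected_b Logical vectors of per-case detection, same
#'   length and order.
#' @param exact_threshold Discordant-count switch to the asymptotic branch
#'   (default 25).
#' @return A list of class `mcnemar_result`: `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_test <- function(detected_a, detected_b, exact_threshold = 25) {
  detected_a <- as.logical(detected_a)
  detected_b <- as.logical(detected_b)
  if (length(detected_a) != length(detected_b)) {
    stop("paired outcomes must have equal length", call. = FALSE)
  }
  b <- sum(detected_a & !detected_b)
  cc <- sum(!detected_a & detected_b)
  n <- b + cc
  if (n == 0L) {
    p <- 1
    method <- "exact"
  } else if (n < exact_threshold) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(b = b, c = cc, p_value = p, method = method),
            class = "mcnemar_result")
}

#' Positive predictive value of a screening test
#'
#' `PPV = prev * sens / (prev * sens + (1 - prev) * (1 - spec))`.
#'
#' @param prevalence,sensitivity,specificity All in \[0, 1\].
#' @return PPV in \[0, 1\].
#' @export
ppv <- function(prevalence, sensitivity, specificity) {
  args <- c(prevalence, sensitivity, specificity)
  if (any(args < 0 | args > 1)) {
    stop("all arguments must lie in [0, 1]", call. = FALSE)
  }
  denom <- prevalence * sensitivity +
    (1 - prevalence) * (1 - specificity)
  if (denom == 0) stop("undefined PPV: no positive calls expected",
                       call. = FALSE)
  prevalence * sensitivity / denom
}

#' Subgroup sensitivity report
#'
#' Tabulates, at a fixed model cut-point, the detected fraction of cases
#' within each level of a clinical grouping variable (stage, histology, ...),
#' together with overall sensitivity and specificity.  Cases with a missing
#' group label and empty levels are omitted from the per-group table.
#'
#' @param positive Logical vector of positive classifications, aligned with
#'   the rows of `metadata`.
#' @param metadata Sample metadata data.frame with a `class` column
#'   (`"non-cancer"` marks controls).
#' @param grouping_field Name of the metadata column to group cases by.
#' @return A list of class `subgroup_report`: `subgroups` (data.frame with
#'   `label`, `n`, `detected`, `sensitivity`), `overall_sensitivity`,
#'   `overall_specificity` (`NA` if no controls), `grouping_field`.
#' @export
subgroup_sensitivities <- function(positive, metadata, grouping_field) {
  stopifnot(length(positive) == nrow(metadata))
  if (!grouping_field %in% names(metadata)) {
    stop("grouping field not found in metadata: ", grouping_field,
         call. = FALSE)
  }
  is_case <- metadata$class != "non-cancer"
  grp <- metadata[[grouping_field]][is_case]
  pos_case <- positive[is_case]
  keep <- !is.na(grp)
  tab <- if (any(keep)) {
    n <- tapply(pos_case[keep], grp[keep], length)
    det <- tapply(pos_case[keep], grp[keep], sum)
    data.frame(label = names(n), n = as.integer(n),
               detected = as.integer(det),
               sensitivity = as.numeric(det / n),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(label = character(), n = integer(), detected = integer(),
               sensitivity = numeric(), stringsAsFactors = FALSE)
  }
  structure(
    list(subgroups = tab,
         overall_sensitivity = if (any(is_case)) mean(pos_case) else NA_real_,
         overall_specificity = if (any(!is_case)) {
           mean(!positive[!is_case])
         } else {
           NA_real_
         },
         grouping_field = grouping_field),
    class = "subgroup_report"
  )
}

#' Evaluate a diagnostic model on a cohort
#'
#' Computes the ROC/AUC of the diagnostic index, sensitivity and specificity
#' at the model cut-point, and optional clinical-subgroup sensitivity
#' reports.
#'
#' @param model A trained `diag_model`.
#' @param expr Cohort expression (`norm_expr` or matrix).
#' @param is_case Logical case labels (taken from `expr$samples$class` when
#'   omitted and available).
#' @param metadata Optional metadata data.frame for subgroup reports.
#' @param subgroups Character vector of metadata columns to report by.
#' @return A list of class `eval_report`: `auc`, `roc`, `sensitivity`,
#'   `specificity`, `cutpoint`, `n_case`, `n_control`, `subgroup_reports`.
#' @export
evaluate_model <- function(model, expr, is_case = NULL, metadata = NULL,
                           subgroups = character()) {
  stopifnot(inherits(model, "diag_model"))
  if (is.null(is_case) && inherits(expr, "norm_expr") &&
      !is.null(expr$samples)) {
    if (is.null(metadata)) metadata <- expr$samples
    is_case <- expr$samples$class != "non-cancer"
  }
  if (is.null(is_case)) stop("is_case labels required", call. = FALSE)
  idx <- diagnostic_index(model, expr)
  roc <- roc_auc(idx, is_case)
  ss <- sens_spec(idx, is_case, model$cutpoint)
  reports <- list()
  if (length(subgroups) && !is.null(metadata)) {
    pos <- idx >= model$cutpoint
    reports <- lapply(subgroups, function(g) {
      subgroup_sensitivities(pos, metadata, g)
    })
    names(reports) <- subgroups
  }
  structure(
    list(auc = roc$auc, roc = roc,
         sensitivity = unname(ss[["sensitivity"]]),
         specificity = unname(ss[["specificity"]]),
         cutpoint = model$cutpoint,
         n_case = roc$n_case, n_control = roc$n_control,
         subgroup_reports = reports),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: AUC %.3f | sensitivity %.1f%% | specificity %.1f%% (cut-point %s)\n",
    x$auc, 100 * x$sensitivity, 100 * x$specificity,
    format(x$cutpoint)))
  cat(sprintf("  %d cases, %d controls\n", x$n_case, x$n_control))
  invisible(x)
}
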