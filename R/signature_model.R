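# Rank-based AUC (Mann-Whitney): fraction of (case, control) pairs with the
# case scored higher, ties half-weighted.  Internal hot path shared by CV,
# bootstrap, and roc_auc.
auc_rank <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- length(scores) - n1
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into folds.
stratified_folds <- function(is_case, folds) {
  fold <- integer(length(is_case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    if (length(idx) < folds) {
      stop("each class needs at least `folds` samples for stratified CV",
           call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Select the panel size by cross-validated AUC
#'
#' Runs stratified k-fold cross-validation over a grid of candidate panel
#' sizes.  Inside each fold, probes are ranked and weighted (moderated t) on
#' the training portion only; the held-out samples are scored with the raw
#' weighted index and the held-out AUC recorded.  The chosen panel size
#' maximizes the mean held-out AUC, with ties resolved toward the smallest
#' panel.
#'
#' @param expr Discovery expression (`norm_expr` or matrix).
#' @param is_case Logical class labels.
#' @param k_grid Candidate panel sizes (default 1..50).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @return A list of class `cv_result`: `k` (chosen size), `k_grid`,
#'   `mean_auc` (per candidate), `fold_auc` (folds x candidates matrix),
#'   `fold` (per-sample assignment), `folds`, `seed`.
#' @export
cv_select_panel_size <- function(expr, is_case, k_grid = 1:50, folds = 10,
                                 seed = 1L) {
  m <- as_expr_matrix(expr)
  is_case <- as.logical(is_case)
  stopifnot(length(is_case) == ncol(m))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (max(k_grid) > nrow(m)) {
    stop("k_grid exceeds the number of probes", call. = FALSE)
  }
  fold <- with_seed(seed, stratified_folds(is_case, folds))
  fold_auc <- matrix(NA_real_, nrow = folds, ncol = length(k_grid),
                     dimnames = list(NULL, k_grid))
  for (f in seq_len(folds)) {
    train <- fold != f
    de <- de_analysis(m[, train, drop = FALSE], is_case[train])
    ranked <- rank_probes(de)
    w <- de$t[match(ranked, de$probe)]
    test_m <- m[ranked[seq_len(max(k_grid))], !train, drop = FALSE]
    test_lab <- is_case[!train]
    for (j in seq_along(k_grid)) {
      k <- k_grid[[j]]
      idx <- drop(crossprod(test_m[seq_len(k), , drop = FALSE],
                            w[seq_len(k)]))
      fold_auc[f, j] <- auc_rank(idx, test_lab)
    }
  }
  mean_auc <- colMeans(fold_auc)
  chosen <- k_grid[[which.max(mean_auc)]]  # which.max takes the first (= smallest k) tie
  structure(
    list(k = chosen, k_grid = k_grid, mean_auc = mean_auc,
         fold_auc = fold_auc, fold = fold, folds = folds, seed = seed),
    class = "cv_result"
  )
}

#' Fit the weighted diagnostic-index model
#'
#' Ranks probes on the full discovery set, takes the top `k`, and uses their
#' signed moderated-t statistics as weights.  The raw index of a sample is
#' the weighted linear sum of its expression over the panel; the model
#' stores the discovery-set raw minimum and maximum so that indices can be
#' mapped affinely to the 0-10 scale (values outside the discovery range are
#' not clamped).
#'
#' @inheritParams cv_select_panel_size
#' @param k Panel size.
#' @param de Optional precomputed [de_analysis()] result for `expr`.
#' @return A list of class `diag_model`: `probes`, `weights`, `raw_min`,
#'   `raw_max`, `cutpoint` (`NA` until set), `k`, `n_discovery`.
#' @export
fit_model <- function(expr, is_case, k, de = NULL) {
  m <- as_expr_matrix(expr)
  is_case <- as.logical(is_case)
  if (k < 1L || k > nrow(m)) {
    stop("k must lie between 1 and the probe count", call. = FALSE)
  }
  if (is.null(de)) de <- de_analysis(m, is_case)
  top <- rank_probes(de)[seq_len(k)]
  w <- setNames(de$t[match(top, de$probe)], top)
  raw <- drop(crossprod(m[top, , drop = FALSE], w))
  raw_min <- min(raw)
  raw_max <- max(raw)
  if (raw_max <= raw_min) {
    stop("degenerate raw index range on the discovery set", call. = FALSE)
  }
  structure(
    list(probes = top, weights = w, raw_min = raw_min, raw_max = raw_max,
         cutpoint = NA_real_, k = as.integer(k),
         n_discovery = ncol(m)),
    class = "diag_model"
  )
}

#' @export
print.diag_model <- function(x, ...) {
  cat("diag_model:", x$k, "miRNA panel\n")
  cat("  probes:", paste(x$probes, collapse = ", "), "\n")
  cat("  cut-point:", if (is.na(x$cutpoint)) "unset" else x$cutpoint, "\n")
  invisible(x)
}

#' Diagnostic index of samples under a model
#'
#' The weighted linear sum of the panel miRNA expression levels, mapped to
#' the 0-10 scale by the discovery-set affine normalization
#' `10 * (raw - raw_min) / (raw_max - raw_min)`.  Samples outside the
#' discovery range yield indices outside \[0, 10\].
#'
#' @param model A `diag_model`.
#' @param expr Expression matrix/`norm_expr` (probes x samples) or a single
#'   named sample vector; all panel probes must be present.
#' @return Numeric vector of normalized indices.
#' @export
diagnostic_index <- function(model, expr) {
  stopifnot(inherits(model, "diag_model"))
  if (is.numeric(expr) && !is.matrix(expr)) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample"))
  }
  m <- as_expr_matrix(expr)
  missing <- setdiff(model$probes, rownames(m))
  if (length(missing)) {
    stop("sample is missing model probe(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- drop(crossprod(m[model$probes, , drop = FALSE], model$weights))
  10 * (raw - model$raw_min) / (model$raw_max - model$raw_min)
}

#' Zero-false-positive cut-point
#'
#' Returns the smallest multiple of `grid_step` strictly greater than the
#' largest control index in the discovery set, so that the positive-iff-index
#' `>=` cut-point rule misclassifies no discovery control (specificity 1 by
#' construction).
#'
#' @param model A `diag_model` (used for validation only).
#' @param discovery_indices Normalized indices of all discovery samples.
#' @param control_mask Logical, `TRUE` for non-cancer controls.
#' @param grid_step Cut-point grid (default 1.0, an integer-valued index
#'   grid; 0.1 expresses finer cut-points).
#' @return The cut-point (numeric); a warning is issued if it exceeds 10.
#' @export
choose_cutpoint <- function(model, discovery_indices, control_mask,
                            grid_step = 1) {
  stopifnot(grid_step > 0, length(discovery_indices) == length(control_mask))
  if (!any(control_mask)) stop("at least one control required", call. = FALSE)
  max_control <- max(discovery_indices[control_mask])
  cut <- grid_step * (floor(max_control / grid_step + 1e-9) + 1)
  if (cut > 10) {
    warning("cut-point exceeds 10: model degenerate on the discovery set")
  }
  cut
}

#' Cut-point attaining a target specificity
#'
#' Finds the smallest threshold among the observed control indices such that
#' the fraction of controls strictly below it reaches the target specificity
#' (the positive-iff-`>=` rule then attains at least that specificity).  When
#' the target requires all controls below the threshold, a value just above
#' the maximum is returned, matching the zero-false-positive rule in the
#' limit of an infinitesimal grid.
#'
#' @param control_indices Numeric control index values.
#' @param target_specificity In (0, 1].
#' @return The threshold (numeric).
#' @export
cutpoint_for_specificity <- function(control_indices, target_specificity) {
  if (length(control_indices) == 0L) stop("no controls", call. = FALSE)
  stopifnot(target_specificity > 0, target_specificity <= 1)
  cand <- sort(unique(control_indices))
  for (t in cand) {
    if (mean(control_indices < t) >= target_specificity) return(t)
  }
  mx <- max(control_indices)
  mx + 1e-9 * (1 + abs(mx))
}

#' Classify a sample with a diagnostic model
#'
#' @param model A `diag_model` with its cut-point set.
#' @param expr Expression matrix or single sample vector.
#' @return Character vector, `"positive"` (index `>=` cut-point) or
#'   `"negative"`.
#' @export
classify <- function(model, expr) {
  if (is.na(model$cutpoint)) stop("model cut-point is not set", call. = FALSE)
  idx <- diagnostic_index(model, expr)
  ifelse(idx >= model$cutpoint, "positive", "negative")
}

#' Train a complete diagnostic model on a discovery set
#'
#' End-to-end model building: panel-size selection by cross-validated AUC,
#' final fit on the full discovery set, 0-10 index normalization, and
#' zero-false-positive cut-point selection.
#'
#' @inheritParams cv_select_panel_size
#' @param grid_step Cut-point grid step (see [choose_cutpoint()]).
#' @param k Optional fixed panel size, skipping cross-validation.
#' @return A `diag_model` with `cutpoint` set and the `cv_result` (if run)
#'   attached as `model$cv`; `model$seed` records the CV seed.
#' @export
train_diagnostic_model <- function(expr, is_case, k_grid = 1:50, folds = 10,
                                   seed = 1L, grid_step = 1, k = NULL) {
  m <- as_expr_matrix(expr)
  is_case <- as.logical(is_case)
  cv <- NULL
  if (is.null(k)) {
    cv <- cv_select_panel_size(m, is_case, k_grid = k_grid, folds = folds,
                               seed = seed)
    k <- cv$k
  }
  model <- fit_model(m, is_case, k)
  idx <- diagnostic_index(model, m)
  model$cutpoint <- choose_cutpoint(model, idx, !is_case,
                                    grid_step = grid_step)
  model$cv <- cv
  model$seed <- seed
  model
}
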