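#' Per-probe two-group linear model fit
#'
#' Fits the two-group (cancer vs non-cancer) linear model to every probe:
#' group means, log fold change (cancer minus control), pooled residual
#' variance, and residual degrees of freedom.
#'
#' @param expr Normalized log2 expression (`norm_expr` or probes x samples
#'   matrix).
#' @param is_case Logical vector over samples, `TRUE` for cancer.
#' @return data.frame with `probe`, `mean_case`, `mean_control`, `logFC`,
#'   `s2` (pooled residual variance), `df` (`n1 + n2 - 2`); `n1`/`n2` stored
#'   as attributes.
#' @export
fit_group_model <- function(expr, is_case) {
  m <- as_expr_matrix(expr)
  is_case <- as.logical(is_case)
  stopifnot(length(is_case) == ncol(m), !anyNA(is_case))
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  x1 <- m[, is_case, drop = FALSE]
  x2 <- m[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2L
  out <- data.frame(
    probe = rownames(m), mean_case = m1, mean_control = m2,
    logFC = m1 - m2, s2 = rss / d, df = d,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

# Invert trigamma(x) = y for x > 0 (y decreasing in x) by bisection on the
# log scale; used to solve the method-of-moments equation for the prior df.
trigamma_inverse <- function(y) {
  lo <- 1e-3
  hi <- 1e7
  if (y >= trigamma(lo)) return(lo)
  if (y <= trigamma(hi)) return(Inf)
  uniroot(function(x) trigamma(exp(x)) - y, lower = log(lo), upper = log(hi),
          tol = 1e-12)$root |> exp()
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse chi-square prior (`d0`, `s02`) to the observed
#' per-probe residual variances by the method of moments on `log(s2)`: under
#' the hierarchical model, `log(s2)` has mean
#' `log(s02) + log(d0/2) - digamma(d0/2) + digamma(d/2) - log(d/2)` and
#' variance `trigamma(d0/2) + trigamma(d/2)`.  The excess of the sample
#' variance of `log(s2)` over its pure-sampling part `trigamma(d/2)` is
#' inverted through the trigamma function to obtain `d0`; when there is no
#' excess spread, `d0 = Inf` (a common variance) is returned.
#'
#' @param s2 Numeric vector of per-probe residual variances (zeros are
#'   excluded from the moment fit; an error is raised if all are zero).
#' @param d Residual degrees of freedom (scalar, shared across probes).
#' @return A list of class `ebayes_prior`: `d0` (prior df, possibly `Inf`)
#'   and `s02` (prior variance).
#' @export
estimate_prior <- function(s2, d) {
  stopifnot(is.numeric(s2), length(d) == 1L, d >= 1)
  s2 <- s2[is.finite(s2)]
  pos <- s2[s2 > 0]
  if (length(pos) == 0L) {
    stop("all residual variances are zero: prior undefined", call. = FALSE)
  }
  if (length(pos) < 10L) {
    stop("at least 10 probes with positive variance required", call. = FALSE)
  }
  z <- log(pos)
  if (max(z) - min(z) < 1e-12) {
    # literally no spread: the common value is the prior variance
    return(structure(list(d0 = Inf, s02 = pos[[1]]), class = "ebayes_prior"))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e)
  excess <- evar - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    half_d0 <- trigamma_inverse(excess)
    d0 <- 2 * half_d0
    s02 <- exp(emean + digamma(half_d0) - log(half_d0))
  }
  structure(list(d0 = d0, s02 = s02), class = "ebayes_prior")
}

#' Moderated t-statistics
#'
#' Shrinks each probe's residual variance toward the prior,
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, and forms the moderated
#' statistic `t = logFC / sqrt(s2_post * (1/n1 + 1/n2))` with `d0 + d`
#' degrees of freedom.  With `d0 = 0` this is exactly the ordinary pooled
#' two-sample t-test; with `d0 = Inf` all probes share the prior variance and
#' the reference distribution is normal.
#'
#' @param logFC,s2,d Per-probe effect, pooled variance, and residual df (as
#'   from [fit_group_model()]; `d` may be scalar).
#' @param params An `ebayes_prior` (use `list(d0 = 0)` for no moderation).
#' @param n1,n2 Group sample sizes.
#' @return data.frame with `t`, `p_value` (two-sided, clamped below at
#'   1e-300), `s2_post`, and `df_total`.
#' @export
moderated_t <- function(logFC, s2, d, params, n1, n2) {
  d0 <- params$d0
  s02 <- if (is.null(params$s02)) 0 else params$s02
  stopifnot(d0 >= 0, n1 >= 1, n2 >= 1)
  if (d0 > 0 && s02 <= 0) stop("s02 must be positive when d0 > 0",
                               call. = FALSE)
  s2_post <- if (is.infinite(d0)) {
    rep_len(s02, length(logFC))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, logFC / se,
              ifelse(logFC == 0, 0, sign(logFC) * Inf))
  p <- 2 * pt(abs(t), df = df_total, lower.tail = FALSE)
  p[is.infinite(t)] <- 0
  p <- pmax(p, 1e-300)
  data.frame(t = t, p_value = p, s2_post = s2_post,
             df_total = rep_len(df_total, length(t)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes FDR-adjusted p-values: with order statistics `p_(1) <= ... <=
#' p_(n)`, `adj_(i) = min_{j >= i} n * p_(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Differential-expression analysis
#'
#' Full case-vs-control analysis: per-probe linear model fit, empirical-Bayes
#' prior estimation, moderated t and two-sided p-values, BH adjustment, and
#' ranking (ascending adjusted p, ties broken by ascending raw p, then
#' descending |t|, then probe id).
#'
#' @inheritParams fit_group_model
#' @param prior Optional `ebayes_prior` to use instead of estimating one
#'   (e.g. `list(d0 = 0)` for the unmoderated test).
#' @return data.frame of class `de_result` with one row per probe: `probe`,
#'   `mean_case`, `mean_control`, `logFC`, `s2`, `df`, `t`, `p_value`,
#'   `adj_p_value`, `rank`; the fitted prior is attached as
#'   `attr(, "prior")`.
#' @export
de_analysis <- function(expr, is_case, prior = NULL) {
  fit <- fit_group_model(expr, is_case)
  n1 <- attr(fit, "n1")
  n2 <- attr(fit, "n2")
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df[[1]])
  mt <- moderated_t(fit$logFC, fit$s2, fit$df, prior, n1, n2)
  out <- cbind(fit, mt[c("t", "p_value", "s2_post")])
  out$adj_p_value <- bh_adjust(out$p_value)
  ord <- order(out$adj_p_value, out$p_value, -abs(out$t), out$probe)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "prior") <- prior
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("de_result", "data.frame")
  out
}

#' Probe ids ordered by differential-expression rank
#'
#' @param de A `de_result` from [de_analysis()].
#' @return Character vector of probe ids, most significant first.
#' @export
rank_probes <- function(de) {
  stopifnot(inherits(de, "de_result"))
  de$probe[order(de$rank)]
}
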