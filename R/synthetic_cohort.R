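#' Configuration for a synthetic serum-miRNA microarray cohort
#'
#' Describes one case/control cohort profiled on an emulated serum miRNA
#' oligo-array: 2588 target-miRNA probes by default, a block of
#' negative-control probes defining background, and three internal-control
#' miRNAs carrying the array-level effect that calibration removes.
#'
#' Intensities are generated on the log2 scale and returned linear.  Each
#' target probe has a baseline log2 mean drawn from
#' `Normal(baseline_log_mean, baseline_log_sd)` and a probe-specific residual
#' standard deviation whose square is drawn from a scaled inverse chi-square
#' hyper-distribution (`probe_noise_prior_df`, `probe_noise_prior_var`), the
#' variance structure the moderated-t model assumes.  Probes named in
#' `planted_signature` are true markers: their baseline is shifted upward by
#' `signature_baseline_boost` (circulating markers are modelled as reliably
#' above background) and their mean is shifted by the planted log2 effect in
#' cancer samples only.
#'
#' @param n_cancer Cancer cases per cancer type.
#' @param n_control Non-cancer controls.
#' @param cancer_types Character vector of cancer-type labels; `n_cancer`
#'   cases are generated for each.
#' @param n_target_probes Number of target miRNA probes (default 2588).
#' @param n_negative_controls Number of negative-control probes (default 50;
#'   the platform's true count is not public, so this is a configurable
#'   emulation choice).
#' @param internal_control_ids Exactly three internal-control probe labels.
#' @param planted_signature Named numeric vector: names are target probe ids,
#'   values are per-probe log2 effect sizes added in cancer samples.  `NULL`
#'   for a null cohort.
#' @param baseline_log_mean,baseline_log_sd Hyper-parameters of the per-probe
#'   baseline log2 mean distribution.
#' @param signature_baseline_boost Added to the baseline mean of planted
#'   probes (log2 units).
#' @param signature_effect_sd Per-case, per-marker sd (log2 units) of the
#'   planted effect: each cancer case sheds each marker at an individual
#'   level drawn from `Normal(effect, signature_effect_sd^2)`.  This tumour
#'   heterogeneity makes any single marker an imperfect classifier while a
#'   panel, which averages over markers, stays strong.
#' @param signature_dropout Probability that a given planted marker is NOT
#'   shed by a given cancer case (its effect is zeroed for that sample); an
#'   alternative, all-or-nothing form of marker heterogeneity (default 0).
#' @param probe_noise_prior_df,probe_noise_prior_var Prior df and scale of the
#'   scaled inverse chi-square distribution of per-probe residual variances.
#' @param negctrl_log_mean,negctrl_log_sd Log2 mean and spread of the shared
#'   negative-control signal distribution (class-independent).
#' @param internal_log_mean Log2 means of the three internal controls
#'   (recycled if scalar).
#' @param internal_log_sd Biological (non-array) sd of internal controls;
#'   near zero so they carry essentially only the array-level shift.
#' @param array_effect_sd Per-sample array effect sd (log2), applied to every
#'   probe on the array; internal-control calibration is designed to remove it.
#' @param site_effects Named numeric vector of per-site additive log2 shifts.
#' @param stage_coupling Optional nonnegative multiplier coupling planted
#'   effect size to tumour stage (effect scaled by
#'   `1 + stage_coupling * (stage_index - 1)`); 0 decouples expression from
#'   stage labels.
#' @param probe_params Optional probe-level parameters from
#'   [draw_probe_params()], so several cohorts (e.g. discovery and
#'   validation) share one platform/population; `NULL` draws fresh ones from
#'   the hyper-distributions.
#' @param qc_failure_fraction,duplicate_fraction Fractions of samples given
#'   QC-violating signals / near-duplicate copies by [generate_cohort].
#' @param duplicate_noise_sd Log2 noise sd for injected duplicates.
#' @param seed Integer seed; fully determines the generated cohort.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_cancer = 208,
                          n_control = 208,
                          cancer_types = "lung",
                          n_target_probes = 2588,
                          n_negative_controls = 50,
                          internal_control_ids = c("miR-149-3p", "miR-2861",
                                                   "miR-4463"),
                          planted_signature = NULL,
                          baseline_log_mean = 7,
                          baseline_log_sd = 1.5,
                          signature_baseline_boost = 1.5,
                          signature_effect_sd = 0.85,
                          signature_dropout = 0,
                          probe_noise_prior_df = 8,
                          probe_noise_prior_var = 0.12,
                          negctrl_log_mean = 4,
                          negctrl_log_sd = 0.15,
                          internal_log_mean = c(9.5, 10, 10.5),
                          internal_log_sd = 0.02,
                          array_effect_sd = 0.3,
                          site_effects = c(hospital = 0.2, biobank = 0,
                                           clinic = -0.2),
                          stage_coupling = 0,
                          probe_params = NULL,
                          qc_failure_fraction = 0,
                          duplicate_fraction = 0,
                          duplicate_noise_sd = 0.01,
                          seed = 1L) {
  cfg <- list(
    n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
    cancer_types = as.character(cancer_types),
    n_target_probes = as.integer(n_target_probes),
    n_negative_controls = as.integer(n_negative_controls),
    internal_control_ids = as.character(internal_control_ids),
    planted_signature = planted_signature,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    signature_baseline_boost = signature_baseline_boost,
    signature_effect_sd = signature_effect_sd,
    signature_dropout = signature_dropout,
    probe_noise_prior_df = probe_noise_prior_df,
    probe_noise_prior_var = probe_noise_prior_var,
    negctrl_log_mean = negctrl_log_mean, negctrl_log_sd = negctrl_log_sd,
    internal_log_mean = internal_log_mean, internal_log_sd = internal_log_sd,
    array_effect_sd = array_effect_sd, site_effects = site_effects,
    stage_coupling = stage_coupling,
    probe_params = probe_params,
    qc_failure_fraction = qc_failure_fraction,
    duplicate_fraction = duplicate_fraction,
    duplicate_noise_sd = duplicate_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$internal_control_ids) != 3L ||
      anyDuplicated(cfg$internal_control_ids)) {
    stop("exactly 3 distinct internal-control probe ids are required",
         call. = FALSE)
  }
  if (cfg$n_cancer < 0L || cfg$n_control < 0L) {
    stop("sample counts must be nonnegative", call. = FALSE)
  }
  if (cfg$n_negative_controls < 2L) {
    stop("at least 2 negative-control probes are required", call. = FALSE)
  }
  sig <- cfg$planted_signature
  if (!is.null(sig)) {
    if (!is.numeric(sig) || is.null(names(sig)) || any(names(sig) == "")) {
      stop("planted_signature must be a named numeric vector", call. = FALSE)
    }
    if (length(sig) > cfg$n_target_probes) {
      stop("planted signature larger than the target probe set", call. = FALSE)
    }
    if (any(names(sig) %in% cfg$internal_control_ids)) {
      stop("planted_signature must be disjoint from internal controls",
           call. = FALSE)
    }
  }
  if (cfg$qc_failure_fraction < 0 || cfg$qc_failure_fraction > 1 ||
      cfg$duplicate_fraction < 0 || cfg$duplicate_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

target_probe_ids <- function(n) sprintf("miR-t%04d", seq_len(n))

# Draw per-probe baseline log2 means and residual sds from the configured
# hyper-distributions; consumes the current RNG stream.
draw_probe_params_inner <- function(config) {
  np <- config$n_target_probes
  tids <- target_probe_ids(np)
  mu <- rnorm(np, config$baseline_log_mean, config$baseline_log_sd)
  names(mu) <- tids
  sig <- config$planted_signature
  if (!is.null(sig)) {
    mu[names(sig)] <- rnorm(length(sig),
                            config$baseline_log_mean +
                              config$signature_baseline_boost, 0.5)
  }
  sigma <- sqrt(config$probe_noise_prior_var * config$probe_noise_prior_df /
                  rchisq(np, config$probe_noise_prior_df))
  names(sigma) <- tids
  list(mu = mu, sigma = sigma)
}

#' Draw the probe-level parameters of a simulated platform
#'
#' Samples each target probe's baseline log2 mean and residual standard
#' deviation from the hyper-distributions in a [cohort_config()].  Passing
#' the result to several configurations (via their `probe_params` field)
#' makes the cohorts share a platform and source population, which is what
#' lets a discovery-set index normalization transfer to a validation set.
#'
#' @param config A `cohort_config`.
#' @param seed Seed for the draw; defaults to the config seed.
#' @return A list with named vectors `mu` and `sigma` over target probes.
#' @export
draw_probe_params <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, draw_probe_params_inner(config))
}

#' Generate a synthetic serum-miRNA cohort
#'
#' Draws a raw (linear-scale) probes x samples intensity table plus probe
#' annotation, per-sample flagged-probe counts, and sample metadata, following
#' the model described in [cohort_config()].  If the configuration requests
#' them, QC-violating samples and near-duplicate samples are injected before
#' the object is returned.
#'
#' @param config A [cohort_config()] object.
#' @param role Cohort role recorded in the metadata (`"discovery"`,
#'   `"validation"`, or `"combined"`).
#' @return An object of class `raw_array`: a list with elements
#'   \describe{
#'     \item{intensity}{numeric matrix, probes x samples, linear scale}
#'     \item{probes}{data.frame with `probe_id` and
#'       `class` (`target` / `negative_control` / `internal_control`)}
#'     \item{flagged}{named integer vector of flagged-probe counts}
#'     \item{samples}{data.frame of sample metadata (`sample_id`, `class`,
#'       `site`, `stage`, `histology`, `sex`, `age`, `smoking`, `role`)}
#'   }
#' @export
generate_cohort <- function(config, role = "discovery") {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  role <- match.arg(role, c("discovery", "validation", "combined"))

  with_seed(config$seed, {
    types <- config$cancer_types
    n_cases <- config$n_cancer * length(types)
    ns <- n_cases + config$n_control
    if (ns < 1L) stop("empty cohort", call. = FALSE)

    class_label <- c(rep(types, each = config$n_cancer),
                     rep("non-cancer", config$n_control))
    sample_id <- sprintf("%s%04d", substr(role, 1, 1), seq_len(ns))
    is_case <- class_label != "non-cancer"

    sites <- names(config$site_effects)
    if (is.null(sites)) sites <- paste0("site", seq_along(config$site_effects))
    # sites assigned independently of class, emulating a source-matched
    # design: confounding site with class would let floored (absent) probes
    # carry site signal through the calibration shift
    site <- sites[1L + (seq_len(ns) %% length(sites))]
    stage_levels <- c("I", "II", "III-IV")
    stage <- ifelse(is_case,
                    sample(stage_levels, ns, TRUE, prob = c(0.72, 0.15, 0.13)),
                    NA_character_)
    histology <- ifelse(is_case,
                        sample(c("adenocarcinoma", "squamous", "other"),
                               ns, TRUE, prob = c(0.78, 0.14, 0.08)),
                        NA_character_)
    sex <- sample(c("male", "female"), ns, TRUE)
    age <- round(rnorm(ns, mean = ifelse(is_case, 65, 55), sd = 10))
    smoking <- sample(c("former/current", "never"), ns, TRUE,
                      prob = c(0.4, 0.6))

    samples <- data.frame(
      sample_id = sample_id, class = class_label, site = site,
      stage = stage, histology = histology, sex = sex, age = age,
      smoking = smoking, role = role, stringsAsFactors = FALSE
    )

    np <- config$n_target_probes
    tids <- target_probe_ids(np)
    sig <- config$planted_signature
    if (!is.null(sig) && !all(names(sig) %in% tids)) {
      stop("planted_signature names must be target probe ids (miR-tNNNN)",
           call. = FALSE)
    }

    # per-probe baseline and residual sd (shared across cohorts when
    # probe_params is supplied)
    pp <- config$probe_params
    if (is.null(pp)) pp <- draw_probe_params_inner(config)
    if (length(pp$mu) != np || length(pp$sigma) != np) {
      stop("probe_params do not match n_target_probes", call. = FALSE)
    }
    mu <- pp$mu
    sigma <- pp$sigma

    shift <- rnorm(ns, 0, config$array_effect_sd) +
      unname(config$site_effects[match(site, sites)])

    log2_target <- mu + matrix(rnorm(np * ns, 0, sigma), nrow = np)
    if (!is.null(sig)) {
      eff <- matrix(0, nrow = length(sig), ncol = ns)
      case_cols <- which(is_case)
      scale_by_stage <- 1 + config$stage_coupling *
        (match(stage[case_cols], stage_levels) - 1)
      eff[, case_cols] <- outer(unname(sig), scale_by_stage)
      if (config$signature_effect_sd > 0) {
        eff[, case_cols] <- eff[, case_cols] +
          matrix(rnorm(length(sig) * length(case_cols), 0,
                       config$signature_effect_sd),
                 nrow = length(sig))
      }
      if (config$signature_dropout > 0) {
        shed <- matrix(runif(length(sig) * length(case_cols)) >=
                         config$signature_dropout,
                       nrow = length(sig))
        eff[, case_cols] <- eff[, case_cols] * shed
      }
      log2_target[match(names(sig), tids), ] <-
        log2_target[match(names(sig), tids), ] + eff
    }
    log2_target <- log2_target + rep(shift, each = np)

    nn <- config$n_negative_controls
    nc_ids <- sprintf("NC-%02d", seq_len(nn))
    log2_neg <- config$negctrl_log_mean +
      matrix(rnorm(nn * ns, 0, config$negctrl_log_sd), nrow = nn) +
      rep(shift, each = nn)

    ic_mu <- rep_len(config$internal_log_mean, 3L)
    log2_ic <- ic_mu + matrix(rnorm(3L * ns, 0, config$internal_log_sd),
                              nrow = 3L) + rep(shift, each = 3L)

    intensity <- 2^rbind(log2_target, log2_neg, log2_ic)
    rownames(intensity) <- c(tids, nc_ids, config$internal_control_ids)
    colnames(intensity) <- sample_id

    probes <- data.frame(
      probe_id = rownames(intensity),
      class = rep(c("target", "negative_control", "internal_control"),
                  c(np, nn, 3L)),
      stringsAsFactors = FALSE
    )
    flagged <- setNames(rpois(ns, 2), sample_id)

    raw <- structure(
      list(intensity = intensity, probes = probes,
           flagged = as.integer(flagged), samples = samples),
      class = "raw_array"
    )
    names(raw$flagged) <- sample_id

    if (config$qc_failure_fraction > 0) {
      raw <- inject_qc_failures(raw, config$qc_failure_fraction,
                                seed = config$seed + 1L)
    }
    if (config$duplicate_fraction > 0) {
      raw <- inject_duplicates(raw, config$duplicate_fraction,
                               noise_sd = config$duplicate_noise_sd,
                               seed = config$seed + 2L)
    }
    raw
  })
}

#' @export
print.raw_array <- function(x, ...) {
  cat("raw_array:", nrow(x$intensity), "probes x", ncol(x$intensity),
      "samples\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(table(x$probes$class)),
                    table(x$probes$class)), collapse = ", "), "\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(x$samples$class)),
                    table(x$samples$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Inject QC-failing samples into a raw array
#'
#' Marks a fraction of samples as low quality by either inflating the spread
#' of their negative-control signals until the coefficient of variation
#' exceeds 0.15, or raising their flagged-probe count above 10 — the two
#' exclusion rules applied by [sample_qc()].
#'
#' @param data A `raw_array`.
#' @param fraction Fraction of samples to corrupt (rounded to a count).
#' @param seed Integer seed.
#' @return The modified `raw_array`, with the affected sample ids and the
#'   failure mode recorded in `attr(, "qc_injected")`.
#' @export
inject_qc_failures <- function(data, fraction, seed = 1L) {
  stopifnot(inherits(data, "raw_array"), fraction >= 0, fraction <= 1)
  ns <- ncol(data$intensity)
  n_bad <- round(fraction * ns)
  if (n_bad == 0L) {
    attr(data, "qc_injected") <- data.frame(sample_id = character(),
                                            mode = character())
    return(data)
  }
  with_seed(seed, {
    bad <- sample(ns, n_bad)
    mode <- rep(c("cv_fail", "flag_fail"), length.out = n_bad)
    neg_rows <- which(data$probes$class == "negative_control")
    for (i in seq_len(n_bad)) {
      j <- bad[[i]]
      if (mode[[i]] == "cv_fail") {
        v <- data$intensity[neg_rows, j]
        # rescale log-deviations until the linear-scale CV clears 0.15
        d <- log(v) - mean(log(v))
        f <- 0.30 / max(sd(d), 1e-8)
        repeat {
          w <- mean(v) * exp(d * f) / mean(exp(d * f))
          if (sd(w) / mean(w) > 0.15) break
          f <- f * 1.5
        }
        data$intensity[neg_rows, j] <- w
      } else {
        data$flagged[[j]] <- 11L + rpois(1, 2)
      }
    }
    attr(data, "qc_injected") <- data.frame(
      sample_id = colnames(data$intensity)[bad], mode = mode,
      stringsAsFactors = FALSE
    )
    data
  })
}

#' Inject near-duplicate samples into a raw array
#'
#' Appends copies of randomly chosen existing samples perturbed by small
#' log2-scale noise, emulating the redundant samples that appear when
#' overlapping cohorts are deposited more than once.
#'
#' @param data A `raw_array`.
#' @param fraction Number of duplicates as a fraction of the current sample
#'   count (rounded).
#' @param noise_sd Log2-scale sd of the perturbation; 0 gives exact copies.
#' @param seed Integer seed.
#' @return The extended `raw_array`; `attr(, "duplicates")` maps each
#'   duplicate id to its original.
#' @export
inject_duplicates <- function(data, fraction, noise_sd = 0.01, seed = 1L) {
  stopifnot(inherits(data, "raw_array"), fraction >= 0, noise_sd >= 0)
  ns <- ncol(data$intensity)
  n_dup <- round(fraction * ns)
  if (n_dup == 0L) {
    attr(data, "duplicates") <- data.frame(duplicate_id = character(),
                                           original_id = character())
    return(data)
  }
  with_seed(seed, {
    orig <- sample(ns, n_dup, replace = n_dup > ns)
    np <- nrow(data$intensity)
    dup_mat <- 2^(log2(data$intensity[, orig, drop = FALSE]) +
                    matrix(rnorm(np * n_dup, 0, noise_sd), nrow = np))
    dup_ids <- paste0(colnames(data$intensity)[orig], "-dup",
                      seq_len(n_dup))
    colnames(dup_mat) <- dup_ids
    data$intensity <- cbind(data$intensity, dup_mat)
    data$flagged <- c(data$flagged,
                      setNames(data$flagged[orig], dup_ids))
    dup_samples <- data$samples[orig, , drop = FALSE]
    dup_samples$sample_id <- dup_ids
    data$samples <- rbind(data$samples, dup_samples)
    rownames(data$samples) <- NULL
    attr(data, "duplicates") <- data.frame(
      duplicate_id = dup_ids,
      original_id = colnames(data$intensity)[orig],
      stringsAsFactors = FALSE
    )
    data
  })
}

#' Simulate a discovery + validation MCED study
#'
#' Convenience wrapper generating the two cohorts of a marker-discovery
#' study on the same platform and signature: a balanced discovery set used
#' for model building and a larger independent validation set.  Defaults
#' emulate a lung-cancer discovery set of 208 cases / 208 controls and a
#' validation set of 1358 cases / 1970 controls with a 4-probe planted
#' signature of +2 log2 units per marker.
#'
#' @param seed Integer seed; the two cohorts use derived sub-seeds.
#' @param n_signature Number of planted marker probes.
#' @param effect Log2 effect size per marker in cancer samples.
#' @param discovery,validation Length-2 integer vectors `c(cases, controls)`.
#' @param ... Further arguments passed on to [cohort_config()] (shared by
#'   both cohorts).
#' @return A list with elements `discovery` and `validation` (both
#'   `raw_array`) and `signature` (the planted named effect vector).
#' @export
simulate_mced_study <- function(seed = 1L, n_signature = 4, effect = 2,
                                discovery = c(208, 208),
                                validation = c(1358, 1970), ...) {
  sig <- setNames(rep(effect, n_signature),
                  target_probe_ids(n_signature))
  cfg_d <- cohort_config(n_cancer = discovery[[1]],
                         n_control = discovery[[2]],
                         planted_signature = sig, seed = seed, ...)
  pp <- draw_probe_params(cfg_d, seed = seed + 900000L)
  cfg_d$probe_params <- pp
  cfg_v <- cohort_config(n_cancer = validation[[1]],
                         n_control = validation[[2]],
                         planted_signature = sig, probe_params = pp,
                         seed = seed + 500000L, ...)
  list(discovery = generate_cohort(cfg_d, role = "discovery"),
       validation = generate_cohort(cfg_v, role = "validation"),
       signature = sig)
}
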