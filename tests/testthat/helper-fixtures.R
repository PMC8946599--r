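# Hand-built raw_array fixtures for QC-level tests, bypassing the generator.
make_raw_array <- function(target, neg, internal, flagged = NULL,
                           classes = NULL) {
  intensity <- rbind(target, neg, internal)
  probes <- data.frame(
    probe_id = rownames(intensity),
    class = rep(c("target", "negative_control", "internal_control"),
                c(nrow(target), nrow(neg), nrow(internal))),
    stringsAsFactors = FALSE
  )
  ns <- ncol(intensity)
  if (is.null(flagged)) flagged <- rep(0L, ns)
  names(flagged) <- colnames(intensity)
  samples <- data.frame(
    sample_id = colnames(intensity),
    class = if (is.null(classes)) rep("non-cancer", ns) else classes,
    site = "site1", stage = NA_character_, histology = NA_character_,
    sex = "female", age = 60, smoking = "never", role = "discovery",
    stringsAsFactors = FALSE
  )
  structure(list(intensity = intensity, probes = probes, flagged = flagged,
                 samples = samples),
            class = "raw_array")
}

# Direct negative-control stats (for presence/background unit examples).
make_nc_stats <- function(mean, sd) {
  structure(list(mean = mean, sd = sd, n_trimmed = 0L, n_used = 10L),
            class = "nc_stats")
}

# Random probes x samples log2 expression matrix with ids.
rand_expr <- function(n_probes, n_samples, seed = 1, mean = 7, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples, mean, sd), nrow = n_probes,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# Small study used by several model-level tests.
small_study <- function(seed = 1, n_probes = 150, disc = c(40, 40),
                        valid = c(60, 60), ...) {
  simulate_mced_study(seed = seed, discovery = disc, validation = valid,
                      n_target_probes = n_probes, ...)
}
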