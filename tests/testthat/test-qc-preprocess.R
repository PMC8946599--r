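test_that("trimmed control statistics follow the 5% trimming rule", {
  s <- trimmed_control_stats(sample(1:20))   # 20 values: trim 1 per end
  expect_equal(s$n_trimmed, 1)
  expect_equal(s$mean, mean(2:19))
  expect_equal(s$sd, sd(2:19))

  s19 <- trimmed_control_stats(19:1)         # below 20 values: no trimming
  expect_equal(s19$n_trimmed, 0)
  expect_equal(s19$mean, mean(1:19))

  same <- trimmed_control_stats(rep(7, 10))
  expect_equal(same$mean, 7)
  expect_equal(same$sd, 0)

  expect_error(trimmed_control_stats(5), "fewer than 2")
})

test_that("sample QC applies the CV and flagged-probe rules strictly", {
  target <- matrix(100, 2, 3, dimnames = list(c("t1", "t2"), c("a", "b", "c")))
  ic <- matrix(1000, 3, 3,
               dimnames = list(c("miR-149-3p", "miR-2861", "miR-4463"), NULL))
  # sample a: CV = 0.20; b: CV = 0.05; c: CV = 0
  neg <- cbind(a = c(80, 120), b = c(95, 105), c = c(100, 100))
  neg <- neg * rep(1, each = 2); rownames(neg) <- c("n1", "n2")
  neg[, "a"] <- 100 + c(-1, 1) * 100 * 0.2 / sqrt(2)
  neg[, "b"] <- 100 + c(-1, 1) * 100 * 0.05 / sqrt(2)
  raw <- make_raw_array(target, neg, ic, flagged = c(0L, 10L, 0L))
  qc <- sample_qc(raw)
  expect_equal(qc$reason, c("cv_fail", "pass", "pass"))
  expect_equal(qc$pass, c(FALSE, TRUE, TRUE))   # flagged == 10 still passes

  raw$flagged[["b"]] <- 11L
  qc <- sample_qc(raw)
  expect_equal(qc$reason[[2]], "flag_fail")

  raw$intensity[c("n1", "n2"), "c"] <- 0
  expect_error(sample_qc(raw), "zero mean")
})

test_that("the trimmed-CV option evaluates the rule on trimmed statistics", {
  raw <- generate_cohort(cohort_config(n_cancer = 4, n_control = 4,
                                       n_target_probes = 20, seed = 13))
  qc <- sample_qc(raw, cv_trimmed = TRUE)
  neg <- raw$intensity[raw$probes$class == "negative_control", ]
  st <- trimmed_control_stats(neg[, 1])
  expect_equal(qc$neg_cv[[1]], st$sd / st$mean)
})

test_that("QC decisions match a brute-force re-evaluation of both rules", {
  raw <- generate_cohort(cohort_config(n_cancer = 30, n_control = 30,
                                       n_target_probes = 50,
                                       qc_failure_fraction = 0.2, seed = 11))
  qc <- sample_qc(raw)
  neg <- raw$intensity[raw$probes$class == "negative_control", ]
  for (j in seq_len(ncol(neg))) {
    cv <- sd(neg[, j]) / mean(neg[, j])
    fail <- cv > 0.15 || raw$flagged[[j]] > 10
    expect_equal(!qc$pass[[j]], fail)
  }
})

test_that("presence calls are strict and monotone in signal", {
  st <- make_nc_stats(100, 10)
  expect_true(presence_call(121, st))
  expect_false(presence_call(120, st))             # boundary: strict
  expect_false(presence_call(100, make_nc_stats(100, 0)))
  sig <- sort(runif(50, 50, 200))
  calls <- presence_call(sig, st)
  expect_true(all(diff(calls) >= 0))               # nondecreasing in signal
})

test_that("background subtraction floors at the configured constant", {
  st <- make_nc_stats(100, 5)
  expect_equal(background_subtract(500, st), 400)
  expect_equal(background_subtract(50, st), 1)
  expect_equal(background_subtract(100, st), 1)
  expect_equal(background_subtract(150, st, floor = 2), 50)
})

test_that("internal-control calibration is exact, idempotent, and removes array shifts", {
  ic_ids <- c("miR-149-3p", "miR-2861", "miR-4463")
  m <- rand_expr(20, 8, seed = 2)
  rownames(m)[1:3] <- ic_ids

  norm <- normalize_internal_controls(m, ic_ids)
  ic_means <- colMeans(norm$expr[ic_ids, ])
  expect_true(all(abs(ic_means - norm$ref_level) < 1e-9))

  again <- normalize_internal_controls(norm$expr, ic_ids)
  expect_true(all(abs(again$shifts) < 1e-12))      # idempotent

  # explicit shift example: controls at (10, 11, 12), reference 10
  one <- matrix(c(10, 11, 12, 5), ncol = 1,
                dimnames = list(c(ic_ids, "t1"), "s1"))
  out <- normalize_internal_controls(one, ic_ids, reference_level = 10)
  expect_equal(unname(out$shifts), -1)
  expect_equal(out$expr["t1", "s1"], 4)

  # two samples differing by a constant array effect agree after calibration
  m2 <- cbind(s1 = m[, 1], s2 = m[, 1] + 3.7)
  out2 <- normalize_internal_controls(m2, ic_ids)
  expect_equal(out2$expr[, "s1"], out2$expr[, "s2"])

  expect_error(normalize_internal_controls(m[-1, ], ic_ids), "missing")
})

test_that("adding a constant to one sample pre-calibration changes nothing", {
  # high baseline keeps every probe clear of the background floor, and a
  # fixed reference level keeps the calibration target data-independent
  raw <- generate_cohort(cohort_config(n_cancer = 5, n_control = 5,
                                       n_target_probes = 40,
                                       baseline_log_mean = 10,
                                       baseline_log_sd = 1, seed = 9))
  shifted <- raw
  shifted$intensity[, 4] <- shifted$intensity[, 4] * 2^1.3
  a <- preprocess_pipeline(raw, reference_level = 10)
  b <- preprocess_pipeline(shifted, reference_level = 10)
  expect_equal(a$expr, b$expr, tolerance = 1e-9)
})

test_that("the preprocessing pipeline is deterministic and tracks presence", {
  raw <- generate_cohort(cohort_config(n_cancer = 15, n_control = 15,
                                       n_target_probes = 120, seed = 6))
  a <- preprocess_pipeline(raw)
  b <- preprocess_pipeline(raw)
  expect_identical(a, b)
  expect_equal(dim(a$expr), c(120, 30))
  expect_identical(dim(a$presence), dim(a$expr))
  expect_true(all(is.finite(a$expr)))
  # absent probes sit at the floor-derived value for their sample
  floored <- !a$presence
  expect_gt(sum(floored), 0)
  expect_gt(mean(a$presence), 0.8)
  # presence-rate filter drops never-present probes
  filt <- preprocess_pipeline(raw, presence_filter = 0.5)
  expect_lt(nrow(filt$expr), nrow(a$expr) + 1)
  expect_true(all(rowMeans(filt$presence) >= 0.5))
})

test_that("an all-failing cohort raises an empty-output error", {
  raw <- generate_cohort(cohort_config(n_cancer = 3, n_control = 3,
                                       n_target_probes = 20, seed = 1))
  raw$flagged[] <- 20L
  expect_error(preprocess_pipeline(raw), "all samples failed")
})
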