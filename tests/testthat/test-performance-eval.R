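test_that("ROC/AUC agrees with pair enumeration and handles ties", {
  r <- roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "nonempty")

  # curve properties
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))

  set.seed(3)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n0 <- sample(2:30, 1)
    sc <- c(sample(1:10, n1, TRUE) + rnorm(n1, 0, 0.1) * rbinom(n1, 1, 0.5),
            sample(1:10, n0, TRUE))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    pairs <- outer(sc[lab], sc[!lab], function(a, b) {
      (a > b) + 0.5 * (a == b)
    })
    expect_equal(roc_auc(sc, lab)$auc, mean(pairs))
  }
})

test_that("AUC is complement-symmetric, transform-invariant, and matches pROC", {
  set.seed(4)
  sc <- rnorm(60)
  lab <- rep(c(TRUE, FALSE), 30)
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(-sc, lab)$auc, 1 - a)
  expect_equal(roc_auc(exp(sc), lab)$auc, a)
  p <- pROC::auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<"))
  expect_equal(a, as.numeric(p))
})

test_that("sensitivity and specificity count strict and inclusive sides correctly", {
  sc <- c(7, 7, 5, 3, 6)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  ss <- sens_spec(sc, lab, 6)
  expect_equal(unname(ss), c(2 / 3, 1 / 2))
  expect_equal(unname(sens_spec(sc, lab, 0)), c(1, 0))
  expect_equal(unname(sens_spec(sc, lab, 100)), c(0, 1))
})

test_that("bootstrap AUC comparison is null on identical scores and powerful", {
  set.seed(5)
  lab <- rep(c(TRUE, FALSE), each = 40)
  sc <- rnorm(80) + lab
  same <- bootstrap_auc_compare(sc, sc, lab, n_boot = 200, seed = 1)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  lab2 <- rep(c(TRUE, FALSE), each = 200)
  good <- rnorm(400) + 2.3 * lab2
  noise <- rnorm(400)
  cmp <- bootstrap_auc_compare(good, noise, lab2, n_boot = 500, seed = 2)
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$auc_a, 0.9)

  expect_warning(bootstrap_auc_compare(sc, sc + 0.1, lab, n_boot = 50,
                                       seed = 1), "n_boot")
  expect_error(bootstrap_auc_compare(sc[1:10], sc, lab), "paired")
})

test_that("McNemar exact branch matches hand binomials; chi-square matches base R", {
  expect_equal(mcnemar_test(logical(0), logical(0))$p_value, 1)
  r <- mcnemar_test(c(rep(TRUE, 10), TRUE), c(rep(FALSE, 10), TRUE))
  expect_equal(r$b, 10)
  expect_equal(r$c, 0)
  expect_equal(r$p_value, 0.001953125)

  # asymptotic branch vs stats::mcnemar.test with continuity correction
  a <- c(rep(TRUE, 20), rep(FALSE, 15), rep(TRUE, 30))
  b <- c(rep(FALSE, 20), rep(TRUE, 15), rep(TRUE, 30))
  ours <- mcnemar_test(a, b)
  expect_equal(ours$method, "chi-square")
  base_p <- mcnemar.test(table(a, b))$p.value
  expect_equal(ours$p_value, base_p)
  expect_error(mcnemar_test(a, b[1:10]), "equal length")
})

test_that("PPV arithmetic and monotonicity", {
  expect_equal(ppv(0.5, 0.8, 0.8), 0.8)
  expect_equal(ppv(0.2, 0.9, 1), 1)
  expect_equal(round(100 * ppv(0.01, 0.85, 0.993)), 55)
  expect_error(ppv(0, 0.5, 1), "undefined")
  expect_error(ppv(1.2, 0.5, 0.5), "\\[0, 1\\]")
  grid <- seq(0.05, 0.95, by = 0.3)
  for (s in grid) for (sp in grid) {
    expect_true(all(diff(sapply(grid, function(pr) ppv(pr, s, sp))) >= 0))
  }
  for (pr in grid) for (s in grid) {
    expect_true(all(diff(sapply(grid, function(sp) ppv(pr, s, sp))) >= 0))
  }
})

test_that("subgroup sensitivity reports match Table-style rounding", {
  meta <- data.frame(
    sample_id = sprintf("s%04d", 1:1000),
    class = c(rep("lung", 900), rep("non-cancer", 100)),
    stage = c(rep("IA", 686), rep("II", 214), rep(NA, 100)),
    stringsAsFactors = FALSE
  )
  positive <- rep(TRUE, 1000)
  positive[1:3] <- FALSE                 # 683/686 detected in IA
  positive[901:1000] <- FALSE            # controls all negative
  rep1 <- subgroup_sensitivities(positive, meta, "stage")
  ia <- rep1$subgroups[rep1$subgroups$label == "IA", ]
  expect_equal(ia$n, 686)
  expect_equal(ia$detected, 683)
  expect_equal(sprintf("%.1f%%", 100 * ia$sensitivity), "99.6%")
  expect_equal(rep1$overall_specificity, 1)

  # all detected -> every subgroup at 1; empty level omitted
  meta$stage[meta$stage == "II"] <- NA
  rep2 <- subgroup_sensitivities(rep(TRUE, 1000), meta, "stage")
  expect_equal(rep2$subgroups$label, "IA")
  expect_true(all(rep2$subgroups$sensitivity == 1))
  expect_error(subgroup_sensitivities(positive, meta, "nope"), "not found")
})

test_that("model evaluation ties the pieces together on a synthetic study", {
  study <- small_study(seed = 31)
  d <- preprocess_pipeline(study$discovery)
  lab <- d$samples$class != "non-cancer"
  model <- train_diagnostic_model(d, lab, k_grid = 1:10, folds = 5, seed = 1)
  ev_d <- evaluate_model(model, d, lab, metadata = d$samples,
                         subgroups = "stage")
  expect_identical(ev_d$specificity, 1)      # zero-FP construction
  v <- preprocess_pipeline(study$validation)
  ev_v <- evaluate_model(model, v)
  expect_gt(ev_v$auc, 0.9)
  expect_s3_class(ev_v$roc, "roc_result")
  srep <- ev_d$subgroup_reports$stage
  expect_equal(sum(srep$subgroups$n), sum(lab))
})
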