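test_that("the normalized index hits 0 and 10 at the discovery extremes", {
  m <- rand_expr(50, 30, seed = 41)
  lab <- rep(c(TRUE, FALSE), each = 15)
  model <- fit_model(m, lab, k = 4)
  idx <- diagnostic_index(model, m)
  expect_equal(min(idx), 0)
  expect_equal(max(idx), 10)
  # monotone when all weights are positive
  mpos <- model
  mpos$weights <- abs(model$weights)
  lower <- m[, 1, drop = FALSE]
  higher <- lower + 1
  colnames(higher) <- "hi"
  expect_gt(diagnostic_index(mpos, higher), diagnostic_index(mpos, lower))
  expect_error(diagnostic_index(model, m[-match(model$probes[1],
                                                rownames(m)), ]),
               "missing model probe")
  expect_error(fit_model(m, lab, k = 51), "between 1 and")
})

test_that("a k=1 model preserves the single probe's AUC", {
  m <- rand_expr(20, 40, seed = 42)
  lab <- rep(c(TRUE, FALSE), each = 20)
  m[5, lab] <- m[5, lab] + 2
  model <- fit_model(m, lab, k = 1)
  idx <- diagnostic_index(model, m)
  sgn <- sign(model$weights[[1]])
  expect_equal(roc_auc(idx, lab)$auc,
               roc_auc(sgn * m[model$probes, ], lab)$auc)
})

test_that("rescaling all weights leaves the normalized index unchanged", {
  m <- rand_expr(30, 20, seed = 43)
  lab <- rep(c(TRUE, FALSE), each = 10)
  model <- fit_model(m, lab, k = 3)
  doubled <- model
  doubled$weights <- 2 * model$weights
  doubled$raw_min <- 2 * model$raw_min
  doubled$raw_max <- 2 * model$raw_max
  expect_equal(diagnostic_index(model, m), diagnostic_index(doubled, m),
               tolerance = 1e-12)
})

test_that("the zero-FP cut-point follows the grid rule", {
  model <- structure(list(cutpoint = NA_real_), class = "diag_model")
  idx <- c(5.7, 3, 2, 8, 9)
  ctrl <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(choose_cutpoint(model, idx, ctrl, grid_step = 1), 6)
  expect_equal(choose_cutpoint(model, idx, ctrl, grid_step = 0.1), 5.8)
  expect_equal(choose_cutpoint(model, c(0, 0, 5), c(TRUE, TRUE, FALSE),
                               grid_step = 1), 1)
  # strictness at an exact multiple
  expect_equal(choose_cutpoint(model, c(6, 9), c(TRUE, FALSE)), 7)
  expect_warning(choose_cutpoint(model, c(10.5, 11), c(TRUE, FALSE)),
                 "exceeds 10")
  expect_error(choose_cutpoint(model, idx, rep(FALSE, 5)), "control")
})

test_that("the specificity-targeted cut-point counts order statistics", {
  expect_equal(cutpoint_for_specificity(1:100, 0.95), 96)
  expect_equal(cutpoint_for_specificity(1:10, 0.5), 6)
  # target 1 behaves like the zero-FP rule with an infinitesimal grid
  ctrl <- runif(50)
  t1 <- cutpoint_for_specificity(ctrl, 1)
  expect_gt(t1, max(ctrl))
  expect_lt(t1 - max(ctrl), 1e-6)
  expect_error(cutpoint_for_specificity(numeric(), 0.95), "no controls")
})

test_that("classification is positive at the cut-point and never on discovery controls", {
  m <- rand_expr(40, 26, seed = 44)
  lab <- rep(c(TRUE, FALSE), each = 13)
  m[1:3, lab] <- m[1:3, lab] + 1.5
  model <- train_diagnostic_model(m, lab, k_grid = 1:5, folds = 4, seed = 1)
  expect_true(all(classify(model, m[, !lab]) == "negative"))
  # boundary behaviour on a hand-built model with exact arithmetic
  unit <- structure(list(probes = "p1", weights = c(p1 = 1), raw_min = 0,
                         raw_max = 10, cutpoint = 6, k = 1L,
                         n_discovery = 2L),
                    class = "diag_model")
  expect_equal(unname(classify(unit, c(p1 = 6))), "positive")
  expect_equal(unname(classify(unit, c(p1 = 6 - 1e-9))), "negative")
  expect_error(classify(structure(list(cutpoint = NA_real_),
                                  class = "diag_model"), c(p1 = 1)),
               "not set")
})

test_that("discovery specificity is exactly 1 after cut-point selection", {
  for (s in 1:5) {
    m <- rand_expr(60, 10 + 2 * s, seed = 50 + s)
    lab <- rep(c(TRUE, FALSE), length.out = ncol(m))
    model <- fit_model(m, lab, k = 3)
    idx <- diagnostic_index(model, m)
    model$cutpoint <- choose_cutpoint(model, idx, !lab)
    ss <- sens_spec(idx, lab, model$cutpoint)
    expect_identical(unname(ss["specificity"]), 1)
  }
})

test_that("stratified CV selects panels deterministically and validates input", {
  m <- rand_expr(50, 30, seed = 45)
  lab <- rep(c(TRUE, FALSE), each = 15)
  m[1:2, lab] <- m[1:2, lab] + 2
  cv1 <- cv_select_panel_size(m, lab, k_grid = 1:8, folds = 5, seed = 9)
  cv2 <- cv_select_panel_size(m, lab, k_grid = 1:8, folds = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_true(cv1$k %in% 1:8)
  expect_equal(unname(cv1$mean_auc[as.character(cv1$k)]), max(cv1$mean_auc))
  expect_error(cv_select_panel_size(m, c(rep(TRUE, 3), rep(FALSE, 27)),
                                    folds = 5), "at least")
  expect_error(cv_select_panel_size(m, lab, k_grid = 1:100, folds = 5),
               "exceeds")
})

test_that("a common affine transform changes neither the chosen k nor any call", {
  study <- small_study(seed = 46, n_probes = 100, disc = c(25, 25),
                       valid = c(30, 30))
  d <- preprocess_pipeline(study$discovery)
  v <- preprocess_pipeline(study$validation)
  lab <- d$samples$class != "non-cancer"
  m1 <- train_diagnostic_model(d$expr, lab, k_grid = 1:10, folds = 5,
                               seed = 2)
  m2 <- train_diagnostic_model(1.8 * d$expr + 4, lab, k_grid = 1:10,
                               folds = 5, seed = 2)
  expect_identical(m1$k, m2$k)
  expect_identical(m1$probes, m2$probes)
  expect_equal(m1$cutpoint, m2$cutpoint)
  expect_identical(classify(m1, v$expr), classify(m2, 1.8 * v$expr + 4))
})

test_that("a single overwhelming marker drives the chosen panel size to 1", {
  ks <- sapply(1:5, function(s) {
    study <- simulate_mced_study(seed = 200 + s, n_signature = 1, effect = 5,
                                 discovery = c(60, 60), validation = c(5, 5),
                                 n_target_probes = 300,
                                 signature_effect_sd = 0.2)
    d <- preprocess_pipeline(study$discovery)
    cv <- cv_select_panel_size(d, d$samples$class != "non-cancer",
                               k_grid = 1:10, folds = 5, seed = s)
    cv$k
  })
  expect_gte(sum(ks == 1), 3)
})
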