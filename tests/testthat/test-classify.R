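make_labelled <- function(n, seed, informative = TRUE) {
  set.seed(seed)
  label <- rbinom(n, 1, 0.35)
  x <- if (informative) label + rnorm(n, sd = 0.5) else rnorm(n)
  data.frame(label = label, x = x, noise1 = rnorm(n), noise2 = rnorm(n),
             noise3 = rnorm(n), recording_id = rep(c("a", "b"), length.out = n))
}

xor_data <- function(n, seed) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  data.frame(label = as.integer(xor(x1 > 0, x2 > 0)), x1 = x1, x2 = x2)
}

test_that("the train/eval split is disjoint, exhaustive and reproducible", {
  d <- make_labelled(1000, 1)
  sp <- split_train_eval(d, seed = 5)
  expect_equal(nrow(sp$train) + nrow(sp$eval), 1000)
  expect_lte(abs(nrow(sp$train) - 800), 1)
  expect_identical(split_train_eval(d, seed = 5)$train, sp$train)
  all_train <- split_train_eval(d, train_frac = 1, seed = 5)
  expect_equal(nrow(all_train$eval), 0)
  by_rec <- split_train_eval(d, train_frac = 0.5, seed = 5,
                             by_recording = TRUE)
  expect_length(intersect(unique(by_rec$train$recording_id),
                          unique(by_rec$eval$recording_id)), 0)
})

test_that("screening ranks predictors and flags uninformative ones", {
  d <- make_labelled(3000, 2)
  sc <- screen_predictors(d, predictors = c("x", "noise1", "noise2"),
                          cv_repeats = 2, seed = 3)
  expect_identical(sc$predictor[1], "x")
  expect_gt(sc$auc[sc$predictor == "x"], 0.9)
  expect_true(all(sc$flagged[sc$predictor != "x"]))

  # near-noiseless predictor separates almost perfectly
  d2 <- data.frame(label = rbinom(2000, 1, 0.4))
  d2$x <- d2$label + rnorm(2000, sd = 0.01)
  sc2 <- screen_predictors(d2, predictors = "x", cv_repeats = 2, seed = 3)
  expect_gt(sc2$auc, 0.99)

  # a label-independent predictor hovers at chance on a large sample
  d3 <- make_labelled(10000, 4, informative = FALSE)
  sc3 <- screen_predictors(d3, predictors = "x", cv_repeats = 2, seed = 3)
  expect_gt(sc3$auc, 0.47); expect_lt(sc3$auc, 0.53)

  # AUC is invariant under strictly monotone transforms
  d$x_mono <- exp(3 * d$x)
  sc4 <- screen_predictors(d, predictors = c("x", "x_mono"),
                           cv_repeats = 2, seed = 3)
  expect_equal(sc4$auc[sc4$predictor == "x"],
               sc4$auc[sc4$predictor == "x_mono"], tolerance = 0.01)
})

test_that("random forests capture the XOR interaction that additive logistic misses", {
  for (seed in 1:5) {
    d <- xor_data(1500, seed)
    sp <- split_train_eval(d, seed = seed)
    lg <- fit_predict(sp$train, sp$eval, "logistic", c("x1", "x2"),
                      cv_repeats = 0, seed = seed)
    rf <- fit_predict(sp$train, sp$eval, "random_forest", c("x1", "x2"),
                      ntree = 300, cv_repeats = 0, seed = seed)
    expect_lte(lg$auc, 0.6)
    expect_gte(rf$auc, 0.9)
    # pairwise product terms rescue the logistic model
    lgi <- fit_predict(sp$train, sp$eval, "logistic", c("x1", "x2"),
                       interactions = TRUE, cv_repeats = 0, seed = seed)
    expect_gte(lgi$auc, 0.9)
  }
})

test_that("permuted labels give chance-level AUC and separable data AUC 1", {
  d <- make_labelled(2000, 7)
  d$label <- sample(d$label)
  sp <- split_train_eval(d, seed = 7)
  rep <- fit_predict(sp$train, sp$eval, "logistic", "x", cv_repeats = 0)
  expect_lt(abs(rep$auc - 0.5), 0.06)

  sep <- data.frame(label = rep(c(0, 1), each = 100),
                    x = c(rnorm(100, -3), rnorm(100, 3)))
  rep2 <- fit_predict(sep, sep, "logistic", "x", cv_repeats = 0)
  expect_equal(rep2$auc, 1)

  single <- data.frame(label = rep(1, 50), x = rnorm(50))
  expect_error(fit_predict(single, sep, "logistic", "x", cv_repeats = 0),
               "single class")
})

test_that("the CV stability pass reports plausible fold AUCs", {
  d <- make_labelled(600, 8)
  sp <- split_train_eval(d, seed = 8)
  rep <- fit_predict(sp$train, sp$eval, "logistic", "x",
                     cv_folds = 5, cv_repeats = 3, seed = 8)
  expect_length(rep$cv_auc, 3)
  expect_true(all(rep$cv_auc > 0.8))
  expect_identical(rep$cv_scheme, list(folds = 5, repeats = 3))
})

test_that("DeLong comparisons behave on identical, distinct and swapped inputs", {
  d <- make_labelled(2000, 9)
  strong <- d$x
  set.seed(10); random <- rnorm(2000)
  expect_equal(delong_compare(strong, strong, d$label), 1)
  p <- delong_compare(strong, random, d$label)
  expect_lt(p, 0.001)
  expect_equal(delong_compare(random, strong, d$label), p, tolerance = 1e-12)
})

test_that("OOB importance singles out informative predictors", {
  d <- make_labelled(1500, 11)
  rf <- fit_predict(split_train_eval(d, seed = 1)$train, d, "random_forest",
                    c("x", "noise1", "noise2", "noise3"),
                    cv_repeats = 0, seed = 11)
  imp <- variable_importance(rf)
  expect_identical(imp$predictor[1], "x")
  expect_equal(imp$importance_normalized[1], 1)
  noise_med <- stats::median(imp$importance[imp$predictor != "x"])
  expect_gte(imp$importance[1], 5 * max(noise_med, 1e-6))

  # a duplicated informative predictor shares importance; both beat noise
  d$x_dup <- d$x + rnorm(nrow(d), sd = 0.01)
  rf2 <- fit_predict(split_train_eval(d, seed = 1)$train, d,
                     "random_forest", c("x", "x_dup", "noise1", "noise2"),
                     cv_repeats = 0, seed = 11)
  imp2 <- variable_importance(rf2)
  noise_max <- max(imp2$importance[grepl("noise", imp2$predictor)])
  expect_true(all(imp2$importance[imp2$predictor %in% c("x", "x_dup")] >
                    noise_max))
})

test_that("the Youden cutoff maximizes sensitivity + specificity - 1", {
  yc <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yc$cutoff, 0.5)   # midpoint of the separating gap
  expect_equal(yc$j, 1)
  set.seed(12)
  null <- youden_cutoff(runif(5000), rbinom(5000, 1, 0.4))
  expect_lt(null$j, 0.08)
  # exhaustive-enumeration oracle on a small mixed case
  scores <- c(0.1, 0.35, 0.4, 0.6, 0.62, 0.9)
  labels <- c(0, 1, 0, 1, 1, 0)
  yc2 <- youden_cutoff(scores, labels)
  brute <- sapply(seq(0, 1, by = 0.001), function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  })
  expect_equal(yc2$j, max(brute), tolerance = 1e-9)
})

test_that("excerpt selection fills the four cells from a constructed stream", {
  rate <- 8; wn <- 60  # 7.5 s at 8 Hz
  seg <- function(lab, pred, qom) {
    list(lab = rep(lab, wn), pred = rep(pred, wn), qom = rep(qom, wn))
  }
  buffer <- list(lab = rep(c(0, 1), wn / 2), pred = rep(c(1, 0), wn / 2),
                 qom = rep(0.5, wn))
  cells <- list(TP = c(1, 1), TN = c(0, 0), FP = c(0, 1), FN = c(1, 0))
  lab <- c(); pred <- c(); qom <- c()
  for (cl in names(cells)) {
    for (k in 1:12) {
      s <- seg(cells[[cl]][1], cells[[cl]][2], ifelse(k %% 2 == 0, 1, 0))
      lab <- c(lab, s$lab, buffer$lab)
      pred <- c(pred, s$pred, buffer$pred)
      qom <- c(qom, s$qom, buffer$qom)
    }
  }
  sel <- select_excerpts(pred, lab, qom, cutoff = 0.5, rate_hz = rate,
                         dur_s = 7.5, majority_s = 4, hop_s = 7.5 / 2)
  expect_equal(nrow(sel), 48)
  expect_equal(unname(table(sel$cell)), rep(12L, 4), ignore_attr = TRUE)
  expect_true(all(table(sel$cell, sel$qom_class) == 6))
  # selected excerpts never overlap
  sel <- sel[order(sel$start_s), ]
  expect_true(all(diff(sel$start_s) >= 7.5 - 1e-9))
})

test_that("excerpt selection enforces the 4-second majority strictly", {
  rate <- 8; n <- 60
  lab <- c(rep(1, 31), rep(0, n - 31))     # 3.875 s of label-positive
  pred <- lab
  expect_warning(
    sel <- select_excerpts(pred, lab, rep(1, n), cutoff = 0.5,
                           rate_hz = rate, dur_s = 7.5, majority_s = 4,
                           hop_s = 7.5),
    "no candidate")
  expect_equal(nrow(sel), 0)

  # an all-TP stream returns only TP excerpts
  lab2 <- rep(1, 8 * 60); pred2 <- rep(1, 8 * 60)
  expect_warning(
    sel2 <- select_excerpts(pred2, lab2, rep(1, length(lab2)), cutoff = 0.5,
                            rate_hz = rate, dur_s = 7.5, majority_s = 4),
    "selected")
  expect_true(all(sel2$cell == "TP"))
  expect_gt(nrow(sel2), 0)
})
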