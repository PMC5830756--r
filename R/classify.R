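quiet_roc <- function(labels, scores) {
  pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' Random row-level train/evaluation split
#'
#' Frame-level random split (80/20 by default). Frames of one recording are
#' strongly autocorrelated, so a row-level split leaks information between
#' train and evaluation sets; for honest generalization to unseen recordings
#' use `by_recording = TRUE`, which splits whole recordings instead.
#'
#' @param table A `predictor_table` (any data frame with a `label` column).
#' @param train_frac Fraction of rows (or recordings) in the training set.
#' @param seed Integer seed.
#' @param stratify Stratify the row-level split by label.
#' @param by_recording Split whole recordings instead of rows.
#' @return List with `train` and `eval` data frames (disjoint, exhaustive).
#' @export
split_train_eval <- function(table, train_frac = 0.8, seed = 1L,
                             stratify = FALSE, by_recording = FALSE) {
  stopifnot(train_frac >= 0, train_frac <= 1)
  set.seed(seed)
  n <- nrow(table)
  if (by_recording) {
    ids <- unique(table$recording_id)
    tr_ids <- sample(ids, round(train_frac * length(ids)))
    idx <- which(table$recording_id %in% tr_ids)
  } else if (stratify) {
    idx <- unlist(lapply(split(seq_len(n), table$label), function(rows) {
      sample(rows, round(train_frac * length(rows)))
    }), use.names = FALSE)
  } else {
    idx <- sample.int(n, round(train_frac * n))
  }
  list(train = table[sort(idx), , drop = FALSE],
       eval = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

cv_fold_auc <- function(data, predictors, folds, repeats, seed) {
  set.seed(seed)
  n <- nrow(data)
  fmla <- stats::as.formula(paste("label ~",
                                  paste(sprintf("`%s`", predictors),
                                        collapse = " + ")))
  vapply(seq_len(repeats), function(r) {
    fold <- sample(rep_len(seq_len(folds), n))
    scores <- numeric(n)
    for (k in seq_len(folds)) {
      fit <- suppressWarnings(
        stats::glm(fmla, data = data[fold != k, , drop = FALSE],
                   family = stats::binomial()))
      scores[fold == k] <- stats::predict(
        fit, newdata = data[fold == k, , drop = FALSE], type = "response")
    }
    as.numeric(pROC::auc(quiet_roc(data$label, scores)))
  }, numeric(1))
}

#' Screen individual predictors by univariate classification rate
#'
#' One univariate logistic regression per predictor, scored by
#' cross-validated out-of-fold AUC on the training set. Predictors whose AUC
#' does not exceed the majority-class baseline rate are flagged for
#' elimination.
#'
#' @param train Training data frame with `label` and predictor columns.
#' @param predictors Predictor names (default: all twelve present).
#' @param cv_folds,cv_repeats Cross-validation scheme (default 10 x 10).
#' @param seed Integer seed for fold assignment.
#' @return Data frame: `predictor`, `auc` (mean over repeats), `baseline`,
#'   `flagged`, sorted by decreasing AUC.
#' @export
screen_predictors <- function(train,
                              predictors = intersect(predictor_columns(),
                                                     names(train)),
                              cv_folds = 10, cv_repeats = 10, seed = 1L) {
  stopifnot("label" %in% names(train), length(unique(train$label)) == 2)
  p1 <- mean(train$label)
  baseline <- max(p1, 1 - p1)
  aucs <- vapply(predictors, function(p) {
    mean(cv_fold_auc(train[, c("label", p)], p, cv_folds, cv_repeats, seed))
  }, numeric(1))
  out <- data.frame(predictor = predictors, auc = aucs,
                    baseline = baseline, flagged = aucs < baseline,
                    row.names = NULL)
  out[order(-out$auc), ]
}

#' Fit a bout classifier and evaluate it on held-out data
#'
#' Trains logistic regression or a 500-tree random forest (`mtry` defaulting
#' to the square root of the number of predictors) on the training set and
#' reports the AUC of its predictions on the held-out evaluation set, with a
#' DeLong 95% confidence interval, the Youden-cutoff confusion asymmetry
#' (false-positive and false-negative rates), and optionally a repeated
#' k-fold cross-validation stability summary within the training set. The
#' models have no tuned hyperparameters, so the CV pass is diagnostic only
#' and does not affect the held-out AUC; `cv_repeats = 0` skips it.
#'
#' @param train,eval Data frames with `label` and predictor columns.
#' @param model_kind `"logistic"` or `"random_forest"`.
#' @param predictor_set Predictor column names.
#' @param ntree Trees in the forest (default 500).
#' @param mtry Variables per split (default `floor(sqrt(p))`).
#' @param interactions For logistic models, add all pairwise product terms.
#' @param cv_folds,cv_repeats CV stability scheme (default 10 x 10; 0
#'   repeats to skip).
#' @param seed Integer seed (fold assignment, forest bootstrap).
#' @return A `classification_report`: `model_kind`, `predictor_set`, `auc`,
#'   `ci95`, `cutoff`, `confusion` (`fp_rate`, `fn_rate`), `cv_scheme`,
#'   `cv_auc` (per-repeat), `eval_scores`, `eval_labels`, `model`, `seed`.
#' @export
fit_predict <- function(train, eval, model_kind = c("logistic",
                                                    "random_forest"),
                        predictor_set = predictor_set_8(), ntree = 500,
                        mtry = NULL, interactions = FALSE,
                        cv_folds = 10, cv_repeats = 10, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(all(predictor_set %in% names(train)),
            all(predictor_set %in% names(eval)))
  if (length(unique(train$label)) < 2) {
    stop("training labels contain a single class")
  }
  set.seed(seed)
  if (model_kind == "logistic") {
    terms <- sprintf("`%s`", predictor_set)
    if (interactions && length(predictor_set) > 1) {
      pairs <- utils::combn(sprintf("`%s`", predictor_set), 2,
                            paste, collapse = ":")
      terms <- c(terms, pairs)
    }
    fmla <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
    model <- suppressWarnings(
      stats::glm(fmla, data = train, family = stats::binomial()))
    scores <- stats::predict(model, newdata = eval, type = "response")
  } else {
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(predictor_set))))
    model <- randomForest::randomForest(
      x = train[, predictor_set, drop = FALSE],
      y = factor(train$label, levels = c(0, 1)),
      ntree = ntree, mtry = mtry, importance = TRUE)
    scores <- stats::predict(model, newdata = eval[, predictor_set,
                                                   drop = FALSE],
                             type = "prob")[, "1"]
  }
  roc <- quiet_roc(eval$label, scores)
  # pROC warns that the DeLong CI of a perfect AUC is degenerate; fine here
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(roc, method = "delong")))
  yj <- youden_cutoff(scores, eval$label)
  pred_pos <- scores >= yj$cutoff
  pos <- eval$label == 1
  confusion <- list(fp_rate = mean(pred_pos[!pos]),
                    fn_rate = mean(!pred_pos[pos]))
  cv_auc <- if (cv_repeats > 0 && model_kind == "logistic") {
    cv_fold_auc(train[, c("label", predictor_set)], predictor_set,
                cv_folds, cv_repeats, seed)
  } else if (cv_repeats > 0) {
    cv_rf_auc(train, predictor_set, ntree, mtry, cv_folds, cv_repeats, seed)
  } else {
    numeric(0)
  }
  structure(list(model_kind = model_kind, predictor_set = predictor_set,
                 auc = as.numeric(pROC::auc(roc)),
                 ci95 = c(lower = ci[1], upper = ci[3]),
                 cutoff = yj$cutoff, youden_j = yj$j,
                 confusion = confusion,
                 cv_scheme = list(folds = cv_folds, repeats = cv_repeats),
                 cv_auc = cv_auc,
                 eval_scores = as.numeric(scores),
                 eval_labels = eval$label,
                 model = model, seed = seed),
            class = "classification_report")
}

cv_rf_auc <- function(data, predictors, ntree, mtry, folds, repeats, seed) {
  set.seed(seed)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(predictors))))
  n <- nrow(data)
  vapply(seq_len(repeats), function(r) {
    fold <- sample(rep_len(seq_len(folds), n))
    scores <- numeric(n)
    for (k in seq_len(folds)) {
      fit <- randomForest::randomForest(
        x = data[fold != k, predictors, drop = FALSE],
        y = factor(data$label[fold != k], levels = c(0, 1)),
        ntree = ntree, mtry = mtry)
      scores[fold == k] <- stats::predict(
        fit, newdata = data[fold == k, predictors, drop = FALSE],
        type = "prob")[, "1"]
    }
    as.numeric(pROC::auc(quiet_roc(data$label, scores)))
  }, numeric(1))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %s, %d predictors: eval AUC = %.3f (CI95 %.3f-%.3f)\n",
    x$model_kind, length(x$predictor_set), x$auc, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Youden cutoff %.3f; fp_rate %.3f, fn_rate %.3f\n",
              x$cutoff, x$confusion$fp_rate, x$confusion$fn_rate))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired nonparametric comparison of two prediction vectors scored on the
#' same evaluation labels.
#'
#' @param predictions_a,predictions_b Numeric score vectors.
#' @param labels Binary labels (0/1).
#' @return Two-sided p-value.
#' @export
delong_compare <- function(predictions_a, predictions_b, labels) {
  if (isTRUE(all.equal(as.numeric(predictions_a),
                       as.numeric(predictions_b)))) {
    return(1)
  }
  t <- pROC::roc.test(quiet_roc(labels, predictions_a),
                      quiet_roc(labels, predictions_b),
                      method = "delong", paired = TRUE)
  as.numeric(t$p.value)
}

#' Out-of-bag permutation importance of a random forest report
#'
#' Mean decrease in out-of-bag classification accuracy when each predictor
#' is perturbed, normalized so the largest importance is 1.
#'
#' @param report A `classification_report` from a `"random_forest"`
#'   [fit_predict()] (or a `randomForest` model).
#' @return Data frame `predictor`, `importance`, `importance_normalized`,
#'   sorted decreasing.
#' @export
variable_importance <- function(report) {
  model <- if (inherits(report, "classification_report")) report$model else
    report
  stopifnot(inherits(model, "randomForest"))
  imp <- randomForest::importance(model, type = 1, scale = FALSE)[, 1]
  norm <- if (max(imp) > 0) imp / max(imp) else imp
  out <- data.frame(predictor = names(imp), importance = as.numeric(imp),
                    importance_normalized = as.numeric(norm),
                    row.names = NULL)
  out[order(-out$importance), ]
}

#' Youden-index optimal classification cutoff
#'
#' Scans thresholds at midpoints between consecutive unique scores (plus the
#' outer extremes) and maximizes J = sensitivity + specificity - 1; ties are
#' broken toward the lowest threshold. A perfectly separating score yields
#' the midpoint of the separating gap with J = 1.
#'
#' @param scores Numeric scores (higher = more bout-like).
#' @param labels Binary labels (0/1).
#' @return List: `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels > 0.5)
  stopifnot(length(scores) == length(labels), any(labels == 1),
            any(labels == 0))
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # lowest threshold among ties
  list(cutoff = thr[best], j = j[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Select stimulus excerpts for the four prediction cells
#'
#' Slides fixed-duration candidate windows over a frame-wise prediction
#' stream and assigns each to a confusion cell (TP/TN/FP/FN) when both the
#' annotation label and the thresholded model prediction hold their class for
#' at least `majority_s` of the window. Window-summed quantity of motion is
#' median-split into high/low across candidates, and up to `n_per_cell`
#' non-overlapping windows per cell are selected, balanced across the
#' quantity-of-motion classes (preferring purer windows; never relaxing the
#' majority criterion). A cell with too few candidates returns fewer, with a
#' warning.
#'
#' @param predictions Numeric model scores per frame.
#' @param labels Binary annotation labels per frame.
#' @param qom Quantity-of-motion [time_series()] (or numeric vector) per
#'   frame.
#' @param cutoff Score threshold (from [youden_cutoff()]).
#' @param rate_hz Frame rate of the streams.
#' @param n_per_cell Excerpts per cell (default 12).
#' @param dur_s Excerpt duration (default 7.5 s).
#' @param majority_s Required per-criterion agreement time (default 4 s).
#' @param hop_s Candidate window hop (default 0.5 s).
#' @param recording_id Identifier stamped on the specs.
#' @return Data frame of excerpt specs: `recording_id`, `start_s`,
#'   `duration_s`, `cell`, `qom_class`, `qom_sum`.
#' @export
select_excerpts <- function(predictions, labels, qom, cutoff, rate_hz,
                            n_per_cell = 12, dur_s = 7.5, majority_s = 4,
                            hop_s = 0.5, recording_id = NA_character_) {
  qv <- if (inherits(qom, "duet_ts")) qom$values else as.numeric(qom)
  n <- length(predictions)
  stopifnot(length(labels) == n, length(qv) == n)
  wn <- round(dur_s * rate_hz)
  dur_eff <- wn / rate_hz  # realized window duration on the frame grid
  hopn <- max(1L, round(hop_s * rate_hz))
  starts <- seq(1L, n - wn + 1L, by = hopn)
  if (length(starts) == 0) stop("stream shorter than one excerpt")
  pred_pos <- as.numeric(predictions >= cutoff)
  lab <- as.numeric(labels > 0.5)
  csum <- function(v) { c0 <- cumsum(c(0, v)); c0[starts + wn] - c0[starts] }
  lab_s <- csum(lab) / rate_hz
  pred_s <- csum(pred_pos) / rate_hz
  qom_sum <- csum(qv)
  cell <- rep(NA_character_, length(starts))
  lab_yes <- lab_s >= majority_s
  lab_no <- (dur_eff - lab_s) >= majority_s
  pred_yes <- pred_s >= majority_s
  pred_no <- (dur_eff - pred_s) >= majority_s
  cell[lab_yes & pred_yes] <- "TP"
  cell[lab_no & pred_no] <- "TN"
  cell[lab_no & pred_yes] <- "FP"
  cell[lab_yes & pred_no] <- "FN"
  cand <- data.frame(start = starts, cell = cell,
                     lab_margin = pmax(lab_s, dur_eff - lab_s),
                     pred_margin = pmax(pred_s, dur_eff - pred_s),
                     qom_sum = qom_sum)[!is.na(cell), ]
  if (nrow(cand) == 0) {
    warning("no candidate windows satisfy the majority criteria")
    return(data.frame(recording_id = character(0), start_s = numeric(0),
                      duration_s = numeric(0), cell = character(0),
                      qom_class = character(0), qom_sum = numeric(0)))
  }
  med <- stats::median(cand$qom_sum)
  cand$qom_class <- ifelse(cand$qom_sum > med, "high", "low")
  purity <- pmin(cand$lab_margin, cand$pred_margin)
  cand <- cand[order(-purity, cand$start), ]
  taken <- matrix(0L, 0, 2)  # start, end (frames) of accepted windows
  sel <- list()
  count <- table(factor(character(0),
                        levels = c(paste0(rep(c("TP", "TN", "FP", "FN"),
                                              each = 2),
                                          "_", c("high", "low")))))
  per_class <- n_per_cell / 2
  for (i in seq_len(nrow(cand))) {
    key <- paste0(cand$cell[i], "_", cand$qom_class[i])
    if (count[key] >= per_class) next
    s0 <- cand$start[i]; e0 <- s0 + wn - 1L
    if (nrow(taken) > 0 &&
        any(s0 <= taken[, 2] & e0 >= taken[, 1])) next
    taken <- rbind(taken, c(s0, e0))
    count[key] <- count[key] + 1
    sel[[length(sel) + 1]] <- data.frame(
      recording_id = recording_id, start_s = (s0 - 1) / rate_hz,
      duration_s = dur_s, cell = cand$cell[i],
      qom_class = cand$qom_class[i], qom_sum = cand$qom_sum[i])
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    data.frame(recording_id = character(0), start_s = numeric(0),
               duration_s = numeric(0), cell = character(0),
               qom_class = character(0), qom_sum = numeric(0))
  if (nrow(out) < 4 * n_per_cell) {
    warning(sprintf("selected %d of %d requested excerpts", nrow(out),
                    4 * n_per_cell))
  }
  out[order(out$start_s), ]
}
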