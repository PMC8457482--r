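# Predictive-power assessment: rank-based AUC, the equal
# sensitivity-specificity threshold, omission errors, the
# outside-region-train / in-region-test spatial hold-out, and stratified
# k-fold cross-validation.

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random used
#' point's score exceeds a random available point's, with ties counting
#' one half.
#'
#' @param scores numeric model scores.
#' @param labels 0/1 labels (1 = used/conflict).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("both labels must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                      # average ranks give the tie halves
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Equal sensitivity-specificity threshold
#'
#' Scans candidate thresholds — the distinct observed scores plus the
#' midpoints between consecutive distinct scores — and returns the one
#' minimizing |sensitivity - specificity|, where sensitivity is the
#' fraction of used points scoring at or above the threshold and
#' specificity the fraction of available points scoring below it. Ties go
#' to the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return the selected threshold.
#' @export
equal_ss_threshold <- function(scores, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("both labels must be present")
  u <- sort(unique(scores))
  cand <- sort(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2))
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  gap <- vapply(cand, function(t) {
    abs(mean(s1 >= t) - mean(s0 < t))
  }, numeric(1))
  cand[which.min(gap)]           # which.min takes the first = lowest
}

#' Omission errors at a threshold
#'
#' Conflict omission is the fraction of used points scoring below the
#' threshold; non-conflict omission the fraction of available points
#' scoring at or above it. "Overall" is reported two ways, because both
#' conventions occur in practice: \code{overall_pooled} (misclassified
#' fraction of all points) and \code{overall_mean} (mean of the two class
#' rates).
#'
#' @inheritParams roc_auc
#' @param threshold score threshold.
#' @return named list: \code{conflict}, \code{nonconflict},
#'   \code{overall_pooled}, \code{overall_mean}.
#' @export
omission_errors <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  conf <- mean(scores[labels == 1] < threshold)
  nonc <- mean(scores[labels == 0] >= threshold)
  miss <- sum(scores[labels == 1] < threshold) +
    sum(scores[labels == 0] >= threshold)
  list(conflict = conf, nonconflict = nonc,
       overall_pooled = miss / length(scores),
       overall_mean = (conf + nonc) / 2)
}

#' Spatial hold-out split
#'
#' Training points fall outside the focal region, test points inside —
#' the design that asks whether a model trained on the wider study area
#' transfers into the focal subregion.
#'
#' @param points a \code{point_set}.
#' @param focal_mask boolean \code{grid_raster} of the focal region.
#' @return list with \code{train} and \code{test} \code{point_set}s.
#' @export
spatial_holdout <- function(points, focal_mask) {
  idx <- cell_index(focal_mask, points$x, points$y)
  ok <- in_grid(focal_mask, idx)
  lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * nrow(focal_mask$values)
  inside <- ok
  inside[ok] <- !is.na(focal_mask$values[lin]) & focal_mask$values[lin] != 0
  if (all(inside)) stop("no training points: focal mask covers every point")
  if (!any(inside)) stop("no test points inside the focal mask")
  train <- points[!inside, , drop = FALSE]
  test <- points[inside, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("point_set", "data.frame")
  for (side in list(train, test))
    if (length(unique(side$label)) < 2)
      warning("a split side does not contain both labels")
  list(train = train, test = test)
}

# score = fitted w at each row of an rspf_data-style design
score_design <- function(fit, x) eval_w(unname(fit$beta), x)

#' Validate a fitted model on a train/test design split
#'
#' Fits the given terms on the training rows (bootstrap off), derives the
#' equal sensitivity-specificity threshold on the training scores, and
#' reports AUC and omission errors on the test rows.
#'
#' @param data an \code{rspf_data} covering all points.
#' @param train_idx,test_idx row indices into \code{data$x}.
#' @param terms term-set to fit (default all).
#' @param gates named numeric \code{c(auc = 0.7, omission = 0.3)} pass/fail
#'   gates.
#' @return a \code{validation_report} row (list).
#' @export
validate_split <- function(data, train_idx, test_idx, terms = data$terms,
                           gates = c(auc = 0.7, omission = 0.3)) {
  d <- design_subset(data, terms)
  fit <- fit_rspf(list(x = d$x[train_idx, , drop = FALSE],
                       y = data$y[train_idx],
                       terms = terms,
                       reference_class = data$reference_class), B = 0)
  thr <- equal_ss_threshold(score_design(fit, d$x[train_idx, , drop = FALSE]),
                            data$y[train_idx])
  sc <- score_design(fit, d$x[test_idx, , drop = FALSE])
  yte <- data$y[test_idx]
  om <- omission_errors(sc, yte, thr)
  auc <- roc_auc(sc, yte)
  list(aic = fit$aic, auc = auc, threshold = thr,
       omission_conflict = om$conflict,
       omission_nonconflict = om$nonconflict,
       overall_pooled = om$overall_pooled,
       overall_mean = om$overall_mean,
       n_train = c(used = sum(data$y[train_idx] == 1),
                   avail = sum(data$y[train_idx] == 0)),
       n_test = c(used = sum(yte == 1), avail = sum(yte == 0)),
       passes = c(auc = unname(auc > gates["auc"]),
                  omission = unname(om$overall_mean < gates["omission"])))
}

# random stratified fold assignment: each label stratum is split as evenly
# as possible across the k folds
stratified_folds <- function(y, k, seed) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (k < 2) stop("k must be >= 2")
  if (k > n1 || k > n0) stop("k exceeds the size of a label stratum")
  fold <- integer(length(y))
  with_seed(seed, {
    fold[y == 1] <- sample(rep_len(seq_len(k), n1))
    fold[y == 0] <- sample(rep_len(seq_len(k), n0))
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions each label stratum into k folds; each fold serves
#' once as the test set for a model trained on the remaining folds
#' (bootstrap off). The classification threshold is always derived on the
#' training scores. Per-fold rows report training AIC, test AUC and
#' omission errors.
#'
#' @param data an \code{rspf_data}.
#' @param terms term-set to fit (default all terms).
#' @param k number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param gates pass/fail gates, as in \code{\link{validate_split}}.
#' @return a \code{cv_report}: \code{per_fold} data.frame and \code{mean}
#'   row.
#' @export
kfold_cv <- function(data, terms = data$terms, k = 5, seed = 1,
                     gates = c(auc = 0.7, omission = 0.3)) {
  fold <- stratified_folds(data$y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    r <- validate_split(data, which(fold != f), which(fold == f),
                        terms = terms, gates = gates)
    data.frame(fold = f, aic = r$aic, auc = r$auc,
               omission_conflict = r$omission_conflict,
               omission_nonconflict = r$omission_nonconflict,
               overall_pooled = r$overall_pooled,
               overall_mean = r$overall_mean)
  })
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1]),
                 fold = fold, k = k, seed = seed, gates = gates),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", x$k))
  print(transform(x$per_fold, aic = round(aic, 2), auc = round(auc, 3),
                  omission_conflict = round(omission_conflict, 3),
                  omission_nonconflict = round(omission_nonconflict, 3),
                  overall_pooled = round(overall_pooled, 3),
                  overall_mean = round(overall_mean, 3)))
  invisible(x)
}
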