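test_that("roc_auc reproduces closed forms and the all-pairs oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 8), rep(c(0, 1), 4)), 0.5)
  # all-pairs concordance oracle on a small mixed instance
  scores <- c(0.1, 0.4, 0.35, 0.8); labels <- c(0, 1, 0, 1)
  pairs <- expand.grid(i = which(labels == 1), j = which(labels == 0))
  conc <- mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                      ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
  expect_equal(roc_auc(scores, labels), conc)
  set.seed(3)
  s <- sample(seq(0, 1, 0.1), 40, replace = TRUE)  # plenty of ties
  y <- rbinom(40, 1, 0.4)
  if (any(y == 1) && any(y == 0)) {
    pr <- expand.grid(i = which(y == 1), j = which(y == 0))
    oracle <- mean(ifelse(s[pr$i] > s[pr$j], 1,
                          ifelse(s[pr$i] == s[pr$j], 0.5, 0)))
    expect_equal(roc_auc(s, y), oracle)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both labels")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  set.seed(21)
  s <- c(stats::rnorm(40, 1), stats::rnorm(60))
  y <- rep(c(1, 0), c(40, 60))
  got <- roc_auc(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("complement-label identity holds exactly, including ties", {
  set.seed(5)
  s <- sample(seq(0, 1, 0.25), 30, replace = TRUE)
  y <- rep(c(0, 1), 15)
  expect_identical(roc_auc(s, y) + roc_auc(s, 1 - y), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  s <- stats::rnorm(50)
  y <- rbinom(50, 1, 0.5); y[1] <- 1; y[2] <- 0
  a0 <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a0)
  expect_equal(roc_auc(rank(s), y), a0)
})

test_that("equal_ss_threshold balances the class rates", {
  s <- c(0.1, 0.15, 0.2, 0.8, 0.85, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  thr <- equal_ss_threshold(s, y)
  expect_gt(thr, 0.2); expect_lte(thr, 0.8)
  om <- omission_errors(s, y, thr)
  expect_equal(om$conflict, 0)
  expect_equal(om$nonconflict, 0)
  # swapped labels reach the same objective value at the mirrored threshold
  obj <- function(t, sc, yy) abs(mean(sc[yy == 1] >= t) - mean(sc[yy == 0] < t))
  thr_sw <- equal_ss_threshold(-s, 1 - y)
  expect_equal(obj(thr, s, y), obj(thr_sw, -s, 1 - y))
  # one used vs one available: a separating cut with zero omissions
  thr2 <- equal_ss_threshold(c(0.2, 0.8), c(0, 1))
  om2 <- omission_errors(c(0.2, 0.8), c(0, 1), thr2)
  expect_equal(om2$conflict + om2$nonconflict, 0)
})

test_that("omission errors match direct counting", {
  s <- c(0.1, 0.6, 0.3, 0.9, 0.2, 0.7)
  y <- c(0, 1, 0, 1, 1, 0)
  om <- omission_errors(s, y, 0.5)
  expect_equal(om$conflict, mean(s[y == 1] < 0.5))
  expect_equal(om$nonconflict, mean(s[y == 0] >= 0.5))
  expect_equal(om$overall_pooled,
               (sum(s[y == 1] < 0.5) + sum(s[y == 0] >= 0.5)) / 6)
  expect_equal(om$overall_mean, (om$conflict + om$nonconflict) / 2)
  # degenerate thresholds
  above <- omission_errors(s, y, 2)
  expect_equal(above$conflict, 1)
  expect_equal(above$nonconflict, 0)
  perfect <- omission_errors(c(0, 0, 1, 1), c(0, 0, 1, 1), 0.5)
  expect_equal(unlist(perfect), c(conflict = 0, nonconflict = 0,
                                  overall_pooled = 0, overall_mean = 0))
  expect_error(omission_errors(s, y, Inf), "finite")
})

test_that("spatial holdout separates train and test by the focal mask", {
  m <- matrix(0, 10, 10); m[6:10, 1:5] <- 1      # lower-left quadrant
  focal <- mask_raster(m, cell = 10)
  set.seed(12)
  pts <- point_set(stats::runif(80, 0, 100), stats::runif(80, 0, 100),
                   rep(c(1, 0), 40))
  sp <- suppressWarnings(spatial_holdout(pts, focal))
  inside_oracle <- pts$x < 50 & pts$y < 50
  expect_setequal(sp$test$id, pts$id[inside_oracle])
  expect_setequal(sp$train$id, pts$id[!inside_oracle])
  expect_true(all(sp$test$x < 50 & sp$test$y < 50))
  full <- mask_raster(matrix(1, 10, 10), cell = 10)
  expect_error(spatial_holdout(pts, full), "no training points")
})

test_that("k-fold partitions are exact, stratified and reproducible", {
  d <- simulate_ua_design(60, ratio = 4, beta0 = -1, betas = c(x1 = 2),
                          seed = 30)
  cv <- kfold_cv(d, k = 5, seed = 7)
  fold <- cv$fold
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 300)
  # stratification: used share per fold within 1 point of the global share
  for (f in 1:5) {
    share <- mean(d$y[fold == f])
    expect_lt(abs(share - mean(d$y)), 0.011)
  }
  cv2 <- kfold_cv(d, k = 5, seed = 7)
  expect_identical(cv$fold, cv2$fold)
  expect_error(kfold_cv(d, k = 100), "stratum")
})

test_that("leave-one-out fold assignment holds one point per stratum per fold", {
  y <- rep(c(1, 0), 6)
  fold <- rspfrisk:::stratified_folds(y, k = 6, seed = 2)
  expect_equal(as.integer(table(fold)), rep(2L, 6)) # one used + one avail
  expect_true(all(tapply(y, fold, sum) == 1))
  expect_error(rspfrisk:::stratified_folds(y, k = 7, seed = 1), "stratum")
})

test_that("strong signal yields high AUC in every fold", {
  d <- simulate_ua_design(400, ratio = 4, beta0 = -5, betas = c(x1 = 6),
                          seed = 55)
  cv <- kfold_cv(d, k = 5, seed = 3)
  expect_true(all(cv$per_fold$auc > 0.8))
  expect_true(all(cv$per_fold$overall_mean >= 0 & cv$per_fold$overall_mean <= 1))
})

test_that("validate_split derives its threshold on training data only", {
  d <- simulate_ua_design(200, ratio = 3, beta0 = -1, betas = c(x1 = 2),
                          seed = 21)
  n <- length(d$y)
  idx <- seq_len(n)
  train <- idx[idx %% 2 == 0]; test <- idx[idx %% 2 == 1]
  r <- validate_split(d, train, test)
  sub <- design_subset <- d$x[train, , drop = FALSE]
  fit <- fit_rspf(list(x = sub, y = d$y[train]), B = 0)
  thr_oracle <- equal_ss_threshold(eval_w(unname(fit$beta), sub), d$y[train])
  expect_equal(r$threshold, thr_oracle)
  expect_named(r$passes, c("auc", "omission"))
})
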