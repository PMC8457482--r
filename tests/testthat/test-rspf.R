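test_that("eval_w matches closed forms and stays in (0,1) at extremes", {
  expect_equal(eval_w(c(0, 0, 0), c(3, -2)), 0.5)
  expect_equal(eval_w(c(0, 1), 1), exp(1) / (1 + exp(1)))
  lo <- eval_w(c(-800, 0), 0)
  expect_gte(lo, 0)
  expect_lt(lo, 1e-300)
  hi <- eval_w(c(800, 0), 0)
  expect_lte(hi, 1)
  expect_gt(hi, 1 - 1e-15)
  expect_error(eval_w(c(0, 1), c(1, 2)), "dimension mismatch")
  expect_error(eval_w(c(0, NA), 1), "finite")
})

test_that("eval_w is monotone in covariates with positive coefficients", {
  beta <- c(-1, 2, 0.5)
  xs <- seq(-3, 3, length.out = 25)
  w1 <- vapply(xs, function(v) eval_w(beta, c(v, 0)), numeric(1))
  expect_true(all(diff(w1) > 0))
})

test_that("the likelihood is exactly zero at beta = 0 and symmetric cases", {
  set.seed(1)
  xu <- matrix(stats::rnorm(20), 10, 2)
  xa <- matrix(stats::rnorm(60), 30, 2)
  expect_identical(neg_log_likelihood(c(0, 0, 0), xu, xa), 0)
  # one used point with covariates equal to the single available point
  xrow <- matrix(c(1.3, -0.4), 1, 2)
  for (b in list(c(0, 1, 1), c(2, -1, 0.5), c(-3, 0, 4)))
    expect_equal(neg_log_likelihood(b, xrow, xrow), 0)
})

test_that("the likelihood matches a naive two-loop oracle to 1e-12", {
  set.seed(42)
  xu <- matrix(stats::rnorm(30), 10, 3)
  xa <- matrix(stats::rnorm(90), 30, 3)
  beta <- c(0.3, -0.7, 1.1, 0.2)
  expect_equal(-neg_log_likelihood(beta, xu, xa),
               naive_loglik(beta, xu, xa), tolerance = 1e-12)
})

test_that("the likelihood is exactly invariant to duplicating availability", {
  set.seed(3)
  xu <- matrix(stats::rnorm(16), 8, 2)
  xa <- matrix(stats::rnorm(40), 20, 2)
  beta <- c(-0.5, 1, 0.3)
  expect_identical(neg_log_likelihood(beta, xu, xa),
                   neg_log_likelihood(beta, xu, rbind(xa, xa)))
})

test_that("analytic gradient agrees with central differences", {
  set.seed(9)
  xu <- matrix(stats::rnorm(40), 20, 2)
  xa <- matrix(stats::rnorm(120), 60, 2)
  beta <- c(0.2, 0.8, -0.6)
  g <- rspfrisk:::nll_gradient(beta, xu, xa)
  num <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- 1e-6
    (neg_log_likelihood(beta + e, xu, xa) -
       neg_log_likelihood(beta - e, xu, xa)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("count_df accounts for intercept, slopes and cover dummies", {
  cont6 <- paste0("v", 1:6)
  expect_identical(count_df(c(cont6, "cover"), "cover", 8), 14L)
  expect_identical(count_df(c(paste0("v", 1:7), "cover"), "cover", 8), 15L)
  expect_identical(count_df(character(0)), 1L)
  expect_identical(count_df(cont6, "cover", 8), 7L)
  expect_error(count_df(c("a", "a")), "duplicated")
})

test_that("aic_of applies the AIC identity and rejects unconverged fits", {
  d <- toy_design(seed = 4)
  fit <- fit_rspf(d, B = 0)
  expect_equal(aic_of(fit), -2 * fit$loglik + 2 * fit$k)
  expect_equal(fit$aic, aic_of(fit))
  expect_equal(fit$k, length(fit$beta))
  bad <- fit; bad$converged <- FALSE
  expect_error(aic_of(bad), "converge")
})

test_that("a 2-parameter fit matches a grid search of the likelihood", {
  d <- toy_design(n_used = 80, n_avail = 240, beta0 = -0.5, b1 = 1, seed = 6)
  fit <- fit_rspf(d, B = 0)
  b0s <- seq(fit$beta[1] - 1, fit$beta[1] + 1, length.out = 101)
  b1s <- seq(fit$beta[2] - 1, fit$beta[2] + 1, length.out = 101)
  xu <- d$x[d$y == 1, , drop = FALSE]; xa <- d$x[d$y == 0, , drop = FALSE]
  grid_nll <- outer(b0s, b1s, Vectorize(function(a, b)
    neg_log_likelihood(c(a, b), xu, xa)))
  best <- which(grid_nll == min(grid_nll), arr.ind = TRUE)[1, ]
  step <- c(diff(b0s)[1], diff(b1s)[1])
  expect_lt(abs(b0s[best[1]] - fit$beta[1]), step[1] + 1e-9)
  expect_lt(abs(b1s[best[2]] - fit$beta[2]), step[2] + 1e-9)
})

test_that("null data rarely produce spuriously significant slopes", {
  # used points drawn uniformly over a landscape (w constant): slope
  # estimates should be statistically indistinguishable from zero. A small
  # fraction of null replicates quasi-separate (the use-availability
  # likelihood's supremum moves to the parameter boundary) and error out;
  # those count as failures here.
  spec0 <- landscape_spec(n_rows = 32, n_cols = 32,
                          covariates = data.frame(name = c("a", "b"),
                                                  range = c(4, 3),
                                                  mean = 0, sd = 1),
                          n_cover_classes = 2)
  flags <- vapply(1:50, function(s) {
    spec0$seed <- 7000 + s
    study <- simulate_landscape(spec0, true_model(0, c(a = 0, b = 0)))
    used <- simulate_conflicts(study, 300, seed = s)
    bg <- generate_background(study$region_mask, used, buffer_radius = 0,
                              ratio = 4, seed = s + 500)
    pts <- rbind(as.data.frame(used[, c("id", "x", "y", "label")]),
                 as.data.frame(bg[, c("id", "x", "y", "label")]))
    pts$id <- seq_len(nrow(pts))
    class(pts) <- c("point_set", "data.frame")
    pts <- extract_values(study$stack, pts)
    d <- rspf_design(pts, continuous = c("a", "b"))
    tryCatch({
      fit <- suppressWarnings(fit_rspf(d, B = 60, seed = s))
      all(abs(fit$beta[c("a", "b")]) < 2 * fit$se[c("a", "b")])
    }, error = function(e) FALSE)
  }, logical(1))
  # conservative binomial bound: per-replicate success ~0.85 with the
  # boundary pathology included
  expect_gte(sum(flags), 36)
})

test_that("bootstrap refits preserve stratum sizes and drop bookkeeping works", {
  d <- toy_design(n_used = 120, n_avail = 360, seed = 8)
  fit <- fit_rspf(d, B = 30, seed = 2)
  expect_equal(fit$n_used, 120)
  expect_equal(fit$n_avail, 360)
  expect_lte(fit$n_boot_dropped, 1)   # <= 5% of 30
  expect_true(all(fit$se >= 0))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  # B = 0 skips the bootstrap entirely
  f0 <- fit_rspf(d, B = 0)
  expect_true(all(is.na(f0$se)))
})

test_that("degenerate designs are rejected with informative errors", {
  d <- toy_design(seed = 3)
  expect_error(fit_rspf(d, m = 1), "m = 0")
  dc <- d; dc$x <- cbind(dc$x, const = 1)
  expect_error(fit_rspf(dc, B = 0), "constant")
  # perfectly separating covariate
  n <- 200
  sep <- list(x = matrix(c(rep(1, 100), rep(-1, 100)) +
                           stats::rnorm(n, 0, 1e-4), ncol = 1,
                         dimnames = list(NULL, "sepvar")),
              y = rep(c(1, 0), each = 100))
  expect_error(suppressWarnings(fit_rspf(sep, B = 0)), "separation")
})

test_that("read_conflict_table builds a fit-ready design from a CSV", {
  set.seed(5)
  df <- data.frame(Conflict = rep(c(1, 0), c(80, 240)),
                   elev = c(stats::rnorm(80, 600, 90),
                            stats::rnorm(240, 480, 90)),
                   popden = stats::rexp(320))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  d <- read_conflict_table(path)
  expect_s3_class(d, "rspf_data")
  expect_equal(sum(d$y), 80)
  expect_equal(colnames(d$x), c("elev", "popden"))
  fit <- fit_rspf(d, B = 0)
  expect_true(fit$converged)
})

test_that("simulated slopes are recovered within bootstrap uncertainty", {
  d <- simulate_ua_design(700, ratio = 5, beta0 = -2,
                          betas = c(x1 = 1, x2 = -0.8), seed = 77)
  fit <- fit_rspf(d, B = 100, seed = 7)
  truth <- attr(d, "truth")
  for (nm in c("x1", "x2"))
    expect_lt(abs(fit$beta[nm] - truth[nm]), 2 * fit$se[nm])
})
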