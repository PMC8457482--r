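test_that("distance_to_feature matches closed forms and handles errors", {
  f <- matrix(0, 5, 5); f[1, 1] <- 1
  d <- distance_to_feature(mask_raster(f, cell = 50))
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[4, 5], 50 * sqrt(3^2 + 4^2))   # 250 m by Pythagoras
  expect_error(distance_to_feature(mask_raster(matrix(0, 4, 4))),
               "no feature cells")
})

test_that("distance_to_feature equals the brute-force oracle on random grids", {
  for (s in 1:8) {
    set.seed(s)
    f <- matrix(stats::runif(256) < 0.08, 16, 16)
    if (!any(f)) f[sample(256, 1)] <- TRUE
    d <- distance_to_feature(mask_raster(f + 0, cell = 30))
    expect_equal(d$values, brute_distance(f, 30), tolerance = 1e-12)
  }
})

test_that("distance is bounded by the distance to any single feature cell", {
  set.seed(9)
  f <- matrix(stats::runif(400) < 0.05, 20, 20)
  f[3, 17] <- TRUE
  d <- distance_to_feature(mask_raster(f + 0, cell = 10))
  feats <- which(f, arr.ind = TRUE)
  for (k in 1:20) {
    i <- sample(20, 1); j <- sample(20, 1)
    pick <- feats[sample(nrow(feats), 1), ]
    expect_lte(d$values[i, j],
               10 * sqrt((i - pick[1])^2 + (j - pick[2])^2) + 1e-9)
  }
})

test_that("reclassify relabels cell-wise and preserves nodata", {
  set.seed(3)
  v <- matrix(sample(1:16, 48, replace = TRUE), 6, 8)
  v[2, 2] <- NA
  r <- grid_raster(v, 50, c(0, 300), kind = "categorical")
  ident <- reclassify(r, stats::setNames(1:16, 1:16))
  expect_equal(ident$values, r$values)
  # collapse 16 codes into 8 classes (pairs)
  to8 <- stats::setNames(rep(1:8, each = 2), 1:16)
  out <- reclassify(r, to8)
  expect_true(all(out$values[!is.na(out$values)] %in% 1:8))
  expect_true(is.na(out$values[2, 2]))
  expect_error(reclassify(r, to8[-3]), "does not cover")
})

test_that("log_transform applies closed forms and preserves ranks and nodata", {
  r <- grid_raster(matrix(1, 3, 3), 50, c(0, 150))
  expect_equal(log_transform(r, offset = 0)$values, matrix(0, 3, 3))
  r2 <- grid_raster(matrix(c(0, exp(1) - 1, 5, NA), 2, 2), 50, c(0, 100))
  lt <- log_transform(r2, offset = 1)
  expect_equal(lt$values[1, 1], 0)
  expect_equal(lt$values[2, 1], 1)
  expect_true(is.na(lt$values[2, 2]))
  set.seed(5)
  r3 <- grid_raster(matrix(stats::rexp(64), 8, 8), 10, c(0, 80))
  expect_equal(rank(log_transform(r3, 1)$values), rank(r3$values))
  expect_error(log_transform(grid_raster(matrix(-2, 2, 2), 10, c(0, 20)), 1),
               "positive")
})

test_that("resample_nearest is identity on the same grid and exact on oracles", {
  r <- toy_raster(nr = 6, nc = 6, cell = 30, seed = 7)
  expect_equal(resample_nearest(r, r)$values, r$values)
  # refining a constant raster stays constant
  const <- grid_raster(matrix(4.2, 4, 4), 60, c(0, 240))
  fine <- resample_nearest(const, rspfrisk:::target_grid(8, 8, 30, c(0, 240)))
  expect_true(all(fine$values == 4.2))
  # factor-3 coarsening vs per-cell nearest-centre lookup
  src <- toy_raster(nr = 9, nc = 9, cell = 10, origin = c(0, 90), seed = 8)
  tg <- rspfrisk:::target_grid(3, 3, 30, c(0, 90))
  got <- resample_nearest(src, tg)
  for (i in 1:3) for (j in 1:3) {
    tx <- (j - 0.5) * 30; ty <- 90 - (i - 0.5) * 30
    cx <- (seq_len(9) - 0.5) * 10; cy <- 90 - (seq_len(9) - 0.5) * 10
    expect_equal(got$values[i, j],
                 src$values[which.min(abs(cy - ty)), which.min(abs(cx - tx))])
  }
  # nodata propagates through nearest-neighbour lookup
  src$values[1, 1] <- NA
  expect_true(is.na(resample_nearest(src, src)$values[1, 1]))
  expect_error(resample_nearest(src, rspfrisk:::target_grid(3, 3, 30, c(1e6, 1e6))),
               "overlap")
})

test_that("crop_align produces bit-identical grids and preserves values", {
  a <- toy_raster(nr = 10, nc = 10, cell = 50, origin = c(0, 500), seed = 1)
  ext <- unname(raster_extent(a))
  same <- crop_align(list(a = a), ext)
  expect_equal(same$layers$a$values, a$values)
  # offset layers end up on one shared grid
  b <- toy_raster(nr = 10, nc = 10, cell = 50, origin = c(100, 550), seed = 2)
  st <- crop_align(list(a = a, b = b), c(100, 400, 100, 400))
  expect_identical(st$layers$a$origin, st$layers$b$origin)
  expect_identical(dim(st$layers$a$values), dim(st$layers$b$values))
  # where grids coincide the cropped layer reproduces the source cells
  got <- st$layers$a
  idx <- rspfrisk:::cell_index(a, cell_centers(got)[, "x"],
                               cell_centers(got)[, "y"])
  expect_equal(as.vector(t(got$values)),
               a$values[idx])
  expect_error(crop_align(list(a = a, b = b), c(-500, -400, -500, -400)),
               "overlap|degenerate")
})

test_that("extract_values matches index arithmetic and flags outsiders", {
  st <- toy_stack(nr = 8, nc = 8, cell = 25, seed = 3)
  const <- grid_raster(matrix(7.5, 8, 8), 25, c(0, 200))
  stc <- raster_stack(list(c = const))
  p <- point_set(12.5, 187.5, 1)           # centre of cell [1,1]
  expect_equal(extract_values(stc, p)$c, 7.5)
  # shared corner of 4 cells resolves by the half-open convention
  pc <- point_set(100, 100, 1)             # corner -> row 5, col 5
  expect_equal(extract_values(stc, pc)$c, 7.5)
  got <- suppressMessages(extract_values(st, point_set(100, 100, 1)))
  expect_equal(got$a, st$layers$a$values[5, 5])
  # random points vs manual row/col arithmetic
  set.seed(11)
  px <- stats::runif(100, 0, 200); py <- stats::runif(100, 0, 200)
  pts <- point_set(px, py, rep(0, 100))
  got <- extract_values(st, pts)
  rows <- floor((200 - py) / 25) + 1; cols <- floor(px / 25) + 1
  expect_equal(got$a, st$layers$a$values[cbind(rows, cols)])
  # outside points dropped with a message
  expect_message(out <- extract_values(st, point_set(-5, 100, 1)), "outside")
  expect_equal(nrow(out), 0)
})

test_that("extracting at every cell centre reproduces the raster", {
  r <- toy_raster(nr = 7, nc = 4, cell = 40, origin = c(0, 280), seed = 12)
  st <- raster_stack(list(v = r))
  cc <- cell_centers(r)
  pts <- point_set(cc[, "x"], cc[, "y"], rep(1, nrow(cc)))
  got <- extract_values(st, pts)
  expect_equal(matrix(got$v, nrow(r$values), byrow = TRUE), r$values)
})
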