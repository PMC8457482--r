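# Synthetic landscapes with a known true selection function. Continuous
# covariates are moving-average-smoothed Gaussian white noise (smoothing
# range in cells controls the autocorrelation length); the categorical
# cover layer comes from thresholding an independent latent field at
# quantile breaks, which keeps classes spatially coherent.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic landscape
#'
#' @param n_rows,n_cols grid dimensions in cells (>= 8).
#' @param cell_size metres per cell.
#' @param covariates data.frame with columns \code{name}, \code{range}
#'   (smoothing range in cells), \code{mean}, \code{sd} — one row per
#'   continuous covariate.
#' @param n_cover_classes number of land-cover classes (>= 2; default 8,
#'   mirroring a reclassified forest/urban/shrubland/... scheme).
#' @param cover_range smoothing range of the latent cover field, in cells.
#' @param seed base RNG seed for the landscape.
#' @return a \code{landscape_spec} list.
#' @export
landscape_spec <- function(n_rows = 64, n_cols = 64, cell_size = 50,
                           covariates = default_covariates(),
                           n_cover_classes = 8, cover_range = 5, seed = 1) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8 cells")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_cover_classes < 2) stop("need at least 2 cover classes")
  need <- c("name", "range", "mean", "sd")
  if (!all(need %in% names(covariates)))
    stop("covariates needs columns: ", paste(need, collapse = ", "))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, covariates = covariates,
                 n_cover_classes = as.integer(n_cover_classes),
                 cover_range = cover_range, seed = seed),
            class = "landscape_spec")
}

#' @rdname landscape_spec
#' @export
default_covariates <- function() {
  data.frame(
    name  = c("elevation", "pop_density", "dist_urban", "road_density"),
    range = c(8, 4, 6, 3),
    mean  = c(400, 1.5, 8000, 1),
    sd    = c(150, 1.0, 4000, 0.6)
  )
}

#' Simulate one spatially autocorrelated covariate field
#'
#' Gaussian white noise smoothed with a square moving-average kernel of the
#' covariate's registered range (range 1 = no smoothing), then rescaled to
#' the registered mean and sd. Identical spec + seed give bit-identical
#' rasters.
#'
#' @param spec a \code{landscape_spec}.
#' @param name a covariate name registered in \code{spec$covariates}.
#' @param seed RNG seed (defaults to a stream derived from the spec seed).
#' @return a continuous \code{grid_raster}.
#' @export
simulate_covariate_field <- function(spec, name, seed = NULL) {
  row <- match(name, spec$covariates$name)
  if (is.na(row)) stop("unknown covariate name: ", name)
  if (is.null(seed)) seed <- spec$seed + row
  def <- spec$covariates[row, ]
  f <- smooth_field(spec$n_rows, spec$n_cols, def$range, seed)
  v <- def$mean + def$sd * f
  grid_raster(v, spec$cell_size, c(0, spec$n_rows * spec$cell_size),
              kind = "continuous")
}

# standardized smoothed white-noise field (mean ~0, sd ~1)
smooth_field <- function(nr, nc, range, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  r <- max(1L, as.integer(round(range)))
  if (r > 1L) {
    half <- r %/% 2L
    z <- box_blur(z, half)
  }
  (z - mean(z)) / stats::sd(z)
}

# moving-average over a (2*half+1)^2 window with edge truncation
box_blur <- function(m, half) {
  if (half < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  csum <- function(x, h) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    hi <- pmin(seq_len(n) + h, n)
    lo <- pmax(seq_len(n) - h, 1L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2, csum, h = half)
  t(apply(m, 1, csum, h = half))
}

#' Categorical cover from a latent field
#'
#' Thresholds a latent continuous raster at strictly increasing breaks,
#' assigning codes 1..(length(breaks)+1). With breaks at the latent field's
#' octiles this yields an eight-class cover layer with roughly equal class
#' shares.
#'
#' @param latent a continuous \code{grid_raster}.
#' @param class_breaks strictly increasing numeric thresholds on the latent
#'   scale.
#' @return a categorical \code{grid_raster}.
#' @export
simulate_cover <- function(latent, class_breaks) {
  stopifnot(is_grid_raster(latent))
  if (length(class_breaks) && any(diff(class_breaks) <= 0))
    stop("class_breaks must be strictly increasing")
  v <- latent$values
  if (length(unique(v[!is.na(v)])) == 1L)
    warning("latent field is constant; all cells fall in a single class")
  codes <- matrix(findInterval(v, class_breaks) + 1L, nrow(v), ncol(v))
  codes[is.na(v)] <- NA_real_
  grid_raster(codes, latent$cell_size, latent$origin, kind = "categorical")
}

#' True selection model
#'
#' Coefficients of the data-generating logistic selection function:
#' an intercept, one slope per continuous covariate, and one coefficient
#' per non-reference cover class (class 1 is the reference).
#'
#' @param beta0 intercept.
#' @param betas named numeric vector; continuous covariate names, plus
#'   optionally \code{cover_<k>} entries for cover classes 2..K.
#' @return a \code{true_model} object.
#' @export
true_model <- function(beta0, betas) {
  if (!all(is.finite(c(beta0, betas)))) stop("coefficients must be finite")
  if (is.null(names(betas)) && length(betas))
    stop("betas must be named")
  structure(list(beta0 = beta0, betas = betas), class = "true_model")
}

#' Assemble a simulated study region
#'
#' Builds the covariate stack (continuous fields plus a \code{cover}
#' layer if the truth references cover classes), a full region mask and a
#' contiguous focal submask.
#'
#' @param spec a \code{landscape_spec}.
#' @param truth a \code{true_model}.
#' @param focal_fraction fraction of region cells in the focal submask.
#' @return a \code{simulated_study} list with elements \code{stack},
#'   \code{truth}, \code{region_mask}, \code{focal_mask}, \code{spec}.
#' @export
simulate_landscape <- function(spec, truth, focal_fraction = 0.25) {
  layers <- list()
  for (nm in spec$covariates$name)
    layers[[nm]] <- simulate_covariate_field(spec, nm)
  wants_cover <- any(grepl("^cover_", names(truth$betas)))
  if (wants_cover || spec$n_cover_classes >= 2) {
    latent <- grid_raster(
      smooth_field(spec$n_rows, spec$n_cols, spec$cover_range,
                   spec$seed + nrow(spec$covariates) + 1L),
      spec$cell_size, c(0, spec$n_rows * spec$cell_size))
    breaks <- stats::quantile(latent$values,
                              probs = seq_len(spec$n_cover_classes - 1L) /
                                spec$n_cover_classes)
    layers$cover <- simulate_cover(latent, unname(breaks))
  }
  stack <- raster_stack(layers)
  region <- grid_raster(matrix(1, spec$n_rows, spec$n_cols), spec$cell_size,
                        c(0, spec$n_rows * spec$cell_size))
  focal <- make_focal_mask(region, focal_fraction)
  structure(list(stack = stack, truth = truth, region_mask = region,
                 focal_mask = focal, spec = spec),
            class = "simulated_study")
}

# true selection probability w(x) for every cell, as a matrix
true_w_matrix <- function(study) {
  truth <- study$truth
  stack <- study$stack
  eta <- matrix(truth$beta0, study$spec$n_rows, study$spec$n_cols)
  for (nm in names(truth$betas)) {
    if (grepl("^cover_", nm)) {
      k <- as.numeric(sub("^cover_", "", nm))
      eta <- eta + truth$betas[[nm]] * (stack$layers$cover$values == k)
    } else {
      if (is.null(stack$layers[[nm]])) stop("truth references unknown layer: ", nm)
      eta <- eta + truth$betas[[nm]] * stack$layers[[nm]]$values
    }
  }
  stats::plogis(eta)
}

#' Draw conflict (used) points from the true selection function
#'
#' Rejection sampler: propose a uniform cell inside the region mask and a
#' uniform position within it, accept with probability w(x) — so w acts as
#' an absolute probability, not a relative weight. Returns exactly
#' \code{n_used} labelled points with covariates extracted from the stack.
#'
#' @param study a \code{simulated_study}.
#' @param n_used number of used points to return.
#' @param seed RNG seed.
#' @return a \code{point_set} (label 1) with attributes \code{acceptance_rate}
#'   and \code{mean_w} (the spatial mean of w over the mask).
#' @export
simulate_conflicts <- function(study, n_used, seed = 1) {
  if (n_used <= 0) stop("n_used must be positive")
  w <- true_w_matrix(study)
  mask <- study$region_mask$values != 0 & !is.na(study$region_mask$values)
  if (!any(mask)) stop("region mask is empty")
  if (max(w[mask]) <= 0) stop("w(x) is zero everywhere on the mask")
  cells <- which(mask)                      # column-major linear indices
  nr <- study$spec$n_rows
  s <- study$spec$cell_size
  y0 <- study$region_mask$origin[2]
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    proposed <- 0; accepted <- 0
    while (length(xs) < n_used) {
      m <- max(2L * (n_used - length(xs)), 1000L)
      cell <- sample(cells, m, replace = TRUE)
      proposed <- proposed + m
      acc <- stats::runif(m) < w[cell]
      accepted <- accepted + sum(acc)
      cell <- cell[acc]
      row <- (cell - 1L) %% nr + 1L
      col <- (cell - 1L) %/% nr + 1L
      xs <- c(xs, (col - 1L + stats::runif(length(cell))) * s)
      ys <- c(ys, y0 - (row - 1L + stats::runif(length(cell))) * s)
    }
    pts <- point_set(xs[seq_len(n_used)], ys[seq_len(n_used)],
                     rep(1L, n_used))
    pts <- extract_values(study$stack, pts)
    attr(pts, "acceptance_rate") <- accepted / proposed
    attr(pts, "n_proposed") <- proposed
    attr(pts, "mean_w") <- mean(w[mask])
    pts
  })
}

#' Contiguous focal submask
#'
#' Grows a square-ish block from one corner of the region until it holds
#' approximately \code{fraction} of the region's cells — a stand-in for a
#' focal subregion used in spatial hold-out validation.
#'
#' @param region_mask boolean \code{grid_raster}.
#' @param fraction target fraction of region cells, in (0, 1].
#' @return a boolean \code{grid_raster} (subset of the region mask).
#' @export
make_focal_mask <- function(region_mask, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  mask <- region_mask$values != 0 & !is.na(region_mask$values)
  n_target <- fraction * sum(mask)
  d <- dim(mask)
  # expand a block from the lower-left corner, one row/col at a time,
  # keeping the block roughly square in region-cell count
  best <- matrix(FALSE, d[1], d[2])
  nr <- 1L; nc <- 1L
  repeat {
    blk <- matrix(FALSE, d[1], d[2])
    blk[(d[1] - nr + 1L):d[1], 1:nc] <- TRUE
    blk <- blk & mask
    best <- blk
    if (sum(blk) >= n_target || (nr == d[1] && nc == d[2])) break
    if ((nr < d[1]) && (nr <= nc || nc == d[2])) nr <- nr + 1L else nc <- nc + 1L
  }
  grid_raster(best + 0, region_mask$cell_size, region_mask$origin)
}

#' Simulate a use-availability design directly
#'
#' Covariate-table-level counterpart of the landscape sampler, for studies
#' of the estimator itself: a large pool of locations with independent
#' standard-normal covariates stands in for the landscape; used points are
#' accepted from the pool with probability w(x; beta), and the availability
#' sample is drawn uniformly from the pool with replacement at
#' \code{ratio} available points per used point.
#'
#' @param n_used number of used points.
#' @param ratio available points per used point (default 5).
#' @param beta0 true intercept.
#' @param betas named vector of true slopes; names become covariate
#'   columns.
#' @param n_noise extra pure-noise covariates appended with true slope 0
#'   (named \code{noise1}, \code{noise2}, ...).
#' @param pool_size number of distinct landscape locations in the pool
#'   (default 4096, the size of a 64 x 64 grid).
#' @param seed RNG seed.
#' @return an \code{rspf_data} with attribute \code{truth} (the full
#'   coefficient vector including zero slopes).
#' @export
simulate_ua_design <- function(n_used, ratio = 5, beta0 = -2,
                               betas = c(x1 = 1, x2 = -1, x3 = 1),
                               n_noise = 0, pool_size = 4096, seed = 1) {
  nm <- c(names(betas), if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  b <- c(betas, rep(0, n_noise))
  with_seed(seed, {
    # one shared pool: used and available points are locations of the same
    # finite landscape, exactly as when both strata are extracted from one
    # raster stack
    pool <- matrix(stats::rnorm(pool_size * length(nm)), ncol = length(nm))
    w <- stats::plogis(beta0 + drop(pool %*% b))
    rows <- integer(0)
    while (length(rows) < n_used) {
      prop <- sample.int(pool_size, pool_size, replace = TRUE)
      rows <- c(rows, prop[stats::runif(pool_size) < w[prop]])
    }
    xu <- pool[rows[seq_len(n_used)], , drop = FALSE]
    xa <- pool[sample.int(pool_size, ratio * n_used, replace = TRUE), ,
               drop = FALSE]
    x <- rbind(xu, xa)
    colnames(x) <- nm
    out <- structure(
      list(x = x, y = c(rep(1L, n_used), rep(0L, nrow(xa))),
           terms = nm, continuous = nm, categorical = NULL,
           reference_class = NULL,
           term_columns = as.list(stats::setNames(seq_along(nm), nm))),
      class = "rspf_data")
    attr(out, "truth") <- c("(Intercept)" = beta0,
                            stats::setNames(b, nm))
    out
  })
}
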