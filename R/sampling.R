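# Conflict-point preparation: mask filtering (drop obviously erroneous
# locations), randomized spatial thinning at a minimum pairwise distance,
# and buffer-excluded background ("non-conflict") point generation.

#' Keep only points inside a boolean mask
#'
#' @param points a \code{point_set}.
#' @param mask a boolean \code{grid_raster} (nonzero = inside).
#' @return the points whose containing cell is inside the mask; the number
#'   excluded is reported via \code{message} and the \code{n_excluded}
#'   attribute.
#' @export
filter_by_mask <- function(points, mask) {
  stopifnot(is_grid_raster(mask))
  idx <- cell_index(mask, points$x, points$y)
  ok <- in_grid(mask, idx)
  lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * nrow(mask$values)
  inside <- ok
  inside[ok] <- !is.na(mask$values[lin]) & mask$values[lin] != 0
  out <- points[inside, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_set", "data.frame")
  n_exc <- sum(!inside)
  if (n_exc) message(n_exc, " point(s) outside the mask were excluded")
  if (!nrow(out)) warning("no points remain after mask filtering")
  attr(out, "n_excluded") <- n_exc
  out
}

#' Randomized spatial thinning
#'
#' Enforces a minimum pairwise distance by repeatedly deleting one point,
#' chosen uniformly at random among those with the greatest number of
#' neighbours closer than \code{min_distance}, until no close pairs remain.
#' The procedure is repeated \code{n_repetitions} times and the run
#' retaining the most points wins (ties go to the earliest run), which makes
#' the randomized greedy scheme a near-optimal approximation to the maximum
#' independent set of the proximity graph.
#'
#' @param points a \code{point_set}.
#' @param min_distance minimum allowed pairwise distance, metres.
#' @param n_repetitions independent randomized runs (default 100).
#' @param seed RNG seed.
#' @return a \code{thinning_result} list: \code{retained}, \code{removed}
#'   (both \code{point_set}s), \code{min_distance}, \code{n_repetitions},
#'   \code{seed}.
#' @export
spatial_thin <- function(points, min_distance, n_repetitions = 100, seed = 1) {
  if (min_distance <= 0) stop("min_distance must be positive")
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  n <- nrow(points)
  keep_best <- seq_len(n)
  if (n > 1) {
    dm <- as.matrix(stats::dist(cbind(points$x, points$y))) < min_distance
    diag(dm) <- FALSE
    keep_best <- with_seed(seed, {
      best <- integer(0)
      for (rep in seq_len(n_repetitions)) {
        alive <- rep(TRUE, n)
        deg <- rowSums(dm)
        while (any(deg[alive] > 0)) {
          worst <- which(alive & deg == max(deg[alive]))
          drop <- if (length(worst) == 1L) worst else
            worst[sample.int(length(worst), 1L)]
          alive[drop] <- FALSE
          nb <- which(dm[drop, ] & alive)
          deg[nb] <- deg[nb] - 1L
          deg[drop] <- 0L
        }
        if (sum(alive) > length(best)) best <- which(alive)
      }
      best
    })
  }
  retained <- points[keep_best, , drop = FALSE]
  removed <- points[setdiff(seq_len(n), keep_best), , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  class(retained) <- class(removed) <- c("point_set", "data.frame")
  structure(list(retained = retained, removed = removed,
                 min_distance = min_distance,
                 n_repetitions = n_repetitions, seed = seed),
            class = "thinning_result")
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("<thinning_result> %d retained / %d input at >= %g m (%d runs)\n",
              nrow(x$retained), nrow(x$retained) + nrow(x$removed),
              x$min_distance, x$n_repetitions))
  invisible(x)
}

#' Background ("non-conflict") point generation
#'
#' Draws \code{ratio * n_used} points uniformly over the region mask minus
#' the union of circular buffers around the used points. Buffers are exact
#' Euclidean discs evaluated per candidate point, so the exclusion is not
#' subject to raster resolution artifacts. Sampling is by rejection with a
#' hard proposal cap.
#'
#' @param region_mask boolean \code{grid_raster} of the study region.
#' @param used a \code{point_set} of used (conflict) points.
#' @param buffer_radius exclusion radius around each used point, metres
#'   (default 5000).
#' @param ratio background points per used point (default 5).
#' @param seed RNG seed.
#' @param max_proposals rejection-sampling cap (default 1e6).
#' @return a \code{point_set} with label 0.
#' @export
generate_background <- function(region_mask, used, buffer_radius = 5000,
                                ratio = 5, seed = 1, max_proposals = 1e6) {
  if (buffer_radius < 0) stop("buffer_radius must be >= 0")
  if (ratio < 1) stop("ratio must be >= 1")
  mask <- region_mask$values != 0 & !is.na(region_mask$values)
  if (!any(mask)) stop("region mask is empty")
  n_target <- as.integer(round(ratio * nrow(used)))
  cells <- which(mask)
  nr <- nrow(region_mask$values)
  s <- region_mask$cell_size
  x0 <- region_mask$origin[1]; y0 <- region_mask$origin[2]

  # cheap upfront degeneracy check on cell centres
  cc_col <- (cells - 1L) %/% nr + 1L
  cc_row <- (cells - 1L) %% nr + 1L
  ccx <- x0 + (cc_col - 0.5) * s
  ccy <- y0 - (cc_row - 0.5) * s
  covered <- covered_by_buffer(ccx, ccy, used, buffer_radius)
  frac_covered <- mean(covered)
  if (all(covered))
    stop(sprintf(
      "eligible area is empty: buffers cover %.1f%% of the region mask",
      100 * frac_covered))

  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    proposed <- 0
    while (length(xs) < n_target) {
      if (proposed >= max_proposals)
        stop(sprintf(
          "proposal cap reached (%g); buffers cover %.1f%% of the region mask",
          max_proposals, 100 * frac_covered))
      m <- min(max(2L * (n_target - length(xs)), 1000L),
               max_proposals - proposed)
      proposed <- proposed + m
      cell <- sample(cells, m, replace = TRUE)
      col <- (cell - 1L) %/% nr + 1L
      row <- (cell - 1L) %% nr + 1L
      px <- x0 + (col - 1L + stats::runif(m)) * s
      py <- y0 - (row - 1L + stats::runif(m)) * s
      ok <- !covered_by_buffer(px, py, used, buffer_radius)
      xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
    }
    point_set(xs[seq_len(n_target)], ys[seq_len(n_target)],
              rep(0L, n_target))
  })
}

# TRUE for candidates within `radius` of any used point
covered_by_buffer <- function(px, py, used, radius) {
  if (!nrow(used) || radius <= 0) return(rep(FALSE, length(px)))
  out <- rep(FALSE, length(px))
  r2 <- radius^2
  for (i in seq_len(nrow(used))) {
    todo <- which(!out)
    if (!length(todo)) break
    dx <- px[todo] - used$x[i]
    dy <- py[todo] - used$y[i]
    out[todo] <- dx * dx + dy * dy < r2
  }
  out
}
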