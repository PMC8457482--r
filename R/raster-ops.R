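#' Euclidean distance to the nearest feature cell
#'
#' Computes, for every cell, the straight-line distance in metres from its
#' centre to the centre of the nearest feature (TRUE) cell. Feature cells
#' get distance 0. Exact (not chamfer) distances via the two-pass
#' lower-envelope squared-distance transform applied along columns then rows.
#'
#' @param feature a boolean \code{grid_raster} (values 0/1, NA treated as 0).
#' @return a continuous \code{grid_raster} of distances in metres.
#' @export
distance_to_feature <- function(feature) {
  stopifnot(is_grid_raster(feature))
  f <- feature$values
  f[is.na(f)] <- 0
  if (!any(f != 0)) stop("no feature cells: distance is undefined")
  nr <- nrow(f); nc <- ncol(f)
  INF <- .Machine$double.xmax / 4

  # pass 1: per column, squared row-distance to nearest feature in column
  g <- matrix(INF, nr, nc)
  g[f != 0] <- 0
  for (j in seq_len(nc)) {
    col <- g[, j]
    if (all(col == INF)) next
    for (i in seq_len(nr)[-1]) col[i] <- min(col[i], col[i - 1] + 1)
    for (i in rev(seq_len(nr)[-nr])) col[i] <- min(col[i], col[i + 1] + 1)
    g[, j] <- col^2
  }

  # pass 2: per row, lower envelope of parabolas j -> g[i,k] + (j-k)^2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    out[i, ] <- dt1d(g[i, ])
  }
  grid_raster(sqrt(out) * feature$cell_size, feature$cell_size,
              feature$origin, kind = "continuous")
}

# 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope)
dt1d <- function(fvals) {
  n <- length(fvals)
  INF <- .Machine$double.xmax / 4
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -INF; z[2] <- INF
  for (q in seq_len(n)[-1]) {
    if (fvals[q] >= INF) next
    repeat {
      p <- v[k]
      if (fvals[p] >= INF) { s <- -INF } else {
        s <- ((fvals[q] + q^2) - (fvals[p] + p^2)) / (2 * q - 2 * p)
      }
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- INF
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- (q - p)^2 + fvals[p]
  }
  out
}

#' Reclassify a categorical raster
#'
#' Cell-wise relabelling through an explicit code map; NA (nodata) cells are
#' preserved. Every code present in the raster must be covered by the map.
#'
#' @param raster a categorical \code{grid_raster}.
#' @param mapping named numeric vector: names are input codes, values output
#'   codes (e.g. \code{c(`11` = 1, `12` = 1, `21` = 2)}).
#' @param category_labels optional labels for the output codes.
#' @return a categorical \code{grid_raster}.
#' @export
reclassify <- function(raster, mapping, category_labels = NULL) {
  stopifnot(is_grid_raster(raster))
  if (raster$kind != "categorical") stop("reclassify() needs a categorical raster")
  v <- raster$values
  present <- sort(unique(v[!is.na(v)]))
  missing <- setdiff(as.character(present), names(mapping))
  if (length(missing))
    stop("mapping does not cover observed code(s): ", paste(missing, collapse = ", "))
  out <- v
  keep <- !is.na(v)
  out[keep] <- unname(mapping[as.character(v[keep])])
  grid_raster(out, raster$cell_size, raster$origin, kind = "categorical",
              category_labels = category_labels)
}

#' Natural-log transform of a raster
#'
#' Cell-wise \code{log(value + offset)}; used for right-skewed layers such
#' as population density and distance-to-forest, whose supports include 0
#' (hence the default +1 offset). NA cells are preserved.
#'
#' @param raster a continuous \code{grid_raster}.
#' @param offset added before taking logs; default 1.
#' @return a continuous \code{grid_raster}.
#' @export
log_transform <- function(raster, offset = 1) {
  stopifnot(is_grid_raster(raster))
  v <- raster$values
  if (any(v + offset <= 0, na.rm = TRUE))
    stop("log_transform: value + offset must be positive at every cell")
  grid_raster(log(v + offset), raster$cell_size, raster$origin,
              kind = "continuous")
}

# target grid descriptor: list(n_rows, n_cols, cell_size, origin)
target_grid <- function(n_rows, n_cols, cell_size, origin) {
  list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
       cell_size = as.numeric(cell_size), origin = as.numeric(origin))
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target cell takes the value of the source cell whose centre is
#' nearest to the target cell centre; categorical codes are therefore never
#' interpolated. Target centres falling outside the source extent become NA.
#'
#' @param raster source \code{grid_raster}.
#' @param grid target grid: a list with \code{n_rows}, \code{n_cols},
#'   \code{cell_size}, \code{origin}, or another \code{grid_raster} to copy
#'   the grid from.
#' @return a \code{grid_raster} on the target grid.
#' @export
resample_nearest <- function(raster, grid) {
  stopifnot(is_grid_raster(raster))
  if (is_grid_raster(grid)) {
    d <- dim(grid$values)
    grid <- target_grid(d[1], d[2], grid$cell_size, grid$origin)
  }
  s <- raster$cell_size
  d <- dim(raster$values)
  tx <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ty <- grid$origin[2] - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  # nearest source centre = round to nearest centre index, then clamp only
  # within half a cell (beyond that the target centre is outside the source)
  jx <- round((tx - raster$origin[1]) / s + 0.5)
  iy <- round((raster$origin[2] - ty) / s + 0.5)
  ok_x <- tx >= raster$origin[1] & tx < raster$origin[1] + d[2] * s
  ok_y <- ty <= raster$origin[2] & ty > raster$origin[2] - d[1] * s
  if (!any(ok_x) || !any(ok_y)) stop("target grid does not overlap the source")
  jx <- pmin(pmax(jx, 1L), d[2])
  iy <- pmin(pmax(iy, 1L), d[1])
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[ok_y, ok_x] <- raster$values[iy[ok_y], jx[ok_x], drop = FALSE]
  grid_raster(out, grid$cell_size, grid$origin, kind = raster$kind,
              category_labels = raster$category_labels)
}

#' Crop and align a set of layers to one extent
#'
#' Snaps the requested extent to the first layer's grid, resamples every
#' layer (nearest neighbour) onto that common grid and returns a
#' \code{raster_stack} whose layers share origin and shape exactly.
#'
#' @param layers named list of \code{grid_raster}s (grids may differ).
#' @param extent numeric \code{(xmin, xmax, ymin, ymax)}.
#' @param cell_size target resolution; defaults to the first layer's.
#' @return a \code{raster_stack}.
#' @export
crop_align <- function(layers, extent, cell_size = NULL) {
  if (is_grid_raster(layers)) layers <- list(layer = layers)
  if (inherits(layers, "raster_stack")) layers <- layers$layers
  if (is.null(cell_size)) cell_size <- layers[[1]]$cell_size
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]
  if (xmax <= xmin || ymax <= ymin) stop("degenerate extent")
  nc <- max(1L, as.integer(ceiling((xmax - xmin) / cell_size - 1e-9)))
  nr <- max(1L, as.integer(ceiling((ymax - ymin) / cell_size - 1e-9)))
  tg <- target_grid(nr, nc, cell_size, c(xmin, ymax))
  for (nm in names(layers)) {
    ext <- raster_extent(layers[[nm]])
    if (ext["xmin"] >= xmax || ext["xmax"] <= xmin ||
        ext["ymin"] >= ymax || ext["ymax"] <= ymin)
      stop("layer does not overlap the extent: ", nm)
  }
  raster_stack(lapply(layers, resample_nearest, grid = tg))
}

#' Extract covariate values at point locations
#'
#' Fills each point's attribute columns with the value of its containing
#' cell in every stack layer. Points outside the stack extent, or sitting on
#' a nodata cell of any layer, are dropped with a message reporting the
#' count.
#'
#' @param stack a \code{raster_stack}.
#' @param points a \code{point_set}.
#' @param drop_incomplete drop points with any NA extraction (default TRUE).
#' @return the \code{point_set} with one column per layer appended.
#' @export
extract_values <- function(stack, points, drop_incomplete = TRUE) {
  stopifnot(inherits(stack, "raster_stack"))
  ref <- stack$layers[[1]]
  idx <- cell_index(ref, points$x, points$y)
  inside <- in_grid(ref, idx)
  if (any(!inside))
    message(sum(!inside), " point(s) outside the stack extent were dropped")
  vals <- matrix(NA_real_, nrow(points), length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  lin <- idx[inside, 1] + (idx[inside, 2] - 1L) * nrow(ref$values)
  for (nm in names(stack$layers))
    vals[inside, nm] <- stack$layers[[nm]]$values[lin]
  out <- cbind(points[, c("id", "x", "y", "label")], as.data.frame(vals))
  keep <- inside
  if (drop_incomplete) {
    complete <- !apply(is.na(vals), 1, any)
    n_nodata <- sum(inside & !complete)
    if (n_nodata) message(n_nodata, " point(s) on nodata cells were dropped")
    keep <- inside & complete
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_set", "data.frame")
  out
}
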