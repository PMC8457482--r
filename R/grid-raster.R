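#' Planar grid raster
#'
#' A minimal single-band raster on a planar coordinate system in metres.
#' Values are stored as a numeric matrix whose first row is the top
#' (northernmost) row of the grid; \code{origin} is the x/y coordinate of the
#' grid's upper-left corner. Cell membership is half-open: a point with
#' x in \code{[x0 + (j-1)*s, x0 + j*s)} falls in column \code{j}, and a point
#' with y in \code{(y0 - i*s, y0 - (i-1)*s]} falls in row \code{i}, so points
#' on shared cell edges resolve deterministically.
#'
#' @param values numeric matrix of cell values (row 1 = top of the grid).
#' @param cell_size cell edge length in metres (single positive number).
#' @param origin length-2 numeric, x/y of the upper-left corner.
#' @param kind \code{"continuous"} or \code{"categorical"}.
#' @param category_labels optional named character vector mapping category
#'   codes (as names) to labels, for categorical rasters.
#'
#' @return an object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, cell_size, origin = c(0, 0),
                        kind = c("continuous", "categorical"),
                        category_labels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite coordinates")
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical raster values must be integer codes")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), kind = kind,
         category_labels = category_labels),
    class = "grid_raster"
  )
}

is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d cells @ %g m, origin (%g, %g), %s\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2], x$kind))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    if (x$kind == "categorical")
      cat("  codes:", paste(sort(unique(v)), collapse = ", "), "\n")
    else
      cat(sprintf("  range: [%g, %g], NA cells: %d\n", min(v), max(v),
                  sum(is.na(x$values))))
  } else cat("  all cells NA\n")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Bounding extent of a raster
#'
#' @param r a \code{grid_raster}.
#' @return named numeric vector \code{(xmin, xmax, ymin, ymax)}.
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$origin[1], xmax = r$origin[1] + d[2] * r$cell_size,
    ymin = r$origin[2] - d[1] * r$cell_size, ymax = r$origin[2])
}

#' Cell-centre coordinates
#'
#' @param r a \code{grid_raster}.
#' @return a two-column matrix (x, y) of every cell centre in row-major
#'   order (row 1 left to right, then row 2, ...).
#' @export
cell_centers <- function(r) {
  d <- dim(r$values)
  s <- r$cell_size
  xs <- r$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- r$origin[2] - (seq_len(d[1]) - 0.5) * s
  cbind(x = rep(xs, times = d[1]), y = rep(ys, each = d[2]))
}

# row/col indices (possibly outside the grid) for point coordinates;
# both axes use the half-open convention documented in grid_raster()
cell_index <- function(r, x, y) {
  s <- r$cell_size
  col <- floor((x - r$origin[1]) / s) + 1L
  row <- floor((r$origin[2] - y) / s) + 1L
  cbind(row = as.integer(row), col = as.integer(col))
}

in_grid <- function(r, idx) {
  d <- dim(r$values)
  idx[, 1] >= 1L & idx[, 1] <= d[1] & idx[, 2] >= 1L & idx[, 2] <= d[2]
}

#' Raster stack: named layers on one shared grid
#'
#' @param layers named list of \code{grid_raster}s sharing cell size, origin
#'   and dimensions exactly.
#' @return an object of class \code{raster_stack}.
#' @export
raster_stack <- function(layers) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a non-empty named list")
  if (!all(vapply(layers, is_grid_raster, logical(1))))
    stop("all layers must be grid_raster objects")
  ref <- layers[[1]]
  same <- vapply(layers, function(l) {
    identical(dim(l$values), dim(ref$values)) &&
      isTRUE(all.equal(l$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(l$origin, ref$origin))
  }, logical(1))
  if (!all(same))
    stop("layers do not share one grid: ", paste(names(layers)[!same], collapse = ", "))
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  d <- dim(ref$values)
  cat(sprintf("<raster_stack> %d layer(s), %d x %d cells @ %g m\n",
              length(x$layers), d[1], d[2], ref$cell_size))
  for (nm in names(x$layers))
    cat(sprintf("  %s (%s)\n", nm, x$layers[[nm]]$kind))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' Point set constructor
#'
#' A labelled point table: used (conflict) points carry label 1, available
#' (background) points label 0. Covariate columns may be appended by
#' \code{\link{extract_values}}.
#'
#' @param x,y point coordinates in metres.
#' @param label integer vector of 0/1 labels.
#' @param id optional identifiers (defaults to sequence).
#' @param ... additional attribute columns (recycled by data.frame rules).
#' @return a \code{data.frame} with class \code{point_set} prepended.
#' @export
point_set <- function(x, y, label, id = seq_along(x), ...) {
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  df <- data.frame(id = id, x = x, y = y, label = as.integer(label), ...)
  class(df) <- c("point_set", "data.frame")
  df
}

covariate_names <- function(points) {
  setdiff(names(points), c("id", "x", "y", "label"))
}
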