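#' Read and write ESRI ASCII grids
#'
#' Plain-text single-band raster interchange. The header records ncols,
#' nrows, the lower-left corner, the cell size and the nodata sentinel;
#' values follow row by row from the top of the grid.
#'
#' @param r a \code{grid_raster}.
#' @param path file path (conventionally \code{.asc}).
#' @param nodata sentinel written for NA cells.
#' @return \code{write_ascii_grid}: the path, invisibly.
#'   \code{read_ascii_grid}: a \code{grid_raster}.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(is_grid_raster(r))
  d <- dim(r$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - d[1] * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  v <- r$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row) paste(format(row, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param kind raster kind to tag on read.
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  grid_raster(m, hdr$cellsize, origin, kind = kind)
}

#' Read and write point tables
#'
#' CSV columns: id, x, y, label, then any covariate columns. GeoJSON export
#' writes a FeatureCollection of Point features with the non-coordinate
#' columns as properties.
#'
#' @param points a \code{point_set}.
#' @param path file path.
#' @return \code{read_points_csv}: a \code{point_set}; writers return the
#'   path invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x", "y", "label")
  if (!all(need %in% names(df)))
    stop("point CSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("point_set", "data.frame")
  df
}

#' @rdname write_points_csv
#' @export
write_points_geojson <- function(points, path) {
  props <- as.data.frame(points)[, setdiff(names(points), c("x", "y")),
                                 drop = FALSE]
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
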