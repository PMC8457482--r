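# Projection of a fitted selection model across a covariate stack into a
# per-cell conflict-probability surface, cropping to a focal region, and
# discretization into ordered risk classes for map export.

#' Project a fitted RSPF across a raster stack
#'
#' Evaluates w(x) cell by cell from the stack's covariate layers. The
#' stack must contain every model term; the categorical cover layer is
#' expanded with the same reference class used in the fit. Cells where any
#' required covariate is nodata become nodata. Rows are processed in
#' blocks so arbitrarily large grids run in bounded memory; the block size
#' never changes the result.
#'
#' @param fit an \code{rspf_fit}.
#' @param stack a \code{raster_stack}.
#' @param block_rows rows per processing block (default 512).
#' @return a continuous \code{grid_raster} of probabilities in (0, 1),
#'   with attribute \code{fit_terms}.
#' @export
project_model <- function(fit, stack, block_rows = 512) {
  stopifnot(inherits(fit, "rspf_fit"), inherits(stack, "raster_stack"))
  terms <- fit$terms
  miss <- setdiff(terms, names(stack$layers))
  if (length(miss)) stop("stack is missing layer(s): ",
                         paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  d <- dim(ref$values)
  slope_names <- names(fit$beta)[-1]
  out <- matrix(NA_real_, d[1], d[2])
  for (start in seq(1L, d[1], by = max(1L, as.integer(block_rows)))) {
    rows <- start:min(start + block_rows - 1L, d[1])
    x <- matrix(NA_real_, length(rows) * d[2], length(slope_names),
                dimnames = list(NULL, slope_names))
    for (nm in terms) {
      vals <- as.vector(stack$layers[[nm]]$values[rows, , drop = FALSE])
      if (stack$layers[[nm]]$kind == "categorical") {
        dcols <- grep(paste0("^", nm, "_"), slope_names, value = TRUE)
        codes <- as.numeric(sub(paste0("^", nm, "_"), "", dcols))
        seen <- unique(vals[!is.na(vals)])
        unseen <- setdiff(seen, c(codes, fit$reference_class))
        if (length(unseen))
          stop("category code(s) absent from the fit: ",
               paste(unseen, collapse = ", "))
        for (i in seq_along(dcols)) {
          col <- as.numeric(vals == codes[i])
          col[is.na(vals)] <- NA_real_
          x[, dcols[i]] <- col
        }
      } else {
        x[, nm] <- vals
      }
    }
    ok <- !apply(is.na(x), 1, any)
    w <- rep(NA_real_, nrow(x))
    if (any(ok)) w[ok] <- eval_w(unname(fit$beta), x[ok, , drop = FALSE])
    out[rows, ] <- matrix(w, length(rows), d[2])
  }
  r <- grid_raster(out, ref$cell_size, ref$origin, kind = "continuous")
  attr(r, "fit_terms") <- terms
  r
}

#' Crop a risk surface to a focal region
#'
#' Values inside the mask are preserved; everything outside becomes nodata.
#'
#' @param risk a \code{grid_raster} of probabilities.
#' @param focal_mask boolean \code{grid_raster} on the same grid.
#' @return a \code{grid_raster}.
#' @export
crop_to_focus <- function(risk, focal_mask) {
  if (!identical(dim(risk$values), dim(focal_mask$values)))
    stop("risk raster and mask are on different grids")
  inside <- focal_mask$values != 0 & !is.na(focal_mask$values)
  if (!any(inside)) stop("focal mask does not overlap the risk raster")
  v <- risk$values
  v[!inside] <- NA_real_
  grid_raster(v, risk$cell_size, risk$origin, kind = "continuous")
}

#' Discretize a risk surface into ordered classes
#'
#' Half-open bins [a, b): a cell equal to a break point goes to the upper
#' class. Classes are coded 1 (lowest risk) to length(breaks) + 1.
#'
#' @param risk a probability \code{grid_raster}.
#' @param breaks strictly increasing break points in (0, 1); may be empty
#'   for a single class.
#' @return a categorical \code{grid_raster}.
#' @export
classify_hotspots <- function(risk, breaks) {
  if (length(breaks)) {
    if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
    if (any(breaks <= 0 | breaks >= 1)) stop("breaks must lie in (0, 1)")
  }
  v <- risk$values
  codes <- matrix(findInterval(v, breaks) + 1L, nrow(v), ncol(v))
  codes[is.na(v)] <- NA_real_
  grid_raster(codes, risk$cell_size, risk$origin, kind = "categorical")
}
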