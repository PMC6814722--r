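#' Define a georeferenced grid
#'
#' A `grid_spec` fixes the geometry shared by all raster layers in an
#' analysis: a square-celled, north-up grid in a projected (metre-unit)
#' coordinate reference system. Row 0 is the northern row and the origin is
#' the grid's north-west corner. Cell `(r, c)` covers the half-open box
#' `[x0 + c*s, x0 + (c+1)*s) x (y0 - (r+1)*s, y0 - r*s]`, which makes
#' point-in-cell assignment unambiguous.
#'
#' @param origin_x X coordinate (m) of the west edge.
#' @param origin_y Y coordinate (m) of the north edge.
#' @param cell_size Cell edge length in metres (cells are square).
#' @param n_rows,n_cols Grid dimensions.
#' @param crs_id Identifier of the projected CRS (an EPSG code).
#'
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(0, 3000, cell_size = 30, n_rows = 100, n_cols = 100)
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs_id = 32722L) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs_id = as.integer(crs_id)),
    class = "grid_spec"
  )
}

#' @export
#' @method print grid_spec
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g), EPSG:%d\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

#' @export
#' @method format grid_spec
format.grid_spec <- function(x, ...) {
  sprintf("%g,%g,%g,%d,%d,%d", x$origin_x, x$origin_y, x$cell_size,
          x$n_rows, x$n_cols, x$crs_id)
}

specs_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' X/Y coordinates of cell centers
#'
#' @param spec A [grid_spec()].
#' @return A list with numeric vectors `x` (length `n_cols`, west to east)
#'   and `y` (length `n_rows`, north to south).
#' @export
cell_centers <- function(spec) {
  list(
    x = spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size,
    y = spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  )
}

## Row/col (1-based) of the cells containing points (x, y); NA outside grid.
## Half-open boxes: west/top edges belong to the cell, east/bottom do not.
cells_of_points <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1L
  dy <- (spec$origin_y - y) / spec$cell_size
  row <- floor(dy) + 1L
  # the north edge (dy == 0) belongs to row 1; interior horizontal edges
  # belong to the cell above (closed top of the half-open box)
  on_edge <- dy == floor(dy) & dy > 0
  row[on_edge] <- row[on_edge] - 1L
  bad <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

raster_semantics <- c("cover_pct", "height_m", "loss_year_code", "hfp",
                      "sci", "fsii", "fhd", "density", "class_label")

default_nodata <- function(semantics) {
  if (semantics %in% c("loss_year_code", "sci", "class_label")) 255 else -9999
}

#' Construct a raster layer
#'
#' The in-memory unit of all map algebra: a numeric matrix tied to a
#' [grid_spec()]. Missing cells are stored as `NA` in `values`; the `nodata`
#' sentinel is only used when writing to or reading from files.
#'
#' @param values Numeric matrix, `n_rows` x `n_cols`, row 1 = northern row.
#' @param spec A [grid_spec()] matching `dim(values)`.
#' @param semantics One of `r paste0('"', raster_semantics, '"', collapse = ", ")`.
#' @param nodata Sentinel written to file for `NA` cells. Defaults to -9999
#'   for continuous layers and 255 for byte-coded ones.
#'
#' @return An object of class `raster_layer`.
#' @examples
#' sp <- grid_spec(0, 90, 30, 3, 3)
#' raster_layer(matrix(0:8, 3, 3, byrow = TRUE), sp, "sci")
#' @export
raster_layer <- function(values, spec, semantics, nodata = NULL) {
  semantics <- match.arg(semantics, raster_semantics)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("`values` must be a ", spec$n_rows, " x ", spec$n_cols,
         " matrix to match `spec`", call. = FALSE)
  if (is.null(nodata)) nodata <- default_nodata(semantics)
  fin <- values[is.finite(values)]
  if (semantics == "cover_pct" && length(fin) && (min(fin) < 0 || max(fin) > 100))
    stop("cover_pct values must lie in [0, 100]", call. = FALSE)
  if (semantics == "loss_year_code" && length(fin) && !all(fin %in% 0:17))
    stop("loss_year_code values must lie in {0..17}", call. = FALSE)
  if (semantics == "height_m" && length(fin) && min(fin) < 0)
    stop("height_m values must be >= 0", call. = FALSE)
  structure(list(spec = spec, values = values, nodata = as.numeric(nodata),
                 semantics = semantics),
            class = "raster_layer")
}

#' @export
#' @method print raster_layer
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  rng <- if (length(v)) sprintf("range [%g, %g]", min(v), max(v)) else "all nodata"
  cat(sprintf("<raster_layer:%s> %d x %d @ %g m, %s, %d nodata cells\n",
              x$semantics, x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              rng, sum(!is.finite(x$values))))
  invisible(x)
}

#' Convert a raster layer to a tibble
#'
#' One row per cell with map coordinates of the cell center, for piping into
#' dplyr/ggplot2.
#'
#' @param x A [raster_layer()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.raster_layer <- function(x, ...) {
  cc <- cell_centers(x$spec)
  nr <- x$spec$n_rows; nc <- x$spec$n_cols
  vals <- as.vector(x$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep(cc$x, each = nr),
    y = rep(cc$y, times = nc),
    value = vals
  )
}

#' Bundle the co-registered input layers
#'
#' Cover, height and loss must share one [grid_spec()]; the human-footprint
#' layer may sit on a coarser grid but must share the CRS.
#'
#' @param cover,height,loss,hfp [raster_layer()] objects with semantics
#'   `cover_pct`, `height_m`, `loss_year_code` and `hfp`.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(cover, height, loss, hfp = NULL) {
  stopifnot(inherits(cover, "raster_layer"), inherits(height, "raster_layer"),
            inherits(loss, "raster_layer"))
  if (!specs_identical(cover$spec, height$spec) ||
      !specs_identical(cover$spec, loss$spec))
    stop("cover, height and loss layers must share an identical grid_spec",
         call. = FALSE)
  if (!is.null(hfp) && hfp$spec$crs_id != cover$spec$crs_id)
    stop("hfp layer must share the stack's CRS", call. = FALSE)
  structure(list(cover = cover, height = height, loss = loss, hfp = hfp),
            class = "layer_stack")
}

#' @export
#' @method print layer_stack
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d x %d @ %g m%s\n",
              x$cover$spec$n_rows, x$cover$spec$n_cols,
              x$cover$spec$cell_size,
              if (is.null(x$hfp)) ", no hfp" else
                sprintf(", hfp @ %g m", x$hfp$spec$cell_size)))
  invisible(x)
}

#' Resample a raster to a new grid by nearest neighbour
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's center. Used to overlay the coarse (~1 km) human-footprint surface
#' on the 30 m condition grid. `NA` propagates; target cells whose centers
#' fall outside the source extent are `NA`.
#'
#' @param layer A [raster_layer()].
#' @param target A [grid_spec()] in the same CRS.
#' @return A [raster_layer()] on `target`.
#' @export
resample_nearest <- function(layer, target) {
  if (layer$spec$crs_id != target$crs_id)
    stop("resample_nearest: CRS mismatch between layer and target",
         call. = FALSE)
  if (specs_identical(layer$spec, target))
    return(raster_layer(layer$values, target, layer$semantics, layer$nodata))
  cc <- cell_centers(target)
  xs <- rep(cc$x, each = target$n_rows)
  ys <- rep(cc$y, times = target$n_cols)
  idx <- cells_of_points(layer$spec, xs, ys)
  out <- rep(NA_real_, target$n_rows * target$n_cols)
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  raster_layer(matrix(out, target$n_rows, target$n_cols),
               target, layer$semantics, layer$nodata)
}

#' Resample a continuous raster by bilinear interpolation
#'
#' Each target cell center is interpolated from the four surrounding source
#' cell centers, the alignment used to put foliage-height-diversity grids
#' onto the condition grid. Any target cell whose four-neighbour support
#' touches an `NA` source cell, or falls outside the source center lattice,
#' becomes `NA`. Output never overshoots the source range.
#'
#' @inheritParams resample_nearest
#' @return A [raster_layer()] on `target`.
#' @export
resample_bilinear <- function(layer, target) {
  if (layer$spec$crs_id != target$crs_id)
    stop("resample_bilinear: CRS mismatch between layer and target",
         call. = FALSE)
  src <- layer$spec
  cc <- cell_centers(target)
  xs <- rep(cc$x, each = target$n_rows)
  ys <- rep(cc$y, times = target$n_cols)
  # fractional position on the source cell-center lattice (0-based)
  fx <- (xs - src$origin_x) / src$cell_size - 0.5
  fy <- (src$origin_y - ys) / src$cell_size - 0.5
  c0 <- floor(fx); r0 <- floor(fy)
  wx <- fx - c0; wy <- fy - r0
  ok <- c0 >= 0 & c0 + 1 <= src$n_cols - 1 & r0 >= 0 & r0 + 1 <= src$n_rows - 1
  out <- rep(NA_real_, length(xs))
  if (any(ok)) {
    r0k <- r0[ok] + 1L; c0k <- c0[ok] + 1L
    v00 <- layer$values[cbind(r0k, c0k)]
    v01 <- layer$values[cbind(r0k, c0k + 1L)]
    v10 <- layer$values[cbind(r0k + 1L, c0k)]
    v11 <- layer$values[cbind(r0k + 1L, c0k + 1L)]
    wxk <- wx[ok]; wyk <- wy[ok]
    out[ok] <- (1 - wyk) * ((1 - wxk) * v00 + wxk * v01) +
      wyk * ((1 - wxk) * v10 + wxk * v11)
  }
  raster_layer(matrix(out, target$n_rows, target$n_cols),
               target, layer$semantics, layer$nodata)
}
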