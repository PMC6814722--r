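#' Construct a classified lidar point cloud
#'
#' A point cloud is a tibble of returns with projected coordinates, an
#' elevation and a ground/vegetation classification, tagged with its
#' acquisition year and CRS. Only transects acquired since 2010 are
#' admissible for validation against the condition index, which matches
#' the index's reference period.
#'
#' @param points A data frame with numeric columns `x`, `y`, `z` (metres)
#'   and a `cls` column with values `"ground"` or `"vegetation"`.
#' @param acquisition_year Calendar year the transect was flown.
#' @param crs_id Projected CRS identifier.
#' @return A tibble of class `point_cloud` with attributes
#'   `acquisition_year` and `crs_id`.
#' @examples
#' point_cloud(data.frame(x = 0, y = 0, z = c(100, 120),
#'                        cls = c("ground", "vegetation")), 2014)
#' @export
point_cloud <- function(points, acquisition_year, crs_id = 32722L) {
  stopifnot(all(c("x", "y", "z", "cls") %in% names(points)))
  if (!all(points$cls %in% c("ground", "vegetation")))
    stop("`cls` must be 'ground' or 'vegetation'", call. = FALSE)
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z)))
    stop("point coordinates must be finite", call. = FALSE)
  out <- tibble::as_tibble(points[c("x", "y", "z", "cls")])
  attr(out, "acquisition_year") <- as.integer(acquisition_year)
  attr(out, "crs_id") <- as.integer(crs_id)
  class(out) <- c("point_cloud", class(out))
  out
}

#' Read a point cloud from delimited text
#'
#' Plain-text fallback for LAS/LAZ: whitespace- or comma-separated columns
#' `x y z cls`, where `cls` is either the word `ground`/`vegetation` or a
#' LAS classification code (2 = ground, any other code = vegetation).
#'
#' @param path File path. A header line is auto-detected.
#' @param acquisition_year,crs_id Passed to [point_cloud()].
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, acquisition_year, crs_id = 32722L) {
  if (!file.exists(path))
    stop("point-cloud file '", path, "' does not exist", call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- is.na(suppressWarnings(as.numeric(fields[1])))
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (!header) names(df)[1:4] <- c("x", "y", "z", "cls")
  if (is.numeric(df$cls))
    df$cls <- ifelse(df$cls == 2, "ground", "vegetation")
  point_cloud(df, acquisition_year, crs_id)
}

#' Write a point cloud to delimited text
#'
#' @param cloud A [point_cloud()].
#' @param path Output path (comma-separated, with header).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud)[c("x", "y", "z", "cls")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize vegetation returns to height above ground
#'
#' For every vegetation point, the ground elevation beneath it is
#' interpolated from its `k` nearest ground-classified points in the x-y
#' plane by inverse-distance-squared weighting
#' (g = sum(z_i / d_i^2) / sum(1 / d_i^2)); a vegetation point exactly on
#' a ground point takes that point's elevation. Fewer than `k` ground
#' points in the cloud means all available ground points are used.
#'
#' @param cloud A [point_cloud()] with at least one ground point.
#' @param k Number of ground neighbours (default 6).
#' @return A tibble of class `normalized_cloud` with columns `x`, `y`,
#'   `height` (metres above ground, may still be negative or above 70
#'   until [filter_points()] is applied), carrying the source cloud's
#'   attributes plus `n_ground`.
#' @export
normalize_heights <- function(cloud, k = 6L) {
  stopifnot(inherits(cloud, "point_cloud"))
  g <- cloud[cloud$cls == "ground", ]
  v <- cloud[cloud$cls == "vegetation", ]
  if (nrow(g) == 0L)
    stop("cloud contains no ground points; cannot normalize", call. = FALSE)
  ground_z <- if (nrow(v)) {
    knn_idw_ground(g$x, g$y, g$z, v$x, v$y, as.integer(k))
  } else numeric(0)
  out <- tibble::tibble(x = v$x, y = v$y, height = v$z - ground_z)
  attr(out, "acquisition_year") <- attr(cloud, "acquisition_year")
  attr(out, "crs_id") <- attr(cloud, "crs_id")
  attr(out, "n_ground") <- nrow(g)
  class(out) <- c("normalized_cloud", class(out))
  out
}

#' Apply the height filters to a normalized cloud
#'
#' Heights above 70 m are discarded (cloud and sensor-noise returns);
#' small negative heights, which arise when a vegetation return sits below
#' the interpolated ground surface, are clamped to 0 so ground-hugging
#' returns still count towards point density.
#'
#' @param cloud A `normalized_cloud` from [normalize_heights()].
#' @param max_height Removal threshold in metres (default 70; strictly
#'   greater heights are removed).
#' @return The filtered `normalized_cloud`.
#' @examples
#' # heights {3, 71, 69.9} -> {3, 69.9}
#' @export
filter_points <- function(cloud, max_height = 70) {
  stopifnot(inherits(cloud, "normalized_cloud"))
  at <- attributes(cloud)
  out <- cloud[cloud$height <= max_height, ]
  out$height <- pmax(out$height, 0)
  for (a in c("acquisition_year", "crs_id", "n_ground"))
    attr(out, a) <- at[[a]]
  class(out) <- unique(c("normalized_cloud", class(out)))
  out
}

## 1-based linear cell id per point (NA outside the grid)
point_cell_ids <- function(spec, x, y) {
  idx <- cells_of_points(spec, x, y)
  ifelse(is.na(idx$row), NA_integer_,
         (idx$col - 1L) * spec$n_rows + idx$row)
}

#' Vegetation point density per grid cell
#'
#' Counts vegetation returns whose x-y position falls in each cell and
#' divides by the cell area, giving points per square metre. Cells sparser
#' than 10 pts/m2 are later excluded from foliage-height-diversity
#' analysis.
#'
#' @param cloud A `normalized_cloud`.
#' @param spec The analysis [grid_spec()] (30 m cells by convention).
#' @return A [raster_layer()] with semantics `"density"`; cells without
#'   points have density 0.
#' @export
point_density <- function(cloud, spec) {
  stopifnot(inherits(cloud, "normalized_cloud"))
  ids <- point_cell_ids(spec, cloud$x, cloud$y)
  counts <- tabulate(ids[!is.na(ids)], nbins = spec$n_rows * spec$n_cols)
  raster_layer(matrix(counts / spec$cell_size^2, spec$n_rows, spec$n_cols),
               spec, "density")
}

#' Foliage height diversity per grid cell
#'
#' For each sufficiently dense cell, vegetation heights are binned at 1 m
#' vertical intervals (`[i, i + 1)` for i = 0..69, with a point at exactly
#' 70 m closing the last bin) and the Shannon index
#' FHD = -sum p_i * log(p_i) is computed over the occupied bins, where p_i
#' is the proportion of the cell's vegetation points in bin i. Cells with
#' density below `density_min` are masked invalid. Natural log by default,
#' so FHD lies in [0, log(70)] for a 70-bin profile.
#'
#' @param cloud A filtered `normalized_cloud` (see [filter_points()]).
#' @param spec The analysis [grid_spec()].
#' @param density_min Validity threshold in points per square metre
#'   (default 10; cells strictly below it are masked).
#' @param log_base Base of the Shannon logarithm (default `exp(1)`).
#' @return An object of class `fhd_grid`: a list with [raster_layer()]s
#'   `fhd` and `density` plus a logical `valid` matrix.
#' @examples
#' sp <- grid_spec(0, 30, 30, 1, 1)
#' cl <- structure(tibble::tibble(x = runif(9000, 0, 30),
#'                                y = runif(9000, 0, 30),
#'                                height = rep(c(1.5, 2.5, 3.5, 4.5), 2250)),
#'                 class = c("normalized_cloud", "tbl_df", "tbl", "data.frame"))
#' compute_fhd(cl, sp)$fhd$values  # log(4)
#' @export
compute_fhd <- function(cloud, spec, density_min = 10, log_base = exp(1)) {
  stopifnot(inherits(cloud, "normalized_cloud"))
  if (any(cloud$height < 0 | cloud$height > 70))
    stop("cloud has heights outside [0, 70]; run filter_points() first",
         call. = FALSE)
  n_cells <- spec$n_rows * spec$n_cols
  ids <- point_cell_ids(spec, cloud$x, cloud$y)
  keep <- !is.na(ids)
  ids <- ids[keep]
  bin <- pmin(floor(cloud$height[keep]), 69)  # height 70 closes bin 69
  counts <- tabulate(ids[!is.na(ids)], nbins = n_cells)
  density <- counts / spec$cell_size^2
  valid <- density >= density_min

  # 70 x n_cells bin-count table in one pass
  bins <- matrix(tabulate((ids - 1L) * 70L + bin + 1L, nbins = 70L * n_cells),
                 nrow = 70L)
  totals <- colSums(bins)
  p <- sweep(bins, 2, pmax(totals, 1), "/")
  plogp <- p * log(p, base = log_base)
  plogp[p == 0] <- 0
  fhd <- -colSums(plogp)
  fhd[!valid | totals == 0] <- NA_real_

  structure(list(
    fhd = raster_layer(matrix(fhd, spec$n_rows, spec$n_cols), spec, "fhd"),
    density = raster_layer(matrix(density, spec$n_rows, spec$n_cols),
                           spec, "density"),
    valid = matrix(valid, spec$n_rows, spec$n_cols)
  ), class = "fhd_grid")
}

#' @export
#' @method print fhd_grid
print.fhd_grid <- function(x, ...) {
  cat(sprintf("<fhd_grid> %d x %d cells, %d valid (density >= threshold)\n",
              x$fhd$spec$n_rows, x$fhd$spec$n_cols, sum(x$valid)))
  invisible(x)
}
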