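#' Human-pressure classes from the Human Footprint index
#'
#' The cumulative Human Footprint (HFP, 0-50) is collapsed into three
#' pressure classes with multiplicative weights: Low (weight 1) for
#' HFP < 4, Medium (weight 5) for 4 <= HFP <= 15, High (weight 10) for
#' HFP > 15. The thresholds match those found relevant to vertebrate
#' endangerment responses to human pressure.
#'
#' @param hfp Human-footprint scores (non-negative).
#' @param thresholds Length-2 numeric, the Low/Medium and Medium/High cut
#'   points (Medium is the closed interval between them).
#' @param weights Named numeric, weights for `LOW`, `MED`, `HIGH`.
#' @return `pressure_class()`: a character vector in `LOW`, `MED`, `HIGH`
#'   (`NA` for negative or missing scores). `pressure_weight()`: the
#'   corresponding numeric weights.
#' @examples
#' pressure_class(c(3.9, 4, 15, 15.1))
#' pressure_weight(c(3.9, 4, 15, 15.1))
#' @export
pressure_class <- function(hfp, thresholds = c(4, 15)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  out <- rep(NA_character_, length(hfp))
  ok <- !is.na(hfp) & hfp >= 0
  x <- hfp[ok]
  out[ok] <- ifelse(x < thresholds[1], "LOW",
             ifelse(x <= thresholds[2], "MED", "HIGH"))
  out
}

PRESSURE_WEIGHTS <- c(LOW = 1, MED = 5, HIGH = 10)

#' @rdname pressure_class
#' @export
pressure_weight <- function(hfp, thresholds = c(4, 15),
                            weights = PRESSURE_WEIGHTS) {
  unname(weights[pressure_class(hfp, thresholds)])
}

#' Forest Structural Integrity Index value
#'
#' FSII = SCI * 1 / (human pressure weight): the structural condition score
#' discounted by the pressure class weight, ranging from 0.1 (SCI 1 under
#' high pressure) to 18 (SCI 18 under low pressure). The published table's
#' printed Low-pressure entry for SCI 1 (0.2) disagrees with the formula
#' (1.0); this implementation follows the formula.
#'
#' @param sci Integer SCI weights in 1-18.
#' @param pclass Pressure class labels (`LOW`, `MED`, `HIGH`), recycled
#'   against `sci`.
#' @param weights Named numeric pressure weights.
#' @return Numeric FSII values.
#' @examples
#' fsii_value(18, "HIGH")  # 1.8
#' fsii_value(6, "MED")    # 1.2
#' @export
fsii_value <- function(sci, pclass, weights = PRESSURE_WEIGHTS) {
  n <- max(length(sci), length(pclass))
  sci <- rep_len(sci, n); pclass <- rep_len(pclass, n)
  ok <- is.na(sci) | (sci %in% 1:18)
  if (!all(ok))
    stop("`sci` values must be integers in 1..18", call. = FALSE)
  if (any(!is.na(pclass) & !pclass %in% names(weights)))
    stop("invalid pressure class label", call. = FALSE)
  sci / unname(weights[pclass])
}

#' The full 18 x 3 FSII table
#'
#' All attainable FSII values: SCI 1-18 crossed with the three pressure
#' classes, evaluated by the formula.
#'
#' @inheritParams fsii_value
#' @return A tibble with columns `sci`, `pressure_class`, `weight`, `fsii`
#'   (54 rows).
#' @examples
#' fsii_table()
#' @export
fsii_table <- function(weights = PRESSURE_WEIGHTS) {
  grid <- tidyr::expand_grid(
    sci = 1:18,
    pressure_class = factor(names(weights), names(weights))
  )
  dplyr::mutate(grid,
                weight = unname(weights[as.character(.data$pressure_class)]),
                fsii = fsii_value(.data$sci,
                                  as.character(.data$pressure_class),
                                  weights))
}

## Modal (most frequent) value of each coarse cell's fine cells; ties break
## toward the smaller value for determinism.
aggregate_modal <- function(layer, target) {
  if (layer$spec$crs_id != target$crs_id)
    stop("aggregate_modal: CRS mismatch", call. = FALSE)
  cc <- cell_centers(layer$spec)
  xs <- rep(cc$x, each = layer$spec$n_rows)
  ys <- rep(cc$y, times = layer$spec$n_cols)
  idx <- cells_of_points(target, xs, ys)
  v <- as.vector(layer$values)
  keep <- !is.na(idx$row) & !is.na(v)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (any(keep)) {
    cellid <- (idx$col[keep] - 1L) * target$n_rows + idx$row[keep]
    tab <- tapply(v[keep], cellid, function(z) {
      t <- table(z)
      as.numeric(names(t)[which.max(t)])
    })
    out[as.integer(names(tab))] <- as.numeric(tab)
  }
  raster_layer(out, target, layer$semantics, layer$nodata)
}

#' Compute the FSII layer
#'
#' Overlays the human-footprint surface on an SCI raster: each cell's SCI
#' is divided by the pressure weight of its HFP class. By default the HFP
#' layer (typically ~1 km) is resampled to the SCI grid by nearest
#' neighbour and the result is at SCI (30 m) resolution; with
#' `at_hfp_resolution = TRUE` the SCI layer is instead aggregated to the
#' HFP grid by modal value and the result is at HFP resolution.
#'
#' @param sci_layer A [raster_layer()] with semantics `"sci"`.
#' @param hfp_layer A [raster_layer()] with semantics `"hfp"`, same CRS
#'   (its grid may be coarser).
#' @param at_hfp_resolution Compute on the HFP grid instead of the SCI
#'   grid.
#' @param thresholds,weights Passed to [pressure_weight()].
#' @return A [raster_layer()] with semantics `"fsii"`.
#' @export
compute_fsii <- function(sci_layer, hfp_layer, at_hfp_resolution = FALSE,
                         thresholds = c(4, 15), weights = PRESSURE_WEIGHTS) {
  stopifnot(inherits(sci_layer, "raster_layer"),
            inherits(hfp_layer, "raster_layer"))
  if (sci_layer$spec$crs_id != hfp_layer$spec$crs_id)
    stop("compute_fsii: SCI and HFP layers are in different CRSs",
         call. = FALSE)
  if (at_hfp_resolution) {
    sci <- aggregate_modal(sci_layer, hfp_layer$spec)
    hfp <- hfp_layer
  } else {
    sci <- sci_layer
    hfp <- resample_nearest(hfp_layer, sci_layer$spec)
  }
  w <- pressure_weight(as.vector(hfp$values), thresholds, weights)
  s <- as.vector(sci$values)
  if (any(!is.na(s) & !s %in% 1:18))
    stop("SCI layer contains values outside 1..18", call. = FALSE)
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s) & !is.na(w)
  out[ok] <- s[ok] / w[ok]
  raster_layer(matrix(out, sci$spec$n_rows, sci$spec$n_cols),
               sci$spec, "fsii")
}
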