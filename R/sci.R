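#' Forest Structural Condition Index (SCI) classification
#'
#' The SCI scores each 30 m forest cell from 1 (short, open-canopy or
#' recently disturbed) to 18 (tall, closed-canopy, no stand-replacing loss
#' since 2000) by crossing three classifications: canopy cover class,
#' canopy height class, and the epoch of the most recent forest loss.
#' [classify_cover()], [classify_height()] and [classify_loss()] implement
#' the individual axes; [sci_weight()] is the published lookup;
#' [compute_sci()] applies the composition to a whole [layer_stack()].
#'
#' Boundary conventions follow the published classification conditionals:
#' cover below 25 percent is the masked class (cover exactly 25 is
#' forested), height at or below 5 m is the shortest class, and the upper
#' bound of every interior class is inclusive (15 m belongs to the 5-15 m
#' class, cover 95 to the 75-95 class).
#'
#' @param cover_pct Canopy cover percentage, 0-100.
#' @param height_m Canopy height in metres, non-negative.
#' @param code Loss-year code: 0 = no loss since 2000, k = loss in calendar
#'   year 2000 + k (1-17 = 2001-2017).
#' @return A character vector of class labels (`NA` for invalid or missing
#'   input): cover in `BELOW25`, `C25_75`, `C75_95`, `ABOVE95`; height in
#'   `H0_5`, `H5_15`, `H15_20`, `H20PLUS`; loss epoch in `NONE`, `MID`
#'   (2001-2012), `RECENT` (2013-2017).
#' @examples
#' classify_cover(c(24.9, 25, 95, 95.1))
#' classify_height(c(5, 15, 20.5))
#' classify_loss(c(0, 12, 13))
#' @name sci_classes
NULL

COVER_LEVELS <- c("BELOW25", "C25_75", "C75_95", "ABOVE95")
HEIGHT_LEVELS <- c("H0_5", "H5_15", "H15_20", "H20PLUS")
EPOCH_LEVELS <- c("NONE", "MID", "RECENT")

#' @rdname sci_classes
#' @export
classify_cover <- function(cover_pct) {
  out <- rep(NA_character_, length(cover_pct))
  ok <- !is.na(cover_pct) & cover_pct >= 0 & cover_pct <= 100
  x <- cover_pct[ok]
  out[ok] <- ifelse(x < 25, "BELOW25",
             ifelse(x <= 75, "C25_75",
             ifelse(x <= 95, "C75_95", "ABOVE95")))
  out
}

#' @rdname sci_classes
#' @export
classify_height <- function(height_m) {
  out <- rep(NA_character_, length(height_m))
  ok <- !is.na(height_m) & height_m >= 0
  x <- height_m[ok]
  out[ok] <- ifelse(x <= 5, "H0_5",
             ifelse(x <= 15, "H5_15",
             ifelse(x <= 20, "H15_20", "H20PLUS")))
  out
}

#' @rdname sci_classes
#' @export
classify_loss <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code) & code %in% 0:17
  x <- code[ok]
  out[ok] <- ifelse(x == 0, "NONE", ifelse(x <= 12, "MID", "RECENT"))
  out
}

## weight[h, c] for the two non-recent epochs; any RECENT epoch, BELOW25
## cover or H0_5 height maps to 1 regardless of the other axes
SCI_WEIGHTS <- list(
  MID = matrix(c(2, 3, 4,
                 5, 6, 7,
                 8, 9, 10), 3, 3, byrow = TRUE,
               dimnames = list(HEIGHT_LEVELS[-1], COVER_LEVELS[-1])),
  NONE = matrix(c(10, 11, 12,
                  13, 14, 15,
                  16, 17, 18), 3, 3, byrow = TRUE,
                dimnames = list(HEIGHT_LEVELS[-1], COVER_LEVELS[-1]))
)

#' Look up the SCI weight for a class combination
#'
#' Vectorised over the three label vectors. Any recent-loss epoch, cover
#' below 25 percent, or height at or below 5 m yields weight 1; otherwise
#' the mid-epoch block runs 2-10 and the no-loss block 10-18, each
#' increasing with height class then cover class.
#'
#' @param epoch,height_class,cover_class Label vectors as returned by
#'   [classify_loss()], [classify_height()], [classify_cover()].
#' @return Integer weights in 1-18 (`NA` where any label is `NA`).
#' @examples
#' sci_weight("NONE", "H20PLUS", "ABOVE95")   # 18
#' sci_weight("RECENT", "H20PLUS", "ABOVE95") # 1
#' @export
sci_weight <- function(epoch, height_class, cover_class) {
  n <- max(length(epoch), length(height_class), length(cover_class))
  epoch <- rep_len(epoch, n)
  height_class <- rep_len(height_class, n)
  cover_class <- rep_len(cover_class, n)
  bad_lab <- function(x, lv) !is.na(x) & !x %in% lv
  if (any(bad_lab(epoch, EPOCH_LEVELS)) ||
      any(bad_lab(height_class, HEIGHT_LEVELS)) ||
      any(bad_lab(cover_class, COVER_LEVELS)))
    stop("invalid class label passed to sci_weight()", call. = FALSE)
  out <- rep(NA_integer_, n)
  ok <- !is.na(epoch) & !is.na(height_class) & !is.na(cover_class)
  one <- ok & (epoch == "RECENT" | cover_class == "BELOW25" |
                 height_class == "H0_5")
  out[one] <- 1L
  rest <- ok & !one
  for (ep in c("MID", "NONE")) {
    sel <- rest & epoch == ep
    if (any(sel))
      out[sel] <- as.integer(
        SCI_WEIGHTS[[ep]][cbind(height_class[sel], cover_class[sel])])
  }
  out
}

#' The full SCI weight table as a tibble
#'
#' One row per (loss epoch, height class, cover class) combination with its
#' SCI weight; the long form of the published 3 x 11 classification table.
#' Useful for inspection, re-weighting and export via
#' [write_weight_table()].
#'
#' @return A tibble with columns `epoch`, `height_class`, `cover_class`,
#'   `weight` (48 rows: 3 x 4 x 4).
#' @examples
#' sci_weight_table()
#' @export
sci_weight_table <- function() {
  grid <- tidyr::expand_grid(
    epoch = factor(EPOCH_LEVELS, EPOCH_LEVELS),
    height_class = factor(HEIGHT_LEVELS, HEIGHT_LEVELS),
    cover_class = factor(COVER_LEVELS, COVER_LEVELS)
  )
  dplyr::mutate(grid, weight = sci_weight(as.character(.data$epoch),
                                          as.character(.data$height_class),
                                          as.character(.data$cover_class)))
}

#' Export / import an SCI weight table
#'
#' Plain-text CSV round-trip of the (epoch, height_class, cover_class,
#' weight) lookup so the weighting can be altered for regional needs and
#' fed back into [compute_sci()].
#'
#' @param table A tibble shaped like [sci_weight_table()].
#' @param path CSV file path.
#' @return `write_weight_table()` returns `path` invisibly;
#'   `read_weight_table()` returns the tibble.
#' @export
write_weight_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("epoch", "height_class", "cover_class", "weight") %in%
                  names(tb)))
  tb$epoch <- factor(tb$epoch, EPOCH_LEVELS)
  tb$height_class <- factor(tb$height_class, HEIGHT_LEVELS)
  tb$cover_class <- factor(tb$cover_class, COVER_LEVELS)
  tb
}

#' Compute the SCI layer from a stack of input rasters
#'
#' Applies the cover, height and loss-epoch classifications cell-wise and
#' looks up the SCI weight. Any cell with missing or out-of-range input in
#' any layer is `NA` in the output.
#'
#' @param stack A [layer_stack()] (the `hfp` slot is ignored here).
#' @param weights Optional custom weight table shaped like
#'   [sci_weight_table()]; defaults to the published weights.
#' @return A [raster_layer()] with semantics `"sci"` and values 1-18.
#' @examples
#' sp <- grid_spec(0, 60, 30, 2, 2)
#' st <- layer_stack(
#'   raster_layer(matrix(100, 2, 2), sp, "cover_pct"),
#'   raster_layer(matrix(30, 2, 2), sp, "height_m"),
#'   raster_layer(matrix(0, 2, 2), sp, "loss_year_code")
#' )
#' compute_sci(st)$values  # all 18
#' @export
compute_sci <- function(stack, weights = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  ep <- classify_loss(as.vector(stack$loss$values))
  hc <- classify_height(as.vector(stack$height$values))
  cc <- classify_cover(as.vector(stack$cover$values))
  w <- if (is.null(weights)) {
    sci_weight(ep, hc, cc)
  } else {
    key <- paste(ep, hc, cc)
    lut <- stats::setNames(weights$weight,
                           paste(weights$epoch, weights$height_class,
                                 weights$cover_class))
    unname(lut[key])
  }
  spec <- stack$cover$spec
  raster_layer(matrix(as.numeric(w), spec$n_rows, spec$n_cols),
               spec, "sci")
}
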