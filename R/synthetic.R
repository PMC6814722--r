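#' Configuration for a synthetic landscape
#'
#' Controls the seeded generator that emulates the classified input
#' rasters: a patchy 18-class condition mosaic on a 30 m grid and a
#' coarser human-footprint surface, with every generated cell's cover,
#' height and loss code drawn from its class's admissible region so the
#' classification is exactly invertible.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell size in metres (default 30).
#' @param n_patches Number of region-growing seeds (patch count).
#' @param sci_class_probabilities Length-18 sampling weights for patch
#'   classes; must sum to 1.
#' @param hfp_cell_size Human-footprint cell size in metres; a multiple of
#'   `cell_size` (default 990, i.e. 33 cells, ~1 km).
#' @param seed Random seed; identical seeds give bit-identical output.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 60, n_cols = 60, cell_size = 30,
                             n_patches = 80,
                             sci_class_probabilities = rep(1 / 18, 18),
                             hfp_cell_size = 990, seed = 1L) {
  stopifnot(length(sci_class_probabilities) == 18,
            abs(sum(sci_class_probabilities) - 1) < 1e-8,
            all(sci_class_probabilities >= 0),
            n_patches >= 1, n_patches <= n_rows * n_cols)
  if (abs(hfp_cell_size / cell_size -
            round(hfp_cell_size / cell_size)) > 1e-9)
    stop("hfp_cell_size must be a multiple of cell_size", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, n_patches = as.integer(n_patches),
                 sci_class_probabilities = sci_class_probabilities,
                 hfp_cell_size = hfp_cell_size, seed = as.integer(seed)),
            class = "landscape_config")
}

## admissible (epoch, height_class, cover_class) combinations per SCI class
admissible_combos <- function() {
  tb <- sci_weight_table()
  split(tb[c("epoch", "height_class", "cover_class")], tb$weight)
}

draw_cover <- function(cls) {
  lo <- c(BELOW25 = 0, C25_75 = 25, C75_95 = 75, ABOVE95 = 95)[cls]
  hi <- c(BELOW25 = 25, C25_75 = 75, C75_95 = 95, ABOVE95 = 100)[cls]
  stats::runif(length(cls), lo, hi)  # open interval, so bounds stay in-class
}

draw_height <- function(cls) {
  lo <- c(H0_5 = 0, H5_15 = 5, H15_20 = 15, H20PLUS = 20)[cls]
  hi <- c(H0_5 = 5, H5_15 = 15, H15_20 = 20, H20PLUS = 35)[cls]
  stats::runif(length(cls), lo, hi)
}

draw_loss <- function(ep) {
  n <- length(ep)
  out <- integer(n)
  out[ep == "MID"] <- sample(1:12, sum(ep == "MID"), replace = TRUE)
  out[ep == "RECENT"] <- sample(13:17, sum(ep == "RECENT"), replace = TRUE)
  out
}

#' Generate a synthetic landscape with known condition classes
#'
#' Seeded region growing first tiles the grid into irregular patches, each
#' assigned an SCI class from the configured probabilities. Cover, height
#' and loss-code layers are then drawn uniformly from each cell's class's
#' admissible region of the classification table, which guarantees that
#' [compute_sci()] recovers the generated truth on every cell. The
#' human-footprint surface is drawn per coarse cell, uniform on 0-50.
#'
#' @param config A [landscape_config()].
#' @return A list with `stack` (a [layer_stack()]), `truth` (the SCI
#'   [raster_layer()] the generator encoded) and `patches` (the region
#'   labels as a [raster_layer()]).
#' @examples
#' ls <- generate_landscape(landscape_config(n_rows = 20, n_cols = 20,
#'                                           n_patches = 12, seed = 7))
#' all(compute_sci(ls$stack)$values == ls$truth$values)
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  P <- matrix(0L, nr, nc)
  seeds <- sample.int(nr * nc, config$n_patches)
  P[seeds] <- seq_len(config$n_patches)

  shift <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  while (any(P == 0L)) {
    grown <- P
    for (d in sample(4)) {
      src <- switch(d, shift(P, 1, 0), shift(P, -1, 0),
                    shift(P, 0, 1), shift(P, 0, -1))
      # stochastic uptake makes patch boundaries irregular
      take <- grown == 0L & src > 0L &
        matrix(stats::runif(nr * nc) < 0.6, nr, nc)
      grown[take] <- src[take]
    }
    if (all(grown == P)) {  # guarantee progress on unlucky sweeps
      src <- shift(P, 1, 0)
      take <- grown == 0L & src > 0L
      grown[take] <- src[take]
    }
    P <- grown
  }

  patch_class <- sample(1:18, config$n_patches, replace = TRUE,
                        prob = config$sci_class_probabilities)
  truth_vals <- matrix(patch_class[P], nr, nc)

  combos <- admissible_combos()
  cls <- as.vector(truth_vals)
  ep <- character(length(cls)); hc <- character(length(cls))
  cc <- character(length(cls))
  for (w in sort(unique(cls))) {
    sel <- which(cls == w)
    cm <- combos[[as.character(w)]]
    pick <- sample.int(nrow(cm), length(sel), replace = TRUE)
    ep[sel] <- as.character(cm$epoch[pick])
    hc[sel] <- as.character(cm$height_class[pick])
    cc[sel] <- as.character(cm$cover_class[pick])
  }
  spec <- grid_spec(0, nr * config$cell_size, config$cell_size, nr, nc)
  cover <- raster_layer(matrix(draw_cover(cc), nr, nc), spec, "cover_pct")
  height <- raster_layer(matrix(draw_height(hc), nr, nc), spec, "height_m")
  loss <- raster_layer(matrix(draw_loss(ep), nr, nc), spec,
                       "loss_year_code")

  ratio <- as.integer(round(config$hfp_cell_size / config$cell_size))
  hfp_spec <- grid_spec(0, nr * config$cell_size, config$hfp_cell_size,
                        ceiling(nr / ratio), ceiling(nc / ratio),
                        spec$crs_id)
  hfp <- raster_layer(
    matrix(stats::runif(hfp_spec$n_rows * hfp_spec$n_cols, 0, 50),
           hfp_spec$n_rows, hfp_spec$n_cols), hfp_spec, "hfp")

  list(stack = layer_stack(cover, height, loss, hfp),
       truth = raster_layer(truth_vals, spec, "sci"),
       patches = raster_layer(P, spec, "class_label"))
}

#' Per-class canopy vertical profile model
#'
#' Describes, for each SCI class, the expected vegetation point density
#' and a three-stratum Gaussian mixture (ground-hugging returns,
#' understory, canopy) over height above ground. Canopy top height and
#' profile evenness grow with class, so the expected binned Shannon
#' diversity is non-decreasing in class; with `saturate = TRUE` classes
#' above 14 reuse the class-14 profile, mimicking the saturation of
#' structural complexity among the highest condition classes.
#'
#' @param saturate Share the class-14 profile across classes 14-18.
#' @param density Expected vegetation point density (pts/m2), recycled to
#'   18 classes.
#' @return A list of class `canopy_profile_model` with `density` (length
#'   18) and `strata`, a tibble of `class`, `stratum`, `weight`, `mean`,
#'   `sd` (heights in metres).
#' @export
canopy_profile_model <- function(saturate = TRUE, density = 12) {
  top <- c(4, 6 + (2:18 - 2) * 1.8)
  wg <- seq(0.55, 0.12, length.out = 18)   # ground-return share falls
  if (saturate) {
    top[top > top[14]] <- top[14]
    wg[15:18] <- wg[14]
  }
  strata <- dplyr::bind_rows(lapply(1:18, function(cl) {
    tibble::tibble(
      class = cl,
      stratum = c("ground", "understory", "canopy"),
      weight = c(wg[cl], (1 - wg[cl]) * 0.45, (1 - wg[cl]) * 0.55),
      mean = c(0.4, 0.38 * top[cl], 0.8 * top[cl]),
      sd = c(0.35, 0.20 * top[cl], 0.13 * top[cl])
    )
  }))
  structure(list(density = rep_len(density, 18), strata = strata,
                 saturate = saturate),
            class = "canopy_profile_model")
}

#' Expected foliage height diversity of a profile model
#'
#' Closed-form Shannon diversity of the 1 m binned height distribution a
#' class's mixture implies, accounting for the pipeline's clamping of
#' negative heights into the first bin and removal of heights above 70 m.
#' This is the oracle that measured per-cell FHD converges to.
#'
#' @param model A [canopy_profile_model()].
#' @param sci_class Class in 1..18 (vectorised).
#' @param log_base Base of the Shannon logarithm.
#' @return Expected FHD value(s).
#' @export
expected_fhd <- function(model, sci_class, log_base = exp(1)) {
  stopifnot(inherits(model, "canopy_profile_model"),
            all(sci_class %in% 1:18))
  vapply(sci_class, function(cl) {
    st <- model$strata[model$strata$class == cl, ]
    edges <- 0:70
    mass <- rep(0, 70)
    for (s in seq_len(nrow(st))) {
      cdf <- stats::pnorm(edges, st$mean[s], st$sd[s])
      m <- diff(cdf)
      m[1] <- cdf[2]           # clamp: everything below 1 m lands in bin 0
      mass <- mass + st$weight[s] * m
    }
    p <- mass / sum(mass)      # condition on height <= 70 (filter rule)
    p <- p[p > 0]
    -sum(p * log(p, base = log_base))
  }, numeric(1))
}

#' Generate a lidar point cloud over a condition truth raster
#'
#' Per cell, a Poisson number of vegetation returns at the class's
#' expected density is scattered uniformly in the cell, with heights drawn
#' from the class's stratum mixture; ground returns are laid down at
#' `ground_density` on a smooth synthetic terrain, and vegetation
#' elevations ride on the same terrain. The result feeds the full
#' normalization / filtering / FHD pipeline.
#'
#' @param truth An SCI [raster_layer()] (e.g. from
#'   [generate_landscape()]).
#' @param model A [canopy_profile_model()].
#' @param seed Random seed.
#' @param ground_density Ground returns per square metre (default 1).
#' @param terrain `function(x, y)` giving ground elevation in metres;
#'   default a gentle sinusoidal surface around 150 m.
#' @param acquisition_year Year tag for the cloud (default 2014).
#' @return A [point_cloud()].
#' @export
generate_point_cloud <- function(truth, model, seed = 1L,
                                 ground_density = 1,
                                 terrain = NULL, acquisition_year = 2014) {
  stopifnot(inherits(truth, "raster_layer"),
            inherits(model, "canopy_profile_model"))
  if (is.null(terrain))
    terrain <- function(x, y) 150 + 8 * sin(x / 180) + 6 * cos(y / 240)
  set.seed(seed)
  spec <- truth$spec
  s <- spec$cell_size
  area <- s^2
  cells <- as_tibble(truth)
  cells <- cells[!is.na(cells$value), ]

  n_veg <- stats::rpois(nrow(cells), model$density[cells$value] * area)
  veg_cell <- rep.int(seq_len(nrow(cells)), n_veg)
  vx <- cells$x[veg_cell] + stats::runif(length(veg_cell), -s / 2, s / 2)
  vy <- cells$y[veg_cell] + stats::runif(length(veg_cell), -s / 2, s / 2)
  vcls <- cells$value[veg_cell]
  # stratum choice and height draw, vectorised over all points at once
  st <- model$strata
  h <- numeric(length(veg_cell))
  u <- stats::runif(length(veg_cell))
  for (cl in unique(vcls)) {
    rows <- st[st$class == cl, ]
    sel <- vcls == cl
    br <- cumsum(rows$weight) / sum(rows$weight)
    k <- findInterval(u[sel], br, left.open = TRUE) + 1L
    h[sel] <- stats::rnorm(sum(sel), rows$mean[k], rows$sd[k])
  }

  n_grd <- stats::rpois(nrow(cells), ground_density * area)
  grd_cell <- rep.int(seq_len(nrow(cells)), n_grd)
  gx <- cells$x[grd_cell] + stats::runif(length(grd_cell), -s / 2, s / 2)
  gy <- cells$y[grd_cell] + stats::runif(length(grd_cell), -s / 2, s / 2)

  pts <- tibble::tibble(
    x = c(vx, gx), y = c(vy, gy),
    z = c(terrain(vx, vy) + h, terrain(gx, gy)),
    cls = rep(c("vegetation", "ground"), c(length(vx), length(gx)))
  )
  point_cloud(pts, acquisition_year, spec$crs_id)
}

#' Simulate validation samples with known group structure
#'
#' Draws the sample table the model-comparison suite consumes directly:
#' FHD is linear in SCI with additive Gaussian random intercepts for
#' transect and for patch-within-transect, plus residual noise. Used to
#' check that the mixed-model suite recovers the generating structure
#' (positive slope, AIC ordering nested < transect < OLS, variance
#' components).
#'
#' @param n_transects,patches_per_transect,cells_per_patch Design size
#'   (defaults 10 x 20 x 9).
#' @param beta0,beta1 Fixed intercept and SCI slope (defaults 0.5, 0.12).
#' @param sd_transect,sd_patch,sd_resid Standard deviations of the
#'   transect intercepts, patch intercepts and residual (defaults 0.3,
#'   0.15, 0.1).
#' @param seed Random seed.
#' @return A `validation_samples` tibble with a `true_fhd` column of
#'   noise-free values alongside the usual fields.
#' @export
simulate_validation_samples <- function(n_transects = 10,
                                        patches_per_transect = 20,
                                        cells_per_patch = 9,
                                        beta0 = 0.5, beta1 = 0.12,
                                        sd_transect = 0.3, sd_patch = 0.15,
                                        sd_resid = 0.1, seed = 1L) {
  set.seed(seed)
  n_patch <- n_transects * patches_per_transect
  n <- n_patch * cells_per_patch
  transect <- rep(seq_len(n_transects), each = patches_per_transect *
                    cells_per_patch)
  patch <- rep(seq_len(n_patch), each = cells_per_patch)
  sci <- rep(sample(1:18, n_patch, replace = TRUE), each = cells_per_patch)
  u_t <- stats::rnorm(n_transects, 0, sd_transect)
  u_p <- stats::rnorm(n_patch, 0, sd_patch)
  mu <- beta0 + beta1 * sci
  fhd <- mu + u_t[transect] + u_p[patch] + stats::rnorm(n, 0, sd_resid)
  out <- tibble::tibble(
    transect_id = sprintf("T%02d", transect),
    patch_id = patch,
    row = NA_integer_, col = NA_integer_,
    sci = as.integer(sci), fhd = fhd, true_fhd = mu
  )
  class(out) <- c("validation_samples", class(out))
  out
}

#' Generate a forest-history class raster for a condition truth
#'
#' Assigns each cell one of the forest-history classes (primary, older
#' secondary, plantation, other) with probabilities tied to its SCI
#' class, so plantations dominate the low classes and primary forest the
#' high ones — the skew the per-class SCI histograms display.
#'
#' @param truth An SCI [raster_layer()].
#' @param seed Random seed.
#' @return A [raster_layer()] with semantics `"class_label"` and codes
#'   1 = primary, 2 = older_secondary, 3 = plantation, 4 = other.
#' @export
generate_forest_classes <- function(truth, seed = 1L) {
  set.seed(seed)
  s <- as.vector(truth$values)
  out <- rep(NA_real_, length(s))
  ok <- which(!is.na(s))
  w_primary <- stats::pnorm((s[ok] - 12) / 3)
  w_second <- stats::dnorm((s[ok] - 10) / 4) * 2.5
  w_plant <- stats::pnorm((6 - s[ok]) / 3)
  w_other <- 0.05
  w <- cbind(w_primary, w_second, w_plant, w_other)
  u <- stats::runif(length(ok)) * rowSums(w)
  cum <- t(apply(w, 1, cumsum))
  out[ok] <- apply(cum >= u, 1, which.max)
  raster_layer(matrix(out, truth$spec$n_rows, truth$spec$n_cols),
               truth$spec, "class_label")
}
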