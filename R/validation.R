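#' Mask cells disturbed after lidar acquisition
#'
#' The condition index is classified from the full loss record, but a cell
#' cleared after the lidar was flown no longer matches the point cloud;
#' such cells are removed from validation. A cell is masked when its loss
#' code exceeds `year - 2000` (strictly: loss in the acquisition year is
#' retained).
#'
#' @param sci A [raster_layer()] with semantics `"sci"`.
#' @param loss An aligned [raster_layer()] with semantics
#'   `"loss_year_code"`.
#' @param year Lidar acquisition year (2001-2017).
#' @return The `sci` layer with post-acquisition-loss cells set to `NA`.
#' @export
mask_post_acquisition_loss <- function(sci, loss, year) {
  stopifnot(year >= 2001, year <= 2017)
  if (!specs_identical(sci$spec, loss$spec))
    stop("sci and loss layers are not aligned", call. = FALSE)
  v <- sci$values
  v[!is.na(loss$values) & loss$values > (year - 2000)] <- NA_real_
  raster_layer(v, sci$spec, "sci")
}

#' Label homogeneous patches of a classified raster
#'
#' Connected components of equal value: two cells belong to the same patch
#' when they share a value and are rook-adjacent (4-connectivity; queen
#' adjacency available via `connectivity = 8`). `NA` cells are background
#' (label 0). Labels are assigned in column-major order of first
#' occurrence, so labelling is deterministic.
#'
#' @param layer A [raster_layer()] (typically semantics `"sci"`).
#' @param connectivity 4 (rook, default) or 8 (queen).
#' @return An object of class `patch_map`: a list with `labels` (a
#'   [raster_layer()], semantics `"class_label"`, 0 = background) and
#'   `info`, a tibble of `patch_id`, `value`, `n_cells`.
#' @export
label_patches <- function(layer, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  v <- layer$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(!is.na(v))
  lab <- matrix(0, nr, nc)
  if (length(idx)) {
    vid <- matrix(0L, nr, nc)
    vid[idx] <- seq_along(idx)
    edge_pairs <- function(dr, dc) {
      r1 <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
      c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
      a <- v[r1, c1, drop = FALSE]
      b <- v[r1 + dr, c1 + dc, drop = FALSE]
      same <- !is.na(a) & !is.na(b) & a == b
      cbind(vid[r1, c1, drop = FALSE][same],
            vid[r1 + dr, c1 + dc, drop = FALSE][same])
    }
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    edges <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1], o[2])))
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    # relabel by first occurrence in column-major cell order
    relab <- match(memb, unique(memb))
    lab[idx] <- relab
  }
  info <- if (length(idx)) {
    tibble::tibble(patch_id = lab[idx], value = v[idx]) |>
      dplyr::count(.data$patch_id, .data$value, name = "n_cells") |>
      dplyr::arrange(.data$patch_id)
  } else {
    tibble::tibble(patch_id = integer(), value = numeric(),
                   n_cells = integer())
  }
  structure(list(labels = raster_layer(lab, layer$spec, "class_label"),
                 info = info),
            class = "patch_map")
}

#' @export
#' @method print patch_map
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d patches over %d labelled cells\n",
              nrow(x$info), sum(x$info$n_cells)))
  invisible(x)
}

#' Extract homogeneous patch cores
#'
#' Validation cells are the cores of homogeneous patches: patches smaller
#' than `min_cells` are dropped, and every remaining cell within
#' `buffer_m` of its patch perimeter is removed. Distance is Chebyshev
#' (square rings), so a 90 m buffer on a 30 m grid erodes three cells in
#' every direction, including diagonals; the raster edge counts as
#' perimeter. A 9 x 9 patch keeps a 3 x 3 core; a 3 x 3 patch erodes away
#' entirely.
#'
#' @param patches A `patch_map` from [label_patches()].
#' @param min_cells Minimum patch size in cells (default 9, i.e. 3 x 3).
#' @param buffer_m Perimeter buffer in metres (default 90); must be a
#'   multiple of the cell size.
#' @return A [raster_layer()] mask (1 = core cell, 0 = not).
#' @export
extract_cores <- function(patches, min_cells = 9, buffer_m = 90) {
  stopifnot(inherits(patches, "patch_map"))
  spec <- patches$labels$spec
  r <- buffer_m / spec$cell_size
  if (abs(r - round(r)) > 1e-9)
    stop("buffer_m must be a multiple of the cell size", call. = FALSE)
  r <- as.integer(round(r))
  lab <- patches$labels$values
  keep <- lab > 0
  nr <- nrow(lab); nc <- ncol(lab)
  pad_lab <- matrix(-1, nr + 2L, nc + 2L)   # outside the raster: perimeter
  pad_lab[2:(nr + 1L), 2:(nc + 1L)] <- lab
  for (i in seq_len(r)) {
    pad_keep <- matrix(FALSE, nr + 2L, nc + 2L)
    pad_keep[2:(nr + 1L), 2:(nc + 1L)] <- keep
    nxt <- keep
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb_lab <- pad_lab[2:(nr + 1L) + dr, 2:(nc + 1L) + dc, drop = FALSE]
      nb_keep <- pad_keep[2:(nr + 1L) + dr, 2:(nc + 1L) + dc, drop = FALSE]
      nxt <- nxt & nb_keep & nb_lab == lab
    }
    keep <- nxt
  }
  if (nrow(patches$info)) {
    small <- patches$info$patch_id[patches$info$n_cells < min_cells]
    keep[lab %in% small] <- FALSE
  }
  raster_layer(keep * 1, spec, "class_label")
}

#' Assemble the validation sample table
#'
#' One record per cell that (a) has a valid foliage-height-diversity
#' estimate, (b) has a condition-index value, and (c) lies in a
#' homogeneous-patch core. The FHD grid must already be aligned to the
#' index grid (see [resample_bilinear()]).
#'
#' @param fhd An `fhd_grid` from [compute_fhd()], or a [raster_layer()]
#'   with semantics `"fhd"` (then all non-`NA` cells count as valid).
#' @param sci A [raster_layer()] with semantics `"sci"` on the same spec.
#' @param cores Core mask from [extract_cores()].
#' @param transect_id Identifier of the lidar transect the cells belong to.
#' @param patches Optional `patch_map`; defaults to [label_patches()] of
#'   `sci`, giving each record its patch id.
#' @return A tibble of class `validation_samples` with columns
#'   `transect_id`, `patch_id`, `row`, `col`, `sci`, `fhd`.
#' @export
build_samples <- function(fhd, sci, cores, transect_id = "T1",
                          patches = NULL) {
  if (inherits(fhd, "fhd_grid")) {
    fhd_layer <- fhd$fhd
    valid <- fhd$valid & !is.na(fhd$fhd$values)
  } else {
    fhd_layer <- fhd
    valid <- !is.na(fhd$values)
  }
  if (!specs_identical(fhd_layer$spec, sci$spec) ||
      !specs_identical(cores$spec, sci$spec))
    stop("fhd, sci and cores must share one grid_spec", call. = FALSE)
  if (is.null(patches)) patches <- label_patches(sci)
  sel <- which(valid & !is.na(sci$values) & cores$values == 1)
  nr <- sci$spec$n_rows
  out <- tibble::tibble(
    transect_id = as.character(transect_id),
    patch_id = as.integer(patches$labels$values[sel]),
    row = ((sel - 1L) %% nr) + 1L,
    col = ((sel - 1L) %/% nr) + 1L,
    sci = as.integer(sci$values[sel]),
    fhd = fhd_layer$values[sel]
  )
  class(out) <- c("validation_samples", class(out))
  out
}

sample_fingerprint <- function(samples) {
  c(n = nrow(samples), sum_fhd = sum(samples$fhd), sum_sci = sum(samples$sci))
}

new_fhd_sci_fit <- function(name, formula_text, fit, samples) {
  structure(list(name = name, formula_text = formula_text, fit = fit,
                 fingerprint = sample_fingerprint(samples)),
            class = "fhd_sci_fit")
}

#' Fit the baseline OLS model of FHD on SCI
#'
#' `FHD = b0 + b1 * SCI + e` by ordinary least squares, with SCI treated
#' as a continuous covariate. The AIC comes from the Gaussian maximum
#' likelihood, so it is comparable with the mixed-model fits.
#'
#' @param samples A `validation_samples` tibble (needs >= 3 records and
#'   >= 2 distinct SCI values).
#' @return An object of class `fhd_sci_fit`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance].
#' @export
fit_ols <- function(samples) {
  if (nrow(samples) < 3 || length(unique(samples$sci)) < 2)
    stop("need >= 3 records with >= 2 distinct SCI values", call. = FALSE)
  fit <- stats::lm(fhd ~ sci, data = samples)
  new_fhd_sci_fit("ols", "FHD = SCI + e", fit, samples)
}

#' Fit a random-intercept mixed model of FHD on SCI
#'
#' Gaussian linear mixed model with a fixed slope on SCI and random
#' intercepts for the grouping: either transect only
#' (`FHD = SCI + (1|transect) + e`) or patch nested in transect
#' (`FHD = SCI + (1|transect/patch) + e`). Fitted by maximum likelihood
#' (not REML) so AIC is comparable across models with identical fixed
#' effects. Non-convergence raises an error carrying the optimizer
#' diagnostics.
#'
#' @param samples A `validation_samples` tibble with `transect_id` (and
#'   `patch_id` for the nested model); needs >= 2 groups.
#' @param grouping `"transect"` or `"patch_in_transect"`.
#' @return An object of class `fhd_sci_fit`.
#' @export
fit_random_intercept <- function(samples,
                                 grouping = c("transect",
                                              "patch_in_transect")) {
  grouping <- match.arg(grouping)
  dat <- tibble::as_tibble(samples)
  dat$transect_id <- factor(dat$transect_id)
  if (nlevels(dat$transect_id) < 2 && grouping == "transect")
    stop("need >= 2 transects for a transect random intercept",
         call. = FALSE)
  if (grouping == "transect") {
    form <- fhd ~ sci + (1 | transect_id)
    name <- "ri_transect"; ftext <- "FHD = SCI + (1|transect) + e"
  } else {
    dat$patch_in_transect <- factor(paste(dat$transect_id, dat$patch_id,
                                          sep = ":"))
    if (nlevels(dat$patch_in_transect) < 2)
      stop("need >= 2 patches for a nested random intercept", call. = FALSE)
    form <- fhd ~ sci + (1 | transect_id) + (1 | patch_in_transect)
    name <- "ri_nested"; ftext <- "FHD = SCI + (1|transect/patch) + e"
  }
  fit <- lme4::lmer(form, data = dat, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  conv <- fit@optinfo$conv
  if (!is.null(conv$lme4$code) && any(unlist(conv$lme4$code) < 0))
    stop("mixed model failed to converge: ",
         paste(unlist(conv$lme4$messages), collapse = "; "), call. = FALSE)
  new_fhd_sci_fit(name, ftext, fit, samples)
}

fit_variances <- function(x) {
  fit <- x$fit
  if (inherits(fit, "lm")) {
    fe <- stats::fitted(fit)
    list(var_fixed = stats::var(fe), var_random = 0,
         var_resid = sum(stats::resid(fit)^2) / stats::df.residual(fit),
         r2 = summary(fit)$r.squared)
  } else {
    fe <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
    vc <- lme4::VarCorr(fit)
    list(var_fixed = stats::var(fe),
         var_random = sum(vapply(vc, function(m) m[1, 1], numeric(1))),
         var_resid = attr(vc, "sc")^2,
         r2 = NULL)
  }
}

#' @export
#' @method print fhd_sci_fit
print.fhd_sci_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fhd_sci_fit:%s> %s | AIC %.2f, R2m %.3f, R2c %.3f, n %d\n",
              x$name, x$formula_text, g$aic, g$r2_marginal,
              g$r2_conditional, g$nobs))
  invisible(x)
}

#' @rdname fit_ols
#' @param x An `fhd_sci_fit`.
#' @param ... Unused.
#' @export
tidy.fhd_sci_fit <- function(x, ...) {
  fit <- x$fit
  if (inherits(fit, "lm")) {
    co <- summary(fit)$coefficients
    fixed <- tibble::tibble(effect = "fixed",
                            term = c("(Intercept)", "sci"),
                            estimate = unname(co[, 1]),
                            std.error = unname(co[, 2]))
    resid <- tibble::tibble(effect = "ran_pars", term = "sd__Observation",
                            estimate = summary(fit)$sigma,
                            std.error = NA_real_)
    dplyr::bind_rows(fixed, resid)
  } else {
    co <- summary(fit)$coefficients
    fixed <- tibble::tibble(effect = "fixed", term = rownames(co),
                            estimate = unname(co[, 1]),
                            std.error = unname(co[, 2]))
    vc <- as.data.frame(lme4::VarCorr(fit))
    rp <- tibble::tibble(effect = "ran_pars",
                         term = paste0("sd__", vc$grp),
                         estimate = vc$sdcor, std.error = NA_real_)
    dplyr::bind_rows(fixed, rp)
  }
}

#' @rdname fit_ols
#' @export
glance.fhd_sci_fit <- function(x, ...) {
  v <- fit_variances(x)
  tot <- v$var_fixed + v$var_random + v$var_resid
  r2m <- v$var_fixed / tot
  r2c <- (v$var_fixed + v$var_random) / tot
  if (!is.null(v$r2)) { r2m <- v$r2; r2c <- v$r2 }
  tibble::tibble(
    name = x$name, formula = x$formula_text,
    aic = stats::AIC(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    r2_marginal = r2m, r2_conditional = r2c,
    sigma = sqrt(v$var_resid),
    nobs = unname(x$fingerprint["n"])
  )
}

#' Rank candidate models by AIC
#'
#' Collects the goodness-of-fit summaries of a set of fits estimated on
#' the same sample and orders them by AIC, ascending (ties keep their
#' original order). Mixed-model rows report marginal and conditional R2;
#' the OLS row repeats its ordinary R2 in both columns.
#'
#' @param fits A list of `fhd_sci_fit` objects on identical samples.
#' @return A tibble with one row per model: `name`, `formula`, `aic`,
#'   `delta_aic`, `r2_marginal`, `r2_conditional`, `nobs`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "fhd_sci_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE,
                                          "fhd_sci_fit")))
  fps <- vapply(fits, function(f) f$fingerprint, numeric(3))
  if (length(fits) > 1 && any(apply(fps, 1, function(r) diff(range(r)) >
                                      1e-8 * (1 + abs(r[1])))))
    stop("fits were not estimated on identical samples", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  out <- tab[c("name", "formula", "aic", "delta_aic", "r2_marginal",
               "r2_conditional", "nobs")]
  class(out) <- c("model_comparison", class(out))
  out
}

#' Relative SCI frequency by forest class
#'
#' Cross-tabulates an SCI raster against a co-registered forest-class
#' raster (primary, older secondary, plantation, other) and reports, for
#' each class, the relative frequency of every SCI value 1-18 — the
#' histogram comparison showing plantation SCI skewed low and primary
#' forest SCI skewed high.
#'
#' @param sci A [raster_layer()] with semantics `"sci"`.
#' @param classes An aligned [raster_layer()] (semantics `"class_label"`)
#'   whose values are codes into `class_names`.
#' @param class_names Names for the class codes 1..k.
#' @return A tibble of class `sci_distribution` with columns
#'   `forest_class`, `sci`, `n`, `freq` (freq sums to 1 within class; all
#'   18 SCI values present per class).
#' @export
sci_distribution_by_class <- function(sci, classes,
                                      class_names = c("primary",
                                                      "older_secondary",
                                                      "plantation",
                                                      "other")) {
  if (!specs_identical(sci$spec, classes$spec))
    stop("sci and classes layers are not aligned", call. = FALSE)
  keep <- !is.na(sci$values) & !is.na(classes$values)
  df <- tibble::tibble(
    forest_class = factor(class_names[classes$values[keep]], class_names),
    sci = factor(sci$values[keep], levels = 1:18)
  )
  out <- df |>
    dplyr::count(.data$forest_class, .data$sci, .drop = FALSE) |>
    dplyr::group_by(.data$forest_class) |>
    dplyr::mutate(freq = .data$n / pmax(sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(sci = as.integer(as.character(.data$sci))) |>
    dplyr::filter(!is.na(.data$forest_class))
  class(out) <- c("sci_distribution", class(out))
  out
}

#' Mean foliage height diversity by SCI class
#'
#' Summary curve underpinning the monotonicity check: mean (and spread) of
#' FHD for each SCI value present in the samples.
#'
#' @param samples A `validation_samples` tibble.
#' @return A tibble with `sci`, `n`, `mean_fhd`, `sd_fhd`.
#' @export
summarize_fhd_by_sci <- function(samples) {
  samples |>
    dplyr::group_by(sci = .data$sci) |>
    dplyr::summarise(n = dplyr::n(), mean_fhd = mean(.data$fhd),
                     sd_fhd = stats::sd(.data$fhd), .groups = "drop") |>
    dplyr::arrange(.data$sci)
}
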