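test_that("post-acquisition loss masking is strict on the acquisition year", {
  sp <- make_spec(2, 2)
  sci <- rand_sci_layer(2, 2, spec = sp)
  loss <- raster_layer(matrix(c(15, 0, 13, 12), 2, 2), sp,
                       "loss_year_code")
  out <- mask_post_acquisition_loss(sci, loss, 2013)
  expect_true(is.na(out$values[1, 1]))        # loss 2015 > 2013
  expect_equal(out$values[2, 1], sci$values[2, 1])  # no loss
  expect_equal(out$values[1, 2], sci$values[1, 2])  # loss == acquisition
  expect_equal(out$values[2, 2], sci$values[2, 2])  # loss before
  expect_error(mask_post_acquisition_loss(sci, loss, 2000), ">= 2001")
})

test_that("patch labelling matches a flood-fill oracle", {
  # uniform layer is a single patch
  uni <- raster_layer(matrix(7, 5, 5), make_spec(5, 5), "sci")
  pm <- label_patches(uni)
  expect_equal(nrow(pm$info), 1)
  expect_equal(pm$info$n_cells, 25)

  # checkerboard: every cell its own patch under rook adjacency
  chk <- raster_layer(outer(1:4, 1:4, function(r, c) (r + c) %% 2 + 1),
                      make_spec(4, 4), "sci")
  pmc <- label_patches(chk)
  expect_equal(nrow(pmc$info), 16)
  # ... but two patches under queen adjacency
  expect_equal(nrow(label_patches(chk, connectivity = 8)$info), 2)

  # random layers, both connectivities, vs brute-force flood fill
  withr::local_seed(19)
  for (rep in 1:6) {
    conn <- if (rep %% 2) 4 else 8
    r <- rand_sci_layer(8, 9, values = 1:3, p_na = 0.15)
    got <- label_patches(r, connectivity = conn)$labels$values
    want <- oracle_label_patches(r$values, connectivity = conn)
    storage.mode(want) <- "double"
    expect_identical(got, want)  # identical labels incl. numbering order
  }
})

test_that("core extraction erodes the perimeter by the Chebyshev buffer", {
  # 9x9 uniform patch in a background frame: 3x3 core survives
  v <- matrix(NA, 11, 11); v[2:10, 2:10] <- 5
  pm <- label_patches(raster_layer(v, make_spec(11, 11), "sci"))
  core <- extract_cores(pm, min_cells = 9, buffer_m = 90)
  want <- matrix(0, 11, 11); want[5:7, 5:7] <- 1
  expect_equal(core$values, want)

  # a 3x3 patch erodes away entirely
  v3 <- matrix(NA, 5, 5); v3[2:4, 2:4] <- 2
  pm3 <- label_patches(raster_layer(v3, make_spec(5, 5), "sci"))
  expect_true(all(extract_cores(pm3)$values == 0))

  # buffer 0 keeps whole patches that meet the size rule
  expect_equal(extract_cores(pm3, min_cells = 9, buffer_m = 0)$values,
               (!is.na(v3)) * 1)
  expect_error(extract_cores(pm3, buffer_m = 45), "multiple")

  # random patch maps vs the per-cell minimum-distance oracle
  withr::local_seed(23)
  for (rep in 1:6) {
    r <- rand_sci_layer(12, 12, values = 1:2, p_na = 0.1)
    pm <- label_patches(r)
    for (buf in c(30, 90)) {
      got <- extract_cores(pm, min_cells = 9, buffer_m = buf)$values == 1
      want <- oracle_core_mask(pm$labels$values, 9, buf / 30)
      expect_identical(got, want)
      expect_true(all(pm$labels$values[got] > 0))  # cores stay in patches
    }
  }
})

test_that("sample construction intersects the three masks", {
  withr::local_seed(31)
  sp <- make_spec(7, 7)
  sci <- rand_sci_layer(7, 7, values = c(4, 9), p_na = 0.1, spec = sp)
  pm <- label_patches(sci)
  cores <- extract_cores(pm, min_cells = 2, buffer_m = 0)
  fhd_vals <- matrix(runif(49, 0.5, 3), 7, 7)
  fhd_vals[sample(49, 12)] <- NA
  fhd <- raster_layer(fhd_vals, sp, "fhd")
  s <- build_samples(fhd, sci, cores, transect_id = "T7", patches = pm)
  want_mask <- !is.na(fhd_vals) & !is.na(sci$values) & cores$values == 1
  expect_equal(nrow(s), sum(want_mask))
  expect_true(all(s$transect_id == "T7"))
  expect_equal(s$fhd, fhd_vals[cbind(s$row, s$col)])
  expect_equal(s$sci, as.integer(sci$values[cbind(s$row, s$col)]))
  expect_equal(s$patch_id, as.integer(pm$labels$values[cbind(s$row, s$col)]))

  # an everywhere-invalid FHD grid yields zero records
  fhd_na <- raster_layer(matrix(NA_real_, 7, 7), sp, "fhd")
  expect_equal(nrow(build_samples(fhd_na, sci, cores)), 0)
})

test_that("OLS recovers exact linear structure and the normal equations", {
  s <- tibble::tibble(transect_id = "T1", patch_id = 1L,
                      row = 1:6, col = 1L,
                      sci = c(2L, 5L, 9L, 12L, 15L, 18L),
                      fhd = 0.1 * c(2, 5, 9, 12, 15, 18) + 0.5)
  class(s) <- c("validation_samples", class(s))
  fit <- fit_ols(s)
  td <- suppressWarnings(tidy(fit))  # summary.lm warns on a perfect fit
  expect_equal(td$estimate[td$term == "sci"], 0.1, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "(Intercept)"], 0.5,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r2_marginal, 1,
               tolerance = 1e-9)

  # slope of the identity points
  s2 <- s[1:3, ]; s2$sci <- 1:3; s2$fhd <- 1:3
  expect_equal(suppressWarnings(tidy(fit_ols(s2)))$estimate[2], 1,
               tolerance = 1e-10)

  # random samples vs closed-form least squares
  withr::local_seed(13)
  s3 <- s
  s3$fhd <- rnorm(6)
  fit3 <- fit_ols(s3)
  X <- cbind(1, s3$sci)
  beta <- solve(t(X) %*% X, t(X) %*% s3$fhd)
  expect_equal(tidy(fit3)$estimate[1:2], as.vector(beta),
               tolerance = 1e-9)

  expect_error(fit_ols(s[1:2, ]), ">= 3")
  s4 <- s; s4$sci <- 5L
  expect_error(fit_ols(s4), "distinct")
})

test_that("random-intercept fits degenerate to OLS without group structure", {
  withr::local_seed(41)
  s <- simulate_validation_samples(n_transects = 6,
                                  patches_per_transect = 5,
                                  cells_per_patch = 6,
                                  sd_transect = 0, sd_patch = 0,
                                  sd_resid = 0.2, seed = 41)
  ols <- fit_ols(s)
  ri <- fit_random_intercept(s, "transect")
  slope <- function(f) tidy(f)$estimate[tidy(f)$term == "sci"]
  expect_lt(abs(slope(ri) - slope(ols)), 1e-6)
  g <- glance(ri)
  expect_lt(g$r2_conditional - g$r2_marginal, 0.02)
})

test_that("variance components are recovered from generated group shifts", {
  s <- simulate_validation_samples(n_transects = 14,
                                  patches_per_transect = 18,
                                  cells_per_patch = 9,
                                  sd_transect = 0.3, sd_patch = 0.15,
                                  sd_resid = 0.1, seed = 99)
  fit <- fit_random_intercept(s, "patch_in_transect")
  td <- tidy(fit)
  sd_of <- function(term) td$estimate[td$term == term]
  expect_equal(sd_of("sd__transect_id"), 0.3, tolerance = 0.35)
  expect_equal(sd_of("sd__patch_in_transect"), 0.15, tolerance = 0.2)
  expect_equal(sd_of("sd__Residual"), 0.1, tolerance = 0.05)
  expect_equal(td$estimate[td$term == "sci"], 0.12, tolerance = 0.05)
  g <- glance(fit)
  expect_gte(g$r2_conditional, g$r2_marginal)
})

test_that("mixed-model ML estimates match a direct likelihood grid search", {
  # small balanced two-group design, checkable by dense-covariance ML
  withr::local_seed(57)
  sci <- rep(c(3, 7, 11, 15), 4)
  grp <- rep(1:2, each = 8)
  y <- 0.4 + 0.1 * sci + c(-0.25, 0.25)[grp] + rnorm(16, 0, 0.1)
  s <- tibble::tibble(transect_id = paste0("T", grp), patch_id = grp,
                      row = NA_integer_, col = NA_integer_,
                      sci = as.integer(sci), fhd = y)
  class(s) <- c("validation_samples", class(s))
  fit <- fit_random_intercept(s, "transect")

  Z <- outer(grp, 1:2, "==") * 1
  X <- cbind(1, sci)
  loglik <- function(tau, sigma) {
    V <- tau^2 * Z %*% t(Z) + sigma^2 * diag(16)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    -0.5 * (determinant(V)$modulus + t(r) %*% Vi %*% r +
              16 * log(2 * pi))
  }
  taus <- seq(0.01, 0.8, by = 0.005)
  sigmas <- seq(0.02, 0.4, by = 0.002)
  ll <- outer(taus, sigmas, Vectorize(loglik))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "sd__transect_id"], taus[best[1]],
               tolerance = 0.02)
  expect_equal(td$estimate[td$term == "sd__Residual"], sigmas[best[2]],
               tolerance = 0.02)
  expect_equal(as.numeric(stats::logLik(fit$fit)), max(ll),
               tolerance = 1e-3)
})

test_that("model comparison sorts by AIC with stable ties", {
  s <- simulate_validation_samples(n_transects = 5,
                                  patches_per_transect = 6,
                                  cells_per_patch = 5, seed = 3)
  fits <- list(fit_ols(s), fit_random_intercept(s, "transect"),
               fit_random_intercept(s, "patch_in_transect"))
  rep <- compare_models(fits)
  expect_equal(rep$name, c("ri_nested", "ri_transect", "ols"))
  expect_true(all(diff(rep$aic) >= 0))
  expect_equal(rep$delta_aic[1], 0)

  single <- compare_models(list(fit_ols(s)))
  expect_equal(nrow(single), 1)

  # fits on different samples refuse to be compared
  s2 <- simulate_validation_samples(n_transects = 5,
                                   patches_per_transect = 6,
                                   cells_per_patch = 5, seed = 4)
  expect_error(compare_models(list(fit_ols(s), fit_ols(s2))),
               "identical samples")
})

test_that("per-class SCI distributions match a cross-tabulation oracle", {
  sp <- make_spec(6, 6)
  # one class, uniform SCI 18
  sci <- raster_layer(matrix(18, 6, 6), sp, "sci")
  cls <- raster_layer(matrix(1, 6, 6), sp, "class_label")
  d <- sci_distribution_by_class(sci, cls)
  expect_equal(d$freq[d$forest_class == "primary" & d$sci == 18], 1)
  expect_equal(sum(d$freq[d$forest_class == "primary"]), 1)

  # disjoint SCI ranges give disjoint histograms
  v <- matrix(c(rep(3, 18), rep(16, 18)), 6, 6)
  cl2 <- raster_layer(matrix(c(rep(3, 18), rep(1, 18)), 6, 6), sp,
                      "class_label")
  d2 <- sci_distribution_by_class(raster_layer(v, sp, "sci"), cl2)
  expect_equal(d2$freq[d2$forest_class == "plantation" & d2$sci == 3], 1)
  expect_equal(d2$freq[d2$forest_class == "primary" & d2$sci == 16], 1)
  expect_equal(sum(d2$n[d2$forest_class == "plantation" & d2$sci == 16]), 0)

  # random layers vs brute-force cross-tab
  withr::local_seed(61)
  scir <- rand_sci_layer(8, 8, p_na = 0.1)
  clsr <- raster_layer(matrix(sample(1:4, 64, TRUE), 8, 8), sp <-
                         make_spec(8, 8), "class_label")
  d3 <- sci_distribution_by_class(scir, clsr)
  for (k in 1:4) for (w in 1:18) {
    keep <- !is.na(scir$values)
    want <- sum(scir$values[keep] == w & clsr$values[keep] == k)
    expect_equal(d3$n[d3$forest_class == levels(d3$forest_class)[k] &
                        d3$sci == w], want)
  }
})
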