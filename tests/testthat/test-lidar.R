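test_that("normalization handles single-ground and constant-surface cases", {
  # one ground point: k collapses to 1, height = z - ground z
  cl <- point_cloud(data.frame(x = c(0, 3), y = c(0, 4),
                               z = c(10, 25),
                               cls = c("ground", "vegetation")), 2014)
  nc <- normalize_heights(cl)
  expect_equal(nc$height, 15)

  # all ground at one elevation: every height is z - e
  withr::local_seed(21)
  g <- data.frame(x = runif(40, 0, 50), y = runif(40, 0, 50), z = 120,
                  cls = "ground")
  v <- data.frame(x = runif(25, 0, 50), y = runif(25, 0, 50),
                  z = runif(25, 120, 150), cls = "vegetation")
  nc2 <- normalize_heights(point_cloud(rbind(g, v), 2014))
  expect_equal(nc2$height, v$z - 120, tolerance = 1e-12)

  # a vegetation point exactly over a ground point takes its elevation
  cl3 <- point_cloud(data.frame(
    x = c(0, 1, 2, 0), y = c(0, 0, 0, 0), z = c(7, 9, 11, 20),
    cls = c("ground", "ground", "ground", "vegetation")), 2014)
  expect_equal(normalize_heights(cl3)$height, 13)

  expect_error(
    normalize_heights(point_cloud(data.frame(x = 1, y = 1, z = 5,
                                             cls = "vegetation"), 2014)),
    "ground")
})

test_that("kNN-IDW normalization matches the brute-force oracle", {
  withr::local_seed(33)
  for (rep in 1:8) {
    ng <- sample(4:60, 1)
    nv <- sample(3:20, 1)
    g <- data.frame(x = runif(ng, 0, 100), y = runif(ng, 0, 100),
                    z = runif(ng, 50, 80), cls = "ground")
    v <- data.frame(x = runif(nv, 0, 100), y = runif(nv, 0, 100),
                    z = runif(nv, 80, 120), cls = "vegetation")
    nc <- normalize_heights(point_cloud(rbind(g, v), 2014))
    want <- v$z - oracle_knn_idw(g$x, g$y, g$z, v$x, v$y, k = 6)
    expect_equal(nc$height, want, tolerance = 1e-9)
  }
})

test_that("height filtering removes >70 m and clamps negatives to zero", {
  sp <- make_spec(1, 1, cell = 30)
  cl <- flat_cloud(x = rep(15, 4), y = rep(15, 4),
                   heights = c(3, 71, 69.9, -0.3), spec = sp)
  nc <- filter_points(normalize_heights(cl))
  expect_setequal(round(nc$height, 6), c(3, 69.9, 0))
  # empty cloud stays empty
  empty <- normalize_heights(point_cloud(
    data.frame(x = 1, y = 1, z = 0, cls = "ground"), 2014))
  expect_equal(nrow(filter_points(empty)), 0)
})

test_that("point density counts vegetation returns per 30 m cell", {
  withr::local_seed(14)
  sp <- make_spec(1, 1, cell = 30)
  cl <- flat_cloud(runif(9000, 0, 30), runif(9000, 0, 30),
                   heights = runif(9000, 1, 30), spec = sp)
  nc <- filter_points(normalize_heights(cl))
  expect_equal(point_density(nc, sp)$values[1, 1], 10)

  # random scatter across a grid vs brute-force point-in-box assignment
  sp2 <- make_spec(3, 4, cell = 30)
  n <- 500
  x <- runif(n, 0, 120); y <- runif(n, 0, 90)
  cl2 <- flat_cloud(x, y, heights = runif(n, 0, 20), spec = sp2)
  nc2 <- filter_points(normalize_heights(cl2))
  dens <- point_density(nc2, sp2)$values
  for (r in 1:3) for (c in 1:4) {
    inbox <- sum(x >= (c - 1) * 30 & x < c * 30 &
                   y > 90 - r * 30 & y <= 90 - (r - 1) * 30)
    expect_equal(dens[r, c], inbox / 900)
  }
  # empty cell has density zero
  sp3 <- make_spec(1, 2, cell = 30)
  cl3 <- flat_cloud(c(5), c(5), heights = 2, spec = sp3)
  expect_equal(point_density(filter_points(normalize_heights(cl3)),
                             sp3)$values[1, 2], 0)
})

test_that("FHD follows the Shannon index of 1 m bins", {
  sp <- make_spec(1, 1, cell = 30)
  n <- 9000
  withr::local_seed(2)
  xy <- list(x = runif(n, 0, 30), y = runif(n, 0, 30))

  # all points in one bin
  g0 <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(xy$x, xy$y, rep(4.2, n), sp))), sp)
  expect_equal(g0$fhd$values[1, 1], 0)

  # equal counts over 4 bins
  g4 <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(xy$x, xy$y, rep(c(1.5, 2.5, 3.5, 4.5), n / 4), sp))), sp)
  expect_equal(g4$fhd$values[1, 1], log(4), tolerance = 1e-12)

  # counts (50, 30, 20) across 3 bins, hand-computed
  h <- rep(c(0.5, 1.5, 2.5), c(4500, 2700, 1800))
  g3 <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(xy$x, xy$y, h, sp))), sp)
  want <- -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2))
  expect_equal(g3$fhd$values[1, 1], want, tolerance = 1e-12)

  # a point at exactly 70 m closes the last bin rather than spilling over
  g70 <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(xy$x, xy$y, rep(c(69.5, 70), n / 2), sp))), sp)
  expect_equal(g70$fhd$values[1, 1], 0)

  # base-2 option
  gb <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(xy$x, xy$y, rep(c(1.5, 2.5, 3.5, 4.5), n / 4), sp))), sp,
    log_base = 2)
  expect_equal(gb$fhd$values[1, 1], 2)
})

test_that("sparse cells are masked and FHD matches the per-cell oracle", {
  withr::local_seed(77)
  sp <- make_spec(2, 3, cell = 30)
  # per-cell target densities straddling the 10 pts/m2 rule
  dens <- matrix(c(12, 9.99, 10, 0.5, 11, 2), 2, 3)
  pts <- do.call(rbind, lapply(seq_len(6), function(i) {
    r <- ((i - 1) %% 2) + 1; c <- ((i - 1) %/% 2) + 1
    n <- round(dens[r, c] * 900)
    data.frame(x = runif(n, (c - 1) * 30, c * 30 - 1e-9),
               y = runif(n, 60 - r * 30 + 1e-9, 60 - (r - 1) * 30),
               h = runif(n, 0, 35))
  }))
  nc <- filter_points(normalize_heights(
    flat_cloud(pts$x, pts$y, pts$h, sp)))
  g <- compute_fhd(nc, sp, density_min = 10)
  counts <- matrix(0, 2, 3)
  for (i in seq_len(6)) counts[i] <- round(dens[i] * 900)
  expect_equal(g$valid, counts / 900 >= 10)
  expect_equal(is.na(g$fhd$values), !g$valid)
  # valid cells match the brute-force Shannon oracle
  ids <- cells_of_points(sp, pts$x, pts$y)
  for (i in which(g$valid)) {
    r <- ((i - 1) %% 2) + 1; c <- ((i - 1) %/% 2) + 1
    sel <- ids$row == r & ids$col == c
    expect_equal(g$fhd$values[r, c], oracle_fhd(pts$h[sel]),
                 tolerance = 1e-9)
  }
})

test_that("FHD is invariant to duplication, order and rigid translation", {
  withr::local_seed(55)
  sp <- make_spec(2, 2, cell = 30)
  n <- 2 * 2 * 900 * 11
  x <- runif(n, 0, 60); y <- runif(n, 0, 60); h <- runif(n, 0, 40)
  base <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(x, y, h, sp))), sp)

  # doubling every point leaves proportions, hence FHD, unchanged
  dbl <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(c(x, x), c(y, y), c(h, h), sp))), sp)
  expect_equal(dbl$fhd$values, base$fhd$values, tolerance = 1e-12)

  # permuting point order changes nothing
  p <- sample(n)
  prm <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(x[p], y[p], h[p], sp))), sp)
  expect_equal(prm$fhd$values, base$fhd$values, tolerance = 1e-12)

  # translating cloud and grid together changes nothing
  sp2 <- grid_spec(1000, 2060, 30, 2, 2, sp$crs_id)
  trl <- compute_fhd(filter_points(normalize_heights(
    flat_cloud(x + 1000, y + 2000, h, sp2))), sp2)
  expect_equal(trl$fhd$values, base$fhd$values, tolerance = 1e-12)

  # range bound
  fin <- base$fhd$values[!is.na(base$fhd$values)]
  expect_true(all(fin >= 0 & fin <= log(70)))
})

test_that("point clouds round-trip through delimited text", {
  withr::local_seed(4)
  cl <- point_cloud(data.frame(x = runif(10), y = runif(10),
                               z = runif(10, 50, 90),
                               cls = rep(c("ground", "vegetation"), 5)),
                    2013, crs_id = 31981L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(cl, f)
  cl2 <- read_point_cloud(f, acquisition_year = 2013, crs_id = 31981L)
  expect_equal(as.data.frame(cl2), as.data.frame(cl), tolerance = 1e-12)
  expect_identical(attr(cl2, "acquisition_year"), 2013L)

  # LAS-style numeric classification codes: 2 = ground, others vegetation
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0 2.0 50.0 2", "1.5 2.5 70.0 5"), f2)
  cl3 <- read_point_cloud(f2, 2014)
  expect_identical(cl3$cls, c("ground", "vegetation"))
})
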