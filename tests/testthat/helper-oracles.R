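## Shared fixtures and independent brute-force oracles.

make_spec <- function(nr = 4, nc = 5, cell = 30, x0 = 0, y0 = nr * cell,
                      crs = 32722L) {
  grid_spec(x0, y0, cell, nr, nc, crs)
}

rand_sci_layer <- function(nr, nc, values = 1:18, p_na = 0, spec = NULL) {
  v <- sample(values, nr * nc, replace = TRUE)
  if (p_na > 0) v[runif(nr * nc) < p_na] <- NA
  raster_layer(matrix(v, nr, nc), spec %||% make_spec(nr, nc), "sci")
}

## flat-terrain cloud whose normalized heights are exactly `heights`:
## a dense ground lattice at z = 0 plus vegetation returns at z = height
flat_cloud <- function(x, y, heights, spec, year = 2014) {
  gx <- seq(spec$origin_x + 1, spec$origin_x + spec$n_cols * spec$cell_size,
            by = 5)
  gy <- seq(spec$origin_y - spec$n_rows * spec$cell_size + 1, spec$origin_y,
            by = 5)
  g <- expand.grid(x = gx, y = gy)
  point_cloud(data.frame(
    x = c(x, g$x), y = c(y, g$y), z = c(heights, rep(0, nrow(g))),
    cls = rep(c("vegetation", "ground"), c(length(x), nrow(g)))
  ), year, spec$crs_id)
}

## brute-force kNN inverse-distance-squared ground interpolation
oracle_knn_idw <- function(gx, gy, gz, qx, qy, k = 6) {
  vapply(seq_along(qx), function(i) {
    d2 <- (gx - qx[i])^2 + (gy - qy[i])^2
    ord <- order(d2, seq_along(d2))[seq_len(min(k, length(d2)))]
    if (d2[ord[1]] == 0) return(gz[ord[1]])
    w <- 1 / d2[ord]
    sum(w * gz[ord]) / sum(w)
  }, numeric(1))
}

## brute-force Shannon index of 1 m bins for one cell's heights
oracle_fhd <- function(heights, log_base = exp(1)) {
  bin <- pmin(floor(heights), 69)
  p <- as.vector(table(bin)) / length(bin)
  stopifnot(abs(sum(p) - 1) < 1e-12)
  -sum(p * log(p, base = log_base))
}

## brute-force flood fill connected components of equal value
oracle_label_patches <- function(values, connectivity = 4) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      apply(1, identity, simplify = FALSE) |>
      Filter(f = function(o) any(o != 0))
  }
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (is.na(values[r0, c0]) || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- cur[1] + o[1]; c <- cur[2] + o[2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (is.na(values[r, c]) || lab[r, c] != 0L) next
        if (values[r, c] != values[cur[1], cur[2]]) next
        lab[r, c] <- nxt
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  lab
}

## per-cell minimum Chebyshev distance (in cells) to any cell outside the
## patch, including beyond the raster edge
oracle_core_mask <- function(lab, min_cells, radius) {
  nr <- nrow(lab); nc <- ncol(lab)
  sizes <- table(lab[lab > 0])
  keep <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] == 0) next
    if (sizes[[as.character(lab[r, c])]] < min_cells) next
    dmin <- min(r - 1, nr - r, c - 1, nc - c) + 1  # edge as perimeter
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (lab[rr, cc] != lab[r, c]) {
        dmin <- min(dmin, max(abs(rr - r), abs(cc - c)))
      }
    }
    keep[r, c] <- dmin > radius
  }
  keep
}
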