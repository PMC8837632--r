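test_that("cell-to-spot aggregation matches a brute-force containment check", {
  set.seed(41)
  spots <- data.frame(barcode = paste0("b", 1:4),
                      x = c(100, 300, 100, 300), y = c(100, 100, 300, 300),
                      section_id = "s1")
  cells <- data.frame(x = runif(20, 0, 400), y = runif(20, 0, 400),
                      area = runif(20, 10, 100), section_id = "s1")
  agg <- aggregate_cells_to_spots(cells, spots, window = 200)
  brute <- vapply(seq_len(4), function(i)
    sum(abs(cells$x - spots$x[i]) <= 100 & abs(cells$y - spots$y[i]) <= 100),
    1L)
  expect_equal(agg$cell_count, brute)
  # a cell exactly at a spot center is counted
  one <- data.frame(x = 300, y = 100, area = 50, section_id = "s1")
  expect_equal(aggregate_cells_to_spots(one, spots, 200)$cell_count,
               c(0L, 1L, 0L, 0L))
  # empty cell table flags every spot for removal
  none <- cells[0, ]
  expect_true(all(aggregate_cells_to_spots(none, spots, 200)$remove))
  bad <- cells; bad$section_id <- "s9"
  expect_error(aggregate_cells_to_spots(bad, spots, 200),
               class = "spatlo_validation_error")
})

test_that("density percentiles and the strict 70% rule behave on toys", {
  d <- density_score(c(1, 2, 3, 4, 5))
  expect_equal(d$density_score, c(0, 25, 50, 75, 100))
  expect_equal(d$is_tlo, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ties <- density_score(rep(7, 6))
  expect_true(all(ties$density_score == 50))
  expect_false(any(ties$is_tlo))
  expect_equal(density_score(3)$density_score, 50)
  # invariant under strictly monotone transforms of the counts
  set.seed(42)
  cnt <- rpois(50, 20)
  expect_equal(density_score(cnt)$density_score,
               density_score(exp(cnt / 10))$density_score)
  # sections are ranked independently
  two <- density_score(c(1, 2, 3, 10, 20, 30),
                       section_id = rep(c("a", "b"), each = 3))
  expect_equal(two$density_score, rep(c(0, 50, 100), 2))
})

test_that("annotation overlap counts flagged annotated spots", {
  d <- density_score(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  ann <- c(rep("other", 7), rep("infiltrate", 3))
  expect_equal(annotation_overlap(d, ann), 1.0)
  ann2 <- c(rep("infiltrate", 3), rep("other", 7))
  expect_equal(annotation_overlap(d, ann2), 0.0)
  expect_error(annotation_overlap(d, rep("other", 10)),
               class = "spatlo_validation_error")
})

test_that("TLO cores are flagged on simulated tissue", {
  fx <- small_sim(seed = 43, spots_per_section = 400, n_sections = 2)
  sim <- fx$sim
  agg <- aggregate_cells_to_spots(sim$cells, sim$spots,
                                  window = attr(sim$cells, "window"))
  d <- density_score(agg$cell_count, agg$section_id)
  expect_gte(annotation_overlap(d, sim$spots$annotation), 0.8)
})

test_that("registration recovers a known similarity transform", {
  set.seed(44)
  n <- 80
  ref <- data.frame(barcode = sprintf("b%03d", 1:n),
                    x = runif(n, 0, 100), y = runif(n, 0, 100),
                    section_id = "A", z = 0)
  th <- 10 * pi / 180; s <- 1.05; t <- c(3, -2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  P <- s * as.matrix(ref[, c("x", "y")]) %*% t(R) +
    matrix(t, n, 2, byrow = TRUE)
  mov <- data.frame(barcode = ref$barcode, x = P[, 1], y = P[, 2],
                    section_id = "B", z = 7)
  vol <- register_sections(rbind(ref, mov), mode = "scaled_rotation",
                           reference = "A")
  tr <- vol$transforms$B
  # recovered transform is the inverse of the applied one
  expect_lt(abs(tr$theta - (-th)), 1e-6)
  expect_lt(abs(tr$scale - 1 / s), 1e-6)
  inv_t <- -(1 / s) * as.vector(t(R) %*% t)
  expect_lt(abs(tr$tx - inv_t[1]), 1e-6)
  expect_lt(abs(tr$ty - inv_t[2]), 1e-6)
  reg <- as.matrix(vol$spots[vol$spots$section_id == "B",
                             c("x_reg", "y_reg")])
  rmsd <- sqrt(mean((reg - as.matrix(ref[, c("x", "y")]))^2))
  expect_lt(rmsd, 1e-6)
  # identical section maps to the identity
  dup <- ref; dup$section_id <- "C"
  vid <- register_sections(rbind(ref, dup), reference = "A")
  expect_lt(abs(vid$transforms$C$theta), 1e-9)
  expect_lt(abs(vid$transforms$C$scale - 1), 1e-9)
  expect_lt(abs(vid$transforms$C$tx) + abs(vid$transforms$C$ty), 1e-9)
  # rigid mode on a scaled copy forces scale 1 with nonzero residual
  vr <- register_sections(rbind(ref, mov), mode = "rigid", reference = "A")
  expect_equal(vr$transforms$B$scale, 1)
  regr <- as.matrix(vr$spots[vr$spots$section_id == "B",
                             c("x_reg", "y_reg")])
  expect_gt(sqrt(mean((regr - as.matrix(ref[, c("x", "y")]))^2)), 1e-6)
})

test_that("registration least squares agrees with a Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(45)
  n <- 50
  X <- matrix(runif(2 * n, 0, 10), n, 2)
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 1.2 * X %*% t(R) + matrix(c(5, 1), n, 2, byrow = TRUE) +
    matrix(rnorm(2 * n, 0, 0.05), n, 2)
  tr <- spatlo:::fit_similarity(X, Y, scale = TRUE)
  fitted <- spatlo:::apply_similarity(X, tr)
  pro <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
  rss_ours <- sum((fitted - Y)^2)
  rss_oracle <- sum(residuals(pro)^2)
  expect_equal(rss_ours, rss_oracle, tolerance = 1e-8)
})

test_that("ICP registration aligns sections without shared barcodes", {
  set.seed(46)
  n <- 200
  base <- matrix(runif(2 * n, 0, 100), n, 2)
  ref <- data.frame(barcode = sprintf("a%03d", 1:n), x = base[, 1],
                    y = base[, 2], section_id = "A", z = 0)
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  # different spots from the same tissue outline: jitter the same points
  P <- (base + matrix(rnorm(2 * n, 0, 0.3), n, 2)) %*% t(R) +
    matrix(c(2, 1), n, 2, byrow = TRUE)
  mov <- data.frame(barcode = sprintf("c%03d", 1:n), x = P[, 1], y = P[, 2],
                    section_id = "B", z = 7)
  vol <- register_sections(rbind(ref, mov), mode = "rigid", reference = "A")
  reg <- as.matrix(vol$spots[vol$spots$section_id == "B",
                             c("x_reg", "y_reg")])
  rmsd0 <- sqrt(mean((as.matrix(mov[, c("x", "y")]) - base)^2))
  rmsd1 <- sqrt(mean((reg - base)^2))
  expect_lt(rmsd1, rmsd0 / 2)
})

test_that("interpolation reproduces constants, linear fields and spot values", {
  set.seed(47)
  x <- runif(50, 0, 10); y <- runif(50, 0, 10)
  gc_ <- interpolate_grid(rep(3.5, 50), x, y, grid_step = 0.5)
  expect_true(all(abs(gc_$z - 3.5) < 1e-9, na.rm = TRUE))
  f <- 2 * x + y
  g <- interpolate_grid(f, x, y, grid_step = 0.5)
  expected <- outer(g$x, g$y, function(a, b) 2 * a + b)
  expect_true(all(abs(g$z - expected) < 1e-9, na.rm = TRUE))
  # corners outside the hull are masked
  expect_true(anyNA(g$z))
  # random field: value at the grid node nearest each spot is within the
  # local linear variation of the input
  v <- rnorm(50)
  gr <- interpolate_grid(v, x, y, grid_step = 0.05)
  for (i in sample(50, 10)) {
    ix <- which.min(abs(gr$x - x[i])); iy <- which.min(abs(gr$y - y[i]))
    if (!is.na(gr$z[ix, iy]))
      expect_lt(abs(gr$z[ix, iy] - v[i]), 0.05 * (max(v) - min(v)) + 0.2)
  }
  expect_error(interpolate_grid(1:5, 1:5, 2 * (1:5) + 1, 0.5),
               class = "spatlo_degenerate_error")
})

test_that("volume interpolation slices equal per-section interpolation", {
  fx <- small_sim(seed = 48, spots_per_section = 120, n_sections = 3,
                  n_genes = 120, depth_mean = 800, markers_per_type = 8)
  sim <- fx$sim
  vol <- register_sections(sim$spots, mode = "rigid")
  vals <- setNames(as.matrix(sim$counts$values)[, 1], sim$spots$barcode)
  vol <- interpolate_volume(vol, vals, grid_step = 5)
  expect_equal(names(vol$grids), names(sort(vol$z)))
  s2 <- "sec02"
  i <- vol$spots$section_id == s2
  direct <- interpolate_grid(vals[vol$spots$barcode[i]],
                             vol$spots$x_reg[i], vol$spots$y_reg[i],
                             grid_step = 5)
  expect_equal(vol$grids[[s2]]$z, direct$z)
})
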