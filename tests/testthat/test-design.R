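test_that("available points fall on the disc-mask intersection", {
  L <- small_landscape()
  ctr <- c(2000, 2000)
  pts <- with_seed_test(1, sample_available(ctr, 1500, L$eligible, 50))
  expect_equal(nrow(pts), 50L)
  d <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)
  expect_true(all(d <= 1500))
  expect_true(all(raster_value(L$eligible, pts$x, pts$y)))
})

test_that("sampling is uniform on an unmasked disc", {
  full <- grid_raster(matrix(TRUE, 100, 100), cellsize = 50)
  ctr <- c(2500, 2500)
  pts <- with_seed_test(2, sample_available(ctr, 2000, full, 20000))
  ## chi-square over concentric equal-area rings
  d2 <- (pts$x - ctr[1])^2 + (pts$y - ctr[2])^2
  ring <- findInterval(d2 / 2000^2, seq(0, 1, by = 0.1), rightmost.closed = TRUE)
  p <- chisq.test(tabulate(ring, 10))$p.value
  expect_gt(p, 0.01)
  ## and over angular sectors
  a <- atan2(pts$y - ctr[2], pts$x - ctr[1])
  sect <- findInterval(a, seq(-pi, pi, length.out = 13), rightmost.closed = TRUE)
  expect_gt(chisq.test(tabulate(sect, 12))$p.value, 0.01)
})

test_that("a disc with no eligible cells raises a stratum-construction error", {
  empty <- grid_raster(matrix(FALSE, 50, 50), cellsize = 30)
  expect_error(sample_available(c(750, 750), 300, empty, 10), "no available cells")
})

test_that("structure counts are boundary-inclusive at the three radii", {
  L <- small_landscape()
  L$structures <- cbind(x = 2000 + c(90, 400, 900), y = c(2000, 2000, 2000))
  ann <- annotate_diurnal(data.frame(x = 2000, y = 2000), L)
  expect_equal(ann$dens100, 1)
  expect_equal(ann$dens500, 2)
  expect_equal(ann$dens1000, 3)
  expect_equal(ann$dist_structure_km, 0.09)
})

test_that("a structure-free map yields zero counts and the diagonal sentinel", {
  L <- small_landscape()
  L$structures <- L$structures[0, , drop = FALSE]
  ann <- annotate_diurnal(data.frame(x = 1000, y = 1500), L)
  expect_equal(ann$dens100 + ann$dens500 + ann$dens1000, 0)
  expect_equal(ann$dist_structure_km,
               sqrt(sum(L$config$extent_m^2)) / 1000)
  expect_true(attr(ann, "distance_sentinel_used"))
})

test_that("diurnal annotation equals brute-force point-in-cell and distance loops", {
  L <- small_landscape(seed = 4)
  set.seed(11)
  pts <- data.frame(x = runif(40, 50, 3950), y = runif(40, 50, 3950))
  ann <- annotate_diurnal(pts, L)
  st <- L$structures
  for (i in seq_len(nrow(pts))) {
    row <- floor(pts$y[i] / 30) + 1
    col <- floor(pts$x[i] / 30) + 1
    expect_equal(as.character(ann$landuse[i]),
                 L$classes[L$landuse$values[row, col]])
    dd <- sqrt((st[, "x"] - pts$x[i])^2 + (st[, "y"] - pts$y[i])^2)
    expect_equal(ann$dist_structure_km[i], min(dd) / 1000, tolerance = 1e-12)
    expect_equal(ann$dens100[i], sum(dd <= 100))
    expect_equal(ann$dens500[i], sum(dd <= 500))
    expect_equal(ann$dens1000[i], sum(dd <= 1000))
  }
})

test_that("roost annotation uses the nearest station width without interpolation", {
  R <- small_river()
  st <- R$stations
  i <- 40L
  ## a point two-fifths of the way to station i+1 keeps station i's width
  pt <- data.frame(x = st$x[i] * 0.6 + st$x[i + 1] * 0.4,
                   y = st$y[i] * 0.6 + st$y[i + 1] * 0.4)
  ann <- annotate_roost(pt, R, "dec_jan")
  expect_equal(ann$width, st$width[i] / 100)
  expect_error(annotate_roost(pt, R, "jul_aug"), "does not match")
})

test_that("bank vegetation stretch means equal an along-centerline window oracle", {
  R <- small_river(seed = 6)
  st <- R$stations
  pts <- data.frame(x = st$x[c(30, 70, 110)], y = st$y[c(30, 70, 110)])
  ann <- annotate_roost(pts, R, "oct_nov")
  for (i in seq_len(nrow(pts))) {
    si <- c(30, 70, 110)[i]
    for (r in c(100, 500, 1000)) {
      sel <- abs(R$bank$arc - st$arc[si]) <= r / 2
      expected <- if (any(sel)) mean(R$bank$height[sel]) else 0
      got <- ann[[paste0("bank_veg_", r)]][i]
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
  ## hand-built bank cells: heights 1, 2, 3 within the window average to 2
  R2 <- R
  R2$bank <- data.frame(x = 0, y = 0, height = c(1, 2, 3),
                        arc = st$arc[50] + c(-200, 0, 200))
  ann2 <- annotate_roost(data.frame(x = st$x[50], y = st$y[50]), R2, "oct_nov")
  expect_equal(ann2$bank_veg_500, 2)
  expect_equal(ann2$bank_veg_100, 2)    # only the centre cell in the window
})

test_that("build_strata produces labelled 1:50 strata inside the disc", {
  L <- small_landscape()
  used <- data.frame(
    individual_id = rep(c("c1", "c2"), each = 5),
    x = runif(10, 1000, 3000), y = runif(10, 1000, 3000)
  )
  ## place used fixes on eligible cells
  S <- build_strata(used, "diurnal", L, seed = 21,
                    constants = study_constants(radius_m = 1500))
  expect_equal(nrow(S), 10L * 51L)
  expect_equal(length(unique(S$stratum_id)), 10L)
  expect_true(all(tapply(S$is_used, S$stratum_id, sum) == 1L))
  expect_true(all(tapply(S$cluster_id, S$stratum_id,
                         function(v) length(unique(v))) == 1L))
  for (s in unique(S$stratum_id)) {
    rows <- S[S$stratum_id == s, ]
    u <- rows[rows$is_used == 1L, ]
    d <- sqrt((rows$x - u$x)^2 + (rows$y - u$y)^2)
    expect_true(all(d <= 1500))
  }
  S2 <- build_strata(used, "diurnal", L, seed = 21,
                     constants = study_constants(radius_m = 1500))
  expect_identical(as.data.frame(S), as.data.frame(S2))
})

test_that("standardization stores a reusable transform", {
  L <- small_landscape()
  used <- data.frame(individual_id = "c1",
                     x = runif(5, 1000, 3000), y = runif(5, 1000, 3000))
  S <- build_strata(used, "diurnal", L, seed = 3, standardize = TRUE,
                    constants = study_constants(radius_m = 1500))
  std <- attr(S, "standardization")
  expect_true(is.list(std))
  expect_equal(mean(S$dens500), 0, tolerance = 1e-10)
  v <- stats::sd(S$dens500)
  if (std$dens500[["sd"]] > 0) expect_equal(v, 1, tolerance = 1e-10)
})
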