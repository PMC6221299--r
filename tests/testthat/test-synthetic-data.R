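test_that("default landscape is dominated by alfalfa/hay near the 88% mark", {
  L <- generate_landscape()
  fr <- landuse_fractions(L)
  expect_true(abs(fr[["alfalfa_hay"]] - 0.88) <= 0.03)
  expect_equal(sum(fr), 1)
})

test_that("landscape generation is deterministic and honors degenerate classes", {
  cfg <- landscape_config(extent_m = c(3000, 3000), seed = 7)
  L1 <- generate_landscape(cfg)
  L2 <- generate_landscape(cfg)
  expect_identical(L1$landuse$values, L2$landuse$values)
  expect_identical(L1$structures, L2$structures)

  p <- c(alfalfa_hay = 0.92, corn = 0, fallow = 0.03, small_grain = 0.02,
         wetland = 0.02, other = 0.01)
  L0 <- generate_landscape(landscape_config(extent_m = c(3000, 3000),
                                            proportions = p, seed = 7))
  expect_false(any(L0$landuse$values == which(L0$classes == "corn")))

  bad <- c(alfalfa_hay = 0.9, corn = 0.2, fallow = 0, small_grain = 0,
           wetland = 0, other = 0)
  expect_error(landscape_config(proportions = bad), "sum to 1")
})

test_that("structure points lie inside the extent and their cells leave the mask", {
  L <- small_landscape()
  ext <- L$config$extent_m
  expect_true(all(L$structures[, "x"] >= 0 & L$structures[, "x"] <= ext[1]))
  expect_true(all(L$structures[, "y"] >= 0 & L$structures[, "y"] <= ext[2]))
  elig <- raster_value(L$eligible, L$structures[, "x"], L$structures[, "y"])
  expect_false(any(elig))
})

test_that("river proportion rasters close to one on every channel pixel", {
  R <- small_river()
  for (p in R$periods) {
    pr <- R$proportions[[p]]
    tot <- pr$water$values + pr$sandbar$values + pr$vegetation$values
    tot <- tot[!is.na(tot)]
    expect_gt(length(tot), 0)
    expect_true(all(abs(tot - 1) <= 1e-6))
  }
})

test_that("river periods are independently perturbed and widths/heights valid", {
  R <- small_river()
  expect_length(R$proportions, 3L)
  expect_false(identical(R$proportions[[1]]$water$values,
                         R$proportions[[2]]$water$values))
  expect_true(all(R$stations$width > 0))
  expect_true(all(R$bank$height >= 0))
  expect_error(river_config(width_range_m = c(-10, 50)), "positive")
})

test_that("channel membership is locally monotone in station width", {
  R <- small_river()
  st <- R$stations
  i <- which.max(st$width)
  ## the half-width point at the widest station is in the channel; the same
  ## lateral offset at the narrowest station is not
  expect_true(in_channel(R, st$x[i] + st$width[i] / 2 - 1, st$y[i]))
  j <- which.min(st$width)
  expect_false(in_channel(R, st$x[j] + st$width[i] / 2 + 1, st$y[j]))
})

test_that("noiseless spectra reproduce stated convex mixtures exactly", {
  cfg <- spectra_config(noise_sd = 0)
  E <- cfg$endmembers
  s1 <- simulate_spectra(cfg, proportions = rbind(c(1, 0, 0)))
  expect_equal(drop(s1$spectra), unname(E["water", ]), tolerance = 1e-12)
  s2 <- simulate_spectra(cfg, proportions = rbind(c(0.4, 0.6, 0)))
  expect_equal(drop(s2$spectra),
               unname(0.4 * E["water", ] + 0.6 * E["sandbar", ]),
               tolerance = 1e-12)
})

test_that("simulated proportions lie on the simplex and config is validated", {
  out <- simulate_spectra(spectra_config(seed = 3), n_pixels = 200)
  expect_equal(unname(rowSums(out$proportions)), rep(1, 200), tolerance = 1e-12)
  expect_true(all(out$proportions >= 0))
  Ebad <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12), c(0, 0, 0, 1, 1, 1))
  expect_error(spectra_config(endmembers = Ebad), "full row rank")
})

test_that("tracks carry one cluster per bird and are seed-deterministic", {
  L <- small_landscape()
  R <- small_river()
  trk1 <- simulate_tracks(L, R, true_model(), n_individuals = 38, n_days = 2,
                          seed = 5)
  expect_length(unique(trk1$individual_id), 38L)
  trk2 <- simulate_tracks(L, R, true_model(), n_individuals = 38, n_days = 2,
                          seed = 5)
  expect_identical(trk1, trk2)
  ## seven fixes per bird-day, strictly increasing timestamps per bird
  expect_equal(nrow(trk1), 38L * 2L * 7L)
  for (d in split(trk1, trk1$individual_id)) {
    expect_true(all(diff(as.numeric(d$timestamp)) > 0))
  }
})

test_that("null selection uses habitat in proportion to availability", {
  ## beta = 0 everywhere: pooled chi-square over 20 seeds against the
  ## eligible-mask class composition
  L <- small_landscape(seed = 2)
  R <- small_river(seed = 2)
  null_truth <- true_model(diurnal = c(ownershippublic = 0),
                           diurnal_formula = ~ ownership)
  obs <- numeric(6)
  for (s in 1:20) {
    trk <- simulate_tracks(L, R, null_truth, n_individuals = 2, n_days = 5,
                           seed = s, p_fly = 0)
    d <- trk[!is.na(trk$truth_period) & trk$truth_period == "diurnal", ]
    obs <- obs + tabulate(raster_value(L$landuse, d$x, d$y), 6)
  }
  avail <- tabulate(L$landuse$values[L$eligible$values], 6)
  keep <- avail > 0
  p <- suppressWarnings(
    chisq.test(obs[keep], p = avail[keep] / sum(avail[keep]))
  )$p.value
  expect_gt(p, 0.01)
})

test_that("strong corn selection enriches corn use beyond its availability", {
  L <- small_landscape(seed = 3)
  R <- small_river(seed = 3)
  corn_truth <- true_model(diurnal = c(landusecorn = 2),
                           diurnal_formula = ~ landuse)
  trk <- simulate_tracks(L, R, corn_truth, n_individuals = 10, n_days = 10,
                         seed = 4, p_fly = 0)
  d <- trk[!is.na(trk$truth_period) & trk$truth_period == "diurnal", ]
  corn_code <- which(L$classes == "corn")
  use_frac <- mean(raster_value(L$landuse, d$x, d$y) == corn_code)
  avail_frac <- mean(L$landuse$values[L$eligible$values] == corn_code)
  expect_gt(use_frac, avail_frac)
})

test_that("simulate_strata is deterministic and respects stratum closure", {
  L <- small_landscape()
  S1 <- simulate_strata(L, truth = true_model(), period = "diurnal",
                        n_clusters = 4, strata_per_cluster = 3, seed = 8)
  S2 <- simulate_strata(L, truth = true_model(), period = "diurnal",
                        n_clusters = 4, strata_per_cluster = 3, seed = 8)
  expect_identical(as.data.frame(S1), as.data.frame(S2))
  counts <- table(S1$stratum_id)
  expect_true(all(counts == 51L))
  expect_true(all(tapply(S1$is_used, S1$stratum_id, sum) == 1L))
})
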