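test_that("landscape partition covers the grid and is deterministic", {
  # degenerate single-pixel case
  p1 <- generate_landscape(1, 1, 1, seed = 3)
  expect_equal(as.vector(p1$municipality), 1L)
  expect_equal(p1$pixel_counts, 1L)

  p <- generate_landscape(60, 60, 12, n_biomes = 3, n_ecoregions = 4, seed = 1)
  expect_equal(sum(p$pixel_counts), 3600)
  expect_true(all(p$pixel_counts > 0))
  expect_equal(sort(unique(as.vector(p$municipality))), 1:12)
  # every municipality has exactly one biome and one ecoregion
  expect_length(p$biome_of, 12)
  expect_length(p$ecoregion_of, 12)
  expect_setequal(unique(p$biome_of), 1:3)
  expect_setequal(unique(p$ecoregion_of), 1:4)
  # municipality areas sum to the grid area
  expect_equal(sum(municipality_areas_km2(p)), 3600 * (0.2317)^2)

  p2 <- generate_landscape(60, 60, 12, n_biomes = 3, n_ecoregions = 4, seed = 1)
  expect_identical(p, p2)
  p3 <- generate_landscape(60, 60, 12, n_biomes = 3, n_ecoregions = 4, seed = 2)
  expect_false(identical(p$municipality, p3$municipality))

  expect_error(generate_landscape(2, 2, 5), "n_municipalities")
  expect_error(generate_landscape(4, 4, 2, n_biomes = 3), "n_biomes")
})

test_that("trajectories track prescribed linear trends", {
  part <- generate_landscape(20, 20, 1, seed = 5)  # one 400-pixel municipality
  px <- (part$cell_size / 1000)^2

  # zero slopes: every year identical to year 1
  spec0 <- make_trend_spec(part, c(woody = 0.5, herb = 0.5))
  cov0 <- generate_trajectories(part, spec0, years = 10, seed = 2)
  for (y in 2:10) expect_identical(cov0$labels[, y], cov0$labels[, 1])

  # +2 pixels/yr of woody over 10 years -> +18 pixels (+-1) realized
  spec2 <- make_trend_spec(part, c(woody = 0.5, herb = 0.5),
                           c(woody = 2 * px, herb = -2 * px))
  cov2 <- generate_trajectories(part, spec2, years = 10, seed = 2)
  wcount <- colSums(cov2$labels == match("woody", cover_classes8()))
  expect_lte(abs((wcount[10] - wcount[1]) - 18), 1)

  # OLS on realized areas recovers the prescribed slope within 5%
  ar <- true_class_areas(cov2)
  w <- ar[ar$class == "woody", ]
  b <- coef(lm(area_km2 ~ year, data = w))[2]
  expect_lt(abs(b - 2 * px) / (2 * px), 0.05)

  # per municipality x year, class areas sum to the municipality area
  tot <- tapply(ar$area_km2, ar$year, sum)
  expect_true(all(abs(tot - 400 * px) < 1e-9))

  # determinism
  cov2b <- generate_trajectories(part, spec2, years = 10, seed = 2)
  expect_identical(cov2$labels, cov2b$labels)

  # impossible (negative-area) trends are clipped with a warning
  spec_neg <- make_trend_spec(part, c(woody = 0.05, herb = 0.95),
                              c(woody = -10 * px, herb = 10 * px))
  expect_warning(generate_trajectories(part, spec_neg, years = 10, seed = 1),
                 "clipped")
})

test_that("composite simulation respects cloud and noise limits", {
  part <- generate_landscape(6, 6, 2, seed = 1)
  spec <- make_trend_spec(part, c(woody = 0.6, ag = 0.4))
  cov <- generate_trajectories(part, spec, years = 2, seed = 1)

  cube0 <- simulate_composites(cov, default_phenology(0.02, cloud_prob = 0), seed = 1)
  expect_true(all(cube0$reliability != 3))

  cube1 <- simulate_composites(cov, default_phenology(0.02, cloud_prob = 1), seed = 1)
  expect_true(all(cube1$reliability == 3))
  # feature tier must be "none" everywhere when every composite is cloudy
  fm <- feature_matrix(cube1, cube1$years[1])
  expect_true(all(fm$tier == "none"))

  # noiseless: band values equal the class curve exactly
  cube_n0 <- simulate_composites(cov, default_phenology(noise_sd = 0, cloud_prob = 0), seed = 1)
  ph <- default_phenology()
  woody_px <- which(cov$labels[, 1] == match("woody", cover_classes8()))
  expect_equal(unname(cube_n0$bands$EVI[woody_px[1], 1:23]),
               unname(ph$curves$woody[, "EVI"]))

  # a class missing from the phenology spec is named in the error
  ph_bad <- default_phenology()
  ph_bad$curves$ag <- NULL
  expect_error(simulate_composites(cov, ph_bad, seed = 1), "ag")
})

test_that("reference samples honor spacing and noise contracts", {
  scene <- demo_scene()
  s <- scene$samples
  # pairwise spacing >= 1000 m
  tr <- s$truth
  ix <- scene$samples$interpretations
  d <- as.matrix(dist(unique(ix[, c("x", "y")])))
  diag(d) <- Inf
  expect_gte(min(d), 1000)
  # two interpretations per sample, each summing to 100
  expect_equal(nrow(ix), 2 * nrow(tr))
  sums <- rowSums(ix[, grep("^pct_", names(ix))])
  expect_true(all(abs(sums - 100) < 1e-6))

  # zero noise, zero disagreement: interpreters identical and equal to truth
  cov <- scene$cover
  s0 <- simulate_reference_samples(cov, 10, interpreter_noise = 0,
                                   disagreement_rate = 0, seed = 4)
  a <- s0$interpretations[s0$interpretations$interpreter == 1, ]
  b <- s0$interpretations[s0$interpretations$interpreter == 2, ]
  pc <- grep("^pct_", names(a))
  expect_equal(a[, pc], b[, pc], ignore_attr = TRUE)
  expect_equal(unname(as.matrix(a[, pc])),
               unname(as.matrix(s0$truth[, grep("^pct_", names(s0$truth))])))

  # n_samples = 0 -> empty result
  s_empty <- simulate_reference_samples(cov, 0, seed = 1)
  expect_equal(nrow(s_empty$interpretations), 0)

  # infeasible spacing errors out
  small <- simulate_scene(rows = 4, cols = 4, n_municipalities = 1,
                          n_biomes = 1, n_ecoregions = 1,
                          n_samples = 0, years = 2, seed = 1)
  expect_error(
    simulate_reference_samples(small$cover, 50, min_spacing_m = 1000, seed = 1),
    "spacing|feasible"
  )
})

test_that("trend recovery holds for the perfect-classifier oracle", {
  # noiseless world + oracle labels: net change equals slope * 9 years
  part <- generate_landscape(30, 30, 3, seed = 8)
  px <- (part$cell_size / 1000)^2
  spec <- make_trend_spec(
    part, c(woody = 0.5, mixed_woody = 0.2, herb = 0.3),
    c(woody = 2 * px, herb = -2 * px)
  )
  cov <- generate_trajectories(part, spec, years = 10, seed = 8)
  ar <- true_class_areas(cov, scheme = "class5")
  for (m in 1:3) {
    w <- ar[ar$class == "woody" & ar$municipality == m, ]
    f <- fit_trend(w$area_km2, w$year)
    expect_lt(abs(f$net - 18 * px), px)  # slope*9 +- one pixel area
  }
})
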