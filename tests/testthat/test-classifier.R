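test_that("tiered routing sends each pixel-year to the right model", {
  res <- demo_classification()
  pair <- res$classifiers[[1]]
  expect_s3_class(pair, "lulc_classifier_pair")
  expect_equal(pair$secondary$n_features, 20)
  expect_equal(pair$initial$n_features, 120)

  # build three rows: full, annual_only, none
  set.seed(1)
  vals <- matrix(runif(23 * 4), 23, 4,
                 dimnames = list(NULL, c("EVI", "red", "NIR", "MIR")))
  f_full <- build_feature_vector(vals, rep(0, 23))
  f_ann <- build_feature_vector(vals, c(rep(3, 12), rep(0, 11)))
  f_none <- build_feature_vector(vals, rep(3, 23))
  feats <- rbind(f_full$features, f_ann$features, f_none$features)
  tier <- c(f_full$tier, f_ann$tier, f_none$tier)
  out <- classify_pixel_year(feats, tier, pair)
  expect_true(is.na(out[3]))                      # none -> No Data
  expect_false(anyNA(out[1:2]))
  expect_equal(unname(attr(out, "routed")),
               c(1L, 1L, 1L))                     # full/annual_only/none

  # noiseless woody signature classifies as woody through both tiers
  ph <- default_phenology()
  woody_vals <- ph$curves$woody
  fw_full <- build_feature_vector(woody_vals, rep(0, 23))
  fw_ann <- build_feature_vector(woody_vals, c(rep(3, 12), rep(0, 11)))
  out_w <- classify_pixel_year(rbind(fw_full$features, fw_ann$features),
                               c("full", "annual_only"), pair)
  expect_equal(out_w, c("woody", "woody"), ignore_attr = TRUE)
})

test_that("training rejects degenerate inputs and echoes configuration", {
  x <- matrix(runif(10 * 120), 10, 120,
              dimnames = list(NULL, feature_names()))
  expect_error(
    train_biome_classifier(x, rep("woody", 10), biome = 9),
    "single class"
  )
  res <- demo_classification()
  expect_equal(res$classifiers[[1]]$config$n_trees, 499)  # scaled-down run
  expect_equal(res$classifiers[[1]]$config$nodesize, 5)
  # determinism of training
  sf <- sample_features(demo_scene()$cube, res$labeled)
  biome <- demo_scene()$partition$biome_of[
    as.vector(demo_scene()$partition$municipality)[res$labeled$pixel]]
  sel <- which(sf$tier == "full" & biome == 1)
  p1 <- train_biome_classifier(sf$features[sel, ], res$labeled$class8[sel],
                               classifier_config(n_trees = 99), seed = 3, biome = 1)
  p2 <- train_biome_classifier(sf$features[sel, ], res$labeled$class8[sel],
                               classifier_config(n_trees = 99), seed = 3, biome = 1)
  expect_identical(oob_accuracy(p1)$confusion, oob_accuracy(p2)$confusion)
})

test_that("accuracy arithmetic matches hand-computed matrices", {
  # identity matrix -> all accuracies 100
  id <- accuracy_from_matrix(diag(c(5, 8, 2)))
  expect_equal(id$overall, 100)
  expect_equal(unname(id$producers), rep(100, 3))
  expect_equal(unname(id$users), rep(100, 3))

  # [[8,2],[3,7]]: overall 75%, producer's {80,70}, user's {72.7,77.8}
  m <- matrix(c(8, 3, 2, 7), 2)  # rows = reference
  acc <- accuracy_from_matrix(m)
  expect_equal(acc$overall, 75.0)
  expect_equal(unname(acc$producers), c(80.0, 70.0))
  expect_equal(round(unname(acc$users), 1), c(72.7, 77.8))
})

test_that("OOB reports group to five classes and echo filtered counts", {
  res <- demo_classification()
  for (a in res$accuracy) {
    expect_equal(dim(a$confusion), c(5, 5))
    expect_equal(a$n, res$classifiers[[a$biome]]$n_samples)
    expect_equal(a$overall, 100 * sum(diag(a$confusion)) / sum(a$confusion))
  }
})

test_that("cross-biome summary is the unweighted mean", {
  r1 <- list(overall = 90, producers = c(a = 80, b = 60),
             users = c(a = 70, b = 90), n = 100)
  r2 <- list(overall = 80, producers = c(a = 60, b = 40),
             users = c(a = 50, b = 70), n = 900)
  s <- summarize_accuracy(list(r1, r2))
  expect_equal(s$mean_overall, 85)  # NOT the sample-weighted 81
  expect_equal(s$sd_overall, sd(c(90, 80)))
  expect_equal(unname(s$mean_producers), c(70, 50))
  # identical reports: mean = common value, sd 0
  s2 <- summarize_accuracy(list(r1, r1))
  expect_equal(s2$mean_overall, 90)
  expect_equal(s2$sd_overall, 0)
})

test_that("annual maps obey the multi-year No-Data exclusion rule", {
  scene <- demo_scene()
  res <- demo_classification()
  # noiseless, cloud-free scene: no No Data anywhere, >= 98% agreement
  expect_equal(sum(res$maps$labels5 == 0), 0)
  truth <- truth_map5(scene$cover)
  expect_gte(mean(res$maps$labels5 == truth), 0.98)

  # force unreliable years on two pixels: 4 of 10 -> excluded everywhere;
  # 3 of 10 -> classified in the other years
  cube2 <- scene$cube
  cube2$reliability[1, 1:(4 * 23)] <- 3L   # pixel 1: years 1-4 fully cloudy
  cube2$reliability[2, 1:(3 * 23)] <- 3L   # pixel 2: years 1-3
  maps2 <- build_annual_maps(cube2, scene$partition, res$classifiers)
  expect_true(all(maps2$labels5[1, ] == 0L))
  expect_true(all(maps2$labels5[2, 1:3] == 0L))
  expect_true(all(maps2$labels5[2, 4:10] != 0L))

  # missing biome classifier is reported by name
  cls <- res$classifiers
  cls[2] <- list(NULL)
  expect_error(build_annual_maps(scene$cube, scene$partition, cls), "2")
})
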