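mini_stack <- function(labels5, rows, cols, years = 2001:2010, part = NULL) {
  # wrap a hand-built label matrix as an lulc_map_stack
  if (is.null(part)) part <- generate_landscape(rows, cols, 1, seed = 1)
  n_m <- length(part$pixel_counts)
  nd <- matrix(0, n_m, ncol(labels5))
  muni <- as.vector(part$municipality)
  for (y in seq_len(ncol(labels5))) {
    frac <- tapply(labels5[, y] == 0L, muni, mean)
    nd[as.integer(names(frac)), y] <- frac
  }
  structure(list(labels5 = labels5, nodata_frac = nd,
                 years = years[seq_len(ncol(labels5))], partition = part),
            class = "lulc_map_stack")
}

test_that("zonal areas use the squared cell size and conserve totals", {
  # 100 woody pixels at 231.7 m -> 5.369 km^2
  lab <- matrix(1L, 100, 10)
  st <- mini_stack(lab, 10, 10)
  at <- municipality_class_areas(st)
  woody <- at[at$class == "woody", ]
  expect_equal(woody$area_km2[1], 100 * 0.2317^2)  # = 5.368489 km^2

  # classes + No Data partition the municipality exactly
  set.seed(3)
  lab2 <- matrix(sample(0:5, 100 * 10, replace = TRUE), 100, 10)
  st2 <- mini_stack(lab2, 10, 10)
  at2 <- municipality_class_areas(st2)
  px <- (231.7 / 1000)^2
  for (y in st2$years) {
    mapped <- sum(at2$area_km2[at2$year == y])
    nodata <- sum(lab2[, y - 2000] == 0) * px
    expect_equal(mapped + nodata, 100 * px)
  }
  # an absent class has zero area
  lab3 <- matrix(1L, 100, 10)
  at3 <- municipality_class_areas(mini_stack(lab3, 10, 10))
  expect_equal(sum(at3$area_km2[at3$class == "water"]), 0)

  # grid mismatch errors
  part_other <- generate_landscape(5, 5, 1, seed = 1)
  expect_error(municipality_class_areas(st, part_other), "differ")
})

test_that("the more-than-1% No-Data rule drops exactly the right years", {
  # municipality of 100 pixels: 2004 has 2% No Data -> dropped;
  # 2005 has exactly 1% -> retained
  lab <- matrix(1L, 100, 10)
  lab[1:2, 4] <- 0L
  lab[1, 5] <- 0L
  st <- mini_stack(lab, 10, 10)
  at <- municipality_class_areas(st)
  flt <- filter_years(at)
  yrs <- unique(flt$year[flt$municipality == 1])
  expect_false(2004 %in% yrs)
  expect_true(2005 %in% yrs)
  expect_length(yrs, 9)
  expect_length(attr(flt, "unestimable"), 0)

  # no No Data anywhere: table unchanged
  at0 <- municipality_class_areas(mini_stack(matrix(1L, 100, 10), 10, 10))
  expect_equal(nrow(filter_years(at0)), nrow(at0))

  # a municipality losing 8 of 10 years becomes unestimable
  lab2 <- matrix(1L, 100, 10)
  lab2[1:5, 1:8] <- 0L
  flt2 <- filter_years(municipality_class_areas(mini_stack(lab2, 10, 10)))
  expect_equal(attr(flt2, "unestimable"), 1L)
  f2 <- fit_all_trends(flt2)
  expect_true(all(!f2$estimable))
})

test_that("trend fits match the closed-form OLS oracle", {
  # perfectly linear series: slope 2, R = 1, net = 18
  f <- fit_trend(seq(100, 118, by = 2), 2001:2010)
  expect_equal(f$slope, 2)
  expect_equal(f$r, 1)
  expect_equal(f$net, 18)
  expect_equal(f$fitted_first, 100)
  expect_equal(f$fitted_last, 118)
  expect_true(f$significant)

  # constant series: the no-change convention
  fc <- fit_trend(rep(7, 10), 2001:2010)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r, 0)
  expect_equal(fc$p, 1)
  expect_equal(fc$net, 0)
  expect_false(fc$significant)

  # noisy series against lm()/cor.test() as independent oracle
  areas <- c(10, 12, 11, 15, 14, 18, 17, 20, 22, 21)
  ft <- fit_trend(areas, 2001:2010)
  ref <- lm(areas ~ I(1:10))
  expect_equal(ft$slope, unname(coef(ref)[2]), tolerance = 1e-9)
  expect_equal(ft$intercept, unname(coef(ref)[1]), tolerance = 1e-9)
  ct <- cor.test(1:10, areas)
  expect_equal(ft$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(ft$p, ct$p.value, tolerance = 1e-9)
  expect_equal(ft$net, 9 * ft$slope)

  # gaps: dropped interior years still evaluate endpoints at 2001/2010
  yrs <- c(2001:2003, 2005:2010)
  ft2 <- fit_trend(seq_along(yrs) * 2 + 100, yrs)
  expect_equal(ft2$n, 9)

  expect_error(fit_trend(1:2, 2001:2002), "at least 3")
  expect_error(fit_trend(1:3, 2001:2005), "length")

  # net change is invariant to adding a constant to all areas
  ft3 <- fit_trend(areas + 500, 2001:2010)
  expect_equal(ft3$net, ft$net)
})

test_that("municipality labels honor the inclusive significance rule", {
  fits <- data.frame(
    municipality = 1:4, class = "woody",
    slope = c(1, -1, 0.5, 0), intercept = 0,
    r = c(0.79, -0.62, 0.5, 0), p = c(0.005, 0.05, 0.06, 1),
    n = 10, fitted2001 = 100, fitted2010 = c(1165, -612, 105, 100),
    net = c(1065, -712, 5, 0), significant = NA, estimable = TRUE
  )
  cl <- classify_municipality(fits)
  expect_equal(cl$direction, c("gain", "loss", "gain", "none"))
  expect_equal(cl$significant, c(TRUE, TRUE, FALSE, FALSE))  # p = 0.05 counts
})

test_that("slope recovery: prescribed trends are recovered from maps", {
  # noiseless scene, real classifier: slopes within 5% of prescription
  scene <- demo_scene()
  res <- demo_classification()
  tr <- run_trends(res$maps, scene$partition)
  sp <- scene$trend_spec
  w <- tr$fits[tr$fits$class == "woody", ]
  true_slope <- sp$slope_km2_yr[sp$class8 == "woody"]
  px <- (scene$partition$cell_size / 1000)^2
  for (m in w$municipality) {
    b_true <- true_slope[m]
    b_est <- w$slope[w$municipality == m]
    # one-pixel-per-year discretization floor for near-zero prescriptions
    tol <- max(0.05 * abs(b_true), 0.35 * px)
    expect_lt(abs(b_est - b_true), tol + 1e-12)
  }

  # dropping one municipality's year never changes the others' fits
  at <- municipality_class_areas(res$maps, scene$partition)
  at_drop <- at[!(at$municipality == 1 & at$year == 2004), ]
  attr(at_drop, "years") <- attr(at, "years")
  f_all <- fit_all_trends(at)
  f_drop <- fit_all_trends(at_drop)
  other <- f_all$municipality != 1
  expect_equal(f_all[other, ], f_drop[f_drop$municipality != 1, ],
               ignore_attr = TRUE)
})
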