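fake_fits <- function(nets, class = "woody", p = 0.01, base = 100) {
  n <- length(nets)
  data.frame(
    municipality = seq_len(n), class = class, slope = nets / 9, intercept = 0,
    r = sign(nets) * 0.8, p = p, n = 10,
    fitted2001 = base, fitted2010 = base + nets, net = nets,
    significant = p <= 0.05, estimable = TRUE
  )
}

test_that("unit assignment picks the greatest overlap with low-id ties", {
  expect_equal(assign_unit(c(A = 60, B = 40)), "A")
  expect_equal(assign_unit(c(B = 10)), "B")
  expect_equal(assign_unit(c(A = 50, B = 50)), "A")
  expect_equal(assign_unit(c(10, 30, 30)), 2)
  expect_error(assign_unit(c(A = 0, B = 0)), "zero overlap")
  expect_error(assign_unit(c(A = -1, B = 2)), "nonnegative")
})

test_that("rollups conserve net change across scales", {
  fits <- fake_fits(c(5, -3, 2, -1, 7, -6))
  # single municipality: rollup equals its fit
  one <- rollup(fits[1, ], 1L, scale = "country")
  expect_equal(one$net, 5)
  expect_equal(one$area_first, 100)
  expect_equal(one$area_last, 105)

  country <- rollup(fits, 1L, scale = "country")
  expect_equal(country$net, sum(fits$net))
  expect_equal(country$net, country$area_last - country$area_first)
  expect_equal(country$net, country$gain_total - country$loss_total)

  # two biomes partition the municipalities: nets sum to the country net
  biome_of <- c(1, 1, 1, 2, 2, 2)
  by_biome <- rollup(fits, biome_of, scale = "biome")
  expect_equal(sum(by_biome$net), country$net)
  eco_of <- c(1, 2, 3, 1, 2, 3)
  by_eco <- rollup(fits, eco_of, scale = "ecoregion")
  expect_equal(sum(by_eco$net), country$net, tolerance = 1e-12)

  expect_error(rollup(fits, c(1, 1, NA, 2, 2, 2)), "unit assignment")
})

test_that("gain/loss partitions count and sum correctly", {
  fits <- fake_fits(c(10, 20, -5, 0, 15))
  gl <- gain_loss_partition(fits)
  expect_equal(gl$n_gain, 3)
  expect_equal(gl$n_loss, 1)
  expect_equal(gl$gain_total, 45)
  expect_equal(gl$loss_total, 5)
  expect_equal(gl$net, 40)
  expect_equal(gl$pct_gain, 60)

  # all zero nets
  gl0 <- gain_loss_partition(fake_fits(rep(0, 4)))
  expect_equal(gl0$n_gain, 0)
  expect_equal(gl0$n_loss, 0)
  expect_equal(gl0$net, 0)

  # significant-only restriction
  fits2 <- fake_fits(c(10, -5, 3))
  fits2$p <- c(0.01, 0.2, 0.05)
  gls <- gain_loss_partition(fits2, significant_only = TRUE)
  expect_equal(gls$n_gain, 2)
  expect_equal(gls$n_loss, 0)

  # count percentages across gain/loss/none differ from 100 by <= 2
  set.seed(1)
  fits3 <- fake_fits(sample(c(-2, 0, 3), 333, replace = TRUE))
  gl3 <- gain_loss_partition(fits3)
  pct_none <- round_half_up(100 * gl3$n_none / gl3$n_total)
  expect_lte(abs(gl3$pct_gain + gl3$pct_loss + pct_none - 100), 2)
})

test_that("hotspot tables rank by |net| and report integer shares", {
  nets <- c(100, -50, 80, 60, -200, 40)
  fits <- fake_fits(nets)
  hg <- hotspots(fits, k = 3, direction = "gain")
  expect_equal(hg$net, c(100, 80, 60))
  expect_equal(attr(hg, "share"), round(100 * 240 / 280))
  hl <- hotspots(fits, k = 1, direction = "loss")
  expect_equal(hl$net, -200)
  expect_equal(attr(hl, "share"), 80)

  # single municipality, k = 1 -> share 100
  h1 <- hotspots(fake_fits(5), k = 1, direction = "gain")
  expect_equal(attr(h1, "share"), 100)

  # k beyond the table truncates with a message
  expect_message(hotspots(fits, k = 10, direction = "gain"), "truncating")

  # ties rank by municipality id
  ft <- fake_fits(c(10, 10, 10))
  ht <- hotspots(ft, k = 2, direction = "gain")
  expect_equal(ht$municipality, c(1, 2))
})

test_that("percent change uses the fitted baseline and flags zero", {
  expect_equal(percent_change(18, 100), 18)
  expect_equal(percent_change(-50, 100), -50)
  pc0 <- percent_change(5, 0)
  expect_true(is.na(pc0))
  expect_true(isTRUE(attr(pc0, "undefined")))
})

test_that("rank-sum size comparison: exact, ties, and symmetry", {
  cs <- compare_sizes(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cs$U, 0)
  expect_equal(cs$p, 0.1)  # exact enumeration of all 20 arrangements
  expect_equal(cs$method, "exact enumeration")

  # identical groups: maximal p
  expect_equal(compare_sizes(c(1, 2), c(1, 2))$p, 1)

  # symmetry: swapping the groups leaves p unchanged
  a <- c(3, 9, 12, 20); b <- c(1, 5, 7)
  expect_equal(compare_sizes(a, b)$p, compare_sizes(b, a)$p)

  # large samples agree with wilcox.test's normal approximation
  set.seed(5)
  x <- rlnorm(30, 6, 1); y <- rlnorm(25, 7, 1)
  cs2 <- compare_sizes(x, y)
  wt <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_equal(cs2$U, unname(wt$statistic))
  expect_equal(cs2$p, wt$p.value, tolerance = 1e-9)

  expect_error(compare_sizes(numeric(0), 1:3), "nonempty")
})
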