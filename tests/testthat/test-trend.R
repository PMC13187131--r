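test_that("Sen's slope matches hand-derived cases", {
  expect_equal(sen_slope(c(1, 2, 3, 4))$slope, 1)
  # pairwise slopes of (0,2,1,4): {2, 0.5, 4/3, -1, 1, 3}; median = 7/6
  expect_equal(sen_slope(c(0, 2, 1, 4))$slope, 7 / 6)
  s <- sen_slope(rep(2, 6))
  expect_equal(s$slope, 0)
  expect_true(s$ci[1] <= 0 && s$ci[2] >= 0)
  expect_error(sen_slope(c(1, 2)), "at least 3")
})

test_that("Mann-Kendall matches the closed-form evaluation", {
  got <- mann_kendall(c(1, 2, 3, 4, 5))
  expect_equal(got$S, 10)
  expect_equal(got$var_s, 5 * 4 * 15 / 18)
  expect_equal(got$Z, 9 / sqrt(got$var_s))
  expect_equal(got$p, 2 * pnorm(-got$Z))
  expect_true(got$significant)
  # constant series: zero variance, not significant, no division error
  cst <- mann_kendall(rep(1, 5))
  expect_equal(cst$S, 0)
  expect_equal(cst$var_s, 0)
  expect_false(cst$significant)
  # antisymmetry under reversal
  x <- c(3, 1, 4, 1, 5, 9, 2)
  expect_equal(mann_kendall(rev(x))$S, -mann_kendall(x)$S)
})

test_that("Sen and MK agree with brute-force oracles on all short series", {
  # exhaustive: all series of length 3..5 with values in {0,1,2}, plus a
  # seeded sample of length 6-7 series (the acceptance suite runs all)
  for (n in 3:5) {
    grids <- expand.grid(rep(list(0:2), n))
    for (r in seq_len(nrow(grids))) {
      x <- as.numeric(grids[r, ])
      expect_equal(sen_slope(x)$slope, sen_oracle(x))
      mk <- mann_kendall(x); or <- mk_oracle(x)
      expect_identical(c(mk$S, mk$var_s, mk$Z), c(or$S, or$var_s, or$Z))
    }
  }
  set.seed(99)
  for (r in 1:60) {
    x <- sample(0:2, sample(6:7, 1), replace = TRUE)
    expect_equal(sen_slope(x)$slope, sen_oracle(x))
    expect_equal(mann_kendall(x)$p, mk_oracle(x)$p)
  }
})

test_that("moving-window strength has the documented bookkeeping and signs", {
  # 39 annual values, 10-year window: exactly 30 window slopes
  x <- rnorm(39)
  expect_length(trend_strength(x)$window_slopes, 30)
  # exactly linear series: all window slopes equal, zero strength, ns
  lin <- 5 + 2 * (1:39)
  st <- trend_strength(lin)
  expect_equal(st$strength, 0)
  expect_false(st$significant)
  # quadratic growth: strictly increasing window slopes, positive strength
  # (brute-force window-slope oracle)
  quad <- (1:39)^2
  stq <- trend_strength(quad)
  oracle_ws <- vapply(1:30, function(i) sen_oracle(quad[i:(i + 9)]), numeric(1))
  expect_equal(stq$window_slopes, oracle_ws)
  expect_true(all(diff(stq$window_slopes) > 0))
  expect_gt(stq$strength, 0)
  expect_true(stq$significant)
  expect_error(trend_strength(rnorm(10), window = 10), "too short")
})

test_that("nine-state symbols follow the sign table", {
  mk <- function(slope, sig, strength, stsig)
    list(slope = slope, significant = sig, strength = strength,
         strength_significant = stsig)
  expect_equal(classify_zone_trend(mk(-2, TRUE, -0.1, TRUE)), "loss_accelerating")
  expect_equal(classify_zone_trend(mk(-2, TRUE, 0.1, TRUE)), "loss_decelerating")
  expect_equal(classify_zone_trend(mk(1, TRUE, -0.1, TRUE)), "gain_decelerating")
  expect_equal(classify_zone_trend(mk(1, TRUE, 0.1, TRUE)), "gain_accelerating")
  expect_equal(classify_zone_trend(mk(1, TRUE, -0.1, FALSE)), "gain")
  expect_equal(classify_zone_trend(mk(1, FALSE, -0.1, TRUE)), "none")
})

test_that("area aggregation conserves totals and builds the stated bins", {
  # elevation spec -1..2 by 0.1 -> 30 bins; latitude 25..31 by 0.5 -> 12
  expect_equal(n_bins(-1, 2, 0.1), 30)
  expect_equal(n_bins(25, 31, 0.5), 12)
  set.seed(4)
  maps <- matrix(sample(1:6, 3 * 40, replace = TRUE), 3, 40)
  elev <- runif(40, -1, 2)
  a_tot <- aggregate_areas(maps, 2000:2002)
  a_bin <- aggregate_areas(maps, 2000:2002,
                           zones = list(values = elev, from = -1, to = 2, by = 0.1))
  for (yr in 2000:2002) {
    expect_equal(sum(a_bin$area_km2[a_bin$year == yr]),
                 sum(a_tot$area_km2[a_tot$year == yr]))
    expect_equal(sum(a_tot$area_km2[a_tot$year == yr]), 40 * 900 / 1e6)
  }
  # single zone raster equals the total series
  a_zone <- aggregate_areas(maps, 2000:2002, zones = rep(7L, 40))
  expect_equal(a_zone$area_km2, a_tot$area_km2)
  expect_error(aggregate_areas(maps, 2000:2002, zones = rep(1L, 10)), "match")
})
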