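test_that("sample allocation is proportional with a floor", {
  expect_equal(unname(allocate_sample(c(0.5, 0.5), 300, min_per_class = 0)),
               c(150, 150))
  # rare class raised to the minimum of 150
  got <- allocate_sample(c(common = 0.99, rare = 0.01), 2000)
  expect_equal(unname(got["rare"]), 150)
  expect_equal(unname(got["common"]), 1980)
  expect_gte(sum(got), 2000)
  expect_error(allocate_sample(c(0.6, 0.6), 100), "sum to 1")
  expect_error(allocate_sample(c(0.5, 0.5), 1), "smaller")
})

test_that("post-stratified estimators match direct formula evaluation", {
  # worked 2x2 example: W = (0.8, 0.2), counts [[90,10],[20,80]]
  cm <- rbind(c(90, 10), c(20, 80))
  est <- post_stratified_estimates(cm, weights = c(0.8, 0.2), total_area = 1000)
  # direct evaluation: p = W_i n_ij / n_i.
  p <- rbind(0.8 * c(0.9, 0.1), 0.2 * c(0.2, 0.8))
  expect_equal(est$p, p, ignore_attr = TRUE)
  expect_equal(est$overall_accuracy, 0.88)
  expect_equal(unname(est$area_proportions), c(0.76, 0.24))
  expect_equal(unname(est$users_accuracy), c(0.9, 0.8))
  expect_equal(unname(est$producers_accuracy), c(0.72 / 0.76, 0.16 / 0.24))
  se1 <- sqrt(0.8^2 * 0.9 * 0.1 / 99 + 0.2^2 * 0.2 * 0.8 / 99)
  expect_equal(unname(est$se_proportions[1]), se1)
  expect_equal(unname(est$areas), 1000 * c(0.76, 0.24))
  # diagonal counts: perfect accuracies, areas equal mapped areas
  d <- post_stratified_estimates(diag(c(50, 50, 50)), weights = c(0.5, 0.3, 0.2),
                                 total_area = 10)
  expect_equal(d$overall_accuracy, 1)
  expect_equal(unname(d$users_accuracy), rep(1, 3))
  expect_equal(unname(d$areas), 10 * c(0.5, 0.3, 0.2))
  # reference proportions always normalize
  set.seed(8)
  for (k in 1:20) {
    cm2 <- matrix(rpois(9, 20) + 1, 3, 3)
    w <- prop.table(runif(3) + 0.1)
    e <- post_stratified_estimates(cm2, w)
    expect_equal(sum(e$area_proportions), 1)
    expect_true(all(c(e$overall_accuracy, e$users_accuracy,
                      e$producers_accuracy) >= 0))
    expect_true(all(c(e$overall_accuracy, e$users_accuracy,
                      e$producers_accuracy) <= 1))
  }
  expect_error(post_stratified_estimates(rbind(c(1, 0), c(5, 5)), c(0.5, 0.5)),
               "single sample")
})

test_that("post-stratified areas are design-unbiased under simulation", {
  # known truth shares and mis-labeling; 200 seeded draws of a stratified
  # sample; the mean estimated area must sit within 2 SE of truth
  set.seed(123)
  W <- c(0.7, 0.2, 0.1)                 # mapped shares (strata weights)
  conf <- rbind(c(0.95, 0.04, 0.01),    # P(ref | map) per stratum
                c(0.05, 0.90, 0.05),
                c(0.02, 0.08, 0.90))
  truth_share <- as.numeric(t(conf) %*% W)
  n_i <- c(300, 200, 150)
  est <- replicate(200, {
    cm <- t(vapply(1:3, function(i) rmultinom(1, n_i[i], conf[i, ])[, 1],
                   integer(3)))
    post_stratified_estimates(cm, W)$area_proportions
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(m - truth_share) < 2 * se + 1e-3))
})

test_that("change-accuracy design yields 120 samples per phase, 840 total", {
  phases <- sprintf("%d-%d", seq(1986, 2016, 5), seq(1990, 2020, 5))
  pa <- expand.grid(phase = phases,
                    stratum = c("permanent_gain", "permanent_loss",
                                "fluctuation", "others"),
                    stringsAsFactors = FALSE)
  pa$area <- runif(nrow(pa), 1, 5)
  d <- change_accuracy_design(pa)
  expect_equal(sum(d$n), 840)
  expect_equal(as.numeric(tapply(d$n, d$phase, sum)), rep(120, 7))
  # weights normalize within phase
  expect_equal(as.numeric(tapply(d$weight, d$phase, sum)), rep(1, 7))
  # an empty stratum in one phase is skipped with a warning
  pa2 <- pa
  pa2$area[pa2$phase == phases[3] & pa2$stratum == "permanent_gain"] <- 0
  expect_warning(d2 <- change_accuracy_design(pa2), "skipped")
  expect_equal(sum(d2$n), 820)
})

driver_fixture <- function(p_truth = c(extreme_weather = 0.36,
                                       human_activity = 0.04,
                                       chronic_stressor = 0.60),
                           n_cell = 20, seed = 1) {
  phases <- sprintf("%d", seq(1986, 2016, 5))
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_along(phases), function(i) {
      data.frame(phase = phases[i], stratum = "permanent_loss",
                 driver = sample(names(p_truth), n_cell, replace = TRUE,
                                 prob = p_truth),
                 weight = runif(1, 1, 3))
    }))
  })
}

test_that("driver proportions and bootstrap intervals behave", {
  s <- driver_fixture()
  got <- driver_proportions(s, n_boot = 200, seed = 5)
  cum <- got$cumulative
  expect_equal(sum(cum$proportion), 1)
  expect_true(all(cum$lo <= cum$proportion + 1e-12 & cum$proportion <= cum$hi + 1e-12))
  # reproducible under the seed
  again <- driver_proportions(s, n_boot = 200, seed = 5)
  expect_identical(got$cumulative, again$cumulative)
  # all-one-driver cell set: proportion 1, CI width 0
  s2 <- s; s2$driver <- "chronic_stressor"
  g2 <- driver_proportions(s2, n_boot = 50, seed = 1)
  chronic <- g2$cumulative[g2$cumulative$driver == "chronic_stressor", ]
  expect_equal(chronic$proportion, 1)
  expect_equal(chronic$hi - chronic$lo, 0)
  # equal weights, half/half drivers
  s3 <- s[s$phase %in% c("1986", "1991"), ]
  s3$weight <- 1
  s3$driver <- rep(c("extreme_weather", "chronic_stressor"), length.out = nrow(s3))
  g3 <- driver_proportions(s3, n_boot = 50, seed = 1)
  expect_equal(g3$cumulative$proportion[g3$cumulative$driver == "extreme_weather"], 0.5)
  # an empty phase x stratum cell is a named error
  s4 <- rbind(s, transform(s[s$phase == "1986", ], stratum = "permanent_gain"))
  expect_error(driver_proportions(s4), "empty cell")
})

test_that("driver trends recover direction and antisymmetry", {
  phases <- seq_len(7)
  up <- data.frame(stratum = "permanent_loss", phase = phases,
                   driver = "extreme_weather",
                   proportion = seq(0.1, 0.7, length.out = 7), weight = 1)
  down <- transform(up, driver = "chronic_stressor",
                    proportion = rev(seq(0.1, 0.7, length.out = 7)))
  tr <- driver_trend(rbind(up, down))
  ew <- tr[tr$driver == "extreme_weather", ]
  cs <- tr[tr$driver == "chronic_stressor", ]
  expect_gt(ew$strength, 0)
  expect_true(ew$significant)
  expect_equal(ew$strength, -cs$strength)
  cst <- data.frame(stratum = "x", phase = phases, driver = "human_activity",
                    proportion = 0.5, weight = 1)
  tc <- driver_trend(cst)
  expect_equal(tc$strength, 0)
  expect_false(tc$significant)
})
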