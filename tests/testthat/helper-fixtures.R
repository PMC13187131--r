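# shared fixtures, built lazily and cached for the whole test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# 32-day observation grid over the full analysis span
obs_times <- function(from = 1984, to = 2024.25) seq(from, to, by = 32 / 365.25)

# a small classifier trained on simulator segments (shared across files)
demo_classifier <- function() {
  fixture("classifier", function() {
    tr <- training_segments(n_per_class = 25, seed = 42)
    list(clf = train_segment_classifier(tr$features, tr$labels, seed = 43),
         train = tr)
  })
}

# water-level model with a multi-year anomaly term; elevation and ramp chosen
# so the inundated fraction stays strictly inside (0, 1): the reflectance is
# then exactly linear in the water level
ablation_tide <- function() {
  tide_model(0, data.frame(amplitude = c(0.06, 0.10),
                           period = c(0.5175251, 1168.8),
                           phase = c(0, 0.4)))
}

# full demo pipeline run, computed once
demo_run <- function() {
  fixture("demo_run", function() {
    cfg <- read_run_config(demo_config_path())
    run_pipeline(cfg)
  })
}

# independent brute-force oracles for Sen / Mann-Kendall ------------------

sen_oracle <- function(x) {
  n <- length(x)
  sl <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) sl <- c(sl, (x[j] - x[i]) / (j - i))
  stats::median(sl)
}

mk_oracle <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  v <- n * (n - 1) * (2 * n + 5)
  for (u in unique(x)) {
    t <- sum(x == u)
    v <- v - t * (t - 1) * (2 * t + 5)
  }
  v <- v / 18
  z <- if (v == 0) 0 else if (S > 0) (S - 1) / sqrt(v) else if (S < 0) (S + 1) / sqrt(v) else 0
  list(S = S, var_s = v, Z = z, p = 2 * pnorm(-abs(z)))
}
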