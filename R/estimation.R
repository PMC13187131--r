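#' Allocate a stratified reference sample
#'
#' Proportional allocation by mapped area share, rounded, with every class
#' below the minimum raised to the minimum (other classes unchanged).
#'
#' @param area_proportions Named numeric vector summing to 1.
#' @param total_n Target total sample size.
#' @param min_per_class Minimum per class (default 150).
#' @return Named integer vector of sample counts; the sum may exceed
#'   `total_n` when the minimum rule binds.
#' @export
#' @examples
#' allocate_sample(c(a = 0.99, b = 0.01), 2000)
allocate_sample <- function(area_proportions, total_n, min_per_class = 150) {
  if (abs(sum(area_proportions) - 1) > 1e-8) stopf("proportions must sum to 1")
  k <- length(area_proportions)
  if (total_n < k) stopf("total_n smaller than the number of classes")
  n <- round(area_proportions * total_n)
  pmax(n, min_per_class)
}

#' Post-stratified accuracy and error-adjusted area estimation
#'
#' The good-practice estimators for a stratified design with the map classes
#' as strata: cell proportions `p_ij = W_i * n_ij / n_i.`, overall accuracy
#' `sum_j p_jj`, user's accuracy `p_ii / p_i.`, producer's accuracy
#' `p_jj / p_.j`, error-adjusted areas `A_total * p_.j`, and the standard
#' error of the reference class proportion
#' `SE(p_.j) = sqrt(sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1))`,
#' with 95% confidence intervals `+/- 1.96 SE`.
#'
#' @param counts Square confusion matrix, rows = map stratum, columns =
#'   reference class (same class order).
#' @param weights Strata weights `W_i` (mapped area proportions, sum 1).
#' @param total_area Total mapped area (any unit; areas returned in it).
#' @return List: `overall_accuracy`, `users_accuracy`, `producers_accuracy`,
#'   `area_proportions` (`p_.j`), `se_proportions`, `areas`, `areas_ci`
#'   (half-widths), `p` (cell proportion matrix).
#' @export
post_stratified_estimates <- function(counts, weights, total_area = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), length(weights) == nrow(counts))
  if (abs(sum(weights) - 1) > 1e-8) stopf("strata weights must sum to 1")
  ni <- rowSums(counts)
  if (any(ni == 0 & weights > 0)) stopf("a stratum with positive weight has no samples")
  if (any(ni == 1 & weights > 0)) stopf("a stratum with a single sample has undefined SE")
  share <- counts / ifelse(ni == 0, 1, ni)
  p <- weights * share
  oa <- sum(diag(p))
  ua <- diag(p) / rowSums(p)
  pa <- diag(p) / colSums(p)
  pj <- colSums(p)
  se <- sqrt(colSums(weights^2 * share * (1 - share) / pmax(ni - 1, 1)))
  list(overall_accuracy = oa, users_accuracy = ua, producers_accuracy = pa,
       area_proportions = pj, se_proportions = se,
       areas = total_area * pj, areas_ci = 1.96 * total_area * se, p = p)
}

#' Stratified change-accuracy sampling design
#'
#' Per five-year phase, 20 samples in each of the three change strata
#' (permanent gain, permanent loss, fluctuation) and 60 in "others": 120 per
#' phase, 840 over seven phases. Strata weights come from the mapped change
#' area of each phase. Phases with an empty stratum are skipped with a
#' warning.
#'
#' @param phase_areas Data frame with columns `phase`, `stratum`,
#'   `area` (mapped area of the stratum in that phase).
#' @param n_change Samples per change stratum per phase.
#' @param n_other Samples for the "others" stratum per phase.
#' @param seed Seed recorded in the design (pixel draws are the caller's).
#' @return Data frame `phase`, `stratum`, `n`, `weight` (area share within
#'   phase); class `stratified_design`.
#' @export
change_accuracy_design <- function(phase_areas, n_change = 20, n_other = 60,
                                   seed = 1L) {
  need <- c("phase", "stratum", "area")
  if (!all(need %in% names(phase_areas))) stopf("phase_areas needs columns %s",
                                                paste(need, collapse = ", "))
  out <- NULL
  for (ph in unique(phase_areas$phase)) {
    sub <- phase_areas[phase_areas$phase == ph, ]
    for (st in unique(sub$stratum)) {
      area <- sub$area[sub$stratum == st]
      if (area <= 0) {
        warnf("phase %s stratum %s has no mapped pixels; cell skipped", ph, st)
        next
      }
      n <- if (st == "others") n_other else n_change
      out <- rbind(out, data.frame(phase = ph, stratum = st, n = n,
                                   weight = area / sum(sub$area)))
    }
  }
  structure(out, seed = seed, class = c("stratified_design", "data.frame"))
}

#' Driver proportions with bootstrap confidence intervals
#'
#' Per phase x stratum cell, the proportion of samples attributed to each
#' driver; cumulative proportions weight the per-phase proportions by the
#' mapped change area of the cell. Uncertainty comes from resampling within
#' each cell (with replacement) `n_boot` times and taking percentile 95%
#' intervals.
#'
#' @param samples Data frame with columns `phase`, `stratum`, `driver`, and
#'   `weight` (mapped change area of the phase x stratum cell).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Seed; results are reproducible under it.
#' @param conf Confidence level.
#' @param require_complete Error on an empty phase x stratum cell (the
#'   designed contract). Set `FALSE` when phases legitimately lack a
#'   stratum (e.g. no mapped change of that type in a period, already
#'   warned about at design time); such cells are then dropped per stratum.
#' @return List with `cumulative` (data frame `stratum`, `driver`,
#'   `proportion`, `lo`, `hi`) and `per_phase` (data frame `stratum`,
#'   `phase`, `driver`, `proportion`, `weight`).
#' @export
driver_proportions <- function(samples, n_boot = 1000, seed = 1L, conf = 0.95,
                               require_complete = TRUE) {
  drivers <- c("extreme_weather", "human_activity", "chronic_stressor")
  if (!all(samples$driver %in% drivers)) stopf("unknown driver label")
  strata <- unique(samples$stratum)
  all_phases <- unique(samples$phase)
  if (require_complete) {
    for (st in strata) for (ph in all_phases) {
      if (!any(samples$stratum == st & samples$phase == ph))
        stopf("empty cell: stratum %s, phase %s", st, ph)
    }
  }
  alpha <- (1 - conf) / 2
  per_phase <- NULL; cumulative <- NULL
  withr::with_seed(seed, {
    for (st in strata) {
      phases <- unique(samples$phase[samples$stratum == st])
      cells <- lapply(phases, function(ph)
        samples[samples$stratum == st & samples$phase == ph, ])
      w <- vapply(cells, function(cl) cl$weight[1], numeric(1))
      props <- vapply(cells, function(cl)
        vapply(drivers, function(d) mean(cl$driver == d), numeric(1)),
        numeric(length(drivers)))   # drivers x phases
      cum <- as.numeric(props %*% w) / sum(w)
      # bootstrap: resample each cell's drivers with replacement
      boot <- matrix(0, n_boot, length(drivers))
      ncell <- vapply(cells, nrow, integer(1))
      for (b in seq_len(n_boot)) {
        bp <- vapply(seq_along(cells), function(i) {
          d <- cells[[i]]$driver[sample.int(ncell[i], ncell[i], replace = TRUE)]
          vapply(drivers, function(dd) mean(d == dd), numeric(1))
        }, numeric(length(drivers)))
        boot[b, ] <- as.numeric(bp %*% w) / sum(w)
      }
      ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
      cumulative <- rbind(cumulative, data.frame(
        stratum = st, driver = drivers, proportion = cum,
        lo = ci[1, ], hi = ci[2, ]))
      per_phase <- rbind(per_phase, data.frame(
        stratum = st,
        phase = rep(phases, each = length(drivers)),
        driver = rep(drivers, length(phases)),
        proportion = as.numeric(props),
        weight = rep(w, each = length(drivers))))
    }
  })
  rownames(cumulative) <- rownames(per_phase) <- NULL
  list(cumulative = cumulative, per_phase = per_phase)
}

#' Trend strength of per-phase driver proportions
#'
#' Sen's slope and Mann-Kendall test on each driver's per-phase proportion
#' series (per stratum), indicating whether the driver's share of change is
#' growing or shrinking across phases.
#'
#' @param per_phase The `per_phase` data frame from [driver_proportions()].
#' @param alpha Significance level.
#' @return Data frame `stratum`, `driver`, `strength` (proportion per
#'   phase), `p`, `significant`.
#' @export
driver_trend <- function(per_phase, alpha = 0.05) {
  out <- NULL
  for (st in unique(per_phase$stratum)) {
    for (d in unique(per_phase$driver)) {
      sub <- per_phase[per_phase$stratum == st & per_phase$driver == d, ]
      sub <- sub[order(sub$phase), ]
      if (nrow(sub) < 3) stopf("need at least 3 phases")
      s <- sen_slope(sub$proportion)
      mk <- mann_kendall(sub$proportion, alpha = alpha)
      out <- rbind(out, data.frame(stratum = st, driver = d,
                                   strength = s$slope, p = mk$p,
                                   significant = mk$significant))
    }
  }
  rownames(out) <- NULL
  out
}
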