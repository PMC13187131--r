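# connected-component labeling on an integer map, 4-connectivity,
# components = maximal sets of equal-valued adjacent cells
label_components <- function(map) {
  nr <- nrow(map); nc <- ncol(map)
  comp <- matrix(0L, nr, nc)
  nextid <- 0L
  stack <- integer(nr * nc)
  for (start in seq_len(nr * nc)) {
    if (comp[start] != 0L) next
    nextid <- nextid + 1L
    val <- map[start]
    top <- 1L; stack[1] <- start
    comp[start] <- nextid
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% nr + 1L; cl <- (cur - 1L) %/% nr + 1L
      if (r > 1L) { nb <- cur - 1L
        if (comp[nb] == 0L && map[nb] == val) { comp[nb] <- nextid; top <- top + 1L; stack[top] <- nb } }
      if (r < nr) { nb <- cur + 1L
        if (comp[nb] == 0L && map[nb] == val) { comp[nb] <- nextid; top <- top + 1L; stack[top] <- nb } }
      if (cl > 1L) { nb <- cur - nr
        if (comp[nb] == 0L && map[nb] == val) { comp[nb] <- nextid; top <- top + 1L; stack[top] <- nb } }
      if (cl < nc) { nb <- cur + nr
        if (comp[nb] == 0L && map[nb] == val) { comp[nb] <- nextid; top <- top + 1L; stack[top] <- nb } }
    }
  }
  comp
}

# 8-neighbourhood offsets of linear indices for a matrix, with bounds checks
neighbors8 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L; cl <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- cl + dc
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- c(out, (cc[keep] - 1L) * nr + rr[keep])
  }
  unique(out)
}

#' Minimum-mapping-unit filter
#'
#' Connected components (4-connectivity) smaller than `min_pixels` are
#' reassigned to the modal label of the component's 8-neighbourhood border
#' pixels (ties broken by the lowest class code), removing salt-and-pepper
#' noise; components of `min_pixels` or more are untouched. Reassignment is
#' repeated until no undersized component remains, so the filter is
#' idempotent.
#'
#' @param map Integer label matrix.
#' @param min_pixels Minimum mapping unit (pixels), default four 30 m pixels.
#' @return The filtered map, with attribute `n_reassigned`.
#' @export
apply_mmu <- function(map, min_pixels = 4) {
  nr <- nrow(map); nc <- ncol(map)
  total <- 0L
  for (pass in seq_len(10L)) {
    comp <- label_components(map)
    sizes <- tabulate(comp)
    small <- which(sizes > 0 & sizes < min_pixels)
    if (!length(small)) break
    newmap <- map
    for (cid in small) {
      cells <- which(comp == cid)
      border <- setdiff(unlist(lapply(cells, neighbors8, nr = nr, nc = nc)), cells)
      if (!length(border)) next   # component fills the whole map
      labs <- map[border]
      tab <- table(labs)
      winners <- as.integer(names(tab)[tab == max(tab)])
      newmap[cells] <- min(winners)
      total <- total + length(cells)
    }
    if (identical(newmap, map)) break
    map <- newmap
  }
  attr(map, "n_reassigned") <- total
  map
}

#' Default size-to-distance table for the contextual water filter
#'
#' A non-decreasing step function: small wetland patches must lie close to
#' open water to be kept; larger patches, being less likely to be
#' misclassified, are allowed a larger distance.
#'
#' @return Data frame with `max_size` (pixels, last row `Inf`) and
#'   `max_distance` (pixels).
#' @export
water_distance_table <- function() {
  data.frame(max_size = c(10, 100, Inf), max_distance = c(10, 30, 100))
}

#' Contextual water-distance filter
#'
#' Tidal-wetland objects (connected components over the wetland classes,
#' dieback included) whose minimum Euclidean distance to the nearest open
#' water pixel exceeds the size-dependent threshold are reassigned to
#' "other". If the map holds no open water at all, every wetland object
#' beyond the maximum threshold is removed and a warning is raised.
#'
#' @param map Integer label matrix.
#' @param table Size-to-distance step function, see [water_distance_table()].
#' @return Filtered map with attribute `n_removed` (objects removed).
#' @export
contextual_water_filter <- function(map, table = water_distance_table()) {
  stopifnot(!is.unsorted(table$max_size), !is.unsorted(table$max_distance))
  codes <- wetland_classes()
  wet_codes <- c(wetland_extent_classes(), codes[["mangrove_dieback"]])
  wet <- matrix(map %in% wet_codes, nrow(map), ncol(map))
  water <- which(map == codes[["open_water"]])
  nr <- nrow(map)
  if (!length(water)) warnf("map contains no open water; distant wetland objects removed")
  comp <- label_components(ifelse(wet, 1L, 0L))
  comp[!wet] <- 0L
  ids <- setdiff(unique(as.vector(comp)), 0L)
  wr <- (water - 1L) %% nr + 1L; wc <- (water - 1L) %/% nr + 1L
  n_removed <- 0L
  for (cid in ids) {
    cells <- which(comp == cid)
    size <- length(cells)
    thr <- table$max_distance[match(TRUE, size <= table$max_size)]
    if (!length(water)) { d <- Inf } else {
      cr <- (cells - 1L) %% nr + 1L; cc <- (cells - 1L) %/% nr + 1L
      d <- sqrt(min(outer(cr, wr, "-")^2 + outer(cc, wc, "-")^2))
    }
    if (d > thr) {
      map[cells] <- codes[["other"]]
      n_removed <- n_removed + 1L
    }
  }
  attr(map, "n_removed") <- n_removed
  map
}

#' Post-process an annual map
#'
#' Applies [apply_mmu()] then [contextual_water_filter()].
#'
#' @param map Integer label matrix.
#' @param min_pixels Minimum mapping unit.
#' @param table Water-distance table.
#' @return Cleaned map.
#' @export
postprocess_map <- function(map, min_pixels = 4, table = water_distance_table()) {
  contextual_water_filter(apply_mmu(map, min_pixels), table)
}
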