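# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: naive loops and closed forms only.

# per-segment Euclidean sum, plain loop
oracle_polyline_length <- function(g) {
  tot <- 0
  for (i in seq_len(nrow(g) - 1L)) {
    tot <- tot + sqrt(sum((g[i + 1L, ] - g[i, ])^2))
  }
  tot
}

# membership of points in an axis-aligned rectangle c(x0, y0, x1, y1)
in_rect <- function(pts, r) {
  pts[, 1L] >= r[1L] & pts[, 1L] <= r[3L] & pts[, 2L] >= r[2L] & pts[, 2L] <= r[4L]
}

# dense point-sampling split oracle for a straight 2-vertex road against
# axis-aligned rectangle districts: sample n points along the line, classify
# each by rectangle, convert occupancy fractions to lengths
oracle_split_lengths <- function(p1, p2, rects, n = 1e5) {
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(p1[1L] + t * (p2[1L] - p1[1L]), p1[2L] + t * (p2[2L] - p1[2L]))
  L <- sqrt(sum((p2 - p1)^2))
  vapply(rects, function(r) mean(in_rect(pts, r)) * L, numeric(1))
}

# naive nearest-distance from points to a set of footprints (points or
# polygon vertices treated via edge-by-edge point-segment distance)
oracle_nearest_distance <- function(pts, footprints) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 == 0) return(sqrt(sum((p - a)^2)))
    t <- max(0, min(1, sum((p - a) * ab) / L2))
    sqrt(sum((p - (a + t * ab))^2))
  }
  apply(pts, 1L, function(p) {
    best <- Inf
    for (fp in footprints) {
      if (nrow(fp) == 1L) {
        best <- min(best, sqrt(sum((p - fp[1L, ])^2)))
      } else {
        n <- nrow(fp)
        inside <- FALSE
        j <- n
        for (i in seq_len(n)) {
          if ((fp[i, 2L] > p[2L]) != (fp[j, 2L] > p[2L]) &&
              p[1L] < (fp[j, 1L] - fp[i, 1L]) * (p[2L] - fp[i, 2L]) /
                (fp[j, 2L] - fp[i, 2L]) + fp[i, 1L]) inside <- !inside
          j <- i
        }
        if (inside) return(0)
        j <- n
        for (i in seq_len(n)) {
          best <- min(best, pt_seg(p, fp[j, ], fp[i, ]))
          j <- i
        }
      }
    }
    best
  })
}

# triple-loop district totals oracle: for each emission record and each
# portion of its road, accumulate R * EO into (district, pollutant, vehicle)
oracle_district_totals <- function(portions, emissions, hours) {
  acc <- new.env()
  for (i in seq_len(nrow(emissions))) {
    e <- emissions[i, ]
    if (!(e$hour %in% hours)) next
    for (j in seq_len(nrow(portions))) {
      if (portions$cts_id[j] != e$cts_id) next
      key <- paste(portions$district[j], e$pollutant, e$vehicle_type, sep = "|")
      old <- if (is.null(acc[[key]])) 0 else acc[[key]]
      acc[[key]] <- old + portions$ratio_R[j] * e$emission_g_per_km
    }
  }
  out <- sort(vapply(ls(acc), function(k) acc[[k]], numeric(1)))
  out
}

# closed-form simple OLS via normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}
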