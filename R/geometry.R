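# Planar geometry primitives for the road/district/building layers.
#
# All coordinates are metres in a single projected planar frame (the frame
# itself -- e.g. a local transverse Mercator grid -- is declared by the data,
# not interpreted here). Polylines and polygon rings are two-column numeric
# matrices of (x, y) vertices; a district or building polygon may be a list of
# rings (multipolygon / holes under the even-odd rule).

#' Construct a road segment
#'
#' A road is a polyline with a road identifier (\code{cts_id}) shared by all
#' records of the same physical street, a per-record identifier, and the
#' "geoid length" \code{dG} carried over from the source network dataset.
#' \code{dG} is stored, never recomputed: the allocation ratio divides the
#' planar clipped length by this source value.
#'
#' @param cts_id road identifier (coerced to character).
#' @param geometry two-column numeric matrix of vertex coordinates in metres,
#'   at least two vertices.
#' @param geoid_length source length dG in metres, must be positive.
#' @param record_id source record identifier; distinct records may share a
#'   \code{cts_id}. Defaults to \code{cts_id}.
#' @return an object of class \code{"road_segment"}.
#' @export
road_segment <- function(cts_id, geometry, geoid_length, record_id = cts_id) {
  geometry <- validate_polyline(geometry)
  if (!is.numeric(geoid_length) || length(geoid_length) != 1L ||
      !is.finite(geoid_length) || geoid_length <= 0) {
    stop("geoid_length must be a single positive finite number")
  }
  structure(
    list(cts_id = as.character(cts_id), record_id = as.character(record_id),
         geometry = geometry, geoid_length = as.numeric(geoid_length)),
    class = "road_segment"
  )
}

#' Construct a district
#'
#' @param name district name.
#' @param geometry a polygon ring (two-column matrix) or list of rings.
#' @param population resident count (non-negative).
#' @param population_pct percentage of the city total population; used by
#'   \code{\link{classify_group}} to split districts into residential
#'   (group 1) and non-residential (group 2).
#' @param group optional residential group (1 or 2); if \code{NULL} it is
#'   derived from \code{population_pct} when that is available.
#' @return an object of class \code{"district"}.
#' @export
district <- function(name, geometry, population, population_pct = NA_real_,
                     group = NULL) {
  geometry <- validate_polygon(geometry)
  if (!is.numeric(population) || population < 0) {
    stop("population must be non-negative")
  }
  if (is.null(group)) {
    group <- if (is.na(population_pct)) NA_integer_ else
      classify_group(population_pct)
  }
  if (!is.na(group) && !group %in% c(1L, 2L)) stop("group must be 1 or 2")
  structure(
    list(name = as.character(name), geometry = geometry,
         population = as.numeric(population),
         population_pct = as.numeric(population_pct),
         group = as.integer(group)),
    class = "district"
  )
}

#' Construct a building/podium footprint
#'
#' @param id footprint identifier.
#' @param geometry either a single (x, y) point (length-2 vector or 1-row
#'   matrix) or a polygon ring.
#' @param height structure height in metres; carried through but unused by
#'   any computation here.
#' @return an object of class \code{"building"}.
#' @export
building <- function(id, geometry, height = NA_real_) {
  if (is.numeric(geometry) && is.null(dim(geometry)) && length(geometry) == 2L) {
    geometry <- matrix(geometry, nrow = 1L)
  }
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 2L || !all(is.finite(geometry))) {
    stop("building geometry must be finite (x, y) coordinates")
  }
  if (nrow(geometry) > 1L) geometry <- validate_polygon(geometry)[[1L]]
  structure(list(id = as.character(id), geometry = geometry,
                 height = as.numeric(height)),
            class = "building")
}

validate_polyline <- function(geometry) {
  geometry <- as.matrix(geometry)
  storage.mode(geometry) <- "double"
  if (ncol(geometry) != 2L) stop("polyline must have two coordinate columns")
  if (nrow(geometry) < 2L) stop("degenerate geometry: polyline needs >= 2 vertices")
  if (!all(is.finite(geometry))) stop("polyline coordinates must be finite")
  dimnames(geometry) <- NULL
  geometry
}

# A polygon is stored as a list of rings. Rings are open (first vertex not
# repeated); a closing duplicate vertex in the input is dropped. Each ring is
# checked for finiteness, non-zero area and (O(n^2), fine at district sizes)
# absence of proper self-intersections.
validate_polygon <- function(geometry) {
  if (is.matrix(geometry) || is.data.frame(geometry)) geometry <- list(as.matrix(geometry))
  if (!is.list(geometry) || length(geometry) == 0L) {
    stop("polygon must be a ring matrix or non-empty list of rings")
  }
  lapply(geometry, function(ring) {
    ring <- as.matrix(ring)
    storage.mode(ring) <- "double"
    if (ncol(ring) != 2L || !all(is.finite(ring))) {
      stop("polygon ring must be finite (x, y) coordinates")
    }
    n <- nrow(ring)
    if (n >= 4L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    if (nrow(ring) < 3L) stop("polygon ring needs >= 3 distinct vertices")
    if (ring_self_intersects(ring)) stop("invalid polygon: ring self-intersects")
    if (abs(ring_area(ring)) <= 0) stop("polygon ring has zero area")
    dimnames(ring) <- NULL
    ring
  })
}

# signed shoelace area of one ring
ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace)
#'
#' Absolute area of a polygon given as a ring or list of rings, in square
#' metres. For a list of rings the absolute ring areas are summed (adequate
#' for disjoint multipolygon parts, which is how district geometries are
#' represented here).
#' @param geometry ring matrix or list of ring matrices.
#' @return area in m^2.
#' @export
polygon_area <- function(geometry) {
  rings <- validate_polygon(geometry)
  sum(vapply(rings, function(r) abs(ring_area(r)), numeric(1)))
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n > 400L) return(FALSE)  # generator-sized rings only; skip O(n^2) blowup
  a <- ring
  b <- ring[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex with edge i
    for (j in js) {
      if (segments_properly_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_properly_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

#' Planar length of a polyline
#'
#' Sum of straight-segment Euclidean lengths, in metres. This is the "actual
#' length" used throughout the allocation: source geoid lengths are read from
#' the data, clipped lengths are always recomputed this way.
#'
#' @param geometry two-column vertex matrix (>= 2 vertices) or a
#'   \code{road_segment}.
#' @return length in metres.
#' @examples
#' polyline_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polyline_length <- function(geometry) {
  if (inherits(geometry, "road_segment")) geometry <- geometry$geometry
  geometry <- validate_polyline(geometry)
  d <- diff(geometry)
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

# Even-odd point-in-polygon over all rings; pts is an n x 2 matrix.
# Boundary points are classified arbitrarily (callers only ever test interior
# midpoints or probe points in general position).
points_in_polygon <- function(pts, rings) {
  pts <- as.matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1L]; py <- pts[, 2L]
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1L]; yi <- ring[i, 2L]
      xj <- ring[j, 1L]; yj <- ring[j, 2L]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

# Clip one polyline to one polygon (even-odd). Returns the kept pieces and
# their total length. Pieces are maximal runs of kept subsegments.
clip_polyline_to_polygon <- function(geometry, rings) {
  geometry <- validate_polyline(geometry)
  nseg <- nrow(geometry) - 1L
  pieces <- list()
  total <- 0
  current <- NULL
  for (s in seq_len(nseg)) {
    p1 <- geometry[s, ]; p2 <- geometry[s + 1L, ]
    d <- p2 - p1
    seglen <- sqrt(sum(d^2))
    if (seglen == 0) next
    ts <- c(0, 1)
    for (ring in rings) {
      n <- nrow(ring)
      j <- n
      for (i in seq_len(n)) {
        e1 <- ring[j, ]; e2 <- ring[i, ]
        j <- i
        e <- e2 - e1
        den <- cross2(d, e)
        if (den == 0) next
        # solve p1 + t d = e1 + u e for (t, u)
        t <- cross2(e1 - p1, e) / den
        u <- cross2(e1 - p1, d) / den
        if (t > 0 && t < 1 && u >= 0 && u <= 1) ts <- c(ts, t)
      }
    }
    ts <- sort(unique(ts))
    tm <- (ts[-1L] + ts[-length(ts)]) / 2
    mids <- cbind(p1[1L] + tm * d[1L], p1[2L] + tm * d[2L])
    keep <- points_in_polygon(mids, rings)
    for (k in seq_along(keep)) {
      if (!keep[k]) { current <- NULL; next }
      a <- p1 + ts[k] * d
      b <- p1 + ts[k + 1L] * d
      total <- total + (ts[k + 1L] - ts[k]) * seglen
      if (!is.null(current) &&
          isTRUE(all.equal(unname(pieces[[current]][nrow(pieces[[current]]), ]),
                           unname(a), tolerance = 1e-12))) {
        pieces[[current]] <- rbind(pieces[[current]], b)
      } else {
        pieces[[length(pieces) + 1L]] <- rbind(a, b)
        current <- length(pieces)
      }
    }
    # a piece may continue into the next polyline segment only if the last
    # subsegment of this one was kept
    if (length(keep) == 0L || !keep[length(keep)]) current <- NULL
  }
  list(pieces = pieces, length = total)
}

#' Split a road across districts (intersect)
#'
#' Clips a road polyline against every district polygon and returns one
#' portion per district the road enters. Each portion carries its planar
#' clipped length \code{actual_length_dA} and the allocation ratio
#' \code{ratio_R = dA / dG}. Parts of the road outside every district are
#' dropped (their length is simply not represented). Clips shorter than
#' \code{tol} metres -- degenerate border tangencies -- are discarded.
#'
#' @param road a \code{road_segment}.
#' @param districts list of \code{district} objects, assumed pairwise
#'   non-overlapping.
#' @param tol minimum clipped length retained, metres.
#' @return a portion data frame (possibly 0-row) with columns
#'   \code{cts_id}, \code{district}, \code{actual_length_dA},
#'   \code{geoid_length_dG}, \code{ratio_R}, and a list column
#'   \code{geometry} of clipped pieces.
#' @export
split_road_by_districts <- function(road, districts, tol = 1e-9) {
  stopifnot(inherits(road, "road_segment"))
  rows <- list()
  for (d in districts) {
    cl <- clip_polyline_to_polygon(road$geometry, d$geometry)
    if (cl$length > tol) {
      rows[[length(rows) + 1L]] <- data.frame(
        cts_id = road$cts_id, district = d$name,
        actual_length_dA = cl$length,
        geoid_length_dG = road$geoid_length,
        ratio_R = cl$length / road$geoid_length,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$geometry <- I(list(cl$pieces))
    }
  }
  if (length(rows) == 0L) return(empty_portions())
  do.call(rbind, rows)
}

empty_portions <- function() {
  out <- data.frame(cts_id = character(), district = character(),
                    actual_length_dA = numeric(), geoid_length_dG = numeric(),
                    ratio_R = numeric(), stringsAsFactors = FALSE)
  out$geometry <- I(list())
  out
}

#' Split many roads across districts
#'
#' Convenience wrapper applying \code{\link{split_road_by_districts}} to each
#' road and binding the portion rows.
#' @param roads list of \code{road_segment}s.
#' @param districts list of \code{district}s.
#' @param tol minimum clipped length retained, metres.
#' @export
split_roads <- function(roads, districts, tol = 1e-9) {
  parts <- lapply(roads, split_road_by_districts, districts = districts, tol = tol)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  if (length(parts) == 0L) return(empty_portions())
  do.call(rbind, parts)
}

#' Dissolve duplicate road records (dissolve)
#'
#' Source networks may hold several records for one physical road. Portions
#' are grouped by (road id, district): lengths are summed and clipped pieces
#' concatenated. A road that after dissolving lies in exactly one district is
#' given a single record with ratio set exactly to 1 (whole-road allocation);
#' roads crossing several districts keep the summed-length ratio
#' \code{sum(dA) / dG} per district.
#'
#' @param portions a portion data frame from \code{\link{split_roads}}.
#' @return a dissolved portion data frame, one row per (road, district).
#' @export
dissolve_records <- function(portions) {
  if (nrow(portions) == 0L) return(portions)
  key <- paste(portions$cts_id, portions$district, sep = "\r")
  idx <- split(seq_len(nrow(portions)), key)
  rows <- lapply(idx, function(i) {
    r <- portions[i[1L], , drop = FALSE]
    r$actual_length_dA <- sum(portions$actual_length_dA[i])
    r$ratio_R <- r$actual_length_dA / r$geoid_length_dG
    r$geometry <- I(list(do.call(c, portions$geometry[i])))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # single-district roads collapse to one record with R = 1
  ndist <- table(out$cts_id)
  single <- out$cts_id %in% names(ndist)[ndist == 1L]
  out$ratio_R[single] <- 1
  out[order(out$cts_id, out$district), , drop = FALSE]
}

#' Human-activity region: buffered union of building footprints
#'
#' The region is the Minkowski dilation of the union of all footprints by
#' \code{distance}: exactly the set of points within \code{distance} metres of
#' some footprint. It is represented implicitly (footprints + radius), so
#' membership and road-selection tests are exact rather than polygonal
#' approximations; \code{\link{region_area}} rasterises it on demand.
#'
#' @param buildings list of \code{building} objects (possibly empty).
#' @param distance buffer distance in metres, > 0. Default 200 m, the radius
#'   taken to represent potential human activity around a facility.
#' @return an object of class \code{"activity_region"}.
#' @export
activity_region <- function(buildings, distance = 200) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0) {
    stop("buffer distance must be a single positive number")
  }
  fps <- lapply(buildings, function(b) {
    if (inherits(b, "building")) b$geometry else as.matrix(b)
  })
  bb <- if (length(fps)) t(vapply(fps, function(m)
    c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]), max(m[, 2L])), numeric(4)))
  else matrix(numeric(0), 0L, 4L)
  structure(list(footprints = fps, distance = distance, bbox = bb),
            class = "activity_region")
}

# min distance from each point in pts (n x 2) to one footprint
dist_points_to_footprint <- function(pts, fp) {
  if (nrow(fp) == 1L) {
    return(sqrt((pts[, 1L] - fp[1L, 1L])^2 + (pts[, 2L] - fp[1L, 2L])^2))
  }
  n <- nrow(fp)
  dmin <- rep(Inf, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    dmin <- pmin(dmin, dist_points_to_segment(pts, fp[j, ], fp[i, ]))
    j <- i
  }
  dmin[points_in_polygon(pts, list(fp))] <- 0
  dmin
}

dist_points_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  }
  t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pts[, 1L] - (a[1L] + t * ab[1L]))^2 + (pts[, 2L] - (a[2L] + t * ab[2L]))^2)
}

#' Distance from points to the nearest footprint of a region
#'
#' @param region an \code{activity_region}.
#' @param pts n x 2 coordinate matrix.
#' @return numeric vector of distances (Inf if the region is empty).
#' @export
region_distance <- function(region, pts) {
  pts <- as.matrix(pts)
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_along(region$footprints)) {
    bb <- region$bbox[k, ]
    # cheap lower bound on the distance via the footprint bounding box
    dx <- pmax(bb[1L] - pts[, 1L], 0, pts[, 1L] - bb[3L])
    dy <- pmax(bb[2L] - pts[, 2L], 0, pts[, 2L] - bb[4L])
    lower <- sqrt(dx^2 + dy^2)
    cand <- which(lower < dmin)
    if (length(cand) == 0L) next
    dmin[cand] <- pmin(dmin[cand],
                       dist_points_to_footprint(pts[cand, , drop = FALSE],
                                                region$footprints[[k]]))
  }
  dmin
}

#' Region membership test
#'
#' TRUE for points lying inside the buffered union, i.e. within the buffer
#' distance of some footprint.
#' @param region an \code{activity_region}.
#' @param pts n x 2 coordinate matrix.
#' @export
region_contains <- function(region, pts) {
  region_distance(region, pts) <= region$distance
}

#' Area of an activity region
#'
#' Deterministic raster estimate: cell centres on a regular grid over the
#' region's bounding box are classified by \code{\link{region_contains}} and
#' counted. The default cell side (buffer distance / 128) keeps the
#' discretisation error well below 1\% for disc-scale regions.
#'
#' @param region an \code{activity_region}.
#' @param cell grid cell side in metres.
#' @return area in m^2 (0 for an empty region).
#' @export
region_area <- function(region, cell = region$distance / 128) {
  if (length(region$footprints) == 0L) return(0)
  xr <- range(region$bbox[, c(1L, 3L)]) + c(-1, 1) * region$distance
  yr <- range(region$bbox[, c(2L, 4L)]) + c(-1, 1) * region$distance
  xs <- seq(xr[1L] + cell / 2, xr[2L], by = cell)
  ys <- seq(yr[1L] + cell / 2, yr[2L], by = cell)
  count <- 0
  for (y in ys) {
    pts <- cbind(xs, y)
    count <- count + sum(region_contains(region, pts))
  }
  count * cell^2
}

# min distance between a polyline and one footprint
dist_polyline_to_footprint <- function(geometry, fp) {
  if (nrow(fp) == 1L) {
    return(min(dist_points_to_polyline(fp, geometry)))
  }
  if (any(points_in_polygon(geometry, list(fp)))) return(0)
  nseg <- nrow(geometry) - 1L
  n <- nrow(fp)
  dmin <- Inf
  for (s in seq_len(nseg)) {
    p1 <- geometry[s, ]; p2 <- geometry[s + 1L, ]
    j <- n
    for (i in seq_len(n)) {
      if (segments_properly_intersect(p1, p2, fp[j, ], fp[i, ])) return(0)
      dmin <- min(dmin,
                  dist_points_to_segment(rbind(p1, p2), fp[j, ], fp[i, ]),
                  dist_points_to_segment(fp[c(j, i), , drop = FALSE], p1, p2))
      j <- i
    }
  }
  dmin
}

dist_points_to_polyline <- function(pts, geometry) {
  pts <- as.matrix(pts)
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(geometry) - 1L)) {
    dmin <- pmin(dmin, dist_points_to_segment(pts, geometry[s, ], geometry[s + 1L, ]))
  }
  dmin
}

#' Select roads intersecting an activity region
#'
#' A road is retained iff its polyline comes within the buffer distance of
#' some footprint (equivalently, iff it intersects the buffered union).
#'
#' @param roads list of \code{road_segment}s.
#' @param region an \code{activity_region}.
#' @return the retained subset (same order as input).
#' @export
select_roads_in_region <- function(roads, region) {
  keep <- vapply(roads, function(rd) {
    g <- rd$geometry
    bb <- c(min(g[, 1L]), min(g[, 2L]), max(g[, 1L]), max(g[, 2L]))
    for (k in seq_along(region$footprints)) {
      fb <- region$bbox[k, ]
      dx <- max(0, fb[1L] - bb[3L], bb[1L] - fb[3L])
      dy <- max(0, fb[2L] - bb[4L], bb[2L] - fb[4L])
      if (sqrt(dx^2 + dy^2) > region$distance) next
      if (dist_polyline_to_footprint(g, region$footprints[[k]]) <= region$distance) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  roads[keep]
}

#' Filter roads by source geoid length
#'
#' Retains roads whose stored geoid length \code{dG} is strictly greater than
#' \code{min_length} ("greater than 1 m" in the source network's QA rule, so
#' a road of exactly 1 m is dropped).
#'
#' @param roads list of \code{road_segment}s.
#' @param min_length threshold in metres (default 1).
#' @export
filter_geoid_length <- function(roads, min_length = 1) {
  if (min_length < 0) stop("min_length must be >= 0")
  roads[vapply(roads, function(r) r$geoid_length > min_length, logical(1))]
}
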