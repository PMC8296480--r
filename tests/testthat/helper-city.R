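# Small fixtures built in code.

# nx x ny grid of axis-aligned square districts with side `cell` metres
make_grid_districts <- function(nx, ny, cell = 1000, pcts = NULL) {
  out <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      x0 <- (ix - 1L) * cell; y0 <- (iy - 1L) * cell
      ring <- rbind(c(x0, y0), c(x0 + cell, y0),
                    c(x0 + cell, y0 + cell), c(x0, y0 + cell))
      pct <- if (is.null(pcts)) 100 / (nx * ny) else pcts[k]
      out[[k]] <- district(sprintf("G%02d", k), ring,
                           population = 1e5 * pct, population_pct = pct)
    }
  }
  out
}

rects_of <- function(districts) {
  lapply(districts, function(d) {
    r <- d$geometry[[1L]]
    c(min(r[, 1L]), min(r[, 2L]), max(r[, 1L]), max(r[, 2L]))
  })
}

# a tiny emission table
make_emissions <- function(cts_ids, hours = 0:23, vehicles = "private car",
                           pollutants = "NOx", EO = 1) {
  g <- expand.grid(cts_id = cts_ids, hour = hours, vehicle_type = vehicles,
                   pollutant = pollutants, stringsAsFactors = FALSE)
  g$emission_g_per_km <- rep_len(EO, nrow(g))
  g
}

# small default city for pipeline tests (kept light; deeper statistical
# checks scale up where they need to)
small_city <- function(seed = 11L, ...) {
  generate_city(city_config(n_roads = 80L, n_buildings = 150L,
                            rng_seed = seed, ...))
}
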