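# shared fixtures, all built in code

water_props <- function(loading = "ON_SHELF", ...) {
  physical_properties(T_eq = 273.15, loading = loading, ...)
}

# hand-built history with an arbitrary axial field, constant in time
const_history <- function(T_fun, n_nodes = 32, t_end = 100, dt = 10,
                          height_mm = 10) {
  time_s <- seq(0, t_end, by = dt)
  z <- (seq_len(n_nodes) - 0.5) * height_mm / n_nodes
  Tz <- vapply(z, T_fun, numeric(1))
  vial_thermal_history(time_s, matrix(Tz, n_nodes, length(time_s)), z)
}

on_visf263 <- function() {
  freezing_protocol("ON_SHELF", "VISF", Tn_target = 263, T_shelf_pre = 258)
}

off_visf263 <- function() {
  freezing_protocol("OFF_SHELF", "VISF", Tn_target = 263, T_shelf_pre = 248)
}

# brute-force per-line extremum scan with the lowest-height tie rule
brute_extrema <- function(T_K, heights) {
  imax <- which(T_K == max(T_K))[1]
  imin <- which(T_K == min(T_K))[1]
  c(Tmin = T_K[imin], Hmin = heights[imin], Tmax = T_K[imax], Hmax = heights[imax])
}

# place axis-aligned rectangles of given areas in one mask
rect_mask <- function(areas, nr = 120, nc = 400) {
  m <- matrix(FALSE, nr, nc)
  col0 <- 3
  for (a in areas) {
    h <- max(2, floor(sqrt(a)))
    w <- ceiling(a / h)
    excess <- h * w - a
    m[3:(2 + h), col0:(col0 + w - 1)] <- TRUE
    if (excess > 0) m[3:(2 + excess), col0 + w - 1] <- FALSE
    col0 <- col0 + w + 3
  }
  m
}
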