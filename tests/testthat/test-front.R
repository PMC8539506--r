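linear_trace <- function(v_mm_min = 0.4, n = 100, dt = 10, z0 = 0.5,
                         noise = 0) {
  t <- seq(0, by = dt, length.out = n)
  data.frame(frame = seq_len(n), time_s = t,
             Tmin_K = 260, Hmin_mm = 0.625, Tmax_K = 272,
             Hmax_mm = pmin(z0 + v_mm_min * t / 60 + noise * rnorm(n), 10))
}

test_that("track_front recovers a known constant velocity", {
  tr <- linear_trace(0.4)
  ft <- track_front(tr, t_nucleation = 0)
  v <- ft$velocity_mm_per_min
  expect_lt(abs(mean(v) - 0.4) / 0.4, 0.02)
})

test_that("a constant Hmax is a zero-velocity plateau", {
  tr <- linear_trace(0)
  ft <- track_front(tr, t_nucleation = 0)
  expect_true(all(abs(ft$velocity_mm_per_min) < 1e-9))
  expect_true(all(ft$phase == "PLATEAU"))
})

test_that("a square-root front is labelled as decelerating", {
  t <- seq(0, 1500, by = 10)
  tr <- data.frame(frame = seq_along(t), time_s = t, Tmin_K = 260,
                   Hmin_mm = 0.625, Tmax_K = 272,
                   Hmax_mm = 10 * sqrt(t / 1500))
  ft <- track_front(tr, t_nucleation = 0)
  expect_lt(attr(ft, "slope2_mm_min"), attr(ft, "slope1_mm_min"))
  expect_true("ASCENT_LINEAR" %in% ft$phase[1:10])
  expect_true(all(ft$phase[ft$time_s > attr(ft, "breakpoint_s")] !=
                    "ASCENT_LINEAR"))
})

test_that("track_front refuses suspended-vial traces", {
  expect_error(track_front(linear_trace(), 0, loading = "OFF_SHELF"),
               "OFF_SHELF")
})

test_that("frozen-layer gradient arithmetic and invariances", {
  expect_equal(frozen_layer_gradient(271, 263, 5), 1.6)
  expect_equal(frozen_layer_gradient(270, 270, 4), 0)
  expect_warning(g0 <- frozen_layer_gradient(271, 263, 0), "Hmax")
  expect_true(is.na(g0))
  # invariant under a uniform temperature offset
  expect_equal(frozen_layer_gradient(271 + 7, 263 + 7, 5),
               frozen_layer_gradient(271, 263, 5))
  # sign preserved for inverted profiles
  expect_lt(frozen_layer_gradient(263, 271, 5), 0)
})

test_that("traced gradient matches the simulator's nodal gradient", {
  h <- simulate_vial_freezing(on_visf263(), seed = 13, early_stop = FALSE)
  st <- render_thermal_stack(h, camera_config(noise_sd = 0), seed = 1)
  res <- process_stack(st)
  vt <- res$vial
  tn <- h$t_nucleation_s
  front <- approx(h$time_s, h$front_position_mm, xout = vt$time_s, rule = 2)$y
  sel <- which(front > 3 * 1.25 & front < 6 * 1.25 & vt$time_s > tn + 150)
  bottom_px <- res$profiles[res$profiles$pixel == 1 & res$profiles$line_idx == 1, ]
  rel_err <- vapply(sel[seq(1, length(sel), length.out = 8)], function(k) {
    g_trace <- frozen_layer_gradient(vt$Tmax_K[k], bottom_px$T_K[k],
                                     vt$Hmax_mm[k])
    i <- which.min(abs(h$time_s - vt$time_s[k]))
    nodes <- h$node_heights_mm
    Tz <- h$T_axial[, i]
    jf <- which.max(Tz)
    g_true <- (Tz[jf] - approx(nodes, Tz, xout = 0.625)$y) / nodes[jf]
    abs(g_trace / g_true - 1)
  }, numeric(1))
  # the 1.25 mm pixel grid quantises Hmax (the denominator), so per-frame
  # errors are dominated by instrument resolution, not by the estimator
  expect_lt(median(rel_err), 0.15)
  expect_lt(max(rel_err), 0.30)
})

test_that("freezing interval handles linear cooling, trivial and missing cases", {
  t <- seq(0, 2400, by = 10)
  Tmax <- pmax(272 - 0.5 * t / 60, 250) # jump to 272 then 0.5 K/min cooling
  tr <- data.frame(frame = seq_along(t), time_s = t, Tmin_K = Tmax - 5,
                   Hmin_mm = 0.625, Tmax_K = Tmax, Hmax_mm = 5)
  got <- freezing_interval(tr, t_nucleation = 0)
  expect_lt(abs(got - (272 - 263) / 0.5 * 60), 11)
  # already below
  tr2 <- tr; tr2$Tmax_K <- 260
  expect_equal(freezing_interval(tr2, 0), 0)
  # never reaches
  tr3 <- tr; tr3$Tmax_K <- 270
  expect_warning(got3 <- freezing_interval(tr3, 0), "never")
  expect_true(is.na(got3))
})

test_that("classification is symmetric under profile negation", {
  t <- rep(seq(0, 2000, by = 10), each = 8)
  px <- rep(1:8, times = length(unique(t)))
  base <- 270 - 0.4 * (px - 1) # bottom clearly warmest
  prof <- data.frame(frame = rep(seq_along(unique(t)), each = 8),
                     time_s = t, pixel = px,
                     height_mm = (px - 0.5) * 1.25, T_K = base)
  lab1 <- classify_inversion(prof, t_nucleation = 1000, after_window_s = 600,
                             T_flat_K = 0)
  prof2 <- prof
  prof2$T_K <- 540 - prof$T_K # negate around the mean
  lab2 <- classify_inversion(prof2, t_nucleation = 1000, after_window_s = 600,
                             T_flat_K = 0)
  expect_equal(lab1$before_nucleation, "HIGHEST")
  expect_equal(lab2$before_nucleation, "LOWEST")
  expect_equal(lab1$after_nucleation, "HIGHEST")
  expect_equal(lab2$after_nucleation, "LOWEST")
})

test_that("too-short classification windows are an error", {
  prof <- data.frame(frame = rep(1:3, each = 8), time_s = rep(c(0, 10, 20), each = 8),
                     pixel = rep(1:8, 3), height_mm = rep((1:8 - 0.5) * 1.25, 3),
                     T_K = 270)
  expect_error(classify_inversion(prof, t_nucleation = 20), "window")
})
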