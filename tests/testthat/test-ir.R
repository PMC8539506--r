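make_stack <- function(frames, n_vials = 1, npx = 8,
                       cam = camera_config(noise_sd = 0)) {
  nlines <- cam$lines_per_vial
  defs <- do.call(rbind, lapply(seq_len(n_vials), function(v) {
    data.frame(vial_id = v, line_idx = seq_len(nlines),
               col = (v - 1) * nlines + seq_len(nlines),
               row_bottom = npx + 1, row_top = 2)
  }))
  structure(list(frames = frames, time_s = (seq_along(frames) - 1) * 10,
                 camera = cam, line_defs = defs, n_vials = n_vials),
            class = "thermal_stack")
}

test_that("extraction maps pixels bottom-up at pixel-centre heights", {
  fr <- matrix(0, 10, 6)
  fr[2:9, ] <- matrix(rep(277:270, 6), 8, 6) # image top -> bottom
  st <- make_stack(list(fr))
  prof <- extract_acquisition_lines(st, emissivity = NA)
  p1 <- prof[prof$line_idx == 1, ]
  expect_equal(p1$T_K, 270:277)
  expect_equal(p1$height_mm, seq(0.625, 9.375, by = 1.25))
})

test_that("out-of-bounds acquisition lines are reported per line", {
  st <- make_stack(list(matrix(270, 10, 6)))
  defs <- st$line_defs
  defs$col[2] <- 99
  expect_error(extract_acquisition_lines(st, defs), "vial 1 line 2")
})

test_that("a stack of N frames and V vials yields 6*V*N line profiles", {
  frames <- replicate(4, matrix(270, 10, 18), simplify = FALSE)
  st <- make_stack(frames, n_vials = 3)
  prof <- extract_acquisition_lines(st, emissivity = NA)
  lt <- line_extrema(prof)
  expect_equal(nrow(lt), 6 * 3 * 4)
})

test_that("emissivity correction inverts the graybody forward model", {
  expect_equal(correct_emissivity(263, 1, 500), 263)
  for (eps in c(0.05, 0.5, 0.91, 1)) {
    expect_equal(correct_emissivity(280, eps, 280), 280, tolerance = 1e-12)
  }
  Tt <- seq(200, 320, by = 5)
  for (eps in c(0.05, 0.3, 0.91, 1)) {
    Ta <- apparent_temperature(Tt, eps, 293)
    expect_equal(correct_emissivity(Ta, eps, 293), Tt, tolerance = 1e-9)
  }
  expect_error(correct_emissivity(263, 0, 293), "emissivity")
  # monotone in T_apparent
  Ta <- apparent_temperature(Tt, 0.91, 293)
  expect_true(all(diff(correct_emissivity(Ta, 0.91, 293)) > 0))
})

test_that("line extrema follow a plain scan with lowest-height ties", {
  T8 <- c(270, 271, 272, 271, 270, 269, 268, 267)
  hgt <- seq(0.625, 9.375, by = 1.25)
  prof <- data.frame(frame = 1, time_s = 0, vial_id = 1, line_idx = 1,
                     pixel = 1:8, height_mm = hgt, T_K = T8)
  lt <- line_extrema(prof)
  expect_equal(c(lt$Tmax_K, lt$Hmax_mm, lt$Tmin_K, lt$Hmin_mm),
               c(272, 3.125, 267, 9.375))
  expect_equal(unname(brute_extrema(T8, hgt)),
               c(lt$Tmin_K, lt$Hmin_mm, lt$Tmax_K, lt$Hmax_mm))
  # degenerate: uniform profile takes the lowest pixel centre for both
  prof$T_K <- 270
  lt <- line_extrema(prof)
  expect_equal(c(lt$Hmax_mm, lt$Hmin_mm, lt$Tmax_K, lt$Tmin_K),
               c(0.625, 0.625, 270, 270))
  # single pixel
  lt1 <- line_extrema(prof[1, ])
  expect_equal(c(lt1$Tmax_K, lt1$Hmax_mm, lt1$Tmin_K, lt1$Hmin_mm),
               c(270, 0.625, 270, 0.625))
})

test_that("vial averaging is extremum-then-average, not the reverse", {
  # six identical lines: vial trace equals any line trace
  lt <- data.frame(time_s = 0, frame = 1, vial_id = 1, line_idx = 1:6,
                   Tmin_K = 265, Hmin_mm = 0.625, Tmax_K = 271,
                   Hmax_mm = 3.125)
  vt <- vial_trace(lt)
  expect_equal(c(vt$Tmax_K, vt$Hmax_mm), c(271, 3.125))
  # alternating Hmax 2.5 / 3.75 -> mean 3.125
  lt$Hmax_mm <- rep(c(2.5, 3.75), 3)
  expect_equal(vial_trace(lt)$Hmax_mm, 3.125)
  # crafted two-line fixture where the two orders disagree
  hgt <- seq(0.625, 9.375, by = 1.25)
  T1 <- c(270, 275, 270, 270, 270, 270, 270, 270) # peak at pixel 2
  T2 <- c(270, 270, 270, 270, 270, 270, 276, 270) # peak at pixel 7
  prof <- rbind(
    data.frame(frame = 1, time_s = 0, vial_id = 1, line_idx = 1, pixel = 1:8,
               height_mm = hgt, T_K = T1),
    data.frame(frame = 1, time_s = 0, vial_id = 1, line_idx = 2, pixel = 1:8,
               height_mm = hgt, T_K = T2))
  vt <- vial_trace(line_extrema(prof))
  # extremum-then-average: (h2 + h7)/2
  expect_equal(vt$Hmax_mm, (hgt[2] + hgt[7]) / 2)
  # average-profile-then-extremum lands on a single pixel instead
  avg_prof <- (T1 + T2) / 2
  h_wrong <- hgt[which.max(avg_prof)]
  expect_false(isTRUE(all.equal(vt$Hmax_mm, h_wrong)))
})

test_that("batch averaging is an equal-weight mean with an envelope", {
  vt <- data.frame(frame = c(1, 1), time_s = 0, vial_id = 1:2,
                   Tmin_K = c(264, 266), Hmin_mm = c(0.625, 0.625),
                   Tmax_K = c(270, 272), Hmax_mm = c(2.5, 3.75))
  bt <- batch_trace(vt)
  expect_equal(bt$Tmax_K, 271)
  expect_equal(c(bt$Hmax_lo, bt$Hmax_hi), c(2.5, 3.75))
  # single vial: identity
  bt1 <- batch_trace(vt[1, ])
  expect_equal(bt1$Tmax_K, 270)
  # permutation invariance
  bt2 <- batch_trace(vt[2:1, ])
  expect_equal(bt$Tmax_K, bt2$Tmax_K)
  expect_equal(bt$Hmax_mm, bt2$Hmax_mm)
})

test_that("nucleation detection flags jumps and ignores humps", {
  t <- seq(0, 1000, by = 10)
  cooling <- 280 - 0.01 * t
  expect_true(is.na(detect_nucleation(t, cooling, jump_K = 2)))
  jumped <- cooling
  jumped[t >= 400] <- jumped[t >= 400] + 5
  expect_lt(abs(detect_nucleation(t, jumped, jump_K = 2) - 400), 11)
  humped <- cooling + 3.5 * exp(-pmax(t - 400, 0) / 60) * (t >= 400)
  expect_true(is.na(detect_nucleation(t, humped, jump_K = 4.5)))
  expect_error(detect_nucleation(t, cooling, window_s = 5), "frame interval")
})

test_that("noiseless render + extraction recovers the nodal field exactly", {
  hs <- simulate_batch(on_visf263(), n_vials = 2, seed = 41)
  cam <- camera_config(noise_sd = 0)
  st <- render_thermal_stack(hs, cam, seed = 1)
  prof <- extract_acquisition_lines(st)
  centres <- (1:8 - 0.5) * cam$mm_per_pixel
  for (v in 1:2) {
    h <- hs[[v]]
    for (k in c(1, 50, length(st$time_s)))  {
      Tcol <- vapply(seq_len(nrow(h$T_axial)), function(i) {
        approx(h$time_s, h$T_axial[i, ], xout = st$time_s[k], rule = 2)$y
      }, numeric(1))
      want <- approx(h$node_heights_mm, Tcol, xout = centres, rule = 2)$y
      got <- prof[prof$vial_id == v & prof$line_idx == 2 & prof$frame == k, ]
      expect_equal(got$T_K, want, tolerance = 1e-9)
    }
  }
})
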