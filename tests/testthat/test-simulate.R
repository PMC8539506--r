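test_that("ON-shelf vial keeps its axial minimum at the bottom node", {
  h <- simulate_vial_freezing(on_visf263(), seed = 2)
  i0 <- which(h$time_s >= h$t_nucleation_s)[1]
  # VISF leaves the evaporatively cooled top the coldest point for a few
  # frames right at nucleation; once that transient relaxes the bottom is
  # the axial minimum in every frame
  i30 <- which(h$time_s >= h$t_nucleation_s + 30)[1]
  post <- h$T_axial[, i30:ncol(h$T_axial)]
  expect_true(all(apply(post, 2, which.min) == 1))
  # and before nucleation too (conduction to the shelf)
  pre <- h$T_axial[, max(1, i0 - 20):(i0 - 1)]
  expect_true(all(apply(pre, 2, which.min) == 1))
})

test_that("OFF-shelf maximum sits in the middle half of the nodes", {
  h <- simulate_vial_freezing(off_visf263(), seed = 3, early_stop = FALSE)
  i0 <- which(h$time_s >= h$t_nucleation_s)[1]
  isol <- which(h$frozen_fraction >= 0.9)[1]
  am <- apply(h$T_axial[, (i0 + 2):isol], 2, which.max)
  n <- nrow(h$T_axial)
  expect_gt(mean(am >= n / 4 & am <= 3 * n / 4), 0.8)
})

test_that("nucleation conserves the adiabatic energy balance per node", {
  h <- simulate_vial_freezing(on_visf263(), seed = 4)
  pr <- h$props
  f <- h$f_nucleation
  Tpre <- h$T_pre_nucleation
  ok <- is.finite(f) & f > 1e-3 & f < 0.59
  expect_gt(sum(ok), 10)
  sensible <- pr$cp_liquid * (pr$T_eq - Tpre[ok])
  latent <- f[ok] * (pr$latent_heat_eq -
                       (pr$cp_liquid - pr$cp_ice) * (pr$T_eq - Tpre[ok]))
  expect_equal(sensible, latent, tolerance = 1e-6)
})

test_that("front position and frozen fraction are monotone", {
  h <- simulate_vial_freezing(on_visf263(), seed = 5)
  expect_true(all(diff(h$frozen_fraction) >= -1e-9))
  expect_true(all(h$frozen_fraction >= 0 & h$frozen_fraction <= 1))
  i0 <- which(h$time_s >= h$t_nucleation_s)[1]
  expect_true(all(diff(h$front_position_mm[i0:length(h$time_s)]) >= -1e-9))
})

test_that("the enthalpy march approaches the one-sided Stefan solution", {
  p <- freezing_protocol("ON_SHELF", "SPONTANEOUS", Tn_target = 273.1,
                         T_shelf_hold = 258, T_shelf_pre = 258,
                         T_final = 258, sim_duration_s = 600)
  pr <- water_props(h_bottom = 1e6, h_side = 1e-6, h_top = 1e-6,
                    env_offset_K = 0)
  h <- simulate_vial_freezing(p, pr, n_nodes = 64, seed = 1, dt_out_s = 2,
                              early_stop = FALSE, spont_rate = 1e6,
                              T_init = 273.149)
  tn <- h$t_nucleation_s
  # independent oracle: transcendental Stefan condition
  St <- pr$cp_ice * 1000 * (273.15 - 258) / (pr$latent_heat_eq * 1000)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  lam <- uniroot(function(l) l * exp(l^2) * erf(l) - St / sqrt(pi),
                 c(1e-6, 2))$root
  alpha <- pr$k_ice / (pr$density * 1000 * pr$cp_ice * 1000)
  sel <- which(h$time_s - tn >= 100 & h$time_s - tn <= 450)
  z_oracle <- 2 * lam * sqrt(alpha * (h$time_s[sel] - tn)) * 1000
  expect_lt(max(abs(h$front_position_mm[sel] / z_oracle - 1)), 0.05)
})

test_that("VISF nucleation spans <= 100 s and spontaneous spans are wider", {
  hs_visf <- simulate_batch(on_visf263(), n_vials = 10, seed = 21)
  span_visf <- diff(range(vapply(hs_visf, function(h) h$t_nucleation_s,
                                 numeric(1))))
  expect_lte(span_visf, 100)
  p_sp <- freezing_protocol("ON_SHELF", "SPONTANEOUS", Tn_target = 263,
                            T_shelf_pre = 258)
  hs_sp <- simulate_batch(p_sp, n_vials = 10, seed = 21)
  span_sp <- diff(range(vapply(hs_sp, function(h) h$t_nucleation_s,
                               numeric(1))))
  expect_gt(span_sp, span_visf)
})

test_that("a colder shelf shortens the ON-shelf freezing interval", {
  interval <- vapply(c(258, 253, 248), function(Th) {
    p <- freezing_protocol("ON_SHELF", "VISF", Tn_target = 263,
                           T_shelf_hold = Th, T_shelf_pre = Th)
    h <- simulate_vial_freezing(p, seed = 6, early_stop = FALSE)
    tn <- h$t_nucleation_s
    colmax <- apply(h$T_axial, 2, max)
    h$time_s[which(colmax <= 263 & h$time_s > tn)[1]] - tn
  }, numeric(1))
  expect_true(all(diff(interval) < 0))
})

test_that("simulate_vial_freezing validates its inputs", {
  expect_error(simulate_vial_freezing(on_visf263(),
                                      physical_properties(loading = "OFF_SHELF")),
               "loading")
  expect_error(simulate_vial_freezing(on_visf263(), n_nodes = 3), "n_nodes")
})
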