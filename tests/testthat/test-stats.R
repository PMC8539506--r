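test_that("beta Q-Q is exact on quantile input and high on matched draws", {
  p <- (seq_len(200) - 0.5) / 200
  exact <- 30 * qbeta(p, 1.2, 15)
  qq <- beta_qq(exact, 1.2, 15, scale_um = 30)
  expect_equal(qq$r_squared, 1, tolerance = 1e-12)
  set.seed(7)
  draws <- 30 * rbeta(2000, 1.2, 15)
  qq2 <- beta_qq(draws, 1.2, 15)
  expect_gt(qq2$r_squared, 0.99)
  # misspecification: uniform draws fit worse than matched beta
  unif <- runif(2000, 0.5, 29.5)
  qq3 <- beta_qq(unif, 1.2, 15)
  expect_lt(qq3$r_squared, qq2$r_squared)
  expect_error(beta_qq(rep(3, 50), 1.2, 15), "constant")
})

test_that("Q-Q r-squared is invariant under rescaling when scale is refitted", {
  set.seed(8)
  x <- 20 * rbeta(500, 1.2, 15)
  r1 <- beta_qq(x)$r_squared
  r2 <- beta_qq(x * 3.7)$r_squared
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("dispersion statistics match hand and brute-force oracles", {
  d <- c(2, 4, 4, 4, 5, 5, 7, 9)
  rep1 <- dispersion_stats(data.frame(eq_diameter_um = d))
  expect_equal(rep1$variance_um2, 32 / 7, tolerance = 1e-12)
  # sort-based quantile oracle (type-7 linear interpolation, by hand)
  s <- sort(d)
  hq <- function(p) {
    k <- (length(s) - 1) * p
    s[floor(k) + 1] + (k - floor(k)) * (s[floor(k) + 2] - s[floor(k) + 1])
  }
  expect_equal(rep1$Q1_um, hq(0.25))
  expect_equal(rep1$Q3_um, hq(0.75))
  expect_equal(rep1$IQR_um, hq(0.75) - hq(0.25))
  # translation invariance
  rep2 <- dispersion_stats(data.frame(eq_diameter_um = d + 11.3))
  expect_equal(rep2$variance_um2, rep1$variance_um2)
  expect_equal(rep2$IQR_um, rep1$IQR_um)
  # all-equal group
  rep3 <- dispersion_stats(data.frame(eq_diameter_um = rep(4, 6)))
  expect_equal(c(rep3$variance_um2, rep3$IQR_um), c(0, 0))
  # brute-force two-pass variance on a random fixture
  set.seed(9)
  x <- rlnorm(400, 2, 0.4)
  rep4 <- dispersion_stats(data.frame(eq_diameter_um = x))
  mu <- sum(x) / length(x)
  expect_equal(rep4$variance_um2, sum((x - mu)^2) / (length(x) - 1),
               tolerance = 1e-9)
  # undersized groups are skipped with a warning
  tab <- data.frame(eq_diameter_um = c(1, 2, 3, 10, 11, 12, 13),
                    g = c("a", "a", "a", "b", "b", "b", "b"))
  expect_warning(rep5 <- dispersion_stats(tab, by = "g"), "fewer than")
  expect_equal(nrow(rep5), 1)
})

test_that("group comparison pairs loadings and counts lower-dispersion OFF", {
  mk <- function(loading, solution, Tn, d) {
    cbind(dispersion_stats(data.frame(eq_diameter_um = d)),
          loading = loading, solution = solution, Tn = Tn)
  }
  d0 <- c(3, 5, 6, 8, 11)
  same <- rbind(mk("ON_SHELF", "suc", 271, d0), mk("OFF_SHELF", "suc", 271, d0))
  cmp <- compare_groups(same)
  expect_equal(cmp$var_diff, 0)
  expect_equal(cmp$iqr_diff, 0)
  # 3 solutions x 2 Tn -> 6 paired rows
  grid <- expand.grid(sol = c("a", "b", "c"), Tn = c(271, 263),
                      stringsAsFactors = FALSE)
  reps <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    rbind(mk("ON_SHELF", grid$sol[i], grid$Tn[i], d0 * 2),
          mk("OFF_SHELF", grid$sol[i], grid$Tn[i], d0))
  }))
  cmp6 <- compare_groups(reps)
  expect_equal(nrow(cmp6), 6)
  expect_true(all(cmp6$off_lower_var & cmp6$off_lower_iqr))
  # unmatched groups are listed
  cmp_un <- compare_groups(rbind(same, mk("ON_SHELF", "lonely", 263, d0)))
  expect_true("lonely/263" %in% attr(cmp_un, "unmatched"))
})
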