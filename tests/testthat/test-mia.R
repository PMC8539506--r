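test_that("brightness equalization removes a ramp and preserves the mean", {
  m <- matrix(100, 150, 150)
  expect_equal(equalize_brightness(m, 31), m, tolerance = 1e-9)
  # pores + linear row ramp
  set.seed(1)
  img <- matrix(150, 300, 300) + matrix(seq(-30, 30, length.out = 300), 300, 300)
  img[140:150, 140:160] <- img[140:150, 140:160] - 80
  eq <- equalize_brightness(img, 101)
  expect_equal(mean(eq), mean(img), tolerance = 1e-6)
  rows <- 60:240
  dev <- abs(rowMeans(eq)[rows] - mean(img))
  expect_lt(max(dev[abs(rows - 145) > 20]), 0.02 * 60)
  # smoothing-subtraction reduces white-noise variance
  noise <- matrix(rnorm(200 * 200), 200, 200)
  expect_lte(var(as.vector(equalize_brightness(noise, 11))),
             var(as.vector(noise)))
  expect_error(equalize_brightness(m, 10), "odd")
  expect_error(equalize_brightness(m, 301), "larger")
})

test_that("the texture matrix unfolds windows row-major with centre column", {
  m <- matrix(1:25, 5, 5)
  b <- bharati_matrix(m, 3)
  expect_equal(dim(b), c(9, 9))
  # centre column equals the interior pixel intensities
  expect_equal(b[, 5], as.vector(m[2:4, 2:4]))
  # constant image: all entries equal, zero-variance columns
  b2 <- bharati_matrix(matrix(7, 6, 6), 3)
  expect_true(all(b2 == 7))
  expect_true(all(apply(b2, 2, var) == 0))
  expect_error(bharati_matrix(m, 4), "odd")
  expect_error(bharati_matrix(matrix(1, 3, 3), 5), "smaller")
})

test_that("PCA scores are orthonormal, ordered, and separate two textures", {
  set.seed(5)
  img <- matrix(200 + rnorm(120 * 120, 0, 2), 120, 120)
  truth <- matrix(FALSE, 120, 120)
  truth[30:60, 40:80] <- TRUE
  truth[80:100, 20:50] <- TRUE
  img[truth] <- 90 + rnorm(sum(truth), 0, 8)
  b <- bharati_matrix(img, 5)
  p <- pca_score_image(b, 2)
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-8)
  expect_true(all(diff(p$explained_var) <= 0))
  s <- p$score_images[[1]]
  thr <- quantile(s, 1 - mean(truth), na.rm = TRUE)
  pred <- !is.na(s) & s > thr
  inner <- !is.na(s)
  agree <- mean(pred[inner] == truth[inner])
  expect_gt(agree, 0.95)
  expect_error(pca_score_image(bharati_matrix(matrix(1, 20, 20), 5)),
               "degenerate")
})

test_that("matrix and shifted-image PCA paths agree", {
  set.seed(6)
  img <- matrix(rnorm(60 * 50, 100, 15), 60, 50)
  p1 <- pca_score_image(bharati_matrix(img, 5), 2)
  p2 <- mia_score_image(img, 5, 2)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8)
  expect_equal(p1$center, p2$center, tolerance = 1e-8)
  expect_equal(p1$score_images[[1]], p2$score_images[[1]], tolerance = 1e-6)
  expect_equal(p1$explained_var, p2$explained_var, tolerance = 1e-8)
})

test_that("score thresholding honours absolute and quantile modes", {
  s <- matrix(NA_real_, 12, 12)
  s[3:10, 3:10] <- seq(0, 1, length.out = 64)
  m_all <- segment_by_score(s, -1)
  expect_equal(sum(m_all$binary), 64)
  m_none <- segment_by_score(s, 2)
  expect_equal(sum(m_none$binary), 0)
  mq <- segment_by_score(s, 0.8, quantile = TRUE)
  expect_lt(abs(sum(mq$binary) / 64 - 0.2), 0.01 + 1 / 64)
})

test_that("Canny finds step edges and closed rings, skips flat fields", {
  expect_equal(sum(edge_filter(matrix(5, 60, 60))), 0)
  # vertical step edge at column 30
  img <- cbind(matrix(50, 60, 30), matrix(200, 60, 30))
  e <- edge_filter(img)
  hit_cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(all(abs(hit_cols - 30.5) <= 1.5))
  expect_gt(sum(e), 40)
  # dark disk on a bright field: closed one-pixel boundary
  xy <- expand.grid(r = 1:80, c = 1:80)
  disk <- matrix(200, 80, 80)
  disk[(xy$r - 40)^2 + (xy$c - 40)^2 <= 15^2] <- 60
  e2 <- edge_filter(disk)
  bg <- icefront:::cc_label_cpp(!e2, 4L)
  border_labs <- unique(c(bg[1, ], bg[80, ], bg[, 1], bg[, 80]))
  inside <- setdiff(unique(as.vector(bg[bg > 0])), border_labs)
  expect_equal(length(inside), 1) # a single enclosed interior: a closed ring
})

test_that("dimensional filter keeps areas in [50, 1000] inclusive", {
  m <- rect_mask(c(30, 50, 500, 1000, 1200))
  out <- combine_and_filter(m, NULL, 50, 1000)
  areas <- sort(tabulate(out$labels[out$labels > 0]))
  expect_equal(areas, c(50, 500, 1000))
  # idempotent
  out2 <- combine_and_filter(out$binary, NULL, 50, 1000)
  expect_equal(out2$binary, out$binary)
  # empty in, empty out
  empty <- combine_and_filter(matrix(FALSE, 10, 10), NULL)
  expect_equal(sum(empty$binary), 0)
  expect_error(combine_and_filter(m, matrix(FALSE, 2, 2)), "shapes")
})

test_that("edge route fills closed contours before filtering", {
  # a ring of edges around an area the score mask missed
  edges <- matrix(FALSE, 40, 40)
  edges[10:25, 10] <- edges[10:25, 25] <- TRUE
  edges[10, 10:25] <- edges[25, 10:25] <- TRUE
  score <- matrix(FALSE, 40, 40)
  out <- combine_and_filter(score, edges, 50, 1000)
  expect_equal(max(tabulate(out$labels[out$labels > 0])), 14 * 14)
  # the filter chain never grows the combined mask
  expect_lte(sum(out$binary), sum(score) + sum(!edges))
})

test_that("region properties match closed forms for disks and squares", {
  xy <- expand.grid(r = 1:50, c = 1:50)
  disk <- matrix((xy$r - 25)^2 + (xy$c - 25)^2 <= 10^2, 50, 50)
  mask <- combine_and_filter(disk, NULL, 1, 1e5)
  tab <- pore_properties(mask, px_size_um = 1)
  expect_lt(abs(tab$area_px / (pi * 100) - 1), 0.05)
  expect_lt(abs(tab$eq_diameter_um / 20 - 1), 0.05)
  # two disjoint 8x8 squares
  sq <- matrix(FALSE, 30, 30)
  sq[2:9, 2:9] <- TRUE
  sq[15:22, 15:22] <- TRUE
  tab2 <- pore_properties(combine_and_filter(sq, NULL, 1, 1e5), 1)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$area_px, c(64, 64))
  expect_equal(tab2$perimeter_px, c(32, 32)) # exposed-edge convention
  expect_equal(tab2$eq_diameter_um, rep(sqrt(4 * 64 / pi), 2),
               tolerance = 1e-12)
  # empty mask
  tab0 <- pore_properties(combine_and_filter(matrix(FALSE, 5, 5), NULL), 1)
  expect_equal(nrow(tab0), 0)
})

test_that("pore percentiles use the linear-interpolation rule", {
  expect_equal(unname(pore_percentiles(1:100)), c(25.75, 75.25))
  expect_equal(unname(pore_percentiles(rep(3.5, 10))), c(3.5, 3.5))
  expect_equal(pore_percentiles(c(1:20, 1:20)), pore_percentiles(1:20))
  expect_error(pore_percentiles(1:3), "at least 4")
})

test_that("segmentation is invariant to a constant intensity offset", {
  gen <- generate_sem_image(pore_spec(n_pores = 60, diameter_scale_um = 60,
                                      porosity_target = 0.15),
                            c(220, 220), 0.5, seed = 8)
  s1 <- segment_pores(gen$image)
  img2 <- gen$image
  img2$intensity <- img2$intensity + 17
  s2 <- segment_pores(img2)
  expect_equal(s1$mask$binary, s2$mask$binary)
  expect_true(all(s1$table$area_px >= 50 & s1$table$area_px <= 1000))
})
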