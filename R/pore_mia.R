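# ---- small image helpers ----------------------------------------------

# shift a matrix by (dr, dc) with replicate (clamped) borders
shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1L), nr), pmin(pmax(seq_len(nc) + dc, 1L), nc)]
}

# windowed box mean via an integral image; window clamped at the borders
box_mean <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (w - 1L) %/% 2L
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  tot <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1, c2 - c1 + 1)
  tot / cnt
}

# separable Gaussian blur with replicate borders
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * shift_clamp(m, j - r - 1L, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * shift_clamp(m2, 0L, j - r - 1L)
  out
}

as_intensity <- function(image) {
  if (inherits(image, "sem_image")) image$intensity else as.matrix(image)
}

# ---- operations --------------------------------------------------------

#' Equalize SEM image brightness
#'
#' Removes the slowly varying charging background by subtracting a moving
#' average and restoring the global mean: `out = in - boxmean(in, window)`,
#' recentred so `mean(out) == mean(in)` exactly.
#'
#' @param image an [sem_image()] or plain matrix.
#' @param window odd box width (pixels), much larger than a pore.
#' @return Same type as the input, equalized.
#' @export
equalize_brightness <- function(image, window = 101) {
  m <- as_intensity(image)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (window > min(dim(m))) stop("window larger than the image")
  out <- m - box_mean(m, window)
  out <- out - mean(out) + mean(m)
  if (inherits(image, "sem_image")) {
    image$intensity <- out
    image
  } else out
}

#' Moving-window texture data matrix
#'
#' Unfolds the image into a matrix with one row per interior pixel (pixels
#' whose `w x w` window lies fully inside the image) and one column per
#' window slot, so PCA can capture both intensity and local texture.
#' Columns are ordered row-major over the window: slot `(wr, wc)` maps to
#' column `(wr - 1) * w + wc`; the centre slot is column `(w^2 + 1) / 2`.
#' Rows follow R's column-major order over the interior grid.
#'
#' @param image image or matrix.
#' @param w odd window width >= 3.
#' @return `n_interior x w^2` matrix with attributes `window`, `image_dim`
#'   and `interior_dim`.
#' @export
bharati_matrix <- function(image, w = 5) {
  m <- as_intensity(image)
  if (w < 3 || w %% 2 == 0) stop("w must be odd and >= 3")
  nr <- nrow(m); nc <- ncol(m)
  if (nr < w || nc < w) stop("image smaller than the window")
  ni_r <- nr - w + 1L; ni_c <- nc - w + 1L
  out <- matrix(0, ni_r * ni_c, w * w)
  for (wr in seq_len(w)) {
    for (wc in seq_len(w)) {
      j <- (wr - 1L) * w + wc
      out[, j] <- as.vector(m[wr:(nr - w + wr), wc:(nc - w + wc)])
    }
  }
  structure(out, window = w, image_dim = c(nr, nc),
            interior_dim = c(ni_r, ni_c))
}

# eigen-decomposition PCA shared by both scoring paths; flips each
# component so the centre-slot loading is negative (dark pores -> high score)
pca_from_cov <- function(cv, mu, n_components, w) {
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] <= 1e-12 * max(1, abs(mu[1]))) {
    stop("degenerate input: all window columns have (near-)zero variance")
  }
  k <- n_components
  load <- ev$vectors[, seq_len(k), drop = FALSE]
  centre <- (w * w + 1) / 2
  for (j in seq_len(k)) {
    s <- load[centre, j]
    if (s == 0) s <- sum(load[, j])
    if (s > 0) load[, j] <- -load[, j]
  }
  list(loadings = load,
       explained_var = ev$values[seq_len(k)] / sum(pmax(ev$values, 0)),
       eigenvalues = ev$values)
}

#' PCA of a texture data matrix, mapped back to score images
#'
#' Columns are mean-centred; loadings are the orthonormal eigenvectors of
#' the column covariance; scores of each retained component are reshaped
#' onto the interior-pixel grid (border pixels have no score and are `NA`).
#' Components are oriented so dark (pore) pixels score high.
#'
#' @param bmat matrix from [bharati_matrix()].
#' @param n_components number of components to retain.
#' @return Object of class `mia_pca`: `loadings` (`w^2 x k`, orthonormal),
#'   `explained_var` (non-increasing), `center`, `score_images` (list of
#'   full-size matrices with `NA` borders), `scores`.
#' @export
pca_score_image <- function(bmat, n_components = 2) {
  w <- attr(bmat, "window")
  idim <- attr(bmat, "image_dim"); intdim <- attr(bmat, "interior_dim")
  if (is.null(w)) stop("input must come from bharati_matrix()")
  stopifnot(n_components >= 1, n_components <= ncol(bmat))
  mu <- colMeans(bmat)
  xc <- sweep(bmat, 2, mu)
  cv <- crossprod(xc) / (nrow(bmat) - 1)
  p <- pca_from_cov(cv, mu, n_components, w)
  scores <- xc %*% p$loadings
  h <- (w - 1L) %/% 2L
  score_images <- lapply(seq_len(n_components), function(j) {
    full <- matrix(NA_real_, idim[1], idim[2])
    full[(h + 1):(idim[1] - h), (h + 1):(idim[2] - h)] <-
      matrix(scores[, j], intdim[1], intdim[2])
    full
  })
  structure(list(loadings = p$loadings, explained_var = p$explained_var,
                 center = mu, scores = scores, score_images = score_images,
                 window = w, image_dim = idim),
            class = "mia_pca")
}

#' Memory-lean PCA scoring of a full image
#'
#' Computes the same column means, covariance, loadings and score images
#' as [bharati_matrix()] + [pca_score_image()] without materialising the
#' unfolded matrix, using shifted-image accumulation.  Intended for
#' full-resolution SEM frames.
#'
#' @inheritParams bharati_matrix
#' @inheritParams pca_score_image
#' @return An `mia_pca` object (without the `scores` matrix).
#' @export
mia_score_image <- function(image, w = 5, n_components = 2) {
  m <- as_intensity(image)
  if (w < 3 || w %% 2 == 0) stop("w must be odd and >= 3")
  nr <- nrow(m); nc <- ncol(m)
  if (nr < w || nc < w) stop("image smaller than the window")
  p2 <- w * w
  sub <- function(j) {
    wr <- (j - 1L) %/% w + 1L; wc <- (j - 1L) %% w + 1L
    m[wr:(nr - w + wr), wc:(nc - w + wc)]
  }
  n <- (nr - w + 1L) * (nc - w + 1L)
  mu <- numeric(p2)
  for (j in seq_len(p2)) mu[j] <- sum(sub(j)) / n
  S2 <- matrix(0, p2, p2)
  for (j in seq_len(p2)) {
    sj <- sub(j)
    for (k in j:p2) S2[j, k] <- S2[k, j] <- sum(sj * sub(k))
  }
  cv <- (S2 - n * tcrossprod(mu)) / (n - 1)
  p <- pca_from_cov(cv, mu, n_components, w)
  h <- (w - 1L) %/% 2L
  score_images <- lapply(seq_len(n_components), function(jc) {
    acc <- matrix(-sum(p$loadings[, jc] * mu), nr - w + 1L, nc - w + 1L)
    for (j in seq_len(p2)) acc <- acc + p$loadings[j, jc] * sub(j)
    full <- matrix(NA_real_, nr, nc)
    full[(h + 1):(nr - h), (h + 1):(nc - h)] <- acc
    full
  })
  structure(list(loadings = p$loadings, explained_var = p$explained_var,
                 center = mu, score_images = score_images, window = w,
                 image_dim = c(nr, nc)),
            class = "mia_pca")
}

#' Threshold a PCA score image into a pore mask
#'
#' `binary = score > threshold`; pixels without a score (window borders)
#' are background.  In quantile mode the threshold is the given quantile
#' of the scored pixels (the score limit is "manually tuned" in practice;
#' the quantile parametrises that choice reproducibly).
#'
#' @param score_image matrix (possibly with `NA` borders).
#' @param threshold absolute score threshold, or a quantile in `[0, 1]`
#'   when `quantile = TRUE`.
#' @param quantile interpret `threshold` as a quantile?
#' @return Object of class `segmentation_mask` with elements `binary`,
#'   `labels` (filled by [combine_and_filter()]), `provenance`.
#' @export
segment_by_score <- function(score_image, threshold, quantile = FALSE) {
  stopifnot(is.finite(threshold))
  thr <- threshold
  if (quantile) {
    stopifnot(threshold >= 0, threshold <= 1)
    thr <- stats::quantile(score_image, threshold, na.rm = TRUE, type = 7,
                           names = FALSE)
  }
  binary <- !is.na(score_image) & score_image > thr
  structure(list(binary = binary, labels = NULL,
                 provenance = list(threshold = thr, quantile_mode = quantile,
                                   quantile = if (quantile) threshold else NA)),
            class = "segmentation_mask")
}

#' Canny edge detection
#'
#' Standard Canny chain: Gaussian smoothing, Sobel gradient, quantised
#' non-maximum suppression, and two-level hysteresis (weak edges are kept
#' only in connected components that contain a strong edge), producing
#' one-pixel-wide curves.
#'
#' @param image image or matrix.
#' @param sigma Gaussian smoothing scale (px).
#' @param lo,hi hysteresis thresholds as fractions of the maximum gradient
#'   magnitude, `0 <= lo < hi`.
#' @return Logical edge matrix.
#' @export
edge_filter <- function(image, sigma = 1.5, lo = 0.1, hi = 0.25) {
  stopifnot(lo >= 0, lo < hi)
  m <- gaussian_blur(as_intensity(image), sigma)
  gx <- (shift_clamp(m, -1, 1) + 2 * shift_clamp(m, 0, 1) + shift_clamp(m, 1, 1) -
           shift_clamp(m, -1, -1) - 2 * shift_clamp(m, 0, -1) - shift_clamp(m, 1, -1)) / 8
  gy <- (shift_clamp(m, 1, -1) + 2 * shift_clamp(m, 1, 0) + shift_clamp(m, 1, 1) -
           shift_clamp(m, -1, -1) - 2 * shift_clamp(m, -1, 0) - shift_clamp(m, -1, 1)) / 8
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx <= .Machine$double.eps) return(matrix(FALSE, nrow(m), ncol(m)))

  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- mag; n2 <- mag
  pick <- function(dr, dc) list(shift_clamp(mag, dr, dc), shift_clamp(mag, -dr, -dc))
  nb <- list(pick(0, 1), pick(1, 1), pick(1, 0), pick(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    n1[sel] <- nb[[s + 1]][[1]][sel]
    n2[sel] <- nb[[s + 1]][[2]][sel]
  }
  keep <- mag >= n1 & mag >= n2
  weak <- keep & mag >= lo * mx
  strong <- keep & mag >= hi * mx
  if (!any(strong)) return(matrix(FALSE, nrow(m), ncol(m)))
  lab <- cc_label_cpp(weak, 8L)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(m), ncol(m))
}

#' Combine score and edge masks, fill closed contours, filter by area
#'
#' The edge mask closes pore boundaries the score threshold leaks: regions
#' of the image fully enclosed by Canny edges are filled and united with
#' the score mask.  The union is labelled with 8-connectivity and a
#' dimensional filter removes components with area strictly below
#' `min_area` or strictly above `max_area` pixels (the bounds themselves
#' survive).
#'
#' @param mask a `segmentation_mask` (or logical matrix).
#' @param edges logical edge matrix from [edge_filter()], or `NULL` to
#'   skip the edge route.
#' @param min_area,max_area inclusive area bounds (px).
#' @return A `segmentation_mask` with `binary` and compact `labels`.
#' @export
combine_and_filter <- function(mask, edges = NULL, min_area = 50,
                               max_area = 1000) {
  binary <- if (inherits(mask, "segmentation_mask")) mask$binary else mask
  prov <- if (inherits(mask, "segmentation_mask")) mask$provenance else list()
  if (!is.null(edges)) {
    if (!all(dim(edges) == dim(binary))) stop("mask and edge shapes differ")
    # fill regions enclosed by edges: background components not touching the border
    bg <- !edges
    labbg <- cc_label_cpp(bg, 4L)
    border_labels <- unique(c(labbg[1, ], labbg[nrow(labbg), ],
                              labbg[, 1], labbg[, ncol(labbg)]))
    border_labels <- border_labels[border_labels > 0]
    enclosed <- bg & !(matrix(labbg %in% border_labels, nrow(bg), ncol(bg)))
    binary <- binary | enclosed
  }
  lab <- cc_label_cpp(binary, 8L)
  nlab <- attr(lab, "n_components")
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab)
    bad <- which(areas < min_area | areas > max_area)
    if (length(bad)) {
      binary[matrix(lab %in% bad, nrow(binary), ncol(binary))] <- FALSE
      lab <- cc_label_cpp(binary, 8L)
    }
  }
  structure(list(binary = binary, labels = lab,
                 provenance = c(prov, list(min_area = min_area,
                                           max_area = max_area,
                                           edge_route = !is.null(edges)))),
            class = "segmentation_mask")
}

#' Region properties of segmented pores
#'
#' Per labelled component: pixel-count area, exposed-edge perimeter (the
#' number of unit pixel edges between the component and anything else --
#' the length of its rasterised boundary), centroid, and the equivalent
#' circular diameter `px_size_um * sqrt(4 * area / pi)` in micrometres.
#'
#' @param mask `segmentation_mask` with labels (see [combine_and_filter()]).
#' @param px_size_um pixel size (um).
#' @param image_id,cake_level metadata columns replicated into the table.
#' @return Data frame (`pore_table`) with one row per pore.
#' @export
pore_properties <- function(mask, px_size_um, image_id = "image",
                            cake_level = "MIDDLE") {
  stopifnot(inherits(mask, "segmentation_mask"), !is.null(mask$labels),
            px_size_um > 0)
  nlab <- attr(mask$labels, "n_components")
  if (is.null(nlab)) nlab <- max(mask$labels)
  if (nlab == 0) {
    out <- data.frame(image_id = character(0), cake_level = character(0),
                      pore_id = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), eq_diameter_um = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    class(out) <- c("pore_table", "data.frame")
    return(out)
  }
  st <- region_stats_cpp(mask$labels, nlab)
  out <- data.frame(image_id = image_id, cake_level = cake_level,
                    pore_id = seq_len(nlab), area_px = st$area_px,
                    perimeter_px = st$perimeter_px,
                    eq_diameter_um = px_size_um * sqrt(4 * st$area_px / pi),
                    centroid_row = st$centroid_row,
                    centroid_col = st$centroid_col)
  class(out) <- c("pore_table", "data.frame")
  out
}

#' First and third quartiles of pore equivalent diameters
#'
#' Linear-interpolation quantile rule (R type 7), shared with the
#' dispersion statistics so both report identical quartiles.
#'
#' @param table a `pore_table` (or numeric vector of diameters).
#' @return Named vector `c(Q1_um, Q3_um)`.
#' @export
pore_percentiles <- function(table) {
  d <- if (is.data.frame(table)) table$eq_diameter_um else table
  if (length(d) < 4) stop("need at least 4 pores for quartiles")
  q <- pore_quantile(d, c(0.25, 0.75))
  c(Q1_um = q[1], Q3_um = q[2])
}

# single quantile implementation shared across modules (linear interpolation)
pore_quantile <- function(x, probs) {
  stats::quantile(x, probs, type = 7, names = FALSE)
}

#' Full MIA segmentation chain for one image
#'
#' Equalization, PCA texture scoring (first component), quantile score
#' threshold, Canny edge route, dimensional filter and region properties.
#'
#' @param image an [sem_image()].
#' @param equalize_window box width for [equalize_brightness()].
#' @param w texture window for the PCA.
#' @param score_quantile quantile threshold on the PC1 score image.
#' @param canny_sigma,canny_lo,canny_hi Canny parameters.
#' @param min_area,max_area dimensional-filter bounds (px).
#' @param image_id overrides the image's `sample_id`.
#' @return List `mask` (filtered `segmentation_mask`), `edges`, `pca`,
#'   `table` (a `pore_table`), `provenance`.
#' @export
segment_pores <- function(image, equalize_window = 101, w = 5,
                          score_quantile = 0.8, canny_sigma = 1.5,
                          canny_lo = 0.1, canny_hi = 0.25,
                          min_area = 50, max_area = 1000,
                          image_id = NULL) {
  stopifnot(inherits(image, "sem_image"))
  if (is.null(image_id)) image_id <- image$sample_id
  eq <- equalize_brightness(image, equalize_window)
  pca <- mia_score_image(eq, w = w, n_components = 2)
  m0 <- segment_by_score(pca$score_images[[1]], score_quantile, quantile = TRUE)
  edges <- edge_filter(eq, canny_sigma, canny_lo, canny_hi)
  mask <- combine_and_filter(m0, edges, min_area, max_area)
  table <- pore_properties(mask, image$px_size_um, image_id, image$cake_level)
  prov <- c(mask$provenance,
            list(equalize_window = equalize_window, window = w,
                 score_quantile = score_quantile, canny_sigma = canny_sigma,
                 canny_lo = canny_lo, canny_hi = canny_hi))
  list(mask = mask, edges = edges, pca = pca, table = table,
       provenance = prov)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  n <- if (!is.null(x$labels)) attr(x$labels, "n_components") else NA
  cat(sprintf("<segmentation_mask> %d x %d px, %s components, %d pore px\n",
              nrow(x$binary), ncol(x$binary), format(n), sum(x$binary)))
  invisible(x)
}
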