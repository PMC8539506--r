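#' Pore population specification for synthetic SEM images
#'
#' Pore equivalent diameters follow a scaled beta law,
#' `diameter_scale_um * Beta(beta_a, beta_b)`, the distribution family
#' reported for freeze-dried cake pores (shape defaults a = 1.2, b = 15).
#'
#' @param beta_a,beta_b beta shape parameters (> 0).
#' @param diameter_scale_um scale (um) mapping the beta support `[0, 1]`
#'   to physical diameters.
#' @param n_pores number of pores to place.
#' @param porosity_target fraction of image area covered by pores at which
#'   placement stops, in (0, 1).
#' @param charging_gradient peak-to-peak intensity amplitude (8-bit units)
#'   of the row-wise brightness ramp emulating SEM charging.
#' @param matrix_level,pore_level,texture_sd mean intensities of matrix and
#'   pore interiors and the Gaussian texture noise (8-bit units).
#' @return Object of class `pore_spec`.
#' @export
pore_spec <- function(beta_a = 1.2, beta_b = 15, diameter_scale_um = 100,
                      n_pores = 2000, porosity_target = 0.18,
                      charging_gradient = 40,
                      matrix_level = 185, pore_level = 60, texture_sd = 10) {
  stopifnot(beta_a > 0, beta_b > 0, diameter_scale_um > 0, n_pores >= 1,
            porosity_target > 0, porosity_target < 1)
  structure(list(beta_a = beta_a, beta_b = beta_b,
                 diameter_scale_um = diameter_scale_um, n_pores = n_pores,
                 porosity_target = porosity_target,
                 charging_gradient = charging_gradient,
                 matrix_level = matrix_level, pore_level = pore_level,
                 texture_sd = texture_sd),
            class = "pore_spec")
}

#' SEM-like image container
#'
#' @param intensity grayscale matrix (0-255 scale).
#' @param px_size_um pixel size (um/pixel).
#' @param cake_level `"TOP"`, `"MIDDLE"` or `"BOTTOM"`.
#' @param sample_id identifier.
#' @return Object of class `sem_image`.
#' @export
sem_image <- function(intensity, px_size_um, cake_level = "MIDDLE",
                      sample_id = "synthetic") {
  intensity <- as.matrix(intensity)
  stopifnot(all(is.finite(intensity)), px_size_um > 0)
  cake_level <- match.arg(cake_level, c("TOP", "MIDDLE", "BOTTOM"))
  structure(list(intensity = intensity, px_size_um = px_size_um,
                 cake_level = cake_level, sample_id = sample_id),
            class = "sem_image")
}

# rasterise a rotated ellipse; returns row/col index vectors within the image
rasterize_ellipse <- function(r0, c0, a, b, theta, nr, nc, grow = 0) {
  a <- a + grow; b <- b + grow
  ext <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cols <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  if (!length(rows) || !length(cols)) return(NULL)
  dr <- outer(rows - r0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - c0)
  x <- dc * cos(theta) + dr * sin(theta)
  y <- -dc * sin(theta) + dr * cos(theta)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Generate a synthetic SEM image of a freeze-dried cake cross-section
#'
#' Dark elliptical pores with beta-distributed diameters are placed by
#' dart throwing without overlap (a two-pixel clearance keeps pores
#' 8-disconnected) onto a bright matrix carrying a row-wise charging
#' gradient and Gaussian texture noise.  Pores are placed in decreasing
#' size order until `n_pores` are down or `porosity_target` is reached.
#' The returned ground truth lists every placed pore with its sampled and
#' rasterised geometry.
#'
#' @param spec a [pore_spec()].
#' @param image_shape `c(rows, cols)`.
#' @param px_size_um pixel size (um).
#' @param seed integer seed; identical seeds give byte-identical images.
#' @param cake_level,sample_id metadata for the image.
#' @return List with `image` (an [sem_image()]), `truth` (data frame:
#'   `pore_id`, `d_um` sampled diameter, `area_px`, `eq_diameter_um` from
#'   the rasterised area, `centroid_row`, `centroid_col`, `placed`) and
#'   `mask` (ground-truth binary pore mask).
#' @export
generate_sem_image <- function(spec = pore_spec(), image_shape = c(512, 512),
                               px_size_um = 0.43, seed = 1,
                               cake_level = "MIDDLE", sample_id = "synthetic") {
  stopifnot(inherits(spec, "pore_spec"), length(image_shape) == 2,
            spec$n_pores >= 1)
  nr <- image_shape[1]; nc <- image_shape[2]
  set.seed(seed)

  d_um <- spec$diameter_scale_um * stats::rbeta(spec$n_pores, spec$beta_a, spec$beta_b)
  ord <- order(d_um, decreasing = TRUE) # large first: better packing
  aspect <- stats::runif(spec$n_pores, 0.7, 1)
  theta <- stats::runif(spec$n_pores, 0, pi)

  occ <- matrix(FALSE, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  n_px_target <- spec$porosity_target * nr * nc
  placed_px <- 0
  acc <- list(d_um = numeric(0), area = numeric(0), crow = numeric(0),
              ccol = numeric(0))
  consec_fail <- 0L
  pid <- 0L
  for (i in ord) {
    if (placed_px >= n_px_target) break
    d_px <- d_um[i] / px_size_um
    a <- d_px / 2 / sqrt(aspect[i])
    b <- d_px / 2 * sqrt(aspect[i])
    ok <- FALSE
    fit <- ceiling(max(a, b)) + 3 # keep pores fully inside the frame
    if (fit >= nr / 2 || fit >= nc / 2) next
    for (att in 1:200) {
      r0 <- stats::runif(1, fit, nr - fit); c0 <- stats::runif(1, fit, nc - fit)
      test <- rasterize_ellipse(r0, c0, a, b, theta[i], nr, nc, grow = 2)
      if (is.null(test) || any(occ[test])) next
      body <- rasterize_ellipse(r0, c0, a, b, theta[i], nr, nc, grow = 0)
      if (is.null(body) || nrow(body) == 0) next
      occ[test] <- TRUE
      mask[body] <- TRUE
      pid <- pid + 1L
      acc$d_um[pid] <- d_um[i]
      acc$area[pid] <- nrow(body)
      acc$crow[pid] <- mean(body[, "row"])
      acc$ccol[pid] <- mean(body[, "col"])
      placed_px <- placed_px + nrow(body)
      ok <- TRUE
      break
    }
    if (!ok) {
      consec_fail <- consec_fail + 1L
      if (consec_fail >= 50L && placed_px < n_px_target && pid < spec$n_pores / 2) {
        stop("porosity target unreachable: repeated placement failures ",
             "(image too small for the requested pore population)")
      }
    } else consec_fail <- 0L
  }
  truth <- data.frame(pore_id = seq_len(pid), d_um = acc$d_um,
                      area_px = acc$area,
                      eq_diameter_um = px_size_um * sqrt(4 * acc$area / pi),
                      centroid_row = acc$crow, centroid_col = acc$ccol)

  img <- matrix(spec$matrix_level, nr, nc)
  img[mask] <- spec$pore_level
  # row-wise charging gradient plus texture noise
  ramp <- seq(-spec$charging_gradient / 2, spec$charging_gradient / 2,
              length.out = nr)
  img <- img + matrix(ramp, nr, nc) + matrix(stats::rnorm(nr * nc, 0, spec$texture_sd), nr, nc)
  img <- pmin(pmax(img, 0), 255)

  list(image = sem_image(img, px_size_um, cake_level, sample_id),
       truth = truth, mask = mask)
}

#' Write / read a grayscale image as plain ASCII PGM (P2)
#'
#' Deliberately text-based so synthetic fixtures remain diff-able; values
#' are rounded to 8-bit.  A JSON sidecar (same path with `.json` appended)
#' carries pixel size and cake-level metadata.
#'
#' @param img an [sem_image()].
#' @param path output path (conventionally `.pgm`).
#' @return `write_pgm` the path, invisibly; `read_pgm` an [sem_image()].
#' @export
write_pgm <- function(img, path) {
  stopifnot(inherits(img, "sem_image"))
  m <- round(pmin(pmax(img$intensity, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  write(t(m), file = con, ncolumns = ncol(m))
  jsonlite::write_json(list(px_size_um = img$px_size_um,
                            cake_level = img$cake_level,
                            sample_id = img$sample_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pgm
#' @param path path to a P2 PGM written by [write_pgm()].
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(txt[1] == "P2")
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
  vals <- as.numeric(txt[-(1:4)])
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list(px_size_um = 1, cake_level = "MIDDLE", sample_id = basename(path))
  sem_image(m, meta$px_size_um, meta$cake_level, meta$sample_id)
}

#' @export
print.sem_image <- function(x, ...) {
  cat(sprintf("<sem_image> %d x %d px at %g um/px, level %s (%s)\n",
              nrow(x$intensity), ncol(x$intensity), x$px_size_um,
              x$cake_level, x$sample_id))
  invisible(x)
}
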