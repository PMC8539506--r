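#' Thermal camera configuration
#'
#' @param fps frame rate (frames/s); the study's sensor tops out at 0.1 fps.
#' @param pixels_per_line pixels covering the cake height on one
#'   acquisition line (8 for a 10 mm cake with this sensor).
#' @param lines_per_vial vertical acquisition lines per vial (6).
#' @param emissivity constant surface emissivity used by the camera
#'   software (0.91 for these vials).
#' @param mm_per_pixel cake height per pixel (mm).
#' @param noise_sd per-pixel Gaussian measurement noise (K).
#' @param T_reflected effective reflected/ambient radiometric temperature
#'   (K) entering the graybody correction.
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(fps = 0.1, pixels_per_line = 8, lines_per_vial = 6,
                          emissivity = 0.91, mm_per_pixel = 10 / pixels_per_line,
                          noise_sd = 0.3, T_reflected = 293) {
  stopifnot(fps > 0, pixels_per_line >= 2, emissivity > 0, emissivity <= 1,
            lines_per_vial >= 1, mm_per_pixel > 0, noise_sd >= 0)
  structure(list(fps = fps, pixels_per_line = pixels_per_line,
                 lines_per_vial = lines_per_vial, emissivity = emissivity,
                 mm_per_pixel = mm_per_pixel, noise_sd = noise_sd,
                 T_reflected = T_reflected),
            class = "camera_config")
}

#' Graybody forward model: true temperature to apparent temperature
#'
#' The camera observes radiance \eqn{\sigma T_{app}^4 = \epsilon \sigma
#' T^4 + (1-\epsilon) \sigma T_{refl}^4}; this evaluates the apparent
#' (radiometric) temperature a camera set to emissivity 1 would report.
#' [correct_emissivity()] is its exact inverse.
#'
#' @param T_true true surface temperature (K), vectorised.
#' @param emissivity surface emissivity in (0, 1].
#' @param T_reflected reflected ambient temperature (K).
#' @return Apparent temperature (K).
#' @export
apparent_temperature <- function(T_true, emissivity, T_reflected) {
  stopifnot(emissivity > 0, emissivity <= 1)
  (emissivity * T_true^4 + (1 - emissivity) * T_reflected^4)^0.25
}

#' Render a thermal image stack from simulated vial histories
#'
#' The synthetic stand-in for the camera: each vial's axial temperature
#' field is linearly interpolated to the pixel-centre heights of its
#' acquisition lines, pushed through the graybody forward model at the
#' camera's emissivity, and perturbed with i.i.d. Gaussian noise.  Vials
#' are laid out left to right; a frame is a single matrix in image-raster
#' order (row 1 = top of image).  Optionally, the transient "hump" that
#' nucleation of a neighbouring vial imprints on a vial's wall pixels
#' (about 3-4 K, decaying over a minute) is injected on the outermost
#' acquisition lines.
#'
#' @param histories list of [vial_thermal_history()] objects on a common
#'   time grid.
#' @param camera a [camera_config()].
#' @param seed integer seed for the rendering noise.
#' @param neighbor_humps inject neighbour-nucleation humps?
#' @param hump_K,hump_decay_s hump amplitude (K) and exponential decay (s).
#' @param margin_rows,margin_cols background border around each vial block.
#' @param T_background true temperature (K) rendered outside the vials.
#' @return An object of class `thermal_stack`: list of frames (apparent
#'   temperature, K), `time_s`, the `camera`, and `line_defs` (data frame
#'   with `vial_id`, `line_idx`, `col`, `row_bottom`, `row_top`).
#' @export
render_thermal_stack <- function(histories, camera = camera_config(), seed = 1,
                                 neighbor_humps = FALSE, hump_K = 3.5,
                                 hump_decay_s = 60,
                                 margin_rows = 2, margin_cols = 1,
                                 T_background = NULL) {
  if (inherits(histories, "vial_thermal_history")) histories <- list(histories)
  stopifnot(length(histories) >= 1, inherits(camera, "camera_config"))
  time_s <- histories[[1]]$time_s
  spans <- vapply(histories, function(h) max(h$time_s), numeric(1))
  if (diff(range(spans)) > stats::median(diff(time_s)) + 1e-9) {
    stop("histories must share a time grid (use simulate_batch, ",
         "which disables early stopping)")
  }
  n_vials <- length(histories)
  npx <- camera$pixels_per_line
  nlines <- camera$lines_per_vial

  # frame times: resample history grid at the camera frame rate
  frame_dt <- 1 / camera$fps
  t_frames <- seq(0, max(time_s), by = frame_dt)
  hist_dt <- if (length(time_s) > 1) stats::median(diff(time_s)) else frame_dt
  if (abs(hist_dt - frame_dt) > 1e-9) {
    warning("history grid does not match the frame rate; resampling in time")
  }

  block_w <- nlines + 2 * margin_cols
  nrow_img <- npx + 2 * margin_rows
  ncol_img <- n_vials * block_w
  px_heights <- (seq_len(npx) - 0.5) * camera$mm_per_pixel

  if (is.null(T_background)) T_background <- camera$T_reflected
  bg_app <- apparent_temperature(T_background, camera$emissivity, camera$T_reflected)

  line_defs <- do.call(rbind, lapply(seq_len(n_vials), function(v) {
    data.frame(vial_id = v, line_idx = seq_len(nlines),
               col = (v - 1) * block_w + margin_cols + seq_len(nlines),
               row_bottom = margin_rows + npx,
               row_top = margin_rows + 1)
  }))

  t_nucs <- vapply(histories, function(h) h$t_nucleation_s, numeric(1))

  # per-vial pixel-centre fields for all frames (n_px x n_frames)
  px_fields <- lapply(histories, function(h) {
    Tt <- t(apply(h$T_axial, 1, function(series) {
      stats::approx(h$time_s, series, xout = t_frames, rule = 2)$y
    })) # n_nodes x n_frames
    apply(Tt, 2, function(Tcol) {
      stats::approx(h$node_heights_mm, Tcol, xout = px_heights, rule = 2)$y
    })
  })

  set.seed(seed)
  frames <- vector("list", length(t_frames))
  for (k in seq_along(t_frames)) {
    tk <- t_frames[k]
    fr <- matrix(bg_app, nrow_img, ncol_img)
    for (v in seq_len(n_vials)) {
      Tpx <- px_fields[[v]][, k]
      for (l in seq_len(nlines)) {
        Tl <- Tpx
        if (neighbor_humps) {
          # wall pixels (outermost lines) pick up neighbours' nucleation bursts
          if (l %in% c(1L, nlines)) {
            nb <- c(v - 1L, v + 1L)
            nb <- nb[nb >= 1 & nb <= n_vials]
            for (w in nb) {
              tn <- t_nucs[w]
              if (is.finite(tn) && tk >= tn) {
                Tl <- Tl + hump_K * exp(-(tk - tn) / hump_decay_s)
              }
            }
          }
        }
        Tapp <- apparent_temperature(Tl, camera$emissivity, camera$T_reflected)
        if (camera$noise_sd > 0) {
          Tapp <- Tapp + stats::rnorm(npx, 0, camera$noise_sd)
        }
        def <- line_defs[line_defs$vial_id == v & line_defs$line_idx == l, ]
        fr[seq(def$row_bottom, def$row_top), def$col] <- Tapp
      }
    }
    frames[[k]] <- fr
  }
  structure(list(frames = frames, time_s = t_frames, camera = camera,
                 line_defs = line_defs, n_vials = n_vials),
            class = "thermal_stack")
}

#' @export
print.thermal_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<thermal_stack> %d frames of %d x %d px, %d vial(s), %.3g fps\n",
              length(x$frames), d[1], d[2], x$n_vials, x$camera$fps))
  invisible(x)
}
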