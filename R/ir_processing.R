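#' Invert the graybody emissivity model
#'
#' Solves \eqn{\sigma T_{app}^4 = \epsilon \sigma T^4 +
#' (1-\epsilon)\sigma T_{refl}^4} for the true surface temperature:
#' \deqn{T = \left[(T_{app}^4 - (1-\epsilon) T_{refl}^4)/\epsilon\right]^{1/4}.}
#' Exact inverse of [apparent_temperature()]; monotone in `T_apparent`.
#' The correction strategy is pluggable at the processing level
#' (see [process_stack()]), this fourth-power inversion being the default.
#'
#' @param T_apparent apparent (radiometric) temperature (K), vectorised.
#' @param emissivity emissivity in (0, 1].
#' @param T_reflected reflected ambient temperature (K).
#' @return True temperature (K).
#' @export
correct_emissivity <- function(T_apparent, emissivity, T_reflected) {
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  rad <- (T_apparent^4 - (1 - emissivity) * T_reflected^4) / emissivity
  if (any(rad < 0)) stop("negative radicand: inputs are not physical")
  rad^0.25
}

#' Extract per-line axial temperature profiles from a thermal stack
#'
#' One profile per (frame, acquisition line).  Pixels are re-ordered so
#' index 1 is the vial bottom and heights are pixel centres,
#' `(p - 0.5) * mm_per_pixel` above the bottom.  No smoothing or filtering
#' of any kind is applied.
#'
#' @param stack a `thermal_stack`.
#' @param defs acquisition-line definitions (data frame with `vial_id`,
#'   `line_idx`, `col`, `row_bottom`, `row_top`); default: the stack's own.
#' @param emissivity,T_reflected if non-`NULL`, apply
#'   [correct_emissivity()] to the extracted values (defaults: the stack
#'   camera's settings).  Pass `NA` to skip correction.
#' @return Data frame (the profile stream) with columns `frame`, `time_s`,
#'   `vial_id`, `line_idx`, `pixel`, `height_mm`, `T_K`.
#' @export
extract_acquisition_lines <- function(stack, defs = stack$line_defs,
                                      emissivity = stack$camera$emissivity,
                                      T_reflected = stack$camera$T_reflected) {
  stopifnot(inherits(stack, "thermal_stack"))
  d <- dim(stack$frames[[1]])
  bad <- defs$col < 1 | defs$col > d[2] | defs$row_top < 1 |
    defs$row_bottom > d[1] | defs$row_top > defs$row_bottom
  if (any(bad)) {
    off <- defs[bad, c("vial_id", "line_idx")]
    stop("acquisition lines outside frame bounds: ",
         paste(sprintf("vial %d line %d", off$vial_id, off$line_idx),
               collapse = ", "))
  }
  npx <- defs$row_bottom[1] - defs$row_top[1] + 1
  mmpp <- stack$camera$mm_per_pixel
  heights <- (seq_len(npx) - 0.5) * mmpp
  nl <- nrow(defs)
  nf <- length(stack$frames)

  # values[pixel, line, frame], pixel 1 = vial bottom
  vals <- vapply(stack$frames, function(fr) {
    vapply(seq_len(nl), function(i) {
      fr[seq(defs$row_bottom[i], defs$row_top[i]), defs$col[i]]
    }, numeric(npx))
  }, matrix(0, npx, nl))

  if (!is.null(emissivity) && !is.na(emissivity)) {
    vals <- correct_emissivity(vals, emissivity, T_reflected)
  }

  data.frame(
    frame = rep(seq_len(nf), each = npx * nl),
    time_s = rep(stack$time_s, each = npx * nl),
    vial_id = rep(rep(defs$vial_id, each = npx), nf),
    line_idx = rep(rep(defs$line_idx, each = npx), nf),
    pixel = rep(seq_len(npx), nl * nf),
    height_mm = rep(heights, nl * nf),
    T_K = as.vector(vals)
  )
}

#' Per-profile extrema: Tmin/Tmax and their heights
#'
#' A plain extremum scan over the pixels of each axial profile (no
#' derivative analysis, no smoothing).  Ties are broken toward the lowest
#' height.
#'
#' @param profiles profile stream from [extract_acquisition_lines()].
#' @return An extrema trace of level `"LINE"`: data frame with `time_s`,
#'   `frame`, `vial_id`, `line_idx`, `Tmin_K`, `Hmin_mm`, `Tmax_K`,
#'   `Hmax_mm`.
#' @export
line_extrema <- function(profiles) {
  stopifnot(nrow(profiles) > 0)
  p <- profiles[order(profiles$frame, profiles$vial_id, profiles$line_idx,
                      profiles$height_mm), ]
  key <- paste(p$frame, p$vial_id, p$line_idx)
  sizes <- rle(key)$lengths
  if (length(unique(sizes)) != 1) stop("ragged profiles: unequal line lengths")
  npx <- sizes[1]
  Tm <- matrix(p$T_K, nrow = npx)
  Hm <- matrix(p$height_mm, nrow = npx)
  # which.max/min on columns take the first maximum = lowest height (tie rule)
  imax <- apply(Tm, 2, which.max)
  imin <- apply(Tm, 2, which.min)
  first <- seq(1, nrow(p), by = npx)
  sel <- function(M, idx) M[cbind(idx, seq_along(idx))]
  out <- data.frame(time_s = p$time_s[first], frame = p$frame[first],
                    vial_id = p$vial_id[first], line_idx = p$line_idx[first],
                    Tmin_K = sel(Tm, imin), Hmin_mm = sel(Hm, imin),
                    Tmax_K = sel(Tm, imax), Hmax_mm = sel(Hm, imax))
  out <- out[order(out$frame, out$vial_id, out$line_idx), ]
  rownames(out) <- NULL
  attr(out, "level") <- "LINE"
  out
}

mean_trace <- function(traces, by_cols, level) {
  key <- interaction(traces[by_cols], drop = TRUE)
  pieces <- split(traces, key)
  out <- do.call(rbind, lapply(pieces, function(p) {
    cbind(p[1, by_cols, drop = FALSE],
          data.frame(Tmin_K = mean(p$Tmin_K), Hmin_mm = mean(p$Hmin_mm),
                     Tmax_K = mean(p$Tmax_K), Hmax_mm = mean(p$Hmax_mm),
                     n_members = nrow(p)))
  }))
  out <- out[order(out$frame), ]
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Average line extrema to the vial level
#'
#' Per frame, the arithmetic mean of the per-line extremum *values* and of
#' their *positions* (extremum first, then average -- not the extremum of
#' an averaged profile).  Frames with missing lines are averaged over the
#' available lines; `n_members` records how many contributed.
#'
#' @param line_traces `LINE`-level trace from [line_extrema()].
#' @return `VIAL`-level extrema trace (one row per frame per vial).
#' @export
vial_trace <- function(line_traces) {
  out <- mean_trace(line_traces, c("frame", "time_s", "vial_id"), "VIAL")
  nexp <- max(out$n_members)
  if (any(out$n_members < nexp)) {
    message(sum(out$n_members < nexp), " frame(s) averaged over fewer lines")
  }
  out
}

#' Average vial traces to the batch level
#'
#' Equal-weight mean of the vial-level extremum values and positions per
#' frame, plus the min/max envelope of the vial `Hmax` and `Tmax` (the
#' shaded bands of batch plots).
#'
#' @param vial_traces `VIAL`-level trace (rows for several vials).
#' @return `BATCH`-level extrema trace with envelope columns
#'   `Hmax_lo/Hmax_hi/Tmax_lo/Tmax_hi`.
#' @export
batch_trace <- function(vial_traces) {
  key <- interaction(vial_traces$frame, drop = TRUE)
  pieces <- split(vial_traces, key)
  out <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(frame = p$frame[1], time_s = p$time_s[1],
               Tmin_K = mean(p$Tmin_K), Hmin_mm = mean(p$Hmin_mm),
               Tmax_K = mean(p$Tmax_K), Hmax_mm = mean(p$Hmax_mm),
               Hmax_lo = min(p$Hmax_mm), Hmax_hi = max(p$Hmax_mm),
               Tmax_lo = min(p$Tmax_K), Tmax_hi = max(p$Tmax_K),
               n_members = nrow(p))
  }))
  out <- out[order(out$frame), ]
  rownames(out) <- NULL
  attr(out, "level") <- "BATCH"
  out
}

#' Detect nucleation from a temperature series
#'
#' Nucleation announces itself as a sudden temperature rise (the latent
#' heat burst).  Returns the earliest time at which the forward-looking
#' rise within `window_s` exceeds `jump_K`, or `NA` for monotone cooling.
#' Neighbour-nucleation humps of about 3-4 K are rejected by choosing
#' `jump_K` above them.
#'
#' @param time_s,T_K sampled series (regular sampling assumed).
#' @param jump_K rise threshold (K).
#' @param window_s forward window (s); must cover at least one frame
#'   interval.
#' @return Nucleation time (s) or `NA_real_`.
#' @export
detect_nucleation <- function(time_s, T_K, jump_K = 2, window_s = 60) {
  stopifnot(length(time_s) == length(T_K), length(time_s) >= 2)
  dt <- stats::median(diff(time_s))
  if (window_s < dt) stop("window_s is shorter than one frame interval")
  w <- max(1L, as.integer(floor(window_s / dt)))
  n <- length(T_K)
  for (i in seq_len(n - 1)) {
    j <- min(n, i + w)
    hits <- which(T_K[(i + 1):j] - T_K[i] > jump_K)
    if (length(hits)) return(time_s[i + hits[1]]) # first elevated frame
  }
  NA_real_
}

#' Full stack-to-traces processing chain
#'
#' Extraction, emissivity correction, per-line extrema, then line-to-vial
#' and vial-to-batch averaging.
#'
#' @inheritParams extract_acquisition_lines
#' @return List with `profiles`, `line` (LINE trace), `vial` (VIAL trace)
#'   and `batch` (BATCH trace).
#' @export
process_stack <- function(stack, defs = stack$line_defs,
                          emissivity = stack$camera$emissivity,
                          T_reflected = stack$camera$T_reflected) {
  profiles <- extract_acquisition_lines(stack, defs, emissivity, T_reflected)
  lt <- line_extrema(profiles)
  vt <- vial_trace(lt)
  bt <- batch_trace(vt)
  list(profiles = profiles, line = lt, vial = vt, batch = bt)
}
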