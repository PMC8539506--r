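#' Track the freezing front from a vial extrema trace
#'
#' For conduction-dominated (ON-shelf) vials the height of the axial
#' temperature maximum is a proxy for the freezing-front position, so the
#' front trajectory is `Hmax` restricted to times after nucleation.
#' Velocity is a central difference over a configurable stencil, and the
#' trajectory is labelled by a two-segment piecewise-linear fit: the
#' steeper first segment is the linear ascent, the second its
#' deceleration (a growing frozen layer adds heat-transfer resistance, so
#' the front slows roughly like the square-root-of-time Stefan solution).
#'
#' @param vial_trace `VIAL`-level (or `BATCH`-level) extrema trace.
#' @param t_nucleation nucleation time (s), e.g. from
#'   [detect_nucleation()].
#' @param loading `"ON_SHELF"` or `"OFF_SHELF"`; OFF-shelf traces are
#'   refused because the mid-height maximum of a suspended vial does not
#'   track a front.
#' @param stencil half-width (frames) of the central velocity difference.
#' @param t_end optional end of the tracking window (s).
#' @param plateau_tol |slope| (mm/min) below which a segment is a plateau.
#' @return Object of class `front_track`: data frame `time_s`,
#'   `z_front_mm`, `velocity_mm_per_min`, `phase`, with the fitted
#'   breakpoint and segment slopes as attributes.
#' @export
track_front <- function(vial_trace, t_nucleation, loading = "ON_SHELF",
                        stencil = 5, t_end = NULL, plateau_tol = 0.02) {
  if (identical(loading, "OFF_SHELF")) {
    stop("OFF_SHELF trace: the axial maximum of a suspended vial sits near ",
         "mid-height and cannot be used to infer the freezing-front position")
  }
  stopifnot(is.finite(t_nucleation))
  tr <- vial_trace[vial_trace$time_s >= t_nucleation, ]
  if (!is.null(t_end)) tr <- tr[tr$time_s <= t_end, ]
  if (nrow(tr) < 3) stop("too few frames after nucleation to track a front")
  t <- tr$time_s
  z <- tr$Hmax_mm
  n <- length(z)

  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - stencil); hi <- min(n, i + stencil)
    v[i] <- (z[hi] - z[lo]) / (t[hi] - t[lo]) * 60
  }

  # two-segment least-squares fit over candidate breakpoints
  fit2 <- function(idx) {
    if (length(idx) < 2) return(list(sse = Inf, slope = NA_real_))
    ft <- stats::lm.fit(cbind(1, t[idx]), z[idx])
    list(sse = sum(ft$residuals^2), slope = ft$coefficients[2] * 60)
  }
  best <- list(sse = Inf, bp = NA_integer_, s1 = NA_real_, s2 = NA_real_)
  for (b in seq(2, n - 1)) {
    f1 <- fit2(seq_len(b)); f2 <- fit2(seq(b + 1, n))
    sse <- f1$sse + f2$sse
    if (sse < best$sse) best <- list(sse = sse, bp = b, s1 = f1$slope, s2 = f2$slope)
  }
  seg_label <- function(slope, other) {
    if (abs(slope) <= plateau_tol) "PLATEAU"
    else if (slope >= other) "ASCENT_LINEAR"
    else "DECELERATION"
  }
  lab1 <- seg_label(best$s1, best$s2)
  lab2 <- seg_label(best$s2, best$s1)
  phase <- c(rep(lab1, best$bp), rep(lab2, n - best$bp))

  out <- data.frame(time_s = t, z_front_mm = z, velocity_mm_per_min = v,
                    phase = phase)
  structure(out, class = c("front_track", "data.frame"),
            breakpoint_s = t[best$bp], slope1_mm_min = best$s1,
            slope2_mm_min = best$s2, t_nucleation_s = t_nucleation)
}

#' Frozen-layer temperature gradient
#'
#' The gradient between the freezing front (at `Tmax`, height `Hmax`) and
#' the vial bottom: `(Tmax - Tbottom) / Hmax` in K/mm.  The sign is
#' preserved, so an inverted profile gives a negative gradient.  `Hmax = 0`
#' yields `NA` with a warning.
#'
#' @param Tmax,Tbottom temperatures (K), vectorised.
#' @param Hmax front height (mm).
#' @return Gradient (K/mm).
#' @export
frozen_layer_gradient <- function(Tmax, Tbottom, Hmax) {
  g <- (Tmax - Tbottom) / Hmax
  zero <- is.finite(Hmax) & Hmax == 0
  if (any(zero)) {
    warning("Hmax = 0: gradient undefined, returning NA")
    g[zero] <- NA_real_
  }
  g
}

#' Freezing interval: nucleation to the 263 K analysis threshold
#'
#' Duration from nucleation until every reported axial temperature stays at
#' or below `T_end` (first sustained crossing, two consecutive frames).
#' Since the axial maximum bounds all pixels, the `Tmax` series of the
#' trace is used.
#'
#' @param vial_trace `VIAL`- or `BATCH`-level extrema trace.
#' @param t_nucleation nucleation time (s).
#' @param T_end threshold temperature (K), default 263.
#' @return Duration (s); 0 when already below at nucleation; `NA` (with a
#'   warning) when the threshold is never reached.
#' @export
freezing_interval <- function(vial_trace, t_nucleation, T_end = 263) {
  stopifnot(is.finite(t_nucleation))
  tr <- vial_trace[vial_trace$time_s >= t_nucleation, ]
  if (nrow(tr) == 0) stop("no frames after nucleation")
  below <- tr$Tmax_K <= T_end
  if (below[1] && (length(below) == 1 || below[2])) return(0)
  sustained <- below & c(below[-1], below[length(below)])
  hit <- which(sustained)
  if (length(hit) == 0) {
    warning("temperature never sustainedly reached T_end")
    return(NA_real_)
  }
  tr$time_s[hit[1]] - t_nucleation
}

#' Classify temperature-gradient direction and VISF inversion
#'
#' Operationalizes the qualitative batch summary: within a window, the
#' bottom pixel is labelled `LOWEST` if its temperature is at least
#' `margin_K` below every other pixel in at least 80 % of the frames
#' (`HIGHEST` symmetric, otherwise `UNCLEAR`).  Labels are computed before
#' nucleation and after nucleation; for VISF runs the vacuum-pulse window
#' is additionally labelled and the inversion flag is `"YES"` when the
#' bottom flips from `LOWEST` before the pulse to `HIGHEST` during it,
#' `"NO"` when it stays `LOWEST`, `"UNCLEAR"` otherwise, and `"NA"` for
#' spontaneous nucleation.  When nucleation follows the pulse onset within
#' fewer than `min_frames` frames (deep supercooling: nucleation before a
#' gradient can develop), the during-pulse label falls back to the
#' before-pulse label.
#'
#' @param profiles profile stream (ideally batch-averaged per pixel, see
#'   [average_profiles()]) with columns `time_s`, `pixel`, `T_K`.
#' @param t_nucleation nucleation time (s).
#' @param t_pulse_start VISF pulse onset (s) or `NA` for spontaneous runs.
#' @param margin_K separation margin (K).
#' @param window_s length (s) of the before window.
#' @param after_skip_s dead time (s) after nucleation before the "after"
#'   window opens (lets the latent-heat burst clear and the frozen-layer
#'   gradient develop).
#' @param after_window_s length (s) of the after window; it should span
#'   the developed freezing interval.
#' @param T_flat_K temperature (K) below which axial gradients fade; the
#'   after window is truncated once the column maximum stays below it
#'   (matching the analysed freezing interval).
#' @param pulse_window_s length (s) of the during-pulse window (ending at
#'   nucleation).
#' @param min_frames minimum frames for a classifiable window.
#' @param frac fraction of frames required for a LOWEST/HIGHEST call.
#' @return Object of class `gradient_label`: list with `before_nucleation`,
#'   `after_nucleation`, `during_pulse`, `visf_inversion`.
#' @export
classify_inversion <- function(profiles, t_nucleation, t_pulse_start = NA,
                               margin_K = 0.2, window_s = 300,
                               after_skip_s = 300, after_window_s = 1200,
                               T_flat_K = 263, pulse_window_s = 100,
                               min_frames = 5, frac = 0.8) {
  stopifnot(is.finite(t_nucleation))
  label_window <- function(t0, t1, allow_short = FALSE) {
    p <- profiles[profiles$time_s >= t0 & profiles$time_s < t1, ]
    frames <- unique(p$time_s)
    if (length(frames) < min_frames) {
      if (allow_short) return(NULL)
      stop("classification window shorter than ", min_frames, " frames")
    }
    per_frame <- vapply(frames, function(tt) {
      q <- p[p$time_s == tt, ]
      q <- q[order(q$pixel), ]
      bot <- q$T_K[1]; rest <- q$T_K[-1]
      c(low = bot <= min(rest) - margin_K, high = bot >= max(rest) + margin_K)
    }, c(low = FALSE, high = FALSE))
    if (mean(per_frame["low", ]) >= frac) "LOWEST"
    else if (mean(per_frame["high", ]) >= frac) "HIGHEST"
    else "UNCLEAR"
  }

  visf <- is.finite(t_pulse_start)
  t_before_end <- if (visf) t_pulse_start else t_nucleation
  before <- label_window(t_before_end - window_s, t_before_end)
  # once everything is below ~263 K the gradients fade; stop the window there
  colmax <- stats::aggregate(T_K ~ time_s, profiles, max)
  post <- colmax[colmax$time_s > t_nucleation, ]
  flat <- post$time_s[post$T_K <= T_flat_K]
  after_start <- t_nucleation + after_skip_s
  after_end <- t_nucleation + after_skip_s + after_window_s
  if (length(flat) && flat[1] > after_start) after_end <- min(after_end, flat[1])
  after <- label_window(after_start, after_end, allow_short = TRUE)
  if (is.null(after)) after <- label_window(after_start,
                                            t_nucleation + after_skip_s + after_window_s)

  during <- NA_character_
  inversion <- "NA"
  if (visf) {
    during <- label_window(max(t_pulse_start, t_nucleation - pulse_window_s),
                           t_nucleation, allow_short = TRUE)
    if (is.null(during)) {
      # nucleation at pulse onset: no gradient had time to develop
      during <- before
    }
    inversion <- if (before == "LOWEST" && during == "HIGHEST") "YES"
    else if (before == "LOWEST" && during == "LOWEST") "NO"
    else "UNCLEAR"
  }
  structure(list(before_nucleation = before, after_nucleation = after,
                 during_pulse = during, visf_inversion = inversion),
            class = "gradient_label")
}

#' Align profile streams on each vial's nucleation time
#'
#' For spontaneous-nucleation batches the vials nucleate at staggered
#' times, so plain batch averaging smears the event.  Each vial's time
#' axis is shifted so its nucleation sits at `t = 0` (times snapped to the
#' frame grid), allowing event-aligned averaging across vials.
#'
#' @param profiles profile stream with `vial_id`.
#' @param t_nucs named or ordered vector of per-vial nucleation times (s);
#'   vials with non-finite times are dropped.
#' @return Profile stream with `time_s` relative to nucleation.
#' @export
align_profiles <- function(profiles, t_nucs) {
  ids <- sort(unique(profiles$vial_id))
  stopifnot(length(t_nucs) == length(ids))
  dt <- stats::median(diff(sort(unique(profiles$time_s))))
  out <- lapply(seq_along(ids), function(i) {
    if (!is.finite(t_nucs[i])) return(NULL)
    p <- profiles[profiles$vial_id == ids[i], ]
    p$time_s <- round((p$time_s - t_nucs[i]) / dt) * dt
    p
  })
  out <- do.call(rbind, out)
  out$frame <- match(out$time_s, sort(unique(out$time_s)))
  out
}

#' Average a profile stream per pixel across lines and vials
#'
#' Batch-mean per-pixel temperature traces, the robust input for
#' [classify_inversion()] (averaging suppresses per-pixel camera noise).
#'
#' @param profiles profile stream.
#' @return Data frame `time_s`, `pixel`, `height_mm`, `T_K`.
#' @export
average_profiles <- function(profiles) {
  key <- paste(profiles$frame, profiles$pixel)
  agg <- stats::aggregate(profiles$T_K,
                          by = list(frame = profiles$frame,
                                    time_s = profiles$time_s,
                                    pixel = profiles$pixel,
                                    height_mm = profiles$height_mm),
                          FUN = mean)
  names(agg)[5] <- "T_K"
  agg[order(agg$frame, agg$pixel), ]
}

#' @export
print.gradient_label <- function(x, ...) {
  cat(sprintf("<gradient_label> before: %s | after: %s | VISF inversion: %s\n",
              x$before_nucleation, x$after_nucleation, x$visf_inversion))
  invisible(x)
}

#' @export
print.front_track <- function(x, ...) {
  cat(sprintf("<front_track> %d frames; slopes %.3g / %.3g mm/min, breakpoint at %.0f s\n",
              nrow(x), attr(x, "slope1_mm_min"), attr(x, "slope2_mm_min"),
              attr(x, "breakpoint_s")))
  invisible(x)
}
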