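#' Write / read a thermal stack as plain-text artifacts
#'
#' Frames are stored in a long CSV (`frame`, `row`, `col`, `T_cK`) with
#' apparent temperatures encoded as integer centikelvin (0.01 K
#' resolution), plus a timestamps CSV (`frame`, `time_s`) and the
#' acquisition-line definitions CSV.  Text encodings keep synthetic
#' fixtures portable and diff-able; the 0.01 K quantisation is below the
#' camera noise floor.
#'
#' @param stack a `thermal_stack`.
#' @param dir output directory (created if missing).
#' @param basename file prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_thermal_stack <- function(stack, dir, basename = "stack") {
  stopifnot(inherits(stack, "thermal_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$frames[[1]])
  long <- data.frame(
    frame = rep(seq_along(stack$frames), each = prod(d)),
    row = rep(rep(seq_len(d[1]), d[2]), length(stack$frames)),
    col = rep(rep(seq_len(d[2]), each = d[1]), length(stack$frames)),
    T_cK = as.integer(round(unlist(stack$frames, use.names = FALSE) * 100))
  )
  files <- c(frames = file.path(dir, paste0(basename, "_frames.csv")),
             times = file.path(dir, paste0(basename, "_timestamps.csv")),
             lines = file.path(dir, paste0(basename, "_lines.csv")),
             camera = file.path(dir, paste0(basename, "_camera.json")))
  utils::write.csv(long, files["frames"], row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(stack$time_s),
                              time_s = stack$time_s),
                   files["times"], row.names = FALSE)
  utils::write.csv(stack$line_defs, files["lines"], row.names = FALSE)
  jsonlite::write_json(unclass(stack$camera), files["camera"],
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname write_thermal_stack
#' @param dir,basename location written by [write_thermal_stack()].
#' @export
read_thermal_stack <- function(dir, basename = "stack") {
  pth <- function(s) file.path(dir, paste0(basename, "_", s))
  long <- utils::read.csv(pth("frames.csv"))
  times <- utils::read.csv(pth("timestamps.csv"))
  defs <- utils::read.csv(pth("lines.csv"))
  cam <- jsonlite::read_json(pth("camera.json"), simplifyVector = TRUE)
  camera <- do.call(camera_config, cam[names(cam) %in% names(formals(camera_config))])
  nr <- max(long$row); ncl <- max(long$col)
  fr_fac <- factor(long$frame, levels = sort(unique(long$frame)))
  frames <- lapply(split(long$T_cK / 100, fr_fac), function(v) {
    matrix(v, nr, ncl) # long CSV is written in column-major frame order
  })
  names(frames) <- NULL
  structure(list(frames = frames, time_s = times$time_s, camera = camera,
                 line_defs = defs, n_vials = length(unique(defs$vial_id))),
            class = "thermal_stack")
}
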