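#' Beta-distribution Q-Q assessment of pore diameters
#'
#' Sorted empirical diameters are paired with the quantiles of a scaled
#' `Beta(a, b)` law at plotting positions `(i - 0.5)/n`, and the linearity
#' of the Q-Q relation is summarised by the r-squared of an ordinary
#' (intercept included) linear fit.  If no scale is given it is fitted by
#' maximum likelihood with the shape parameters held fixed, so the
#' r-squared is invariant under positive rescaling of the data.
#'
#' @param diameters_um pore diameters (um), `n >= 20`.
#' @param a,b beta shape parameters (defaults 1.2 and 15).
#' @param scale_um scale mapping `[0, 1]` to um, or `NULL` to fit it.
#' @return Object of class `beta_qq`: `empirical_q`, `theoretical_q`
#'   (both non-decreasing), `r_squared`, `a`, `b`, `scale_um`,
#'   `scale_fitted`.
#' @export
beta_qq <- function(diameters_um, a = 1.2, b = 15, scale_um = NULL) {
  stopifnot(length(diameters_um) >= 20, all(diameters_um > 0), a > 0, b > 0)
  x <- sort(diameters_um)
  if (diff(range(x)) <= 0) stop("constant data: degenerate quantiles")
  fitted <- is.null(scale_um)
  if (fitted) {
    nll <- function(s) {
      -sum(stats::dbeta(pmin(x / s, 1 - 1e-12), a, b, log = TRUE) - log(s))
    }
    scale_um <- stats::optimize(nll, c(max(x) * (1 + 1e-9), max(x) * 10))$minimum
  }
  stopifnot(scale_um > 0)
  n <- length(x)
  p <- (seq_len(n) - 0.5) / n
  theo <- scale_um * stats::qbeta(p, a, b)
  # r^2 of the intercept-included linear fit = squared Pearson correlation
  r2 <- stats::cor(x, theo)^2
  structure(list(empirical_q = x, theoretical_q = theo, r_squared = r2,
                 a = a, b = b, scale_um = scale_um, scale_fitted = fitted),
            class = "beta_qq")
}

#' Dispersion statistics of pore diameters per group
#'
#' Per group: sample variance (n - 1 denominator), first and third
#' quartiles by the shared linear-interpolation quantile rule, and the
#' interquartile range `IQR = Q3 - Q1` -- the dispersion measures used to
#' compare loading configurations and nucleation temperatures.
#'
#' @param table a `pore_table`-like data frame with `eq_diameter_um`.
#' @param by character vector of grouping columns in `table`; `NULL`
#'   treats the table as a single group.
#' @param min_n groups smaller than this are skipped with a warning.
#' @return Data frame (`dispersion_report`) with `group_id`, the grouping
#'   columns, `n_pores`, `variance_um2`, `Q1_um`, `Q3_um`, `IQR_um`.
#' @export
dispersion_stats <- function(table, by = NULL, min_n = 4) {
  stopifnot(is.data.frame(table), "eq_diameter_um" %in% names(table))
  groups <- if (is.null(by)) list(all = table)
  else split(table, interaction(table[by], drop = TRUE, sep = "/"))
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]$eq_diameter_um
    if (length(d) < min_n) {
      warning("group '", g, "' has fewer than ", min_n, " pores; skipped")
      return(NULL)
    }
    q <- pore_quantile(d, c(0.25, 0.75))
    cbind(data.frame(group_id = g, n_pores = length(d),
                     variance_um2 = stats::var(d),
                     Q1_um = q[1], Q3_um = q[2], IQR_um = q[2] - q[1]),
          groups[[g]][1, by, drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("dispersion_report", "data.frame")
  out
}

#' Compare dispersion between paired ON- and OFF-shelf groups
#'
#' Groups sharing every pairing key (typically solution and nucleation
#' temperature) but differing in loading are paired, and the signs of the
#' ON-minus-OFF differences of variance and IQR are reported, with a
#' summary count of pairs where the OFF-shelf group is less disperse.
#'
#' @param reports a `dispersion_report` containing a `loading` column
#'   with values `"ON_SHELF"`/`"OFF_SHELF"` (plus the pairing keys).
#' @param pairing character vector of pairing key columns.
#' @return Data frame with one row per pair (`var_diff`, `iqr_diff`,
#'   `off_lower_var`, `off_lower_iqr`), unmatched groups listed in the
#'   `unmatched` attribute and the OFF-lower counts in `summary`.
#' @export
compare_groups <- function(reports, pairing = c("solution", "Tn")) {
  stopifnot(is.data.frame(reports), "loading" %in% names(reports),
            all(pairing %in% names(reports)))
  on <- reports[reports$loading == "ON_SHELF", ]
  off <- reports[reports$loading == "OFF_SHELF", ]
  m <- merge(on, off, by = pairing, suffixes = c("_on", "_off"))
  out <- data.frame(m[pairing],
                    variance_on = m$variance_um2_on,
                    variance_off = m$variance_um2_off,
                    IQR_on = m$IQR_um_on, IQR_off = m$IQR_um_off,
                    var_diff = m$variance_um2_on - m$variance_um2_off,
                    iqr_diff = m$IQR_um_on - m$IQR_um_off)
  out$off_lower_var <- out$var_diff > 0
  out$off_lower_iqr <- out$iqr_diff > 0
  key <- function(df) do.call(paste, c(df[pairing], sep = "/"))
  matched <- key(m)
  unmatched <- c(setdiff(key(on), matched), setdiff(key(off), matched))
  structure(out,
            unmatched = unmatched,
            summary = c(n_pairs = nrow(out),
                        off_lower_var = sum(out$off_lower_var),
                        off_lower_iqr = sum(out$off_lower_iqr)))
}

#' @export
print.beta_qq <- function(x, ...) {
  cat(sprintf("<beta_qq> n = %d vs Beta(%g, %g) x %.3g um%s: r^2 = %.5f\n",
              length(x$empirical_q), x$a, x$b, x$scale_um,
              if (x$scale_fitted) " (ML scale)" else "", x$r_squared))
  invisible(x)
}
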