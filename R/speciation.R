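#' Iron speciation arithmetic
#'
#' Ferrous fraction from a Fe2+/Fe3+ ratio, and electron energy-loss
#' spectroscopy (EELS) white-line analysis: continuum subtraction at the Fe
#' L2,3 edges, L3/L2 integrated-intensity ratio, and conversion of that ratio
#' to a ferric fraction through a configurable monotone calibration. The
#' white-line ratio rises with the mean iron oxidation state, which is what
#' makes it usable as a valence probe; the calibration curve itself is
#' instrument- and method-dependent and is therefore shipped as data, never
#' hard-coded.
#'
#' @name speciation
NULL

#' Ferrous fraction from a Fe2+/Fe3+ ratio
#'
#' A ratio `r` of ferrous to ferric iron corresponds to a ferrous fraction
#' `r / (1 + r)` of total iron.
#'
#' @param fe2_to_fe3_ratio non-negative ratio.
#' @return fraction of total iron in the ferrous state, in \[0, 1).
#' @export
#' @examples
#' ferrous_fraction(5.6) # 0.848, i.e. 85% ferrous
ferrous_fraction <- function(fe2_to_fe3_ratio) {
  if (any(fe2_to_fe3_ratio < 0)) stop("ratio must be non-negative")
  fe2_to_fe3_ratio / (1 + fe2_to_fe3_ratio)
}

#' Construct an EELS spectrum
#'
#' @param energy_ev strictly increasing energy-loss grid, eV, length >= 16.
#' @param counts non-negative intensities, same length.
#' @return list of class `eels_spectrum`.
#' @export
eels_spectrum <- function(energy_ev, counts) {
  if (length(energy_ev) != length(counts)) stop("grids must have equal length")
  if (length(energy_ev) < 16) stop("spectrum needs at least 16 points")
  if (any(diff(energy_ev) <= 0)) stop("energy grid must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(energy_ev = as.numeric(energy_ev),
                 counts = as.numeric(counts)),
            class = "eels_spectrum")
}

#' Simulate a synthetic Fe L2,3 EELS spectrum
#'
#' Two Gaussian white lines on an optional continuum, for testing and
#' demonstration. Defaults place the L3 line at 709 eV and the L2 line
#' 13.2 eV higher.
#'
#' @param l3_area,l2_area integrated areas of the two lines.
#' @param l3_center,l2_center line centres, eV.
#' @param width Gaussian SD of both lines, eV.
#' @param energy_ev energy grid.
#' @param background function of energy giving continuum counts, or NULL.
#' @return an [eels_spectrum()].
#' @export
synth_eels_spectrum <- function(l3_area = 2, l2_area = 1, l3_center = 709,
                               l2_center = 722.2, width = 1.2,
                               energy_ev = seq(695, 745, by = 0.1),
                               background = NULL) {
  g <- function(a, mu) a * stats::dnorm(energy_ev, mu, width)
  counts <- g(l3_area, l3_center) + g(l2_area, l2_center)
  if (!is.null(background)) counts <- counts + background(energy_ev)
  eels_spectrum(energy_ev, pmax(counts, 0))
}

# trapezoid integral of y over x restricted to [lo, hi]
.trapz_window <- function(x, y, lo, hi) {
  sel <- x >= lo & x <= hi
  if (sum(sel) < 2) stop("integration window contains fewer than 2 points")
  xs <- x[sel]; ys <- y[sel]
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' White-line L3/L2 ratio of an Fe L-edge EELS spectrum
#'
#' Locates the L3 and L2 peak maxima, subtracts a configurable continuum
#' model, and integrates the background-subtracted counts over a window
#' around each peak by the trapezoid rule.
#'
#' Continuum models: `"double_arctan"` (default) places an arctan step under
#' each white line, anchored at the peak positions, with the classic 2:1
#' height partition scaled to the post-L2 continuum level; `"linear"`
#' interpolates a straight line between the pre-edge and post-edge mean
#' levels; `"none"` subtracts nothing (appropriate for already
#' background-subtracted spectra).
#'
#' @param spectrum an [eels_spectrum()].
#' @param background `"double_arctan"`, `"linear"` or `"none"`.
#' @param windows list with `l3` and `l2`, each `c(lo, hi)` in eV, or NULL to
#'   use +/- `half_width` around the detected peak maxima.
#' @param half_width default half-width of the auto windows, eV.
#' @param min_separation_ev minimum L3--L2 peak separation assumed when
#'   locating the two maxima.
#' @return list with `l3_area`, `l2_area`, `ratio`, `l3_peak_ev`,
#'   `l2_peak_ev`, `separation_ev`.
#' @export
white_line_ratio <- function(spectrum,
                             background = c("double_arctan", "linear", "none"),
                             windows = NULL, half_width = 2,
                             min_separation_ev = 6) {
  background <- match.arg(background)
  stopifnot(inherits(spectrum, "eels_spectrum"))
  e <- spectrum$energy_ev
  y <- spectrum$counts
  if (all(y == 0)) stop("spectrum has no intensity")

  l3_peak <- e[which.max(y)]
  after <- e > l3_peak + min_separation_ev
  if (!any(after)) stop("no L2 region beyond the L3 peak")
  l2_peak <- e[after][which.max(y[after])]

  if (is.null(windows)) {
    windows <- list(l3 = l3_peak + c(-1, 1) * half_width,
                    l2 = l2_peak + c(-1, 1) * half_width)
  }
  for (w in windows) {
    if (w[1] < min(e) || w[2] > max(e)) {
      stop("integration window lies outside the energy grid")
    }
  }

  bg <- switch(background,
    none = rep(0, length(e)),
    linear = {
      pre <- mean(y[e < l3_peak - 3 * half_width])
      post <- mean(y[e > l2_peak + 3 * half_width])
      if (!is.finite(pre)) pre <- y[1]
      if (!is.finite(post)) post <- y[length(y)]
      stats::approx(c(min(e), max(e)), c(pre, post), xout = e)$y
    },
    double_arctan = {
      post <- mean(y[e > l2_peak + 3 * half_width])
      if (!is.finite(post)) post <- y[length(y)]
      step <- function(e0) atan(pi * (e - e0)) / pi + 0.5
      post * (2 / 3 * step(l3_peak) + 1 / 3 * step(l2_peak))
    })
  ys <- y - bg

  l3_area <- .trapz_window(e, ys, windows$l3[1], windows$l3[2])
  l2_area <- .trapz_window(e, ys, windows$l2[1], windows$l2[2])
  if (l2_area <= 0) stop("non-positive L2 area after continuum subtraction")
  list(l3_area = l3_area, l2_area = l2_area, ratio = l3_area / l2_area,
       l3_peak_ev = l3_peak, l2_peak_ev = l2_peak,
       separation_ev = l2_peak - l3_peak)
}

#' Valence calibration for the white-line ratio
#'
#' Anchor points mapping an L3/L2 intensity ratio to the ferric fraction
#' Fe3+/sum(Fe), interpolated monotonically. The default anchors are a
#' synthetic curve shaped like published universal white-line calibrations
#' (ratio rising from the all-ferrous to the all-ferric endmember); any
#' quantitative use must supply the calibration measured under the same
#' acquisition and integration conventions as the spectra.
#'
#' @param ratio,fraction equal-length anchor vectors; `fraction` in \[0, 1\]
#'   and monotone in `ratio`.
#' @return list of class `valence_calibration`.
#' @export
valence_calibration <- function(ratio = c(3.0, 4.2, 5.5),
                                fraction = c(0, 0.5, 1)) {
  if (length(ratio) != length(fraction) || length(ratio) < 2) {
    stop("need at least 2 matching anchor points")
  }
  o <- order(ratio)
  ratio <- ratio[o]; fraction <- fraction[o]
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  if (any(diff(fraction) < 0)) {
    stop("anchors must be monotone: fraction non-decreasing in ratio")
  }
  structure(list(ratio = ratio, fraction = fraction),
            class = "valence_calibration")
}

#' Ferric fraction from a white-line ratio
#'
#' Monotone (linear between anchors) interpolation of a
#' [valence_calibration()]. Ratios outside the calibrated span are refused
#' unless `extrapolate = TRUE`, in which case the nearest endmember value is
#' returned.
#'
#' @param ratio observed L3/L2 ratio.
#' @param calibration a [valence_calibration()].
#' @param extrapolate allow ratios outside the anchor span.
#' @return ferric fraction Fe3+/sum(Fe) in \[0, 1\].
#' @export
ferric_fraction_from_ratio <- function(ratio,
                                       calibration = valence_calibration(),
                                       extrapolate = FALSE) {
  stopifnot(inherits(calibration, "valence_calibration"))
  lo <- min(calibration$ratio); hi <- max(calibration$ratio)
  if (!extrapolate && (ratio < lo || ratio > hi)) {
    stop(sprintf("ratio %.3f outside calibrated span [%.3f, %.3f]",
                 ratio, lo, hi))
  }
  stats::approx(calibration$ratio, calibration$fraction, xout = ratio,
                rule = 2)$y
}
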