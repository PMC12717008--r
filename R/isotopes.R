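#' Iron isotope patterns
#'
#' An isotope pattern is the vector of fractional molar abundances of the four
#' stable iron isotopes (54Fe, 56Fe, 57Fe, 58Fe). Patterns are the currency of
#' all tracer mixing and inversion arithmetic in this package: every iron pool
#' (circulating erythrocyte iron, an administered tracer dose) is described by
#' one.
#'
#' @name isotopes
NULL

# atomic masses of the stable iron isotopes, g/mol
.FE_ISOTOPES <- c(`54` = 53.9396, `56` = 55.9349, `57` = 56.9354, `58` = 57.9333)

.ISO_NAMES <- c("a54", "a56", "a57", "a58")

#' Construct and validate an isotope pattern
#'
#' @param a54,a56,a57,a58 fractional molar abundances; must be in \[0, 1\] and
#'   sum to 1 within `tol`.
#' @param tol tolerance on the sum-to-one constraint.
#' @return a named numeric vector of class `iso_pattern`.
#' @export
#' @examples
#' iso_pattern(0.05845, 0.91754, 0.02119, 0.00282)
iso_pattern <- function(a54, a56, a57, a58, tol = 1e-9) {
  x <- c(a54 = a54, a56 = a56, a57 = a57, a58 = a58)
  if (any(!is.finite(x))) stop("isotope abundances must be finite")
  if (any(x < 0) || any(x > 1)) stop("isotope abundances must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("isotope abundances must sum to 1 (got %.12f)", sum(x)))
  }
  structure(x, class = "iso_pattern")
}

#' @export
print.iso_pattern <- function(x, ...) {
  cat("<iso_pattern>", paste(sprintf("%s=%.5f", .ISO_NAMES, unclass(x)),
                             collapse = " "), "\n")
  invisible(x)
}

as_iso_pattern <- function(x, tol = 1e-9) {
  if (inherits(x, "iso_pattern")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4) stop("an isotope pattern has exactly 4 components")
  iso_pattern(x[1], x[2], x[3], x[4], tol = tol)
}

#' Natural iron isotope abundances
#'
#' Standard reference abundances of the four stable iron isotopes
#' (54Fe 0.05845, 56Fe 0.91754, 57Fe 0.02119, 58Fe 0.00282).
#'
#' @return an `iso_pattern`.
#' @export
natural_iron_pattern <- function() {
  iso_pattern(0.05845, 0.91754, 0.02119, 0.00282)
}

#' Default enriched tracer patterns
#'
#' Synthetic default abundance patterns for the three enriched tracers used in
#' the cross-over design (a 54Fe-enriched, a 57Fe-enriched and a 58Fe-enriched
#' material). These are configuration data, not measured certificates: real
#' analyses must substitute the supplier's certified patterns.
#'
#' @return a named list of `iso_pattern`s with names `"54Fe"`, `"57Fe"`,
#'   `"58Fe"`.
#' @export
default_tracer_patterns <- function() {
  list(
    `54Fe` = iso_pattern(0.998, 0.002, 0.000, 0.000),
    `57Fe` = iso_pattern(0.001, 0.049, 0.948, 0.002),
    `58Fe` = iso_pattern(0.001, 0.040, 0.020, 0.939)
  )
}

#' Molar mass of an iron pool from its isotope pattern
#'
#' Abundance-weighted mean of the isotopic atomic masses; needed to convert an
#' administered elemental-iron mass into moles of iron.
#'
#' @param pattern an `iso_pattern` (or coercible 4-vector).
#' @return molar mass in g/mol.
#' @export
#' @examples
#' pattern_molar_mass(natural_iron_pattern()) # ~55.845
pattern_molar_mass <- function(pattern) {
  p <- as_iso_pattern(pattern)
  sum(unclass(p) * .FE_ISOTOPES)
}

# ratios of each abundance to 56Fe (named r54, r57, r58)
pattern_to_ratios <- function(pattern) {
  p <- unclass(as_iso_pattern(pattern))
  if (p[["a56"]] <= 0) stop("cannot form ratios to 56Fe: zero 56Fe abundance")
  c(r54 = p[["a54"]] / p[["a56"]],
    r57 = p[["a57"]] / p[["a56"]],
    r58 = p[["a58"]] / p[["a56"]])
}

# rebuild a normalized pattern from ratios to 56Fe
ratios_to_pattern <- function(r) {
  a56 <- 1 / (1 + sum(r))
  iso_pattern(r[["r54"]] * a56, a56, r[["r57"]] * a56, r[["r58"]] * a56,
              tol = 1e-6)
}
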