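# Affine between-analyzer transference: y = slope * x + intercept per
# analyte, including composition of two published maps sharing a source
# platform. Composed coefficients are carried at full precision; 3-dp
# published coefficients are a display convention only.

#' Create a transference map
#'
#' An affine conversion of analyte values between two analyzer platforms.
#'
#' @param analyte Analyte name.
#' @param source,target Platform labels.
#' @param slope Dimensionless slope, must be > 0 (monotone conversion).
#' @param intercept Additive term in analyte units.
#' @return Object of class \code{"transference_map"}.
#' @examples
#' transference_map("creatinine", "Abbott", "Roche", 0.965, -0.447)
#' @export
transference_map <- function(analyte, source, target, slope, intercept) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be a positive number")
  structure(list(analyte = analyte, source = source, target = target,
                 slope = slope, intercept = intercept),
            class = "transference_map")
}

#' @export
print.transference_map <- function(x, ...) {
  cat(sprintf("%s: %s -> %s: y = %.6g x %s %.6g\n", x$analyte, x$source,
              x$target, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept)))
  invisible(x)
}

#' Apply a transference map
#'
#' @param map A \code{\link{transference_map}}.
#' @param x Numeric values on the source platform scale (vectorized).
#' @param analyte Optional analyte name; a mismatch with the map is an error.
#' @return \code{slope * x + intercept}.
#' @export
transfer <- function(map, x, analyte = NULL) {
  if (!is.null(analyte) && !identical(analyte, map$analyte)) {
    stop("map is for '", map$analyte, "', not '", analyte, "'")
  }
  map$slope * x + map$intercept
}

#' Compose two maps through their common source platform
#'
#' Given A->B and A->C maps for the same analyte, returns the B->C map,
#' algebraically equal to inverting A->B then applying A->C:
#' slope = slope_ac / slope_ab,
#' intercept = intercept_ac - (slope_ac / slope_ab) * intercept_ab.
#'
#' @param a_to_b,a_to_c \code{\link{transference_map}}s sharing analyte and
#'   source platform.
#' @return The composed B->C \code{\link{transference_map}}.
#' @export
compose_maps <- function(a_to_b, a_to_c) {
  if (!identical(a_to_b$analyte, a_to_c$analyte)) {
    stop("maps are for different analytes")
  }
  if (!identical(a_to_b$source, a_to_c$source)) {
    stop("maps do not share a source platform")
  }
  if (a_to_b$slope == 0) stop("cannot invert a zero-slope map")
  s <- a_to_c$slope / a_to_b$slope
  transference_map(a_to_b$analyte, a_to_b$target, a_to_c$target,
                   slope = s,
                   intercept = a_to_c$intercept - s * a_to_b$intercept)
}

#' Invert a transference map
#'
#' @param map A \code{\link{transference_map}}.
#' @return The target->source map; \code{transfer(invert_map(m),
#'   transfer(m, x))} equals \code{x} to machine precision.
#' @export
invert_map <- function(map) {
  transference_map(map$analyte, map$target, map$source,
                   slope = 1 / map$slope,
                   intercept = -map$intercept / map$slope)
}

#' Published platform transference formulas
#'
#' The four published affine formulas from the Abbott ARCHITECT c8000
#' platform: creatinine (enzymatic) x 0.965 - 0.447 to Roche Cobas and
#' x 0.903 - 1.192 to Beckman Coulter AU; urea x 0.941 + 0.143 to Roche and
#' x 0.961 + 0.110 to Beckman.
#'
#' @return Named list of \code{\link{transference_map}}s.
#' @export
published_platform_maps <- function() {
  list(
    creatinine_abbott_roche   = transference_map("creatinine", "Abbott", "Roche",   0.965, -0.447),
    creatinine_abbott_beckman = transference_map("creatinine", "Abbott", "Beckman", 0.903, -1.192),
    urea_abbott_roche         = transference_map("urea", "Abbott", "Roche",   0.941, 0.143),
    urea_abbott_beckman       = transference_map("urea", "Abbott", "Beckman", 0.961, 0.110)
  )
}

#' Default Roche-to-Beckman maps
#'
#' Composes the published Abbott-based formulas through the common Abbott
#' source: creatinine (x + 0.447) x 0.936 - 1.192 and urea
#' (x - 0.143) x 1.021 + 0.110 at printed precision (full precision is used
#' internally). Uric acid has no published conversion and gets an identity
#' map.
#'
#' @return Named list of \code{\link{transference_map}}s by analyte.
#' @export
default_transfer_maps <- function() {
  pm <- published_platform_maps()
  list(
    creatinine = compose_maps(pm$creatinine_abbott_roche, pm$creatinine_abbott_beckman),
    urea       = compose_maps(pm$urea_abbott_roche, pm$urea_abbott_beckman),
    uric_acid  = transference_map("uric_acid", "Roche", "Beckman", 1, 0)
  )
}

#' Transfer a record set between platforms
#'
#' Applies the per-analyte maps to the \code{value} column. Analytes with no
#' map are left unchanged with a message.
#'
#' @param records Canonical record data.frame.
#' @param maps Named list of \code{\link{transference_map}}s by analyte;
#'   defaults to \code{\link{default_transfer_maps}}.
#' @return The record data.frame with transferred values.
#' @export
transfer_records <- function(records, maps = default_transfer_maps()) {
  for (a in unique(records$analyte)) {
    sel <- records$analyte == a
    if (is.null(maps[[a]])) {
      message("no transference map for '", a, "'; values left unchanged")
      next
    }
    records$value[sel] <- transfer(maps[[a]], records$value[sel], analyte = a)
  }
  records
}
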