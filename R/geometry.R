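# Angular geometry: the measurement scheme, principal-plane correction,
# ground footprints and hot-spot feasibility. Solar ephemeris in solar.R.

#' The default 61-position measurement scheme
#'
#' Nadir, a 5-degree ring with 12 azimuth positions and 10/20/30-degree
#' rings with 16 azimuth positions each (61 positions in total). Azimuths
#' are referenced to the solar principal plane (0 = backward scattering);
#' each ring contains the principal plane (0/180) and the orthogonal plane
#' (90/270), with spacing tightened toward the principal plane where the
#' reflectance anisotropy is strongest.
#'
#' @param ring5,ring16 azimuth half-layouts (degrees in [0, 180]) for the
#'   12- and 16-position rings; entries in (0, 180) are mirrored about the
#'   principal plane.
#' @return a [MeasurementScheme-class].
#' @examples
#' sch <- defaultScheme()
#' nrow(positions(sch))  # 61
#' @export
defaultScheme <- function(ring5 = c(0, 25, 55, 90, 125, 155, 180),
                          ring16 = c(0, 15, 35, 60, 90, 120, 145, 165, 180)) {
  mirror <- function(half) {
    inner <- half[half > 0 & half < 180]
    sort(wrap360(c(half, 360 - inner)))
  }
  MeasurementScheme(list(
    list(zenith = 0, azimuths = 0),
    list(zenith = 5, azimuths = mirror(ring5)),
    list(zenith = 10, azimuths = mirror(ring16)),
    list(zenith = 20, azimuths = mirror(ring16)),
    list(zenith = 30, azimuths = mirror(ring16))))
}

#' Read / write a measurement scheme as a plain-text angle list
#'
#' Two whitespace-separated columns: view zenith and view azimuth (degrees,
#' principal-plane referenced), one row per position.
#'
#' @param path file path.
#' @return a [MeasurementScheme-class].
#' @export
readScheme <- function(path) {
  tab <- read.table(path, col.names = c("zenith", "azimuth"),
                    comment.char = "#")
  zs <- sort(unique(tab$zenith))
  MeasurementScheme(lapply(zs, function(z)
    list(zenith = z, azimuths = sort(wrap360(tab$azimuth[tab$zenith == z])))))
}

#' @rdname readScheme
#' @param scheme a [MeasurementScheme-class].
#' @export
writeScheme <- function(scheme, path) {
  pos <- positions(scheme)
  writeLines(c("# view_zenith view_azimuth (deg, principal-plane referenced)",
               sprintf("%g %g", pos$zenith, pos$azimuth)), path)
  invisible(path)
}

#' Per-ring principal-plane correction offsets
#'
#' The scheme's azimuths are referenced to the solar principal plane at the
#' session start, but the sun's azimuth moves during the ~20 min a hemisphere
#' takes. Before each ring is measured, the azimuth module can be rotated by
#' the offset returned here: the solar-azimuth change between the session
#' start and that ring's start time.
#'
#' @param latitude,longitude site coordinates (decimal degrees).
#' @param startTime session start (`POSIXct` UTC or ISO string with offset).
#' @param ringTimes per-ring start times (same format), ordered, >= start.
#' @return numeric vector of offsets in degrees (positive = sun moved
#'   clockwise), one per ring.
#' @export
principalPlaneCorrection <- function(latitude, longitude, startTime,
                                     ringTimes) {
  if (is.character(startTime)) startTime <- parseTimestamp(startTime)
  if (is.character(ringTimes)) ringTimes <- parseTimestamp(ringTimes)
  if (any(as.numeric(ringTimes) < as.numeric(startTime)))
    stop("ring times must not precede the session start", call. = FALSE)
  if (is.unsorted(as.numeric(ringTimes)))
    stop("ring times must be ordered", call. = FALSE)
  az0 <- solarPosition(latitude, longitude, startTime)$azimuth
  az <- solarPosition(latitude, longitude, ringTimes)$azimuth
  azimuthDiff(az, az0)
}

#' Ground footprint of the sensor cone
#'
#' Edge-ray construction on a horizontal plane: the sensor sits at
#' `slantDistance` from the target centre along the view direction; the
#' boundary rays of the cone of full opening angle `ifov` are intersected
#' with the ground. The intersection is an ellipse whose major extent (along
#' the view azimuth) follows from the two in-plane edge rays at
#' `viewZenith +- ifov/2`; the cross-track width and area come from the full
#' boundary. At nadir the footprint is a circle.
#'
#' @param viewZenith view zenith angle, degrees.
#' @param slantDistance sensor-to-target distance along the view direction,
#'   metres (instrument arc radius, 2.02 m by default).
#' @param ifov full opening angle of the foreoptic, degrees (8.5 default).
#' @return list of class `FootprintEllipse`: `centerOffset` (m, along the
#'   view-azimuth direction from the plot centre), `majorAxis`, `minorAxis`
#'   (full extents, m), `area` (m2).
#' @examples
#' round(footprint(0)$majorAxis, 3)    # 0.300 m at nadir
#' round(footprint(30)$majorAxis, 3)   # 0.348 m at the 30-degree position
#' @export
footprint <- function(viewZenith, slantDistance = 2.02, ifov = 8.5) {
  a <- ifov / 2
  if (viewZenith < 0 || viewZenith + a >= 90)
    stop("view zenith too close to grazing for this IFOV", call. = FALSE)
  if (slantDistance <= 0) stop("slantDistance must be > 0", call. = FALSE)
  th <- deg2rad(viewZenith)
  h <- slantDistance * cos(th)          # sensor height above ground
  x0 <- slantDistance * sin(th)         # horizontal offset of sensor
  # in-plane edge rays
  xNear <- x0 - h * tan(th - deg2rad(a))
  xFar <- x0 - h * tan(th + deg2rad(a))
  major <- abs(xFar - xNear)
  # full cone boundary: axis from sensor toward the target centre
  u <- c(-sin(th), 0, -cos(th))
  v1 <- c(cos(th), 0, -sin(th)); v2 <- c(0, 1, 0)
  t <- seq(0, 2 * pi, length.out = 2001)[-1]
  ar <- deg2rad(a)
  dirs <- cbind(cos(ar) * u[1] + sin(ar) * (cos(t) * v1[1]),
                cos(ar) * u[2] + sin(ar) * (sin(t) * v2[2]),
                cos(ar) * u[3] + sin(ar) * (cos(t) * v1[3]))
  s <- -h / dirs[, 3]
  px <- x0 + s * dirs[, 1]
  py <- s * dirs[, 2]
  minor <- max(py) - min(py)
  center <- (max(px) + min(px)) / 2
  structure(list(centerOffset = center, majorAxis = major,
                 minorAxis = minor, area = pi * major * minor / 4),
            class = "FootprintEllipse")
}

#' @export
print.FootprintEllipse <- function(x, ...) {
  cat(sprintf(
    "FootprintEllipse: major %.1f cm, minor %.1f cm, area %.0f cm2, center offset %.1f cm\n",
    100 * x$majorAxis, 100 * x$minorAxis, 1e4 * x$area, 100 * x$centerOffset))
  invisible(x)
}

#' Footprints for every ring of a scheme
#'
#' @param scheme a [MeasurementScheme-class].
#' @inheritParams footprint
#' @return data.frame with one row per ring zenith.
#' @export
footprintTable <- function(scheme, slantDistance = 2.02, ifov = 8.5) {
  zs <- vapply(scheme@rings, function(r) r$zenith, numeric(1))
  do.call(rbind, lapply(zs, function(z) {
    f <- footprint(z, slantDistance, ifov)
    data.frame(zenith = z, majorAxis = f$majorAxis, minorAxis = f$minorAxis,
               area = f$area, centerOffset = f$centerOffset)
  }))
}

#' Can the hot spot occur?
#'
#' The hot spot (sensor aligned with the sun, self-shadowing artifacts)
#' requires the sun zenith to be reachable by the view zenith. With a
#' 30-degree maximum view zenith and Arctic sun zeniths always above 43
#' degrees, it cannot occur.
#'
#' @param maxViewZenith maximum view zenith of the instrument, degrees.
#' @param minSunZenith minimum sun zenith over the observing period, degrees.
#' @return `TRUE` iff `minSunZenith <= maxViewZenith`.
#' @export
hotspotPossible <- function(maxViewZenith, minSunZenith) {
  stopifnot(maxViewZenith >= 0, maxViewZenith <= 90,
            minSunZenith >= 0, minSunZenith <= 90)
  minSunZenith <= maxViewZenith
}

#' Minimum solar zenith angle over one year
#'
#' Sweeps the ephemeris over a full year and returns the smallest solar
#' zenith angle encountered; used to establish hot-spot feasibility bounds
#' for a site.
#'
#' @param latitude,longitude site coordinates (decimal degrees).
#' @param year calendar year to sweep.
#' @param stepMinutes sweep resolution in minutes (default 5).
#' @return minimum solar zenith in degrees.
#' @export
minSolarZenith <- function(latitude, longitude = 0, year = 2012,
                           stepMinutes = 5) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1), tz = "UTC")
  times <- seq(t0, t1, by = stepMinutes * 60)
  min(solarPosition(latitude, longitude, times)$zenith)
}
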