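# Presentation surfaces: 2D polar hemisphere plots, 3D anisotropy surfaces
# and principal-plane transects. Interpolation here is presentation-only;
# all statistics elsewhere are computed on the raw scheme nodes.

#' Interpolate scattered scheme values onto a polar grid
#'
#' Bilinear interpolation in (view zenith, view azimuth): per ring, circular
#' linear interpolation over azimuth; across rings, linear in zenith. Exact
#' at the scheme nodes. Inside the innermost ring the field blends toward
#' the nadir value.
#'
#' @param positions data.frame with `zenith`, `azimuth` (degrees).
#' @param v numeric values at the positions.
#' @param nZenith,nAzimuth grid resolution.
#' @return list `zenith`, `azimuth` (grid axes) and `z` (matrix
#'   `nZenith` x `nAzimuth`).
#' @export
interpolateHemisphere <- function(positions, v, nZenith = 61,
                                  nAzimuth = 181) {
  stopifnot(nrow(positions) == length(v))
  zs <- sort(unique(positions$zenith))
  gz <- seq(0, max(zs), length.out = nZenith)
  ga <- seq(0, 360, length.out = nAzimuth)
  ringVal <- function(z, a) {
    # value on ring with zenith z at azimuths a (circular linear interp)
    sel <- positions$zenith == z
    az <- positions$azimuth[sel]; vv <- v[sel]
    if (length(az) == 1) return(rep(vv, length(a)))
    o <- order(az); az <- az[o]; vv <- vv[o]
    azx <- c(az, az[1] + 360); vvx <- c(vv, vv[1])
    a2 <- ifelse(a < az[1], a + 360, a)
    approx(azx, vvx, a2, rule = 2)$y
  }
  ringMat <- vapply(zs, ringVal, numeric(length(ga)), a = ga)  # nAz x nRings
  z <- matrix(NA_real_, nZenith, nAzimuth)
  for (j in seq_along(ga)) {
    z[, j] <- approx(zs, ringMat[j, ], gz, rule = 2)$y
  }
  list(zenith = gz, azimuth = ga, z = z)
}

polarXY <- function(zenith, azimuth) {
  # backward-scattering half (azimuth 0) up, sun at the bottom
  list(x = zenith * sin(deg2rad(azimuth)), y = zenith * cos(deg2rad(azimuth)))
}

drawPolarFrame <- function(maxZ) {
  for (r in pretty(c(0, maxZ))[-1]) {
    t <- seq(0, 2 * pi, length.out = 181)
    lines(r * sin(t), r * cos(t), col = "grey60", lty = 3)
    text(0, r, sprintf("%g°", r), cex = 0.6, col = "grey40", pos = 3)
  }
  for (aa in seq(0, 330, by = 30))
    lines(c(0, maxZ * sin(deg2rad(aa))), c(0, maxZ * cos(deg2rad(aa))),
          col = "grey85", lty = 3)
  text(0, maxZ * 1.12, "backward (PP)", cex = 0.7)
  text(0, -maxZ * 1.12, "forward (sun)", cex = 0.7)
}

#' 2D polar hemisphere plot
#'
#' Filled polar plot of per-position values (HCRF at one wavelength, ANIF,
#' NDVI, drift indicator...) interpolated across the sampled cone, with the
#' scheme positions overplotted. Orientation: principal plane vertical,
#' backward-scattering half up, sun at the bottom.
#'
#' @param positions data.frame with `zenith`, `azimuth`, or a
#'   [HemisphereDataset-class] (then `v` may be a wavelength index).
#' @param v values per position.
#' @param file output PNG path.
#' @param main plot title.
#' @param palette colour palette name for [grDevices::hcl.colors()].
#' @param width,height,res PNG device parameters.
#' @return `file`, invisibly.
#' @export
plotHemisphere2D <- function(positions, v, file, main = "",
                             palette = "viridis", width = 900, height = 900,
                             res = 150) {
  if (is(positions, "HemisphereDataset")) positions <- positions@positions
  if (all(!is.finite(v))) stop("all values missing", call. = FALSE)
  g <- interpolateHemisphere(positions, v)
  maxZ <- max(g$zenith)
  png(file, width = width, height = height, res = res)
  on.exit(dev.off())
  par(mar = c(1, 1, 3, 1))
  plot(NA, xlim = c(-maxZ, maxZ) * 1.2, ylim = c(-maxZ, maxZ) * 1.2,
       asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  zl <- range(g$z, finite = TRUE)
  cols <- hcl.colors(64, palette)
  colOf <- function(val) cols[pmin(64, pmax(1, 1 + floor(
    63.999 * (val - zl[1]) / max(zl[2] - zl[1], .Machine$double.eps))))]
  nz <- length(g$zenith); na <- length(g$azimuth)
  for (i in seq_len(nz - 1)) for (j in seq_len(na - 1)) {
    r <- c(g$zenith[i], g$zenith[i + 1])
    a <- c(g$azimuth[j], g$azimuth[j + 1])
    xy <- polarXY(c(r[1], r[2], r[2], r[1]), c(a[1], a[1], a[2], a[2]))
    polygon(xy$x, xy$y, border = NA,
            col = colOf(mean(g$z[i:(i + 1), j:(j + 1)])))
  }
  drawPolarFrame(maxZ)
  pxy <- polarXY(positions$zenith, positions$azimuth)
  points(pxy$x, pxy$y, pch = 21, bg = "white", cex = 0.5)
  # colour bar
  xb <- seq(-maxZ, maxZ, length.out = 65)
  for (k in 1:64) rect(xb[k], -maxZ * 1.3, xb[k + 1], -maxZ * 1.24,
                       col = cols[k], border = NA)
  text(c(-maxZ, maxZ), -maxZ * 1.36, sprintf("%.3g", zl), cex = 0.6)
  invisible(file)
}

#' Principal-plane transect plot
#'
#' Values along the solar principal plane versus signed view zenith
#' (positive = backward scattering), one curve per requested wavelength.
#'
#' @param hem a [HemisphereDataset-class].
#' @param quantity `"hcrf"`, `"anif"` or `"ndvi"`.
#' @param wavelengthsNm wavelengths to draw (ignored for NDVI).
#' @param file output PNG path.
#' @param tolerance plane-membership tolerance, degrees.
#' @param width,height,res PNG device parameters.
#' @return `file`, invisibly.
#' @export
plotPPTransect <- function(hem, quantity = c("hcrf", "anif", "ndvi"),
                           wavelengthsNm = c(479, 549, 672, 864), file,
                           tolerance = 7.5, width = 1000, height = 700,
                           res = 150) {
  quantity <- match.arg(quantity)
  pos <- hem@positions
  back <- pos$zenith == 0 | abs(azimuthDiff(pos$azimuth, 0)) <= tolerance
  fwd <- pos$zenith == 0 | abs(azimuthDiff(pos$azimuth, 180)) <= tolerance
  if (sum(back | fwd) < 2)
    stop("principal plane not populated", call. = FALSE)
  signedZ <- c(pos$zenith[back], -pos$zenith[fwd])
  sel <- c(which(back), which(fwd))
  o <- order(signedZ)

  png(file, width = width, height = height, res = res)
  on.exit(dev.off())
  par(mar = c(4, 4, 3, 1))
  if (quantity == "ndvi") {
    vi <- viAngular(hem)
    y <- vi$ndvi[sel][o]
    plot(signedZ[o], y, type = "b", pch = 19,
         xlab = "view zenith (deg, + = backward)", ylab = "NDVI",
         main = "NDVI along the solar principal plane")
  } else {
    m <- if (quantity == "hcrf") hem@hcrf else hem@anif
    idx <- vapply(wavelengthsNm, function(b)
      which.min(abs(hem@wavelengths - b)), integer(1))
    ys <- m[sel, idx, drop = FALSE][o, , drop = FALSE]
    cols <- hcl.colors(length(idx), "Dark 3")
    plot(NA, xlim = range(signedZ), ylim = range(ys, finite = TRUE),
         xlab = "view zenith (deg, + = backward)", ylab = toupper(quantity),
         main = sprintf("%s along the solar principal plane",
                        toupper(quantity)))
    for (k in seq_along(idx))
      lines(signedZ[o], ys[, k], type = "b", pch = 19, col = cols[k])
    legend("topleft", legend = sprintf("%.0f nm",
                                       hem@wavelengths[idx]),
           col = cols, lty = 1, pch = 19, cex = 0.7, bty = "n")
  }
  invisible(file)
}

#' 3D hemisphere surface plot
#'
#' Perspective surface of per-position values over the sampled cone
#' (elevation = value), same interpolation and orientation conventions as
#' [plotHemisphere2D()].
#'
#' @inheritParams plotHemisphere2D
#' @param theta,phi viewing angles passed to [graphics::persp()].
#' @return `file`, invisibly.
#' @export
plotHemisphere3D <- function(positions, v, file, main = "", theta = 30,
                             phi = 30, width = 900, height = 900,
                             res = 150) {
  if (is(positions, "HemisphereDataset")) positions <- positions@positions
  g <- interpolateHemisphere(positions, v, nZenith = 31, nAzimuth = 73)
  x <- outer(g$zenith, sin(deg2rad(g$azimuth)))
  y <- outer(g$zenith, cos(deg2rad(g$azimuth)))
  png(file, width = width, height = height, res = res)
  on.exit(dev.off())
  # persp needs a regular x/y grid; draw in (zenith, azimuth) space instead
  persp(g$zenith, g$azimuth, g$z, theta = theta, phi = phi,
        xlab = "view zenith (deg)", ylab = "view azimuth (deg)",
        zlab = "value", main = main, col = "lightgreen", shade = 0.5,
        ticktype = "detailed")
  invisible(file)
}
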