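#' Planar dose distribution
#'
#' Container for a 2-D dose image on a uniform square-pixel grid: a matrix
#' (rows = y, columns = x) plus pixel pitch, the beam-coordinate position of
#' the image centre, the plane's longitudinal position z (mm from isocenter,
#' positive downstream) and the nominal energy. Used for scintillator spot
#' images and ion-chamber-array QA planes alike.
#'
#' @param dose Numeric matrix, rows indexed by y, columns by x.
#' @param pitch_mm Pixel pitch (mm), square pixels.
#' @param origin Length-2 numeric, (x, y) of the image centre (mm).
#' @param z_mm Plane position along the beam axis (mm from isocenter).
#' @param energy Nominal beam energy (MeV) or `NA`.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(dose, pitch_mm, origin = c(0, 0), z_mm = 0,
                       energy = NA_real_) {
  stopifnot(is.matrix(dose), pitch_mm > 0, length(origin) == 2)
  structure(
    list(dose = dose, pitch_mm = pitch_mm, origin = as.numeric(origin),
         z_mm = as.numeric(z_mm), energy = as.numeric(energy)),
    class = "dose_plane"
  )
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf(
    "<dose_plane> %d x %d px, pitch %.3g mm, z = %+.0f mm, energy %s MeV\n",
    nrow(x$dose), ncol(x$dose), x$pitch_mm, x$z_mm, format(x$energy)))
  invisible(x)
}

#' Axis coordinates of a dose plane
#' @param plane A [dose_plane()].
#' @return List with `x` (column centres, mm) and `y` (row centres, mm).
#' @export
plane_axes <- function(plane) {
  nx <- ncol(plane$dose)
  ny <- nrow(plane$dose)
  list(
    x = plane$origin[1] + (seq_len(nx) - (nx + 1) / 2) * plane$pitch_mm,
    y = plane$origin[2] + (seq_len(ny) - (ny + 1) / 2) * plane$pitch_mm
  )
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.dose_plane <- function(x, ...) {
  ax <- plane_axes(x)
  tibble::tibble(
    x_mm = rep(ax$x, each = nrow(x$dose)),
    y_mm = rep(ax$y, times = ncol(x$dose)),
    dose = as.vector(x$dose),
    z_mm = x$z_mm
  )
}

# bilinear interpolation of a plane at arbitrary (x, y); NA outside extent
plane_interp <- function(plane, x, y) {
  ax <- plane_axes(plane)
  h <- plane$pitch_mm
  fx <- (x - ax$x[1]) / h
  fy <- (y - ax$y[1]) / h
  nx <- length(ax$x)
  ny <- length(ax$y)
  ok <- fx >= -1e-9 & fx <= nx - 1 + 1e-9 & fy >= -1e-9 & fy <= ny - 1 + 1e-9
  # clamp exact edge hits into the boundary cell
  ix <- pmin(pmax(floor(fx), 0), nx - 2)
  iy <- pmin(pmax(floor(fy), 0), ny - 2)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  ixo <- ix[ok]; iyo <- iy[ok]
  tx <- fx[ok] - ixo
  ty <- fy[ok] - iyo
  d <- plane$dose
  i11 <- iyo + 1 + ny * ixo          # [iy+1, ix+1] in column-major
  v <- d[i11] * (1 - tx) * (1 - ty) +
    d[i11 + ny] * tx * (1 - ty) +
    d[i11 + 1] * (1 - tx) * ty +
    d[i11 + ny + 1] * tx * ty
  out[ok] <- v
  out
}

#' Write a dose plane as an ASCII grid file
#'
#' Plain-text format: three header lines (`z_mm`, `pitch_mm`,
#' `origin_xy_mm`) followed by the dose matrix, one image row per line.
#'
#' @param plane A [dose_plane()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plane_ascii <- function(plane, path) {
  hdr <- c(
    sprintf("# z_mm %.6g", plane$z_mm),
    sprintf("# pitch_mm %.6g", plane$pitch_mm),
    sprintf("# origin_xy_mm %.6g %.6g", plane$origin[1], plane$origin[2])
  )
  writeLines(hdr, path)
  utils::write.table(plane$dose, path, append = TRUE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an ASCII grid dose plane
#' @param path File written by [write_plane_ascii()].
#' @return A [dose_plane()].
#' @export
read_plane_ascii <- function(path) {
  hdr <- readLines(path, n = 3)
  val <- function(line) as.numeric(strsplit(sub("^# \\S+ ", "", line), " ")[[1]])
  m <- as.matrix(utils::read.table(path, skip = 3))
  dimnames(m) <- NULL
  dose_plane(m, pitch_mm = val(hdr[2]), origin = val(hdr[3]),
             z_mm = val(hdr[1]))
}

#' Write / read an IDD curve as two-column CSV
#'
#' Columns `depth_mm`, `dose`; the nominal energy travels in a `# energy`
#' comment line.
#'
#' @param curve An [idd_curve].
#' @param path File path.
#' @return `path` invisibly / an [idd_curve].
#' @export
write_idd_csv <- function(curve, path) {
  lines <- c(sprintf("# energy_mev %.6g", nominal_energy(curve)),
             "depth_mm,dose",
             sprintf("%.10g,%.10g", curve$depth_mm, curve$dose))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_idd_csv
#' @export
read_idd_csv <- function(path) {
  e <- as.numeric(sub("^# energy_mev ", "", readLines(path, n = 1)))
  d <- utils::read.csv(path, comment.char = "#")
  idd_curve(d$depth_mm, d$dose, nominal_energy = e)
}
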