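#' Volumetric image with world geometry
#'
#' Container for a 3-D scalar intensity grid with per-axis voxel spacing
#' (mm), world origin (mm) and anatomical orientation. The package works in
#' a right-handed world frame with axes (left-to-right, posterior-to-
#' anterior, inferior-to-superior); grid axis 1 runs left-right, axis 2
#' ventrodorsal, axis 3 inferior-superior ("RAS"). A voxel's world position
#' is its centre: `origin + (index - 1) * spacing` for 1-based indices.
#'
#' @param voxels 3-D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin Numeric length-3, world position (mm) of voxel (1,1,1).
#' @param orientation Orientation string; only `"RAS"` is used internally.
#' @return An object of class `volume_image`.
#' @seealso [read_volume()], [write_volume()], [extract_coronal_slice()],
#'   [resample_rigid()]
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = "RAS") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("volume_image: 'voxels' must be a 3-D array", call. = FALSE)
  if (any(dim(voxels) < 1L))
    stop("volume_image: grid must have at least 1 voxel per axis", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("volume_image: 'spacing' components must all be > 0", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("volume_image: 'origin' must be a numeric 3-vector", call. = FALSE)
  if (!identical(orientation, "RAS"))
    stop("volume_image: 'orientation' must be \"RAS\" ",
         "(read_volume reorients other layouts)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat("volume_image ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n  origin (", paste(format(x$origin), collapse = ", "),
      ") mm, orientation ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

# world extent of the voxel-centre grid along one axis (1=LR, 2=PA, 3=IS)
volume_extent <- function(vol, axis) {
  n <- dim(vol$voxels)[axis]
  c(vol$origin[axis], vol$origin[axis] + (n - 1) * vol$spacing[axis])
}

#' Read a volumetric image from a NIfTI file
#'
#' Reads a NIfTI-1 volume, reorients the grid to the package's canonical
#' RAS axis layout (left-right, posterior-anterior, inferior-superior), and
#' returns a [volume_image()] whose spacing and origin come from the file's
#' spatial affine. Intensities are not modified.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_volume: expected 3-D data, got ", length(dim(img)),
         " dimensions", call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  af <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)
  if (anyNA(spacing) || any(spacing <= 0))
    stop("read_volume: non-positive 'spacing' in header: ",
         paste(format(spacing), collapse = ", "), call. = FALSE)
  origin <- as.numeric(af[1:3, 4])
  volume_image(array(as.numeric(img), dim = dim(img)),
               spacing = spacing, origin = origin)
}

#' Write a volumetric image to a NIfTI file
#'
#' Writes a [volume_image()] as NIfTI-1 with a diagonal RAS affine carrying
#' the spacing and origin, so that [read_volume()] round-trips voxels,
#' spacing and origin.
#'
#' @param vol A [volume_image()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("write_volume: destination not writable: ", path, call. = FALSE)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  af <- diag(c(vol$spacing, 1))
  af[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(af, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(af, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Coronal (frontal-plane) slice of a volume
#'
#' Returns the grid plane nearest to the requested ventrodorsal position
#' `y_mm` (nearest-plane rule: pixel values are taken verbatim from the
#' volume, never interpolated). In-plane axis 1 is left-right, axis 2
#' inferior-superior.
#'
#' @param vol A [volume_image()].
#' @param y_mm Ventrodorsal world position (mm) of the requested plane; must
#'   lie within the volume extent along the posterior-anterior axis.
#' @return An object of class `slice2d` with fields `pixels` (matrix),
#'   `pixel_spacing` (mm), `origin` (world x/z of pixel (1,1)),
#'   `plane_position` (true mm coordinate of the selected plane) and
#'   `plane_axis`.
#' @export
extract_coronal_slice <- function(vol, y_mm) {
  stopifnot(inherits(vol, "volume_image"))
  ext <- volume_extent(vol, 2L)
  half <- vol$spacing[2] / 2
  if (y_mm < ext[1] - half || y_mm > ext[2] + half)
    stop(sprintf(
      "extract_coronal_slice: y_mm = %.3f outside volume extent [%.3f, %.3f] mm",
      y_mm, ext[1] - half, ext[2] + half), call. = FALSE)
  j <- round((y_mm - vol$origin[2]) / vol$spacing[2]) + 1
  j <- min(max(j, 1L), dim(vol$voxels)[2])
  structure(list(
    pixels = vol$voxels[, j, , drop = TRUE],
    pixel_spacing = vol$spacing[c(1, 3)],
    origin = vol$origin[c(1, 3)],
    plane_position = vol$origin[2] + (j - 1) * vol$spacing[2],
    plane_axis = "posterior-anterior"),
    class = "slice2d")
}

#' @export
print.slice2d <- function(x, ...) {
  cat("slice2d ", paste(dim(x$pixels), collapse = " x "),
      " pixels at y = ", format(x$plane_position), " mm (normal: ",
      x$plane_axis, ")\n", sep = "")
  invisible(x)
}

#' Rigidly resample a volume
#'
#' Resamples `vol` under the rigid transform `t` (which maps source world
#' coordinates to target world coordinates) onto the same grid as the
#' input, using trilinear interpolation. Target voxels that map outside the
#' source grid receive `fill` (default: the source minimum, so that
#' downstream bone thresholding is robust to the fill region).
#'
#' @param vol A [volume_image()].
#' @param t A [rigid_transform()].
#' @param fill Fill intensity for out-of-source voxels.
#' @return A [volume_image()] on the same grid as `vol`.
#' @export
resample_rigid <- function(vol, t, fill = min(vol$voxels)) {
  stopifnot(inherits(vol, "volume_image"), inherits(t, "rigid_transform"))
  if (max(abs(t$rotation - diag(3))) == 0 && all(t$translation == 0))
    return(vol)
  inv <- invert_transform(t)
  vox <- resample_trilinear_cpp(
    as.numeric(vol$voxels), as.integer(dim(vol$voxels)),
    vol$spacing, vol$origin, inv$rotation, inv$translation, fill)
  volume_image(vox, spacing = vol$spacing, origin = vol$origin)
}
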