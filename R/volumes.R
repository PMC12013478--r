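#' 3D image volume with voxel geometry
#'
#' Lightweight container for a 3D scalar field (e.g. a T2-weighted image,
#' a normalized image, or a vesselness map) together with its voxel
#' spacing in mm and an optional 4x4 voxel-to-world affine. Voxel indices
#' are 0-based in the affine convention: the affine maps 0-based voxel
#' centers to world (RAS) coordinates, as in the NIfTI header.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(spacing, 1))` when written to file.
#' @return An object of class `image_volume` with fields `data`,
#'   `spacing`, `affine`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_numeric_array3(data, "data")
  if (anyNA(data)) stop("volume data contains NaN/NA values")
  spacing <- check_spacing(spacing)
  affine <- check_affine(affine)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "image_volume")
}

#' 3D binary mask with voxel geometry
#'
#' Boolean field on a voxel grid: brain masks, CSF segmentations,
#' exclusion templates, lesion masks, ROIs and PVS segmentations all take
#' this form.
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.numeric(data)) {
    u <- unique(as.vector(data))
    if (any(is.na(u))) stop("mask data contains NA values")
    frac <- u[u > 0 & u < 1]
    if (length(frac) > 0)
      stop("mask contains fractional values strictly between 0 and 1 ",
           "(looks like a probability map, not a binary mask): e.g. ",
           format(frac[1]))
    data <- data != 0
  }
  if (!is.logical(data)) stop("mask data must be logical or numeric")
  if (anyNA(data)) stop("mask data contains NA values")
  data <- as_logical_array3(data)
  spacing <- check_spacing(spacing)
  affine <- check_affine(affine)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  intensity range:", format(range(x$data)), "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  true voxels:", sum(x$data), "(",
      format(mask_volume_mm3(x)), "mm^3 )\n")
  invisible(x)
}

#' Physical volume of one voxel in mm^3
#' @param x an `image_volume` or `binary_mask`.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Physical volume of a mask in mm^3 (true-voxel count times voxel volume)
#' @param mask a `binary_mask`.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume_mm3(mask)
}

# ---- internal validators ----------------------------------------------------

as_numeric_array3 <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop(what, " must be a 3D array, got ",
         if (is.array(data)) paste0(length(dim(data)), "D") else class(data)[1])
  if (any(dim(data) < 1)) stop(what, " has a zero-length axis")
  storage.mode(data) <- "double"
  data
}

as_logical_array3 <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("mask must be a 3D array")
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths in mm")
  spacing
}

check_affine <- function(affine) {
  if (is.null(affine)) return(NULL)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || anyNA(affine))
    stop("affine must be a finite 4x4 matrix")
  unname(affine)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6))
}

stop_grid_mismatch <- function(what) {
  stop("grid mismatch: ", what, " must share dimensions and voxel spacing")
}

# Effective voxel-to-world affine: stored affine, or spacing on the diagonal.
effective_affine <- function(x) {
  if (!is.null(x$affine)) x$affine else diag(c(x$spacing, 1))
}

# ---- NIfTI IO ---------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file into an [image_volume]. Spacing is taken
#' from the header `pixdim`; the voxel-to-world affine from the
#' sform/qform. Integer-typed images are promoted to double. Volumes that
#' are not 3D, carry non-positive spacing, or contain NaN voxels are
#' rejected.
#'
#' @param path path to a NIfTI file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  nii <- read_nifti_checked(path)
  image_volume(array(as.numeric(nii), dim = dim(nii)),
               spacing = as.numeric(RNifti::pixdim(nii)),
               affine = unclass_affine(RNifti::xform(nii)))
}

#' Read a NIfTI file as a binary mask
#'
#' Nonzero voxels map to `TRUE`, zero to `FALSE`. Files containing
#' fractional values strictly between 0 and 1 are rejected: they signal a
#' probability map, which must be thresholded explicitly by the user.
#'
#' @param path path to a NIfTI file.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  nii <- read_nifti_checked(path)
  binary_mask(array(as.numeric(nii), dim = dim(nii)),
              spacing = as.numeric(RNifti::pixdim(nii)),
              affine = unclass_affine(RNifti::xform(nii)))
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) != 3)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  sp <- as.numeric(RNifti::pixdim(nii))
  if (any(sp <= 0)) stop("non-positive voxel spacing in header: ", path)
  if (anyNA(as.vector(nii))) stop("volume contains NaN voxels: ", path)
  nii
}

unclass_affine <- function(xf) {
  m <- unname(matrix(as.numeric(xf), 4, 4))
  attributes(m) <- list(dim = c(4L, 4L))
  m
}

#' Write a binary mask to NIfTI
#'
#' Writes the mask as uint8 0/1 with its spacing in `pixdim` and its
#' affine (or a spacing-diagonal default) in the sform, so that
#' `read_mask(write_mask(m, f))` reproduces the mask voxel-for-voxel and
#' its spacing to header precision.
#'
#' @param mask a [binary_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  write_nifti_with_geometry(arr, mask, path, datatype = "uint8")
}

#' Write an image volume to NIfTI
#'
#' @param volume an [image_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  write_nifti_with_geometry(volume$data, volume, path, datatype = "double")
}

write_nifti_with_geometry <- function(arr, geom, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  attr(arr, "pixdim") <- geom$spacing
  nii <- RNifti::asNifti(arr, datatype = datatype)
  af <- effective_affine(geom)
  nii <- RNifti::`sform<-`(nii, structure(af, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Resample a mask onto a target grid by nearest neighbor
#'
#' Transfers a co-registered mask onto the grid of a target volume. Each
#' output voxel takes the value of the nearest input voxel center under
#' the composed affine map (target voxel -> world -> input voxel).
#' Nearest-neighbor only, so the output stays strictly binary. If the two
#' grids are identical and no affines are stored, the identity transform
#' is used.
#'
#' @param mask a [binary_mask] to resample.
#' @param target an [image_volume] or [binary_mask] defining the output grid.
#' @return A [binary_mask] on the target grid.
#' @export
resample_mask_nearest <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"))
  if (same_grid(mask, target) && is.null(mask$affine) && is.null(target$affine))
    return(binary_mask(mask$data, mask$spacing, NULL))
  if ((is.null(mask$affine) || is.null(target$affine)) && !same_grid(mask, target))
    stop("grids differ and affines are missing; supply affines on both inputs")

  comp <- solve(effective_affine(mask)) %*% effective_affine(target)
  d <- dim(target$data)
  # 0-based voxel index grid of the target
  ii <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  jj <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  kk <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  src <- comp %*% rbind(ii, jj, kk, 1)
  si <- as.integer(round(src[1, ])); sj <- as.integer(round(src[2, ]))
  sk <- as.integer(round(src[3, ]))
  dm <- dim(mask$data)
  inside <- si >= 0L & si < dm[1] & sj >= 0L & sj < dm[2] & sk >= 0L & sk < dm[3]
  out <- logical(prod(d))
  idx <- (si[inside] + 1L) +
    as.numeric(sj[inside]) * dm[1] +
    as.numeric(sk[inside]) * dm[1] * dm[2]
  out[inside] <- mask$data[idx]
  binary_mask(array(out, dim = d), spacing = target$spacing,
              affine = target$affine)
}
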