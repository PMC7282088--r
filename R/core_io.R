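#' @include AllClasses.R
NULL

#' Read a DWI series from NIfTI files
#'
#' Loads the b=0 volume and the three directional high-b volumes for one
#' lesion. All four volumes must share a grid; a mismatch is an error
#' naming the offending volume. Negative voxels are clamped to 0 (noise
#' floor) with a warning reporting the count.
#'
#' @param paths named list or character vector with elements \code{s0},
#'   \code{r}, \code{p}, \code{s} giving the NIfTI file paths.
#' @param bHigh b-value of the directional volumes (s/mm^2).
#' @param spacing voxel spacing (dx, dy, dz) in mm; if \code{NULL}, taken
#'   from the NIfTI header of the b=0 volume.
#' @param lesionId identifier carried through the pipeline.
#' @return A [DWISeries-class].
#' @export
readDWISeries <- function(paths, bHigh = 800, spacing = NULL,
                          lesionId = "lesion") {
  need <- c("s0", DIRECTIONS)
  if (!all(need %in% names(paths)))
    stop("paths must name volumes 's0', 'r', 'p' and 's'; missing: ",
         paste(setdiff(need, names(paths)), collapse = ", "))
  vols <- lapply(need, function(k) {
    img <- RNifti::readNifti(paths[[k]])
    arr <- array(as.numeric(img), dim = dim(img))
    attr(arr, "pixdim") <- RNifti::pixdim(img)
    arr
  })
  names(vols) <- need
  ref <- dim(vols$s0)
  for (k in DIRECTIONS)
    if (!identical(dim(vols[[k]]), ref))
      stop(sprintf("volume '%s' has shape %s, expected %s", k,
                   paste(dim(vols[[k]]), collapse = "x"),
                   paste(ref, collapse = "x")))
  if (is.null(spacing)) spacing <- attr(vols$s0, "pixdim")[1:3]
  for (k in need) attr(vols[[k]], "pixdim") <- NULL
  DWISeries(s0 = vols$s0, sHigh = vols[DIRECTIONS], bHigh = bHigh,
            spacing = spacing, lesionId = lesionId)
}

#' Write / read scalar volumes as NIfTI
#'
#' Volumes are stored as 32-bit float NIfTI with the voxel spacing in the
#' header; the round trip is lossless to single precision.
#'
#' @param vol 3D numeric array.
#' @param path output \code{.nii} / \code{.nii.gz} path.
#' @param spacing voxel spacing (dx, dy, dz), mm.
#' @return \code{writeVolume} returns \code{path} invisibly;
#'   \code{readVolume} returns the array with a \code{"spacing"} attribute.
#' @export
writeVolume <- function(vol, path, spacing = c(1.25, 1.25, 2.5)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)
  arr
}

#' Write / read binary masks as NIfTI
#'
#' Masks are stored as unsigned 8-bit \{0, 1\} NIfTI; the round trip is
#' bit-exact. Reading a file whose payload is not binary is an error.
#'
#' @param mask logical matrix or 3D logical array.
#' @param path output path.
#' @param spacing voxel spacing in mm (length 2 for 2D, 3 for 3D masks).
#' @return \code{writeMask} returns \code{path} invisibly; \code{readMask}
#'   returns a logical array (2D masks come back as matrices).
#' @export
writeMask <- function(mask, path, spacing = NULL) {
  if (!(is.logical(mask) || all(mask %in% c(0, 1))))
    stop("mask must be binary")
  arr <- array(as.integer(mask), dim = dim(mask))
  if (is.null(spacing)) spacing <- rep(1, length(dim(mask)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.numeric(img)
  if (!all(vals %in% c(0, 1)))
    stop("file does not contain a binary mask: ", path)
  array(vals > 0, dim = dim(img))
}

#' Read / write a cohort table
#'
#' The cohort table is a plain data frame with one row per lesion x reader:
#' columns \code{lesion_id}, \code{reader_id}, \code{label}
#' (benign/malignant), \code{field_strength}, optionally
#' \code{roi_area_cm2} (index-slice ROI area used by [filterCohort()]) and
#' path columns referencing volumes/masks on disk. \code{lesion_id} x
#' \code{reader_id} pairs must be unique.
#'
#' @param path CSV file path.
#' @param cohort data frame to write.
#' @return \code{readCohort} returns the validated data frame.
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateCohort(df)
  df
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  validateCohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

validateCohort <- function(df) {
  need <- c("lesion_id", "reader_id", "label")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("lesion_id", "reader_id")]))
    stop("lesion_id x reader_id pairs must be unique")
  if (nrow(df) && !all(df$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  invisible(TRUE)
}

#' Physical area of a 2D mask
#'
#' @param mask logical matrix.
#' @param spacing in-plane pixel spacing (dx, dy) in mm.
#' @param units \code{"mm2"} or \code{"cm2"}.
#' @return Pixel count times pixel area, in the requested units.
#' @export
maskArea <- function(mask, spacing = c(1.25, 1.25), units = c("mm2", "cm2")) {
  units <- match.arg(units)
  a <- sum(mask) * spacing[1] * spacing[2]
  if (units == "cm2") a / 100 else a
}
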