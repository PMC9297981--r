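#' Construct a 3D HU volume
#'
#' A `cbct_volume` is a 3D scalar grid of Hounsfield units with isotropic
#' spacing, an origin (world coordinate of the center of voxel `[1,1,1]`), and
#' optionally a voxelwise tissue label map with a code table.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing voxel edge length in mm (isotropic).
#' @param origin numeric length-3, mm offset of the first voxel center.
#' @param labels optional integer array of tissue codes, same shape as
#'   `values`.
#' @param label_table optional named integer vector mapping tissue name to
#'   code; required when `labels` is given.
#' @return an object of class `cbct_volume`.
#' @export
cbct_volume <- function(values, spacing = 1, origin = c(0, 0, 0),
                        labels = NULL, label_table = NULL) {
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.null(labels)) {
    if (!identical(dim(labels), dim(values)))
      stop("'labels' must have the same shape as 'values'")
    if (is.null(label_table)) stop("'label_table' required with 'labels'")
    if (!all(unique(as.vector(labels)) %in% label_table))
      stop("every label code must appear in 'label_table'")
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 labels = labels, label_table = label_table),
            class = "cbct_volume")
}

#' @export
dim.cbct_volume <- function(x) dim(x$values)

#' @export
print.cbct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cbct_volume> %d x %d x %d voxels @ %.3g mm, HU range [%.0f, %.0f]%s\n",
              d[1], d[2], d[3], x$spacing, min(x$values), max(x$values),
              if (is.null(x$labels)) "" else sprintf(", %d tissue labels",
                                                    length(x$label_table))))
  invisible(x)
}

#' Write a volume to NIfTI
#'
#' Writes the HU grid (and, when present, the label map as a sibling
#' `<stem>_labels.nii.gz`) with the voxel spacing recorded in the header.
#'
#' @param v a [cbct_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$values, pixdim = rep(v$spacing, 3))
  RNifti::writeNifti(img, path)
  if (!is.null(v$labels)) {
    lpath <- sub("(\\.nii(\\.gz)?)$", "_labels\\1", path)
    RNifti::writeNifti(RNifti::asNifti(v$labels + 0L,
                                       pixdim = rep(v$spacing, 3)), lpath)
  }
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path path to a NIfTI file written by [write_volume()] or any
#'   HU-valued NIfTI volume.
#' @param labels_path optional path to a parallel integer label volume.
#' @param label_table named integer vector decoding `labels_path`.
#' @return a [cbct_volume].
#' @export
read_volume <- function(path, labels_path = NULL, label_table = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1]
  labs <- NULL
  if (!is.null(labels_path)) {
    labs <- array(as.integer(RNifti::readNifti(labels_path)),
                  dim = dim(img))
  }
  cbct_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
              labels = labs, label_table = label_table)
}
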