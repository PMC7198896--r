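#' Label volume container
#'
#' A 3D integer label image with voxel spacing, an optional voxel-to-world
#' affine, and a tag recording whether it lives in native (subject) or
#' template space. Background is always label 0.
#'
#' @param data 3D array of non-negative integer labels.
#' @param spacing numeric length-3, mm per axis (strictly positive).
#' @param affine optional 4x4 voxel-to-world matrix.
#' @param space_tag `"native"` or `"template"`.
#' @return An object of class `cbp_label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         space_tag = c("native", "template")) {
  space_tag <- match.arg(space_tag)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing, affine = affine,
                 space_tag = space_tag),
            class = "cbp_label_volume")
}

#' @export
print.cbp_label_volume <- function(x, ...) {
  cat("<cbp_label_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, space ", x$space_tag, "\n", sep = "")
  labs <- sort(unique(as.vector(x$data)))
  cat("  labels: ", paste(utils::head(labs, 12), collapse = " "),
      if (length(labs) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a 3D label volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D integer
#'   label image.
#' @param space_tag space tag to attach (`"native"` or `"template"`).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, space_tag = "native") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D volume: ", path, " has ", length(dim(img)), " dimensions")
  arr <- array(as.vector(img), dim = dim(img))
  if (any(abs(arr - round(arr)) > 1e-8))
    stop("expected integer label data in ", path,
         "; found non-integer values (not rounding silently)")
  arr <- round(arr)
  spacing <- RNifti::pixdim(img)[1:3]
  label_volume(arr, spacing = spacing,
               affine = structure(RNifti::xform(img), class = NULL),
               space_tag = space_tag)
}

#' Write a label volume to NIfTI
#'
#' Labels are stored in the smallest integer type that holds the maximum
#' label.
#'
#' @param vol a [label_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cbp_label_volume"))
  maxlab <- max(vol$data)
  dtype <- if (maxlab <= 255L) "uint8" else if (maxlab <= 32767L) "int16" else "int32"
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Seed-voxel coordinate list
#'
#' The ordered list of voxel coordinates of a seed mask. The order is
#' canonical: every connectivity-matrix row is aligned to it. Coordinates
#' are 0-based (x, y, z) triples in raster order (x fastest, z slowest).
#'
#' @param coords integer matrix with 3 columns (x, y, z), 0-based.
#' @param reference_shape integer length-3 extent of the volume the
#'   coordinates index into.
#' @return Object of class `cbp_coords`.
#' @export
voxel_coords <- function(coords, reference_shape) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  reference_shape <- as.integer(reference_shape)
  stopifnot(length(reference_shape) == 3L)
  if (nrow(coords)) {
    if (any(coords < 0) ||
        any(coords >= matrix(reference_shape, nrow(coords), 3, byrow = TRUE)))
      stop("coordinates out of the reference shape")
    if (anyDuplicated(coords)) stop("duplicate voxel coordinates")
  }
  structure(list(coords = coords, reference_shape = reference_shape),
            class = "cbp_coords")
}

#' @export
print.cbp_coords <- function(x, ...) {
  cat("<cbp_coords> ", nrow(x$coords), " voxels in a ",
      paste(x$reference_shape, collapse = "x"), " grid (0-based)\n", sep = "")
  invisible(x)
}

#' Convert a binary mask to an ordered coordinate list
#'
#' Foreground voxels are listed in raster order: x varies fastest, z
#' slowest, 0-based. This order is the canonical seed order used by every
#' connectivity-matrix row.
#'
#' @param mask a [label_volume()] whose labels are all 0 or 1.
#' @return A [voxel_coords()] list.
#' @export
mask_to_coords <- function(mask) {
  stopifnot(inherits(mask, "cbp_label_volume"))
  if (!all(mask$data %in% c(0L, 1L)))
    stop("mask is not binary: labels must all be 0 or 1")
  idx <- which(mask$data == 1L, arr.ind = TRUE)   # column-major = raster order
  coords <- idx - 1L
  colnames(coords) <- c("x", "y", "z")
  voxel_coords(coords, dim(mask$data))
}

#' Paint a coordinate list back into a binary mask
#'
#' Inverse of [mask_to_coords()].
#'
#' @param coords a [voxel_coords()] list.
#' @param spacing voxel spacing for the resulting volume.
#' @return A binary [label_volume()].
#' @export
coords_to_mask <- function(coords, spacing = c(1, 1, 1)) {
  stopifnot(inherits(coords, "cbp_coords"))
  arr <- array(0L, dim = coords$reference_shape)
  if (nrow(coords$coords)) arr[coords$coords + 1L] <- 1L
  label_volume(arr, spacing = spacing)
}

#' Write a coordinate list as plain text
#'
#' One line per voxel: three 0-based integers separated by single spaces,
#' no header.
#'
#' @param coords a [voxel_coords()] list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coords_text <- function(coords, path) {
  stopifnot(inherits(coords, "cbp_coords"))
  lines <- apply(coords$coords, 1L, paste, collapse = " ")
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read a plain-text coordinate list
#'
#' @param path text file written by [write_coords_text()].
#' @param reference_shape length-3 extent the coordinates index into.
#' @return A [voxel_coords()] list.
#' @export
read_coords_text <- function(path, reference_shape) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(voxel_coords(matrix(integer(0), 0, 3), reference_shape))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 3L))
    stop("coordinate file must have exactly 3 integers per line")
  m <- matrix(as.integer(unlist(parts)), ncol = 3, byrow = TRUE)
  voxel_coords(m, reference_shape)
}

#' Read a multi-ROI batch list file
#'
#' Each non-empty, non-comment row describes one region of interest to
#' parcellate, with whitespace-separated fields in the order: data
#' directory, subject-list file, working directory, ROI name, and maximum
#' number of clusters K. Lines starting with `#` are skipped.
#'
#' @param path batch list file (TXT).
#' @return A data.frame with columns `data_dir`, `subject_list`,
#'   `working_dir`, `roi_name`, `max_clusters`.
#' @export
read_roi_batch <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- which(keep)
  if (!length(rows))
    return(data.frame(data_dir = character(0), subject_list = character(0),
                      working_dir = character(0), roi_name = character(0),
                      max_clusters = integer(0), stringsAsFactors = FALSE))
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5L)
      stop("row ", i, ": expected 5 fields (data_dir subject_list ",
           "working_dir roi_name max_clusters), got ", length(f))
    k <- suppressWarnings(as.integer(f[5]))
    if (is.na(k)) stop("row ", i, ": max_clusters is not an integer: ", f[5])
    if (k < 2L) stop("row ", i, ": max_clusters must be >= 2, got ", k)
    data.frame(data_dir = f[1], subject_list = f[2], working_dir = f[3],
               roi_name = f[4], max_clusters = k, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(rows, parse_row))
}
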