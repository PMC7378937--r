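#' Write / read a 4D dataset as NIfTI-1
#'
#' Images are written with the phantom voxel size (1 x 1 x 5 mm by default)
#' in the affine; the data array round-trips bit-identically.
#'
#' @param data 4D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm triple.
#' @return \code{read_nifti_dataset} returns the 4D array (with pixel
#'   dimensions in attribute \code{voxel_size}).
#' @export
write_nifti_dataset <- function(data, path, voxel_size = c(1, 1, 5)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(data)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_dataset
#' @export
read_nifti_dataset <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  out
}

#' Read a 4D dataset together with its protocol, with validation
#'
#' @param image_path NIfTI path of the 4D series.
#' @param protocol_path JSON protocol path.
#' @return list with \code{data} (4D array) and \code{protocol}.
#' @export
read_qmri_data <- function(image_path, protocol_path) {
  data <- read_nifti_dataset(image_path)
  protocol <- protocol_from_json(protocol_path)
  if (length(dim(data)) != 4L) stop("expected a 4D image")
  if (dim(data)[4] != nrow(protocol)) {
    stop(sprintf("protocol has %d measurements but image has %d volumes",
                 nrow(protocol), dim(data)[4]))
  }
  list(data = data, protocol = protocol)
}

#' Persist / load a phantom
#'
#' The phantom is stored as plain files in a directory: volume fraction maps
#' as one 4D NIfTI (vWM, vGM, vCSF), each tissue's per-voxel parameter maps
#' as a 4D NIfTI, and a JSON sidecar with the seed, the grid metadata and
#' the fixed CSF parameters. The round trip reproduces all parameters
#' exactly (within float64 serialisation).
#'
#' @param phantom an \code{sc_phantom}.
#' @param dir directory to create/write.
#' @return \code{phantom_load} returns an \code{sc_phantom}.
#' @export
phantom_save <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- phantom$fractions
  dims <- fr$grid_shape
  fracs <- array(c(fr$vWM, fr$vGM, fr$vCSF), dim = c(dims, 3L))
  write_nifti_dataset(fracs, file.path(dir, "fractions.nii.gz"),
                      fr$voxel_size)
  for (tis in c("wm", "gm")) {
    par <- phantom[[paste0(tis, "_params")]]
    cols <- setdiff(names(par), "voxel")
    maps <- array(NA_real_, dim = c(dims, length(cols)))
    for (j in seq_along(cols)) {
      m <- array(NA_real_, dims)
      m[par$voxel] <- par[[cols[j]]]
      maps[, , , j] <- m
    }
    write_nifti_dataset(maps, file.path(dir, paste0(tis, "_params.nii.gz")),
                        fr$voxel_size)
  }
  jsonlite::write_json(list(
    seed = phantom$seed, geometry_seed = fr$seed, grid_shape = dims,
    voxel_size = fr$voxel_size,
    param_names = setdiff(names(phantom$wm_params), "voxel"),
    csf_params = as.list(phantom$csf_params)
  ), file.path(dir, "phantom.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname phantom_save
#' @export
phantom_load <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "phantom.json"))
  fracs <- read_nifti_dataset(file.path(dir, "fractions.nii.gz"))
  dims <- dim(fracs)[1:3]
  fr <- structure(list(
    grid_shape = dims, voxel_size = as.numeric(meta$voxel_size),
    vWM = fracs[, , , 1], vGM = fracs[, , , 2], vCSF = fracs[, , , 3],
    cord_mask = (fracs[, , , 1] + fracs[, , , 2]) > 0,
    seed = as.integer(meta$geometry_seed)
  ), class = "vol_fractions")
  read_par <- function(tis) {
    maps <- read_nifti_dataset(file.path(dir, paste0(tis, "_params.nii.gz")))
    idx <- which(!is.na(maps[, , , 1]))
    par <- as.data.frame(lapply(seq_along(meta$param_names), function(j) {
      m <- maps[, , , j]
      m[idx]
    }))
    names(par) <- meta$param_names
    par$voxel <- idx
    par
  }
  csf <- as.data.frame(meta$csf_params)
  structure(list(fractions = fr, wm_params = read_par("wm"),
                 gm_params = read_par("gm"), csf_params = csf,
                 seed = as.integer(meta$seed)), class = "sc_phantom")
}
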