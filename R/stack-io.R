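#' Multi-channel 3D image stack
#'
#' The package's in-memory container for a confocal acquisition: one 3D voxel
#' grid per channel, physical voxel spacing, and channel-role labels. Roles
#' name what each stain marks: `nuclei` (DAPI), `zo1` (tight junctions),
#' `laminin` (basement membrane), `nakatpase` (basolateral pump membranes),
#' `tubulin` (acetylated tubulin, primary cilia). A 2D widefield image is a
#' stack with a single z-plane.
#'
#' @param voxels named list of 3D numeric arrays, one per channel, each with
#'   dim `(y, x, z)`; names are the channel roles. z index 1 is the
#'   basal-most plane.
#' @param voxel_size numeric `(dz, dy, dx)` in micrometres.
#' @param bit_depth 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, bit_depth = 16) {
  stopifnot(is.list(voxels), length(voxels) >= 1, !is.null(names(voxels)))
  roles <- names(voxels)
  if (anyDuplicated(roles)) stop("channel roles must be unique", call. = FALSE)
  dims <- lapply(voxels, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      length(unique(dims)) != 1L) {
    stop("all channels must be 3D arrays of identical dimensions",
         call. = FALSE)
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive (dz, dy, dx) in um", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(
    list(voxels = voxels,
         voxel_size = stats::setNames(as.numeric(voxel_size),
                                      c("dz", "dy", "dx")),
         channel_roles = roles, bit_depth = bit_depth),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d x %d x %d (y,x,z), voxel %.3g x %.3g x %.3g um (dz,dy,dx), %d-bit\n",
    length(x$voxels), paste(x$channel_roles, collapse = ", "),
    d[1], d[2], d[3], x$voxel_size["dz"], x$voxel_size["dy"],
    x$voxel_size["dx"], x$bit_depth))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels[[1]])

#' Extract one channel of a stack
#'
#' @param stack an [image_stack()].
#' @param role channel role name.
#' @return 3D numeric array `(y, x, z)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% stack$channel_roles) {
    stop("channel role `", role, "` not present in stack (has: ",
         paste(stack$channel_roles, collapse = ", "), ")", call. = FALSE)
  }
  stack$voxels[[role]]
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Stacks are stored as plain multi-page TIFF (pages ordered channel-major:
#' all z-planes of channel 1, then channel 2, ...) with a JSON sidecar
#' (`<path>.json`) carrying the acquisition metadata a reader needs: voxel
#' spacing in micrometres, channel roles, array shape and bit depth.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path (`.tif`); the sidecar is written next to it.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxdn <- 2^stack$bit_depth - 1
  pages <- list()
  for (role in stack$channel_roles) {
    arr <- stack$voxels[[role]]
    for (k in seq_len(dim(arr)[3])) {
      pages[[length(pages) + 1L]] <- pmin(pmax(arr[, , k] / maxdn, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(voxel_size_um = as.list(stack$voxel_size),
               channel_roles = stack$channel_roles,
               shape_yxz = dim(stack$voxels[[1]]),
               bit_depth = stack$bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maxdn <- 2^meta$bit_depth - 1
  d <- meta$shape_yxz
  voxels <- list()
  i <- 0L
  for (role in meta$channel_roles) {
    arr <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      i <- i + 1L
      arr[, , k] <- round(pages[[i]] * maxdn)
    }
    voxels[[role]] <- arr
  }
  image_stack(voxels,
              voxel_size = unlist(meta$voxel_size_um),
              bit_depth = meta$bit_depth)
}
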