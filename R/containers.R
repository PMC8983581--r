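#' Image stack container
#'
#' A minimal in-memory container for a multi-channel 3-D fluorescence
#' stack. Voxels are stored as a 4-D array in channel-z-y-x order with
#' explicit physical voxel sizes in micrometres; all package geometry is
#' anisotropy-aware through `voxel_size`. Coordinates are voxel-centred
#' and 0-based internally; physical positions are `(index) * voxel_size`.
#'
#' @param voxels numeric array, dim `c(channels, nz, ny, nx)` (a 3-D
#'   array is promoted to a single channel). Intensities must be
#'   non-negative.
#' @param voxel_size numeric length 3, `(z, y, x)` spacing in um, all > 0.
#' @param channel_names character vector, one name per channel. Defaults
#'   to `"protein"`, `"dna"` for two channels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, channel_names = NULL) {
  if (length(dim(voxels)) == 3L) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  stopifnot(length(dim(voxels)) == 4L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive (z, y, x) spacings in um")
  }
  if (any(voxels < 0)) stop("intensities must be non-negative")
  nc <- dim(voxels)[1]
  if (is.null(channel_names)) {
    channel_names <- if (nc == 2L) c("protein", "dna") else paste0("ch", seq_len(nc))
  }
  stopifnot(length(channel_names) == nc)
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d (z,y,x), voxel %s um\n",
              d[1], paste(x$channel_names, collapse = ", "),
              d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Extract one channel of an image stack as a 3-D array
#'
#' @param stack an [image_stack].
#' @param channel channel index or name.
#' @return numeric 3-D array, dim `(nz, ny, nx)`.
#' @export
stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(stack$voxels)
  array(stack$voxels[channel, , , ], dim = d[2:4])
}

#' Label volume container
#'
#' Integer region labels (0 = background) aligned with an
#' [image_stack]: either nuclei or puncta, as recorded in `kind`.
#'
#' @param labels integer 3-D array `(nz, ny, nx)`; non-negative.
#' @param voxel_size `(z, y, x)` spacing in um.
#' @param kind `"nuclei"` or `"puncta"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, kind = c("nuclei", "puncta")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(labels)) == 3L, all(labels >= 0))
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size), kind = kind),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(setdiff(unique(as.integer(x$labels)), 0L))
  cat(sprintf("<label_volume> kind=%s, %d object(s), dim %s\n",
              x$kind, n, paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Number of labelled objects in a label volume
#' @param labels a [label_volume].
#' @return integer count of distinct positive labels.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  length(setdiff(unique(as.integer(labels$labels)), 0L))
}

# volume of one voxel in um^3
voxel_volume <- function(voxel_size) prod(voxel_size)

check_aligned <- function(labels, stack) {
  if (!all(dim(labels$labels) == dim(stack$voxels)[2:4])) {
    stop("label volume and stack shapes differ")
  }
  invisible(TRUE)
}
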