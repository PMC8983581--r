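# Stack and table I/O. Stacks are written as multi-plane 32-bit float
# TIFFs (channel-fastest plane order, "XYCZT") with an OME-style
# companion XML sidecar carrying dimensions, channel names, physical
# voxel sizes and the intensity scale (TIFF floats are stored in [0, 1],
# so intensities are divided by a recorded scale on write and restored on
# read).

companion_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".companion.ome.xml")
}

#' Write an image stack to TIFF with voxel-size metadata
#'
#' @param stack an [image_stack].
#' @param path output TIFF path; a companion `*.companion.ome.xml`
#'   metadata file is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  planes <- vector("list", d[1] * d[2])
  k <- 0L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {   # channel varies fastest (XYCZT)
      k <- k + 1L
      planes[[k]] <- matrix(stack$voxels[ch, z, , ] / scale, nrow = d[3], ncol = d[4])
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)

  root <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(root, "Image", Name = basename(path))
  px <- xml2::xml_add_child(
    img, "Pixels",
    DimensionOrder = "XYCZT", Type = "float",
    SizeC = as.character(d[1]), SizeZ = as.character(d[2]),
    SizeY = as.character(d[3]), SizeX = as.character(d[4]), SizeT = "1",
    PhysicalSizeZ = format(stack$voxel_size[1], digits = 12),
    PhysicalSizeY = format(stack$voxel_size[2], digits = 12),
    PhysicalSizeX = format(stack$voxel_size[3], digits = 12)
  )
  for (ch in seq_len(d[1])) {
    xml2::xml_add_child(px, "Channel", ID = as.character(ch - 1L),
                        Name = stack$channel_names[ch])
  }
  xml2::xml_add_child(img, "IntensityScale",
                      Value = format(scale, digits = 17))
  xml2::write_xml(root, companion_path(path))
  invisible(path)
}

parse_physical_sizes <- function(xml) {
  px <- xml2::xml_find_first(xml, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  getnum <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(
    voxel_size = c(getnum("PhysicalSizeZ"), getnum("PhysicalSizeY"),
                   getnum("PhysicalSizeX")),
    size_c = getnum("SizeC"), size_z = getnum("SizeZ"),
    channels = xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  )
}

#' Read an image stack from TIFF / OME-TIFF
#'
#' Reads a multi-plane TIFF into channel-z-y-x order. Voxel sizes come
#' from (in order of priority) an explicit override, the companion
#' OME-style XML sidecar written by [write_stack()], or an OME
#' ImageDescription embedded in the TIFF by another writer. The override
#' always wins, with a notice.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional `(z, y, x)` spacing in um.
#' @param n_channels channel count, used only when no metadata states it
#'   (plain TIFFs); default 1.
#' @return an [image_stack].
#' @export
read_stack <- function(path, voxel_size_override = NULL, n_channels = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  if (!is.list(planes)) planes <- list(planes)

  meta <- NULL
  scale <- 1
  cp <- companion_path(path)
  if (file.exists(cp)) {
    xml <- xml2::read_xml(cp)
    meta <- parse_physical_sizes(xml)
    sc <- xml2::xml_attr(xml2::xml_find_first(xml, ".//IntensityScale"), "Value")
    if (!is.na(sc)) scale <- as.numeric(sc)
  } else {
    desc <- attr(planes[[1]], "description")
    if (!is.null(desc) && nzchar(desc) && grepl("PhysicalSize", desc)) {
      meta <- tryCatch(parse_physical_sizes(xml2::read_xml(desc)),
                       error = function(e) NULL)
    }
  }

  voxel_size <- if (!is.null(meta)) meta$voxel_size else NULL
  if (!is.null(voxel_size_override)) {
    if (!is.null(voxel_size)) {
      message("voxel_size_override supplied; ignoring metadata voxel size")
    }
    voxel_size <- voxel_size_override
  }
  if (is.null(voxel_size) || anyNA(voxel_size)) {
    stop("no voxel size in metadata and no voxel_size_override given")
  }

  nc <- if (!is.null(meta) && !is.na(meta$size_c)) as.integer(meta$size_c) else as.integer(n_channels)
  np <- length(planes)
  if (np %% nc != 0) stop("plane count is not a multiple of the channel count")
  nz <- np %/% nc
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  vox <- array(0, dim = c(nc, nz, ny, nx))
  k <- 0L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      k <- k + 1L
      pl <- planes[[k]]
      if (length(dim(pl)) == 3L) pl <- pl[, , 1]  # grey stored with samples dim
      vox[ch, z, , ] <- pl * scale
    }
  }
  nm <- if (!is.null(meta) && length(meta$channels) == nc && !anyNA(meta$channels)) {
    meta$channels
  } else NULL
  image_stack(vox, voxel_size, nm)
}

#' Write per-punctum / per-nucleus record tables as CSV
#'
#' Missing metrics (e.g. K_p for a zero-punctum nucleus) are written as
#' empty fields, never as 0, so downstream summaries can apply the
#' include/exclude-zero-punctum conventions faithfully.
#'
#' @param records a data.frame (may have zero rows if `empty_ok`).
#' @param path output CSV path.
#' @param empty_ok allow writing a header-only file for empty record
#'   lists.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path, empty_ok = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0 && !empty_ok) {
    stop("record list is empty; pass empty_ok = TRUE to write a header-only file")
  }
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a table written by [write_tables()]
#' @param path CSV path.
#' @return data.frame; empty fields become `NA`.
#' @export
read_tables <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
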