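#' Calibrated multi-channel 3D image stack
#'
#' Container for confocal z-stack data: a 4-D intensity array indexed
#' `(channel, z, y, x)`, the physical voxel spacing in micrometres, and a
#' biological role for every channel. All volumetric quantification in the
#' package runs on this object; conversions from voxel counts to cubic
#' micrometres use `prod(spacing)`.
#'
#' @param voxels 4-D numeric array with dimensions `(channel, z, y, x)`.
#'   Intensities must be finite and non-negative.
#' @param spacing Numeric length-3 vector: physical size of one voxel along
#'   `(z, y, x)` in micrometres; all entries strictly positive.
#' @param channel_roles Character vector, one entry per channel, each one of
#'   `"TH"`, `"GLIA_IBA1"`, `"GLIA_GFAP"`, `"NUCLEAR"`, `"OTHER"`.
#'
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `spacing` and `channel_roles`.
#' @examples
#' vox <- array(0L, dim = c(1, 4, 8, 8))
#' stk <- image_stack(vox, spacing = c(1, 0.5, 0.5), channel_roles = "TH")
#' dim(stk$voxels)
#' @export
image_stack <- function(voxels, spacing, channel_roles) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    abort("`voxels` must be a 4-D array with dimensions (channel, z, y, x)")
  if (!is.numeric(voxels))
    abort("`voxels` must be numeric")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    abort("intensities must be finite")
  if (any(voxels < 0))
    abort("intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    abort("`spacing` must be 3 strictly positive values (z, y, x) in um")
  nchan <- dim(voxels)[1]
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != nchan)
    abort(sprintf("`channel_roles` must name all %d channels", nchan))
  bad <- setdiff(channel_roles, CHANNEL_ROLES)
  if (length(bad))
    abort(sprintf("unknown channel role(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(voxels = voxels, spacing = spacing, channel_roles = channel_roles),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d z x %d y x %d x voxels, spacing (%g, %g, %g) um\n",
    d[1], paste(x$channel_roles, collapse = ", "), d[2], d[3], d[4],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack An [image_stack()].
#' @param role Channel role to extract (e.g. `"TH"`). The first channel
#'   carrying that role is returned.
#' @return 3-D array `(z, y, x)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  idx <- match(role, stack$channel_roles)
  if (is.na(idx))
    abort(sprintf("stack has no channel with role '%s'", role))
  arr <- stack$voxels[idx, , , , drop = FALSE]
  array(arr, dim = dim(stack$voxels)[-1])
}

#' Voxel volume of a stack in cubic micrometres
#' @param spacing Length-3 spacing vector `(z, y, x)` in um, or an
#'   [image_stack()].
#' @return Scalar um^3 per voxel.
#' @export
voxel_volume <- function(spacing) {
  if (inherits(spacing, "image_stack")) spacing <- spacing$spacing
  prod(as.numeric(spacing))
}

# ---- TIFF reading --------------------------------------------------------

parse_description <- function(desc) {
  out <- list(spacing = NULL, channels = NULL, slices = NULL, roles = NULL)
  if (is.null(desc) || !nzchar(desc)) return(out)
  if (grepl("<OME", desc, fixed = TRUE)) {
    px <- tryCatch({
      doc <- xml2::read_xml(desc)
      xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
    }, error = function(e) NULL)
    if (!is.null(px) && !inherits(px, "xml_missing")) {
      a <- function(n) {
        v <- xml2::xml_attr(px, n)
        if (is.na(v)) NULL else as.numeric(v)
      }
      sz <- a("PhysicalSizeZ"); sy <- a("PhysicalSizeY"); sx <- a("PhysicalSizeX")
      if (!is.null(sz) && !is.null(sy) && !is.null(sx))
        out$spacing <- c(sz, sy, sx)
      out$channels <- a("SizeC")
      out$slices <- a("SizeZ")
    }
    return(out)
  }
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- regmatches(lines, regexec("^([A-Za-z]+)=(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  getv <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else vals[i]
  }
  psz <- getv("PhysicalSizeZ"); psy <- getv("PhysicalSizeY"); psx <- getv("PhysicalSizeX")
  if (!is.null(psz) && !is.null(psy) && !is.null(psx)) {
    out$spacing <- as.numeric(c(psz, psy, psx))
  } else if (!is.null(getv("spacing"))) {
    out$spacing <- c(as.numeric(getv("spacing")), NA, NA)  # z only (ImageJ)
  }
  if (!is.null(getv("channels"))) out$channels <- as.numeric(getv("channels"))
  if (!is.null(getv("slices"))) out$slices <- as.numeric(getv("slices"))
  if (!is.null(getv("ChannelRoles")))
    out$roles <- strsplit(getv("ChannelRoles"), ",", fixed = TRUE)[[1]]
  out
}

#' Read a calibrated multi-channel TIFF / OME-TIFF stack
#'
#' Pages are interpreted in hyperstack order with channel fastest: page
#' `(z - 1) * n_channels + c` holds channel `c` of slice `z`. Voxel spacing is
#' taken from embedded metadata (OME `PhysicalSizeX/Y/Z`, or the
#' ImageJ-style/plain-text description written by [write_stack()]); when the
#' file carries none, `spacing_override` must be supplied — the reader never
#' silently assumes a default calibration, because every volume in the
#' pipeline is reported in um^3.
#'
#' @param path Path to a TIFF file whose pages all share one shape.
#' @param spacing_override Optional `(z, y, x)` spacing in um used when the
#'   file has no usable spacing metadata (and overriding it when given).
#' @param channel_roles Character vector of roles, one per channel. May be
#'   omitted when the file itself records roles (files from [write_stack()]).
#' @param n_channels Number of channels; inferred from metadata when absent,
#'   else from `length(channel_roles)`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL, channel_roles = NULL,
                       n_channels = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    abort("inconsistent plane shapes across TIFF pages")
  if (length(dim(pages[[1]])) != 2L)
    abort("expected single-sample (grayscale) planes")

  desc <- attr(pages[[1]], "description")
  meta <- parse_description(desc)

  nchan <- n_channels %||% meta$channels %||%
    (if (!is.null(channel_roles)) length(channel_roles) else 1L)
  nchan <- as.integer(nchan)
  if (length(pages) %% nchan != 0L)
    abort(sprintf("page count %d is not a multiple of %d channels",
                  length(pages), nchan))
  nz <- length(pages) %/% nchan

  spacing <- spacing_override
  if (is.null(spacing)) {
    spacing <- meta$spacing
    if (!is.null(spacing) && anyNA(spacing)) {
      # ImageJ files store z spacing in the description and x/y in the
      # resolution tags (pixels per unit)
      xres <- attr(pages[[1]], "x.resolution")
      yres <- attr(pages[[1]], "y.resolution") %||% xres
      if (!is.null(xres) && is.finite(xres) && xres > 0)
        spacing <- c(spacing[1], 1 / yres, 1 / xres)
    }
  }
  if (is.null(spacing) || anyNA(spacing))
    abort(paste0("no voxel spacing in file metadata and no `spacing_override` ",
                 "given; refusing to guess a calibration"))

  roles <- channel_roles %||% meta$roles
  if (is.null(roles))
    abort("no channel roles in file metadata; pass `channel_roles`")
  if (length(roles) != nchan)
    abort("channel role mapping does not match the number of channels")

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0L, dim = c(nchan, nz, ny, nx))
  for (z in seq_len(nz)) {
    for (ch in seq_len(nchan)) {
      vox[ch, z, , ] <- pages[[(z - 1L) * nchan + ch]]
    }
  }
  image_stack(vox, spacing = spacing, channel_roles = roles)
}

# ---- TIFF writing --------------------------------------------------------

# Minimal baseline TIFF writer: uncompressed, 16-bit grayscale, one strip per
# page, little-endian, with an ImageDescription tag on the first page carrying
# the calibration. The installed TIFF bindings cannot write description tags,
# and the calibration must live inside the file, so this subset is written
# directly; tiff::readTIFF reads the result back (see read_stack).
write_tiff16 <- function(pages, path, description) {
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]]); np <- length(pages)
  draw <- c(charToRaw(description), as.raw(0))
  ld <- length(draw)                       # ASCII tag count incl. the NUL
  if (length(draw) %% 2L == 1L) draw <- c(draw, as.raw(0))  # even file layout
  ldpad <- length(draw)
  psize <- nx * ny * 2L
  desc_off <- 8L
  strip_off <- function(p) 8L + ldpad + (p - 1L) * psize
  ifd_start <- 8L + ldpad + np * psize
  ifd_size <- function(p) if (p == 1L) 2L + 10L * 12L + 4L else 2L + 9L * 12L + 4L
  ifd_off <- function(p) ifd_start + if (p == 1L) 0L else ifd_size(1L) + (p - 2L) * ifd_size(2L)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_start)
  writeBin(draw, con)
  for (p in seq_len(np)) {
    vals <- as.integer(t(pages[[p]]))
    writeBin(vals, con, size = 2L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (p in seq_len(np)) {
    w2(if (p == 1L) 10L else 9L)
    entry(256L, 4L, 1L, nx)                     # ImageWidth
    entry(257L, 4L, 1L, ny)                     # ImageLength
    entry(258L, 3L, 1L, 16L)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                     # Compression: none
    entry(262L, 3L, 1L, 1L)                     # Photometric: BlackIsZero
    if (p == 1L) entry(270L, 2L, ld, desc_off)  # ImageDescription
    entry(273L, 4L, 1L, strip_off(p))           # StripOffsets
    entry(277L, 3L, 1L, 1L)                     # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                     # RowsPerStrip
    entry(279L, 4L, 1L, psize)                  # StripByteCounts
    w4(if (p < np) ifd_off(p + 1L) else 0L)     # next IFD
  }
  invisible(path)
}

#' Write a stack to a calibrated multi-page TIFF
#'
#' Writes 16-bit grayscale pages in hyperstack order (channel fastest) with
#' the voxel spacing and channel roles embedded in the file's description
#' tag, so `read_stack(write_stack(stack, path))` restores the voxel grid
#' bit-for-bit together with its calibration. Intensities must already be
#' integers in `[0, 65535]`; the writer refuses to quantise silently.
#'
#' @param stack An [image_stack()].
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path)))
    abort(sprintf("directory does not exist: %s", dirname(path)))
  v <- stack$voxels
  if (any(v != round(v)) || any(v > 65535))
    abort("voxels must be integers in [0, 65535] for 16-bit TIFF output")
  d <- dim(v)
  desc <- paste0(
    "ImageJ=1.53t\n",
    sprintf("images=%d\n", d[1] * d[2]),
    sprintf("channels=%d\n", d[1]),
    sprintf("slices=%d\n", d[2]),
    "hyperstack=true\nunit=micron\n",
    sprintf("spacing=%.17g\n", stack$spacing[1]),
    sprintf("PhysicalSizeZ=%.17g\n", stack$spacing[1]),
    sprintf("PhysicalSizeY=%.17g\n", stack$spacing[2]),
    sprintf("PhysicalSizeX=%.17g\n", stack$spacing[3]),
    sprintf("ChannelRoles=%s", paste(stack$channel_roles, collapse = ","))
  )
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      pages[[(z - 1L) * d[1] + ch]] <- matrix(v[ch, z, , ], nrow = d[3], ncol = d[4])
    }
  }
  write_tiff16(pages, path, desc)
  invisible(path)
}

#' Project a stack along z
#'
#' Produces the single-plane representation used for figure-style display:
#' per channel, all z slices are reduced to one by maximum-intensity or sum
#' projection. Quantification in this package always runs on the full 3D
#' stack; the projection exists for visual inspection only.
#'
#' @param stack An [image_stack()] with at least one z slice.
#' @param method `"max"` (default) or `"sum"`.
#' @return An [image_stack()] with a single z slice and unchanged `(y, x)`
#'   spacing.
#' @export
project_stack <- function(stack, method = c("max", "sum")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  d <- dim(stack$voxels)
  out <- array(0, dim = c(d[1], 1L, d[3], d[4]))
  for (ch in seq_len(d[1])) {
    chan <- array(stack$voxels[ch, , , ], dim = d[2:4])
    out[ch, 1, , ] <- apply(chan, c(2, 3), if (method == "max") max else sum)
  }
  if (is.integer(stack$voxels) && method == "max") storage.mode(out) <- "integer"
  image_stack(out, spacing = stack$spacing, channel_roles = stack$channel_roles)
}
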