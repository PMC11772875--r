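# Minimal baseline TIFF 6.0 + OME-XML reader/writer.
#
# The pipeline's canonical on-disk form is an OME-TIFF: uncompressed,
# little-endian, 16-bit unsigned, one strip per plane, planes ordered per the
# OME DimensionOrder (XYZCT as written here: Z fastest, then C, then T), with
# the OME-XML metadata block in the ImageDescription of the first IFD. No
# pre-installed R package reads TIFF in this environment, so the subset the
# pipeline needs is implemented here; anything outside that subset
# (compression, tiles, bit depths other than 8/16) is rejected loudly.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)

#' Write an image stack to OME-TIFF
#'
#' Writes an uncompressed little-endian 16-bit OME-TIFF (axes `TCZYX`,
#' DimensionOrder `XYZCT`) with physical voxel sizes, frame interval and
#' channel roles recorded in the OME-XML header. Intensities are rounded and
#' clipped to the unsigned 16-bit range.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @param ome embed OME-XML metadata (default). With `ome = FALSE` a plain
#'   multi-page TIFF is written: no voxel size, no channel roles - readers
#'   must then supply `metadata_overrides`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, ome = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  nt <- d[1]; nc <- d[2]; nz <- d[3]; ny <- d[4]; nx <- d[5]
  desc_raw <- raw(0)
  if (ome) {
    desc <- ome_xml(stack)
    desc_raw <- c(charToRaw(desc), as.raw(0L))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0L))
  }

  n_planes <- nt * nc * nz
  plane_bytes <- nx * ny * 2
  p0 <- 8 + length(desc_raw)
  ifd0 <- p0 + n_planes * plane_bytes
  entries_first <- if (ome) 11L else 10L
  entries_rest <- 10L
  sz_first <- 2 + entries_first * 12 + 4
  sz_rest <- 2 + entries_rest * 12 + 4

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  writeBin(desc_raw, con)

  # pixel data: planes z-fastest, then c, then t; rows are Y, x fastest
  for (t in seq_len(nt)) for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    pl <- stack$data[t, ch, z, , ]
    dim(pl) <- c(ny, nx)
    v <- as.integer(round(pmin(pmax(as.vector(t(pl)), 0), 65535)))
    v <- v - 65536L * (v > 32767L)  # low 16 bits unchanged
    writeBin(v, con, size = 2, endian = "little")
  }

  w_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3 && count == 1) { # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (p in seq_len(n_planes)) {
    first <- p == 1
    strip_off <- p0 + (p - 1) * plane_bytes
    next_ifd <- if (p == n_planes) 0L else
      ifd0 + sz_first + (p - 1) * sz_rest
    writeBin(as.integer(if (first) entries_first else entries_rest), con,
             size = 2, endian = "little")
    w_entry(256, 4, 1, nx)
    w_entry(257, 4, 1, ny)
    w_entry(258, 3, 1, 16)
    w_entry(259, 3, 1, 1)
    w_entry(262, 3, 1, 1)
    if (first && ome) w_entry(270, 2, length(desc_raw), 8)
    w_entry(273, 4, 1, strip_off)
    w_entry(277, 3, 1, 1)
    w_entry(278, 4, 1, ny)
    w_entry(279, 4, 1, plane_bytes)
    w_entry(339, 3, 1, 1)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

ome_xml <- function(stack) {
  d <- dim(stack$data)
  vz <- stack$voxel_size_um
  ti <- if (is.na(stack$frame_interval_s)) "" else
    sprintf(' TimeIncrement="%.10g" TimeIncrementUnit="s"',
            stack$frame_interval_s)
  chans <- paste0(sprintf(
    '      <Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
    seq_len(d[2]) - 1L, stack$channel_roles), collapse = "\n")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">\n',
    '  <Image ID="Image:0" Name="condensatr">\n',
    sprintf(paste0(
      '    <Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="uint16"',
      ' SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d"',
      ' PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeZ="%.10g"',
      ' PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm"',
      ' PhysicalSizeZUnit="µm"%s>\n'),
      d[5], d[4], d[3], d[2], d[1], vz[3], vz[2], vz[1], ti),
    chans, "\n",
    '      <TiffData/>\n',
    '    </Pixels>\n',
    '  </Image>\n',
    '</OME>')
}

read_tiff_planes <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read '", path, "'")
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 8) stop("'", path, "' is not a TIFF file")
  hdr <- rawToChar(raw[1:2])
  endian <- if (hdr == "II") "little" else if (hdr == "MM") "big" else
    stop("'", path, "' is not a TIFF file")
  rd <- function(off, n, size, signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  magic <- rd(2, 1, 2)
  if (magic != 42) stop("'", path, "' is not a baseline TIFF")
  ifd_off <- rd(4, 1, 4)

  planes <- list()
  desc <- NULL
  width <- height <- NULL
  while (ifd_off != 0) {
    n_ent <- rd(ifd_off, 1, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(eo, 1, 2, signed = FALSE)
      type <- rd(eo + 2, 1, 2)
      count <- rd(eo + 4, 1, 4)
      tsz <- TIFF_TYPE_SIZES[type]
      nbytes <- tsz * count
      voff <- if (nbytes <= 4) eo + 8 else rd(eo + 8, 1, 4)
      val <- switch(as.character(type),
        "2" = {
          b <- raw[(voff + 1):(voff + count)]
          while (length(b) && b[length(b)] == as.raw(0)) b <- b[-length(b)]
          rawToChar(b)
        },
        "3" = rd(voff, count, 2, signed = FALSE),
        "4" = rd(voff, count, 4),
        rd(voff, min(count, 1), min(tsz, 4)))
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    comp <- g(259, 1)
    if (comp != 1) stop("compressed TIFF not supported (compression=", comp,
                        ")")
    bps <- g(258, 1)
    if (!bps %in% c(8, 16)) stop("unsupported bit depth: ", bps)
    if (g(277, 1) != 1) stop("only single-sample planes supported")
    w <- g(256); h <- g(257)
    if (is.null(width)) { width <- w; height <- h }
    if (w != width || h != height) stop("mixed plane sizes not supported")
    if (is.null(desc)) desc <- g(270)
    offs <- g(273); cnts <- g(279, rep(w * h * bps / 8, length(offs)))
    px <- integer(0)
    for (s in seq_along(offs)) {
      nv <- cnts[s] / (bps / 8)
      px <- c(px, readBin(raw[(offs[s] + 1):(offs[s] + cnts[s])], "integer",
                          n = nv, size = bps / 8, endian = endian,
                          signed = FALSE))
    }
    m <- matrix(px, nrow = w, ncol = h)  # x fastest in file
    planes[[length(planes) + 1]] <- t(m) # -> (Y, X)
    ifd_off <- rd(ifd_off + 2 + n_ent * 12, 1, 4)
  }
  list(planes = planes, description = desc, width = width, height = height)
}

parse_ome <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(name) {
    v <- xml2::xml_attr(px, name)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  roles <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
  list(size = c(t = at("SizeT"), c = at("SizeC"), z = at("SizeZ"),
                y = at("SizeY"), x = at("SizeX")),
       order = xml2::xml_attr(px, "DimensionOrder"),
       voxel_size_um = c(at("PhysicalSizeZ"), at("PhysicalSizeY"),
                         at("PhysicalSizeX")),
       frame_interval_s = at("TimeIncrement"),
       channel_roles = roles)
}

#' Read an OME-TIFF or plain multi-page TIFF into an image stack
#'
#' Axes are normalized to `(T, C, Z, Y, X)` with singleton axes inserted as
#' needed. For OME-TIFF the shape, voxel size, frame interval and channel
#' roles come from the embedded OME-XML. For a plain TIFF the voxel size
#' must be supplied via `metadata_overrides` (it is never silently assumed),
#' and the page count is interpreted as Z unless a shape override says
#' otherwise.
#'
#' @param path TIFF file path.
#' @param metadata_overrides optional list with any of `voxel_size_um`
#'   (z,y,x in um), `shape` (named `c(t=, c=, z=)`), `frame_interval_s`,
#'   `channel_roles`. Overrides win over file metadata.
#' @return an [image_stack].
#' @export
read_stack <- function(path, metadata_overrides = list()) {
  tp <- read_tiff_planes(path)
  ome <- parse_ome(tp$description)
  ov <- metadata_overrides
  n_planes <- length(tp$planes)

  if (!is.null(ome) && !any(is.na(ome$size))) {
    nt <- ome$size["t"]; nc <- ome$size["c"]; nz <- ome$size["z"]
  } else if (!is.null(ov$shape)) {
    s <- ov$shape
    nt <- if (!is.na(s["t"])) s["t"] else 1
    nc <- if (!is.na(s["c"])) s["c"] else 1
    nz <- if (!is.na(s["z"])) s["z"] else n_planes / (nt * nc)
  } else {
    nt <- 1; nc <- 1; nz <- n_planes
  }
  nt <- as.integer(unname(nt)); nc <- as.integer(unname(nc))
  nz <- as.integer(unname(nz))
  if (nt * nc * nz != n_planes)
    stop("declared shape T*C*Z = ", nt * nc * nz, " does not match ",
         n_planes, " planes")

  voxel <- ov$voxel_size_um
  if (is.null(voxel) && !is.null(ome)) voxel <- ome$voxel_size_um
  if (is.null(voxel) || any(is.na(voxel)))
    stop("voxel size missing: supply metadata_overrides$voxel_size_um ",
         "(never assumed to be 1 um)")

  order <- if (!is.null(ome) && !is.na(ome$order)) ome$order else "XYZCT"
  if (!order %in% c("XYZCT", "XYCZT"))
    stop("unsupported DimensionOrder: ", order)

  ny <- tp$height; nx <- tp$width
  arr <- array(0, dim = c(nt, nc, nz, ny, nx))
  p <- 0L
  if (order == "XYZCT") {
    for (t in seq_len(nt)) for (ch in seq_len(nc)) for (z in seq_len(nz)) {
      p <- p + 1L
      arr[t, ch, z, , ] <- tp$planes[[p]]
    }
  } else {
    for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
      p <- p + 1L
      arr[t, ch, z, , ] <- tp$planes[[p]]
    }
  }

  fi <- ov$frame_interval_s
  if (is.null(fi)) fi <- if (!is.null(ome)) ome$frame_interval_s else NA_real_
  roles <- ov$channel_roles
  if (is.null(roles) && !is.null(ome) && length(ome$channel_roles) == nc &&
      !any(is.na(ome$channel_roles)))
    roles <- ome$channel_roles
  image_stack(arr, voxel_size_um = voxel, frame_interval_s = fi,
              channel_roles = roles)
}
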