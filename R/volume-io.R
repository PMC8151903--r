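# Volume I/O: NIfTI via RNifti, plus a minimal DICOM series reader/writer
# (explicit VR little endian, uncompressed) sufficient for CT slice series.
#
# Conventions (all other modules assume these):
#   * arrays are indexed (slice, row, col), 1-based in R;
#   * voxel (s, r, c) sits at origin + ((c-1) dx, (r-1) dy, (s-1) D) mm;
#   * the slice index increases with physical z.

#' Read a CT volume from a NIfTI file or a DICOM series directory
#'
#' DICOM slices are sorted by physical slice position (z of
#' ImagePositionPatient), not by file name. The inter-slice distance is taken
#' from the sorted positions and must be consistent across the series.
#'
#' @param path path to a `.nii`/`.nii.gz` file or to a directory containing a
#'   DICOM series.
#' @param spacingTolerance maximum allowed relative deviation between
#'   successive slice spacings in a DICOM series.
#' @return A [CtVolume-class].
#' @export
readCtVolume <- function(path, spacingTolerance = 1e-3) {
  if (dir.exists(path)) {
    readDicomSeries(path, spacingTolerance)
  } else if (file.exists(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3)
      stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dimensions")
    pd <- RNifti::pixdim(img)
    if (any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("missing or non-positive pixdim spacing in NIfTI header")
    af <- RNifti::xform(img)
    ctVolume(aperm(arr, c(3, 2, 1)), pixelSpacing = pd[1:2],
             sliceDistance = pd[3], origin = af[1:3, 4])
  } else {
    stop("no such file or directory: ", path)
  }
}

#' Write a CT volume as NIfTI
#'
#' @param volume a [CtVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype storage datatype passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
writeCtVolume <- function(volume, path, datatype = "int16") {
  writeNiftiVolume(volume@intensities, volume, path, datatype)
}

#' Write a binary label map as NIfTI (uint8 payload)
#'
#' The written file re-reads bitwise identical (labels) with geometry
#' preserved to float32 header precision.
#'
#' @param volume a [LabelVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeLabelmap <- function(volume, path) {
  if (!is(volume, "LabelVolume"))
    stop("writeLabelmap expects a LabelVolume")
  if (!all(volume@labels %in% c(0L, 1L)))
    stop("label map must be binary (0/1); found other values")
  writeNiftiVolume(volume@labels, volume, path, "uint8")
}

#' Read a label map written by [writeLabelmap()]
#'
#' @param path NIfTI path.
#' @return A [LabelVolume-class].
#' @export
readLabelmap <- function(path) {
  v <- readCtVolume(path)
  labelVolume(round(v@intensities), pixelSpacing = v@pixelSpacing,
              sliceDistance = v@sliceDistance, origin = v@origin)
}

writeNiftiVolume <- function(arr, geom, path, datatype) {
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- c(geom@pixelSpacing, geom@sliceDistance)
  af <- diag(c(geom@pixelSpacing, geom@sliceDistance, 1))
  af[1:3, 4] <- geom@origin
  RNifti::qform(img) <- structure(af, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

## ---- minimal DICOM (explicit VR little endian) ----

dcmTags <- list(
  sopInstance   = c(0x0008L, 0x0018L),
  instanceNum   = c(0x0020L, 0x0013L),
  position      = c(0x0020L, 0x0032L),
  orientation   = c(0x0020L, 0x0037L),
  samples       = c(0x0028L, 0x0002L),
  rows          = c(0x0028L, 0x0010L),
  cols          = c(0x0028L, 0x0011L),
  pixelSpacing  = c(0x0028L, 0x0030L),
  bitsAlloc     = c(0x0028L, 0x0100L),
  bitsStored    = c(0x0028L, 0x0101L),
  highBit       = c(0x0028L, 0x0102L),
  pixelRep      = c(0x0028L, 0x0103L),
  sliceSpacing  = c(0x0018L, 0x0088L),
  pixelData     = c(0x7FE0L, 0x0010L))

writeUint16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                         endian = "little")

writeDcmElement <- function(con, group, element, vr, value) {
  writeUint16(con, c(group, element))
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    writeBin(raw(2), con)
    if (vr == "OW") {
      writeBin(2L * length(value), con, size = 4, endian = "little")
      writeBin(as.integer(value), con, size = 2, endian = "little")
    } else stop("unsupported VR in writer: ", vr)
  } else {
    if (vr == "US") {
      writeUint16(con, length(value) * 2L)
      writeUint16(con, value)
    } else { # string VRs: DS, IS, UI, CS, LO ...
      s <- paste(value, collapse = "\\")
      nb <- nchar(s, type = "bytes")
      pad <- nb %% 2 == 1
      writeUint16(con, nb + pad)
      writeChar(s, con, nchars = nb, eos = NULL)
      if (pad) # UI pads with a nul byte, text VRs with a space
        writeBin(if (vr == "UI") raw(1) else charToRaw(" "), con)
    }
  }
}

#' Write a CT volume as a single-frame DICOM series
#'
#' One uncompressed explicit-VR little-endian file per slice, with
#' Rows/Columns, PixelSpacing, ImagePositionPatient and SpacingBetweenSlices
#' populated from the volume geometry. Intended for fixture generation and
#' interoperability tests; intensities are stored as signed 16-bit.
#'
#' @param volume a [CtVolume-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param fileOrder optional permutation of slice indices controlling the
#'   mapping of slices to file names (file names need not be sorted by
#'   position; readers must sort by position).
#' @return the directory path, invisibly.
#' @export
writeDicomSeries <- function(volume, dir, prefix = "slice",
                             fileOrder = seq_len(dim(volume)[1])) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume)
  arr <- round(volume@intensities)
  if (min(arr) < -32768 || max(arr) > 32767)
    stop("intensities outside int16 range")
  for (i in seq_along(fileOrder)) {
    s <- fileOrder[i]
    f <- file.path(dir, sprintf("%s_%03d.dcm", prefix, i))
    con <- file(f, "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, nchars = 4, eos = NULL)
    # file meta: transfer syntax only
    writeDcmElement(con, 0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
    z <- volume@origin[3] + (s - 1) * volume@sliceDistance
    writeDcmElement(con, 0x0008L, 0x0018L, "UI",
                    sprintf("1.2.826.0.1.3680043.9999.%d", s))
    writeDcmElement(con, 0x0018L, 0x0088L, "DS",
                    format(volume@sliceDistance, digits = 10))
    writeDcmElement(con, 0x0020L, 0x0013L, "IS", as.character(s))
    writeDcmElement(con, 0x0020L, 0x0032L, "DS",
                    format(c(volume@origin[1], volume@origin[2], z), digits = 10))
    writeDcmElement(con, 0x0020L, 0x0037L, "DS",
                    c("1", "0", "0", "0", "1", "0"))
    writeDcmElement(con, 0x0028L, 0x0002L, "US", 1L)
    writeDcmElement(con, 0x0028L, 0x0010L, "US", d[2])
    writeDcmElement(con, 0x0028L, 0x0011L, "US", d[3])
    writeDcmElement(con, 0x0028L, 0x0030L, "DS",
                    format(c(volume@pixelSpacing[2], volume@pixelSpacing[1]),
                           digits = 10))
    writeDcmElement(con, 0x0028L, 0x0100L, "US", 16L)
    writeDcmElement(con, 0x0028L, 0x0101L, "US", 16L)
    writeDcmElement(con, 0x0028L, 0x0102L, "US", 15L)
    writeDcmElement(con, 0x0028L, 0x0103L, "US", 1L)
    # PixelData row-major (rows of columns)
    writeDcmElement(con, 0x7FE0L, 0x0010L, "OW",
                    as.vector(t(arr[s, , ])))
    close(con)
  }
  invisible(dir)
}

parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or unsupported DICOM encoding in ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vstart + len - 1L > n) stop("truncated DICOM element in ", path)
    valueRaw <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, raw = valueRaw)
    pos <- vstart + len
  }
  out
}

dcmString <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(strsplit(rawToChar(el$raw[el$raw != as.raw(0)]), "\\", fixed = TRUE)[[1]])
}

dcmNumeric <- function(el) as.numeric(dcmString(el))

dcmUS <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) / 2, size = 2,
          signed = FALSE, endian = "little")
}

tagKey <- function(tag) sprintf("%04X,%04X", tag[1], tag[2])

readDicomSeries <- function(dir, spacingTolerance = 1e-3) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parseDicomFile)
  need <- function(el, name, tag, f) {
    if (is.null(el))
      stop(sprintf("missing DICOM tag (%s) %s in %s", tagKey(tag), name, f))
    el
  }
  meta <- lapply(seq_along(slices), function(i) {
    el <- slices[[i]]; f <- files[i]
    pos <- dcmNumeric(need(el[[tagKey(dcmTags$position)]],
                           "ImagePositionPatient", dcmTags$position, f))
    ps <- dcmNumeric(need(el[[tagKey(dcmTags$pixelSpacing)]],
                          "PixelSpacing", dcmTags$pixelSpacing, f))
    rows <- dcmUS(need(el[[tagKey(dcmTags$rows)]], "Rows", dcmTags$rows, f))
    cols <- dcmUS(need(el[[tagKey(dcmTags$cols)]], "Columns", dcmTags$cols, f))
    pr <- dcmUS(el[[tagKey(dcmTags$pixelRep)]])
    pd <- need(el[[tagKey(dcmTags$pixelData)]], "PixelData", dcmTags$pixelData, f)
    px <- readBin(pd$raw, "integer", n = length(pd$raw) / 2, size = 2,
                  signed = !identical(pr, 0L), endian = "little")
    list(z = pos[3], origin = pos, spacing = c(ps[2], ps[1]),
         rows = rows, cols = cols, pixels = px)
  })
  sp <- t(vapply(meta, function(m) m$spacing, numeric(2)))
  if (nrow(unique(round(sp, 9))) != 1)
    stop("inconsistent in-plane PixelSpacing (0028,0030) across DICOM series")
  rows <- unique(vapply(meta, function(m) m$rows, integer(1)))
  cols <- unique(vapply(meta, function(m) m$cols, integer(1)))
  if (length(rows) != 1 || length(cols) != 1)
    stop("inconsistent Rows/Columns across DICOM series")
  ord <- order(vapply(meta, function(m) m$z, numeric(1)))
  meta <- meta[ord]
  ns <- length(meta)
  if (ns > 1) {
    dz <- diff(vapply(meta, function(m) m$z, numeric(1)))
    if (any(dz <= 0)) stop("duplicate slice positions in DICOM series")
    if (max(dz) - min(dz) > spacingTolerance * mean(dz))
      stop("inconsistent slice spacing in DICOM series (beyond tolerance)")
    D <- mean(dz)
  } else {
    el <- slices[[1]][[tagKey(dcmTags$sliceSpacing)]]
    if (is.null(el))
      stop(sprintf("single-slice series without SpacingBetweenSlices (%s)",
                   tagKey(dcmTags$sliceSpacing)))
    D <- dcmNumeric(el)
  }
  arr <- array(0, c(ns, rows, cols))
  for (s in seq_len(ns))
    arr[s, , ] <- matrix(meta[[s]]$pixels, nrow = rows, ncol = cols,
                         byrow = TRUE)
  ctVolume(arr, pixelSpacing = meta[[1]]$spacing, sliceDistance = D,
           origin = c(meta[[1]]$origin[1:2], meta[[1]]$z))
}

#' Physical coordinates of voxel centres
#'
#' @param x a volumetric object.
#' @param voxels n-by-3 matrix of 1-based (slice, row, col) indices.
#' @return n-by-3 matrix of (x, y, z) positions in mm.
#' @export
voxelToPhysical <- function(x, voxels) {
  voxels <- matrix(voxels, ncol = 3)
  cbind(x@origin[1] + (voxels[, 3] - 1) * x@pixelSpacing[1],
        x@origin[2] + (voxels[, 2] - 1) * x@pixelSpacing[2],
        x@origin[3] + (voxels[, 1] - 1) * x@sliceDistance)
}
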