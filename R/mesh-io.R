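# Mesh, landmark and resection-path I/O.
# PLY (ascii + binary little-endian read, ascii write), OFF (ascii), STL
# (ascii + binary read, ascii write; STL vertices are merged on read).
# Landmarks: CSV (label, vertex_index). Resection paths: JSON arrays of 3D
# points keyed by path label.

#' Read a triangle mesh (PLY, OFF or STL)
#'
#' @param path file path; format inferred from the extension.
#' @return a [TriangleMesh-class].
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = readPly(path),
         off = readOff(path),
         stl = readStl(path),
         stop("unsupported mesh format: ", ext))
}

#' Write a triangle mesh (ASCII PLY, OFF or STL)
#'
#' ASCII output is bit-stable: writing the same mesh twice produces
#' identical files.
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path; format inferred from the extension.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = writePly(mesh, path),
         off = writeOff(mesh, path),
         stl = writeStl(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

fmtNum <- function(x) formatC(x, format = "g", digits = 9)

writePly <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(mesh@vertices)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(mesh@faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  writeLines(apply(mesh@vertices, 1, function(v)
    paste(fmtNum(v), collapse = " ")), con)
  writeLines(apply(mesh@faces - 1L, 1, function(f)
    paste(c(3, f), collapse = " ")), con)
}

readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 200) stop("malformed PLY header")
  }
  fmt <- sub("^format ", "", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub(".*vertex ", "", grep("element vertex", hdr,
                                             value = TRUE)))
  nf <- as.integer(sub(".*face ", "", grep("element face", hdr,
                                           value = TRUE)))
  vprops <- grep("^property (float|double)", hdr, value = TRUE)
  if (startsWith(fmt, "ascii")) {
    txt <- readLines(con)
    vl <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    verts <- t(vapply(vl, function(x) as.numeric(x[1:3]), numeric(3)))
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(x) {
      n <- as.integer(x[1])
      if (n != 3) stop("non-triangular PLY face")
      as.integer(x[2:4]) + 1L
    }, integer(3)))
  } else if (startsWith(fmt, "binary_little_endian")) {
    sz <- if (grepl("double", vprops[1])) 8L else 4L
    verts <- matrix(readBin(con, "numeric", n = nv * length(vprops),
                            size = sz, endian = "little"),
                    ncol = length(vprops), byrow = TRUE)[, 1:3, drop = FALSE]
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (n != 3) stop("non-triangular PLY face")
      faces[i, ] <- readBin(con, "integer", 3, size = 4,
                            endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  triangleMesh(verts, faces)
}

writeOff <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(mesh@vertices), nrow(mesh@faces), 0)), con)
  writeLines(apply(mesh@vertices, 1, function(v)
    paste(fmtNum(v), collapse = " ")), con)
  writeLines(apply(mesh@faces - 1L, 1, function(f)
    paste(c(3, f), collapse = " ")), con)
}

readOff <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (!grepl("OFF", txt[1])) stop("not an OFF file")
  cnt <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  vl <- strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+")
  verts <- t(vapply(vl, function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  triangleMesh(verts, faces)
}

writeStl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices; f <- mesh@faces
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
             (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
             (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    ln <- sqrt(sum(n^2)); if (ln > 0) n <- n / ln
    writeLines(c(paste("facet normal", paste(fmtNum(n), collapse = " ")),
                 "  outer loop",
                 paste("    vertex", apply(p, 1, function(q)
                   paste(fmtNum(q), collapse = " "))),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

readStl <- function(path) {
  raw <- readBin(path, "raw", n = 80)
  isAscii <- identical(rawToChar(raw[1:5]), "solid") &&
    any(grepl("facet", readLines(path, n = 20, warn = FALSE)))
  if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    coords <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      coords[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  key <- apply(coords, 1, function(p) paste(format(p, digits = 12),
                                            collapse = ","))
  uk <- unique(key)
  verts <- coords[match(uk, key), , drop = FALSE]
  faces <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  triangleMesh(verts, faces)
}

#' Read / write landmark files (CSV: label, vertex_index)
#'
#' Vertex indices are stored 0-based on disk and returned 1-based.
#'
#' @param path CSV path.
#' @return named integer vector of 1-based vertex indices, names = labels.
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  out <- as.integer(df[[2]]) + 1L
  names(out) <- as.character(df[[1]])
  out
}

#' @rdname readLandmarks
#' @param landmarks named integer vector of 1-based vertex indices.
#' @export
writeLandmarks <- function(landmarks, path) {
  utils::write.csv(data.frame(label = names(landmarks),
                              vertex_index = as.integer(landmarks) - 1L),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write resection paths as JSON
#'
#' JSON object keyed by path label, each value an n-by-3 array of points.
#'
#' @param path JSON file path.
#' @return list of [ResectionPath-class].
#' @export
readResectionPaths <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(names(obj), function(lb) resectionPath(obj[[lb]], lb))
}

#' @rdname readResectionPaths
#' @param paths list of [ResectionPath-class].
#' @export
writeResectionPaths <- function(paths, path) {
  obj <- stats::setNames(lapply(paths, function(p) p@points),
                         vapply(paths, function(p) p@label, character(1)))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
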