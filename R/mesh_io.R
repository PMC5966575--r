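# Mesh readers/writers for VTK legacy ASCII polydata, PLY (ASCII and
# binary little-endian) and OFF.  Format is chosen by file extension.
# No mesh-I/O package exists in the target environment, so the three
# text-book formats are handled here directly.

#' Read a triangle mesh
#'
#' Supports VTK legacy polydata (`.vtk`, ASCII), PLY (`.ply`, ASCII or
#' binary little-endian) and OFF (`.off`).  Non-triangular polygons are
#' fan-triangulated.
#'
#' @param path input file path; format chosen by extension.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = .read_vtk(path),
         ply = .read_ply(path),
         off = .read_off(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; `.vtk`, `.ply` or `.off`.
#' @param binary for PLY only: write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = .write_vtk(mesh, path),
         ply = .write_ply(mesh, path, binary),
         off = .write_off(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

.fmt_coords <- function(m) {
  apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
}

.write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "shapefilt surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nv, "float")), con)
  writeLines(.fmt_coords(mesh$vertices), con)
  writeLines(paste("POLYGONS", nf, 4 * nf), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
}

.read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  up <- toupper(txt)
  if (!any(grepl("^ASCII", up)))
    stop("only ASCII legacy VTK files are supported: ", path)
  tok <- scan(text = paste(txt, collapse = "\n"), what = "character",
              quiet = TRUE, comment.char = "#")
  tu <- toupper(tok)
  ip <- match("POINTS", tu)
  if (is.na(ip)) stop("no POINTS section in ", path)
  nv <- as.integer(tok[ip + 1])
  coords <- as.numeric(tok[(ip + 3):(ip + 2 + 3 * nv)])
  v <- matrix(coords, ncol = 3, byrow = TRUE)
  ifc <- match("POLYGONS", tu)
  if (is.na(ifc)) stop("no POLYGONS section in ", path)
  nf <- as.integer(tok[ifc + 1])
  total <- as.integer(tok[ifc + 2])
  ints <- as.integer(tok[(ifc + 3):(ifc + 2 + total)])
  .polys_to_tris(v, ints, nf)
}

# parse a [count, i1..icount]* polygon stream (0-based), fan-triangulating
.polys_to_tris <- function(v, ints, nf) {
  faces <- vector("list", nf)
  p <- 1L
  for (f in seq_len(nf)) {
    k <- ints[p]
    idx <- ints[(p + 1L):(p + k)] + 1L
    p <- p + k + 1L
    if (k < 3L) stop("polygon with fewer than 3 vertices")
    faces[[f]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }
  tri_mesh(v, do.call(rbind, faces))
}

.write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(mesh$vertices), nrow(mesh$faces), 0)), con)
  writeLines(.fmt_coords(mesh$vertices), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
}

.read_off <- function(path) {
  tok <- scan(path, what = "character", quiet = TRUE, comment.char = "#")
  if (toupper(tok[1]) != "OFF") stop("not an OFF file: ", path)
  nv <- as.integer(tok[2]); nf <- as.integer(tok[3])
  coords <- as.numeric(tok[5:(4 + 3 * nv)])
  v <- matrix(coords, ncol = 3, byrow = TRUE)
  ints <- as.integer(tok[(5 + 3 * nv):length(tok)])
  .polys_to_tris(v, ints, nf)
}

.write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0"
              else "format ascii 1.0",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(.fmt_coords(mesh$vertices), con)
    writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                     mesh$faces[, 3] - 1), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (f in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, f]), con, size = 4L, endian = "little")
    }
  }
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII, line by line
  header <- character()
  repeat {
    line <- ""
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (length(ch) == 0L) stop("unexpected end of PLY header: ", path)
      if (ch == as.raw(10L)) break
      line <- paste0(line, rawToChar(ch))
    }
    line <- sub("\r$", "", line)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  vprops <- length(grep("^property (float|double)",
                        header[seq(grep("^element vertex", header),
                                   grep("^element face", header))]))
  if (binary) {
    v <- matrix(readBin(con, "numeric", n = nv * vprops, size = 4L,
                        endian = "little"),
                ncol = vprops, byrow = TRUE)[, 1:3, drop = FALSE]
    faces <- matrix(0L, nf, 3)
    for (f in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", 1L))
      idx <- readBin(con, "integer", n = k, size = 4L, endian = "little")
      if (k != 3L) stop("only triangular PLY faces are supported")
      faces[f, ] <- idx + 1L
    }
    tri_mesh(v, faces)
  } else {
    tok <- scan(con, what = "character", quiet = TRUE)
    nums <- as.numeric(tok)
    v <- matrix(nums[seq_len(nv * vprops)], ncol = vprops,
                byrow = TRUE)[, 1:3, drop = FALSE]
    ints <- as.integer(nums[(nv * vprops + 1):length(nums)])
    .polys_to_tris(v, ints, nf)
  }
}
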