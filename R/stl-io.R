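#' Read a triangulated surface from an STL file
#'
#' Supports both ASCII and binary STL. STL stores each triangle's vertices
#' independently; coincident vertices are merged (exact coordinate match
#' after rounding to `digits` significant digits) so that shared-edge
#' topology — and hence watertightness checking — is recovered.
#'
#' @param path Path to an `.stl` file.
#' @param sink_direction Sinking direction attached to the mesh.
#' @param digits Significant digits used when merging coincident vertices.
#' @return An [oriented_mesh()].
#' @export
read_stl <- function(path, sink_direction = c(0, 0, -1), digits = 10) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  close(con)
  txt_head <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head)
  if (is_ascii) {
    # binary files may also start with "solid"; confirm by looking for "facet"
    lines <- readLines(path, n = 50L, warn = FALSE)
    is_ascii <- any(grepl("facet", lines, fixed = TRUE))
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("no triangles found in ", path, call. = FALSE)
  key <- paste(signif(tri[, 1], digits), signif(tri[, 2], digits), signif(tri[, 3], digits))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  oriented_mesh(verts, faces, sink_direction)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  out <- matrix(NA_real_, nrow = 3L * n_tri, ncol = 3L)
  for (k in seq_len(n_tri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L) # attribute byte count
    out[(3L * (k - 1L) + 1L):(3L * k), ] <- matrix(rec[4:12], ncol = 3L, byrow = TRUE)
  }
  out
}

#' Write a mesh to an STL file
#'
#' @param mesh An [oriented_mesh()].
#' @param path Output path.
#' @param name Solid name written in the header.
#' @param binary Write little-endian binary STL instead of ASCII (default
#'   FALSE). Binary STL stores single-precision floats, so coordinates are
#'   rounded to about 7 significant digits.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "mesh", binary = FALSE) {
  stopifnot(inherits(mesh, "oriented_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC(name, width = -80))[1:80]
    header[is.na(header)] <- as.raw(0)
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (k in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[k, ], a[k, ], b[k, ], cc[k, ])), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (k in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[k, 1], nrm[k, 2], nrm[k, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[k, 1], a[k, 2], a[k, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[k, 1], b[k, 2], b[k, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", cc[k, 1], cc[k, 2], cc[k, 3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
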