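#' Write a mesh or scene to STL
#'
#' Binary STL: 80-byte header, little-endian uint32 triangle count, then
#' per triangle a float32 normal, three float32 vertices and a uint16
#' attribute. ASCII STL follows the `solid ... endsolid` grammar. A scene
#' writes one `solid` block per part in ASCII; in binary, where the format
#' has no multi-solid notion, the parts are concatenated into one solid.
#' Coordinates are in mm (STL itself is unitless; mm is this package's
#' convention, recorded in sidecar metadata where applicable).
#'
#' @param x a `tri_mesh` or `mesh_scene`.
#' @param path output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(x, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  parts <- if (inherits(x, "mesh_scene")) x$parts
           else if (inherits(x, "tri_mesh")) list(solid = x)
           else stop("x must be a tri_mesh or mesh_scene")
  if (dialect == "binary") {
    v <- do.call(rbind, lapply(parts, function(m) {
      # quantize vertices to float32 first so that a write/read/write cycle
      # is bit-identical after the first write
      m$vertices <- float32_round(m$vertices)
      f <- m$faces
      n2 <- face_normals2(m)
      nn <- n2 / pmax(sqrt(rowSums(n2^2)), .Machine$double.xmin)
      # per triangle: normal, v1, v2, v3 (12 floats)
      t(cbind(float32_round(nn), m$vertices[f[, 1], , drop = FALSE],
              m$vertices[f[, 2], , drop = FALSE],
              m$vertices[f[, 3], , drop = FALSE]))
    }))
    ntri <- length(v) / 12L
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "phantomforge binary STL (mm)"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    # 50-byte records: 12 little-endian float32 + zero uint16 attribute
    fbytes <- writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
    rec <- raw(50L * ntri)
    pos <- rep((seq_len(ntri) - 1L) * 50L, each = 48L) + seq_len(48L)
    rec[pos] <- fbytes
    writeBin(rec, con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(parts)) {
      m <- parts[[nm]]
      f <- m$faces
      n2 <- face_normals2(m)
      nn <- n2 / pmax(sqrt(rowSums(n2^2)), .Machine$double.xmin)
      writeLines(sprintf("solid %s", nm), con)
      v1 <- m$vertices[f[, 1], , drop = FALSE]
      v2 <- m$vertices[f[, 2], , drop = FALSE]
      v3 <- m$vertices[f[, 3], , drop = FALSE]
      txt <- sprintf(
        "facet normal %.9g %.9g %.9g\nouter loop\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nendloop\nendfacet",
        nn[, 1], nn[, 2], nn[, 3],
        v1[, 1], v1[, 2], v1[, 3],
        v2[, 1], v2[, 2], v2[, 3],
        v3[, 1], v3[, 2], v3[, 3])
      writeLines(txt, con)
      writeLines(sprintf("endsolid %s", nm), con)
    }
  }
  invisible(path)
}

# round doubles to the nearest float32-representable value
float32_round <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' Read an STL file
#'
#' Auto-detects binary versus ASCII. Duplicate vertices within a solid are
#' merged exactly (bitwise-equal coordinates), reconstructing shared
#' topology from the triangle soup.
#'
#' @param path STL file path.
#' @return A `tri_mesh`, or a named list of `tri_mesh` for a multi-solid
#'   ASCII file.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("STL parse error: file too short (", sz, " bytes)")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[1:min(80, length(head_raw))])) &&
    {
      txt <- tryCatch(rawToChar(head_raw), error = function(e) "")
      grepl("facet", txt) || sz < 84
    }
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84)
    stop("STL parse error: binary file truncated at byte ", sz,
         " (need at least 84)")
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  expect <- 84 + 50 * ntri
  if (sz != expect)
    stop("STL parse error: triangle count ", ntri, " implies ", expect,
         " bytes but file has ", sz, " (mismatch at byte offset 80)")
  payload <- readBin(con, "raw", n = 50 * ntri)
  keep <- rep(rep(c(TRUE, FALSE), c(48L, 2L)), ntri)
  floats <- readBin(payload[keep], "double", n = 12 * ntri, size = 4,
                    endian = "little")
  soup_to_mesh(matrix(floats, 12))
}

soup_to_mesh <- function(tri) {
  ntri <- ncol(tri)
  verts_all <- rbind(t(tri[4:6, , drop = FALSE]),
                     t(tri[7:9, , drop = FALSE]),
                     t(tri[10:12, , drop = FALSE]))
  key <- paste(verts_all[, 1], verts_all[, 2], verts_all[, 3])
  uid <- !duplicated(key)
  vmap <- match(key, key[uid])
  faces <- cbind(vmap[seq_len(ntri)],
                 vmap[ntri + seq_len(ntri)],
                 vmap[2 * ntri + seq_len(ntri)])
  tri_mesh(verts_all[uid, , drop = FALSE], faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  solid_starts <- grep("^solid", lines)
  if (!length(solid_starts)) stop("STL parse error: no 'solid' keyword")
  out <- list()
  for (s in seq_along(solid_starts)) {
    from <- solid_starts[s]
    to <- if (s < length(solid_starts)) solid_starts[s + 1] - 1 else length(lines)
    block <- lines[from:to]
    nm <- sub("^solid\\s*", "", block[1])
    if (!any(grepl("^endsolid", block)))
      stop("STL parse error: solid '", nm, "' lacks endsolid")
    vl <- grep("^vertex", block, value = TRUE)
    if (length(vl) %% 3 != 0)
      stop("STL parse error: vertex count ", length(vl),
           " is not a multiple of 3 in solid '", nm, "'")
    nums <- matrix(as.numeric(unlist(strsplit(sub("^vertex\\s+", "", vl),
                                              "\\s+"))), ncol = 3, byrow = TRUE)
    ntri <- nrow(nums) / 3
    idx3 <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    tri <- matrix(0, 12, ntri)
    tri[4:6, ] <- t(nums[idx3[, 1], , drop = FALSE])
    tri[7:9, ] <- t(nums[idx3[, 2], , drop = FALSE])
    tri[10:12, ] <- t(nums[idx3[, 3], , drop = FALSE])
    out[[if (nzchar(nm)) nm else paste0("solid", s)]] <- soup_to_mesh(tri)
  }
  if (length(out) == 1L) out[[1]] else out
}
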