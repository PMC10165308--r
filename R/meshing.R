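#' Construct a triangle mesh
#'
#' A `tri_mesh` is a triangle surface in mm: an N x 3 vertex matrix and an
#' M x 3 face index matrix with counter-clockwise winding (outward normals,
#' positive signed volume for closed surfaces).
#'
#' @param vertices N x 3 numeric matrix of coordinates in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param role optional organ/compartment role tag.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, role = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, role = role),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("Triangle mesh", if (!is.null(x$role)) paste0("[", x$role, "]"), ":",
      nrow(x$vertices), "vertices,", nrow(x$faces), "faces")
  wt <- is_watertight(x)
  if (wt) cat(", volume", format(round(signed_volume_mL(x), 3)), "mL")
  cat(if (wt) ", watertight\n" else ", open\n")
  invisible(x)
}

# signed enclosed volume in mL by the divergence theorem (tetrahedra to origin)
signed_volume_mL <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  vol6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(vol6) / 6 / 1000
}

# per-face scaled normals (cross product, length = 2 * area)
face_normals2 <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a mesh
#' @param mesh a `tri_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_normals2(mesh)^2))) / 2

#' Check that a mesh is a closed, consistently wound 2-manifold
#'
#' Every directed half-edge must be matched by exactly one opposite
#' half-edge (so each undirected edge borders exactly two faces with
#' consistent winding), and no degenerate (zero-area) faces are allowed.
#'
#' @param mesh a `tri_mesh`.
#' @param details if `TRUE`, return a list with diagnostic counts instead
#'   of a logical.
#' @return Logical, or a diagnostics list.
#' @export
is_watertight <- function(mesh, details = FALSE) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  n <- nrow(mesh$vertices)
  key <- (he_from - 1) * n + he_to
  rkey <- (he_to - 1) * n + he_from
  dup <- anyDuplicated(key) > 0L
  unmatched <- sum(!(key %in% rkey))
  degen <- sum(rowSums(face_normals2(mesh)^2) == 0)
  ok <- !dup && unmatched == 0L && degen == 0L && nrow(f) > 0L
  if (!details) return(ok)
  list(watertight = ok, duplicated_halfedges = dup,
       unmatched_halfedges = unmatched, degenerate_faces = degen)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem (signed tetrahedron) sum, exact for polyhedral input
#' up to floating point. The mesh must be watertight and outward-wound.
#'
#' @param mesh a `tri_mesh`.
#' @return Volume in mL (1 mL = 1000 mm^3).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is_watertight(mesh))
    stop("mesh is not watertight; enclosed volume undefined")
  v <- signed_volume_mL(mesh)
  if (v < 0)
    stop("negative signed volume: inverted winding (inward normals)")
  v
}

# --- surface extraction -----------------------------------------------------

# 0.5 iso-surface of a binary mask under nearest-neighbour interpolation:
# the boundary faces of the voxel set, as quads split into triangles.
# Returns a tri_mesh in world mm. Enclosed volume equals voxel volume.
mask_surface <- function(mask, spacing) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  gx <- pd[1] + 1L; gy <- pd[2] + 1L  # corner-grid dims (padded)
  corner_id <- function(ci, cj, ck) ci + gx * (cj + gy * ck) + 1L

  quads <- vector("list", 6)
  q <- 0L
  # for each signed axis, faces where pm TRUE and neighbour FALSE
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (sh in shifts) {
    ii <- seq_len(pd[1]); jj <- seq_len(pd[2]); kk <- seq_len(pd[3])
    src_i <- pmin(pmax(ii + sh[1], 1L), pd[1])
    src_j <- pmin(pmax(jj + sh[2], 1L), pd[2])
    src_k <- pmin(pmax(kk + sh[3], 1L), pd[3])
    nb <- pm[src_i, src_j, src_k, drop = FALSE]
    w <- which(pm & !nb)
    q <- q + 1L
    if (!length(w)) { quads[[q]] <- matrix(integer(0), 0, 4); next }
    co <- arrayInd(w, pd) - 1L  # padded voxel coords, 0-based
    i <- co[, 1]; j <- co[, 2]; k <- co[, 3]
    # voxel (i,j,k) spans corners (i-1..i, j-1..j, k-1..k) in padded corner grid
    cq <- if (sh[1] == 1L) {
      cbind(corner_id(i, j - 1L, k - 1L), corner_id(i, j, k - 1L),
            corner_id(i, j, k), corner_id(i, j - 1L, k))
    } else if (sh[1] == -1L) {
      cbind(corner_id(i - 1L, j - 1L, k - 1L), corner_id(i - 1L, j - 1L, k),
            corner_id(i - 1L, j, k), corner_id(i - 1L, j, k - 1L))
    } else if (sh[2] == 1L) {
      cbind(corner_id(i - 1L, j, k - 1L), corner_id(i - 1L, j, k),
            corner_id(i, j, k), corner_id(i, j, k - 1L))
    } else if (sh[2] == -1L) {
      cbind(corner_id(i - 1L, j - 1L, k - 1L), corner_id(i, j - 1L, k - 1L),
            corner_id(i, j - 1L, k), corner_id(i - 1L, j - 1L, k))
    } else if (sh[3] == 1L) {
      cbind(corner_id(i - 1L, j - 1L, k), corner_id(i, j - 1L, k),
            corner_id(i, j, k), corner_id(i - 1L, j, k))
    } else {
      cbind(corner_id(i - 1L, j - 1L, k - 1L), corner_id(i - 1L, j, k - 1L),
            corner_id(i, j, k - 1L), corner_id(i, j - 1L, k - 1L))
    }
    quads[[q]] <- cq
  }
  allq <- do.call(rbind, quads)
  if (is.null(allq) || nrow(allq) == 0L) stop("empty region: no surface")
  faces <- rbind(allq[, c(1, 2, 3)], allq[, c(1, 3, 4)])
  uid <- sort(unique(as.vector(allq)))
  faces[] <- match(faces, uid)
  # corner id -> padded corner coords -> world mm (unpad by one voxel)
  id0 <- uid - 1L
  ci <- id0 %% gx
  cj <- (id0 %/% gx) %% gy
  ck <- id0 %/% (gx * gy)
  # corner value c corresponds to world c * spacing (padding already removed
  # because corners were taken relative to the padded voxel grid minus one)
  verts <- cbind(ci * spacing[1], cj * spacing[2], ck * spacing[3])
  tri_mesh(verts, faces)
}

#' Extract the surface of one organ as a triangle mesh
#'
#' Extracts the 0.5 iso-level surface of the organ's binary mask under
#' nearest-neighbour interpolation: the exact boundary of the voxel set,
#' with vertices on the voxel-corner grid in world mm. The enclosed volume
#' of the extracted mesh equals the voxel-count volume exactly; Laplacian
#' smoothing ([laplacian_smooth()]) subsequently removes the staircase.
#' The region should be a single connected component
#' (see [clean_label_region()]); a non-manifold surface (possible when
#' voxels of the region touch only along an edge) raises an extraction
#' error with diagnostics.
#'
#' @param phantom a `voxel_phantom`.
#' @param label organ id, role or name.
#' @return A watertight `tri_mesh` tagged with the organ's role.
#' @export
extract_surface <- function(phantom, label) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  id <- resolve_label(phantom, label)
  mask <- phantom$labels == id
  if (!any(mask)) stop("empty region: label ", id, " has no voxels")
  mesh <- mask_surface(mask, phantom$spacing)
  diag_ <- is_watertight(mesh, details = TRUE)
  if (!diag_$watertight)
    stop("extraction produced a non-manifold surface (",
         diag_$unmatched_halfedges, " unmatched half-edges, ",
         diag_$degenerate_faces, " degenerate faces); ",
         "clean the label region first")
  mesh$role <- phantom$organ_table$role[phantom$organ_table$id == id]
  mesh
}

# sparse uniform-weight vertex adjacency operator (row-normalized)
vertex_adjacency_op <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse duplicate edge entries to weight 1
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / pmax(deg, 1)) %*% A
}

#' Uniform-weight Laplacian smoothing
#'
#' Moves every vertex toward the centroid of its edge-connected neighbours
#' by a factor `lambda` per iteration: `v <- v + lambda * (mean(N(v)) - v)`.
#' Face connectivity is untouched, so watertightness is preserved. The
#' relative volume change is recorded in the `"volume_change"` attribute.
#'
#' @param mesh a `tri_mesh`.
#' @param iterations number of smoothing passes, `>= 0` (default 20).
#' @param lambda step factor in `(0, 1]` (default 0.5).
#' @return The smoothed `tri_mesh`.
#' @export
laplacian_smooth <- function(mesh, iterations = 20L, lambda = 0.5) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (iterations < 0) stop("iterations must be >= 0")
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  if (iterations == 0) return(mesh)
  W <- vertex_adjacency_op(mesh)
  V <- mesh$vertices
  v0 <- signed_volume_mL(mesh)
  for (it in seq_len(iterations)) {
    V <- (1 - lambda) * V + lambda * as.matrix(W %*% V)
  }
  out <- mesh
  out$vertices <- V
  attr(out, "volume_change") <- signed_volume_mL(out) / v0 - 1
  out
}

#' Icosphere primitive
#'
#' Icosahedron subdivided `subdivisions` times with midpoint insertion and
#' projection to the sphere; the standard geodesic sphere used for sphere
#' fixtures and the spherical tumour insert.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions subdivision level (level 5 gives 20480 faces).
#' @param center sphere center, mm.
#' @return A watertight `tri_mesh`.
#' @export
icosphere <- function(radius, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    n <- nrow(v)
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ufirst <- !duplicated(ekey)
    mid_of <- match(ekey, ekey[ufirst])
    mids <- (v[e[ufirst, 1], , drop = FALSE] + v[e[ufirst, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- n + mid_of[seq_len(nrow(f))]
    m23 <- n + mid_of[nrow(f) + seq_len(nrow(f))]
    m31 <- n + mid_of[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  verts <- sweep(v * radius, 2, center, `+`)
  tri_mesh(verts, f)
}

#' Axis-aligned cube mesh
#'
#' @param edge edge length in mm.
#' @param origin minimum corner (default the world origin).
#' @return A 12-triangle watertight `tri_mesh` with outward winding.
#' @export
cube_mesh <- function(edge = 10, origin = c(0, 0, 0)) {
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  v <- sweep(as.matrix(g) * edge, 2, origin, `+`)
  # corner index: 1 + x + 2y + 4z
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = 0, normal -x
    c(2, 4, 8), c(2, 8, 6),   # x = 1, normal +x
    c(1, 2, 6), c(1, 6, 5),   # y = 0, normal -y
    c(3, 8, 4), c(3, 7, 8),   # y = 1, normal +y
    c(1, 4, 2), c(1, 3, 4),   # z = 0, normal -z
    c(5, 6, 8), c(5, 8, 7))   # z = 1, normal +z
  tri_mesh(v, f)
}

# --- shell extrusion --------------------------------------------------------

# unit outward vertex normals, area-weighted over incident faces
vertex_normals <- function(mesh) {
  fn <- face_normals2(mesh)
  n <- nrow(mesh$vertices)
  idx <- as.vector(mesh$faces)
  contrib <- rowsum(fn[rep(seq_len(nrow(fn)), 3), , drop = FALSE], idx)
  acc <- matrix(0, n, 3)
  acc[as.integer(rownames(contrib)), ] <- contrib
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, .Machine$double.eps)
}

#' Extrude a hollow shell from a surface
#'
#' Displaces every vertex outward along its area-weighted vertex normal by
#' the wall thickness, giving the outer surface of a hollow printable
#' shell. The input should be smoothed first so the curvature radius stays
#' large against the thickness; if any face of the offset surface folds
#' over (normal reversal), an extrusion error reports the affected faces.
#'
#' @param mesh a smoothed, watertight `tri_mesh` (the inner surface).
#' @param thickness wall thickness in mm, `> 0` (2 mm for organs, 1 mm for
#'   medulla compartments in the default design).
#' @return An object of class `shell_pair`: list with `inner`, `outer`
#'   (both `tri_mesh`) and `thickness_mm`.
#' @export
extrude_shell <- function(mesh, thickness) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is.numeric(thickness) || thickness <= 0)
    stop("wall thickness must be positive")
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  vn <- vertex_normals(mesh)
  outer_mesh <- mesh
  outer_mesh$vertices <- mesh$vertices + thickness * vn
  fn_in <- face_normals2(mesh)
  fn_out <- face_normals2(outer_mesh)
  flipped <- which(rowSums(fn_in * fn_out) <= 0)
  if (length(flipped))
    stop("extrusion self-intersection: ", length(flipped),
         " folded faces near vertices ",
         paste(utils::head(unique(as.vector(mesh$faces[flipped, ])), 5),
               collapse = ", "))
  if (signed_volume_mL(outer_mesh) <= signed_volume_mL(mesh))
    stop("extrusion failed: outer volume not larger than inner volume")
  structure(list(inner = mesh, outer = outer_mesh, thickness_mm = thickness),
            class = "shell_pair")
}

#' @export
print.shell_pair <- function(x, ...) {
  cat("Hollow shell: wall", x$thickness_mm, "mm, inner",
      format(round(signed_volume_mL(x$inner), 2)), "mL, outer",
      format(round(signed_volume_mL(x$outer), 2)), "mL\n")
  invisible(x)
}

# --- point/mesh distance machinery -----------------------------------------

# chunked brute-force nearest vertex (small problems / fallback)
nearest_vertex_brute <- function(points, verts, ids = seq_len(nrow(points))) {
  best <- integer(length(ids))
  chunk <- max(1L, floor(5e6 / nrow(verts)))
  for (from in seq(1L, length(ids), by = chunk)) {
    sel <- ids[from:min(from + chunk - 1L, length(ids))]
    d2 <- outer(points[sel, 1], verts[, 1], `-`)^2 +
          outer(points[sel, 2], verts[, 2], `-`)^2 +
          outer(points[sel, 3], verts[, 3], `-`)^2
    best[from:(from + length(sel) - 1L)] <- max.col(-d2, ties.method = "first")
  }
  best
}

# exact nearest-vertex index per query point: uniform-grid hash over the
# 27-cell neighbourhood (numeric keys, sorted lookup), brute force for
# queries whose nearest vertex is farther than one cell
nearest_vertex <- function(points, verts, cell = NULL) {
  np <- nrow(points); nv <- nrow(verts)
  if (as.double(np) * nv <= 4e6) return(nearest_vertex_brute(points, verts))
  if (is.null(cell)) {
    bb <- apply(verts, 2, range)
    cell <- max(max(bb[2, ] - bb[1, ]) / 25, 1e-6)
  }
  o <- pmin(apply(verts, 2, min), apply(points, 2, min)) - 2 * cell
  vk <- floor(sweep(verts, 2, o) / cell)
  pk <- floor(sweep(points, 2, o) / cell)
  M <- max(vk, pk) + 3
  key_of <- function(k) k[, 1] + M * (k[, 2] + M * k[, 3])
  vkey <- key_of(vk)
  ordv <- order(vkey)
  skey <- vkey[ordv]
  pkey <- key_of(pk)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offkey <- off[, 1] + M * off[, 2] + M * M * off[, 3]
  best <- rep(NA_integer_, np)
  bestd2 <- rep(Inf, np)
  for (oo in offkey) {
    tk <- pkey + oo
    lo <- findInterval(tk - 0.5, skey) + 1L
    hi <- findInterval(tk + 0.5, skey)
    cnt <- hi - lo + 1L
    sel <- which(cnt > 0L)
    if (!length(sel)) next
    pid <- rep(sel, cnt[sel])
    vid <- ordv[sequence(cnt[sel], from = lo[sel])]
    d2 <- (verts[vid, 1] - points[pid, 1])^2 +
          (verts[vid, 2] - points[pid, 2])^2 +
          (verts[vid, 3] - points[pid, 3])^2
    ord2 <- order(pid, d2)
    first <- !duplicated(pid[ord2])
    p2 <- pid[ord2][first]
    dmin <- d2[ord2][first]
    v2 <- vid[ord2][first]
    w <- dmin < bestd2[p2]
    best[p2[w]] <- v2[w]
    bestd2[p2[w]] <- dmin[w]
  }
  # the 27-cell search is exact only within one cell of the query
  pending <- which(!(sqrt(bestd2) <= cell))
  if (length(pending))
    best[pending] <- nearest_vertex_brute(points, verts, pending)
  best
}

# exact distance from points to the triangles incident to given vertices
# (vectorized point-triangle distance, Ericson-style region clamping)
point_triangle_dist <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c_
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- pmax(va + vb + vc, .Machine$double.xmin)
  v <- vb / denom; w <- vc / denom
  # start from interior projection, then clamp by region
  res <- a + v * ab + w * ac
  reg1 <- d1 <= 0 & d2 <= 0                               # vertex a
  res[reg1, ] <- a[reg1, ]
  reg2 <- d3 >= 0 & d4 <= d3                              # vertex b
  res[reg2, ] <- b[reg2, ]
  reg3 <- d6 >= 0 & d5 <= d6                              # vertex c
  res[reg3, ] <- c_[reg3, ]
  regAB <- vc <= 0 & d1 >= 0 & d3 <= 0 & !reg1 & !reg2 & !reg3
  if (any(regAB)) {
    t <- d1[regAB] / (d1[regAB] - d3[regAB])
    res[regAB, ] <- a[regAB, ] + t * ab[regAB, ]
  }
  regAC <- vb <= 0 & d2 >= 0 & d6 <= 0 & !reg1 & !reg2 & !reg3 & !regAB
  if (any(regAC)) {
    t <- d2[regAC] / (d2[regAC] - d6[regAC])
    res[regAC, ] <- a[regAC, ] + t * ac[regAC, ]
  }
  regBC <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0 &
    !reg1 & !reg2 & !reg3 & !regAB & !regAC
  if (any(regBC)) {
    t <- (d4[regBC] - d3[regBC]) /
      ((d4[regBC] - d3[regBC]) + (d5[regBC] - d6[regBC]))
    res[regBC, ] <- b[regBC, ] + t * (c_[regBC, ] - b[regBC, ])
  }
  sqrt(rowSums((p - res)^2))
}

# unsigned distance from each point to the mesh surface, localized around
# the nearest vertex (exact for smooth meshes where the closest triangle is
# incident to the nearest vertex)
surface_distance <- function(points, mesh) {
  f <- mesh$faces
  nv <- nearest_vertex(points, mesh$vertices)
  incident <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  pair_p <- integer(0); pair_f <- integer(0)
  fl <- incident[as.character(nv)]
  lens <- lengths(fl)
  pair_p <- rep(seq_len(nrow(points)), lens)
  pair_f <- unlist(fl, use.names = FALSE)
  d <- point_triangle_dist(points[pair_p, , drop = FALSE],
                           mesh$vertices[f[pair_f, 1], , drop = FALSE],
                           mesh$vertices[f[pair_f, 2], , drop = FALSE],
                           mesh$vertices[f[pair_f, 3], , drop = FALSE])
  dv <- sqrt(rowSums((points - mesh$vertices[nv, , drop = FALSE])^2))
  out <- dv
  agg <- tapply(d, pair_p, min)
  out[as.integer(names(agg))] <- pmin(out[as.integer(names(agg))], agg)
  out
}

#' Mean wall distance of a shell
#'
#' Mean nearest-point distance from the outer-surface vertices to the inner
#' surface; for a clean extrusion this equals the wall thickness.
#'
#' @param shell a [extrude_shell()] result.
#' @return Mean distance in mm.
#' @export
mean_wall_distance <- function(shell) {
  stopifnot(inherits(shell, "shell_pair"))
  mean(surface_distance(shell$outer$vertices, shell$inner))
}

# --- point-in-mesh and voxelization ----------------------------------------

# z-ray crossing parity. points: N x 3. Returns logical inside flags.
# Query x/y are nudged by a tiny irrational offset so rays avoid vertices
# and edges.
point_in_mesh <- function(points, mesh, eps = 1e-7) {
  v <- mesh$vertices; f <- mesh$faces
  px <- points[, 1] + eps * pi; py <- points[, 2] + eps * exp(1)
  pz <- points[, 3]
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]; az <- v[f[, 1], 3]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]; bz <- v[f[, 2], 3]
  cx <- v[f[, 3], 1]; cy <- v[f[, 3], 2]; cz <- v[f[, 3], 3]
  # 2-D bins over triangle bounding boxes
  xr <- range(v[, 1]); yr <- range(v[, 2])
  nbx <- max(1L, min(256L, floor(sqrt(nrow(f)))))
  nby <- nbx
  sx <- (xr[2] - xr[1]) / nbx + 1e-12; sy <- (yr[2] - yr[1]) / nby + 1e-12
  tx0 <- floor((pmin(ax, bx, cx) - xr[1]) / sx); tx1 <- floor((pmax(ax, bx, cx) - xr[1]) / sx)
  ty0 <- floor((pmin(ay, by, cy) - yr[1]) / sy); ty1 <- floor((pmax(ay, by, cy) - yr[1]) / sy)
  # triangle -> bins expansion
  reps <- (tx1 - tx0 + 1) * (ty1 - ty0 + 1)
  tri_id <- rep(seq_len(nrow(f)), reps)
  binx <- unlist(mapply(function(a0, a1, k) rep(a0:a1, times = k),
                        tx0, tx1, ty1 - ty0 + 1, SIMPLIFY = FALSE))
  biny <- unlist(mapply(function(b0, b1, k) rep(rep(b0:b1, each = k), 1),
                        ty0, ty1, tx1 - tx0 + 1, SIMPLIFY = FALSE))
  binkey <- binx + (nbx + 2) * biny
  tri_by_bin <- split(tri_id, binkey)
  pbx <- pmin(pmax(floor((px - xr[1]) / sx), 0), nbx - 1)
  pby <- pmin(pmax(floor((py - yr[1]) / sy), 0), nby - 1)
  pkey <- as.character(pbx + (nbx + 2) * pby)
  cand <- tri_by_bin[pkey]
  lens <- lengths(cand)
  if (sum(lens) == 0) return(rep(FALSE, nrow(points)))
  pp <- rep(seq_len(nrow(points)), lens)
  tt <- unlist(cand, use.names = FALSE)
  # 2-D point-in-triangle (signed areas)
  qx <- px[pp]; qy <- py[pp]
  s1 <- (bx[tt] - ax[tt]) * (qy - ay[tt]) - (by[tt] - ay[tt]) * (qx - ax[tt])
  s2 <- (cx[tt] - bx[tt]) * (qy - by[tt]) - (cy[tt] - by[tt]) * (qx - bx[tt])
  s3 <- (ax[tt] - cx[tt]) * (qy - cy[tt]) - (ay[tt] - cy[tt]) * (qx - cx[tt])
  inside2d <- (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  keep <- which(inside2d)
  if (!length(keep)) return(rep(FALSE, nrow(points)))
  pp <- pp[keep]; tt <- tt[keep]
  # plane z at (qx, qy): solve from plane normal
  nrm <- face_normals2(mesh)
  nx <- nrm[tt, 1]; ny <- nrm[tt, 2]; nz <- nrm[tt, 3]
  # degenerate-in-z triangles (nz == 0) cannot be crossed by a vertical ray
  ok <- nz != 0
  pp <- pp[ok]; tt <- tt[ok]
  zhit <- az[tt] - ((px[pp] - ax[tt]) * nx[ok] + (py[pp] - ay[tt]) * ny[ok]) / nz[ok]
  above <- zhit > pz[pp]
  cnt <- tabulate(pp[above], nbins = nrow(points))
  cnt %% 2L == 1L
}

#' Rasterize a closed mesh onto a voxel grid
#'
#' Marks a voxel inside when its center lies inside the surface (vertical
#' ray-crossing parity). The grid follows the package's world convention:
#' voxel `(i, j, k)` (0-based) has its center at `((i + 0.5) s)` mm.
#'
#' @param mesh a watertight `tri_mesh`.
#' @param spacing voxel spacing in mm (scalar or triple).
#' @param dims integer triple: grid dimensions. Defaults to the smallest
#'   grid containing the mesh.
#' @return Logical 3-D array mask.
#' @export
voxelize_mesh <- function(mesh, spacing, dims = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is_watertight(mesh)) stop("mesh is not watertight; cannot voxelize")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(dims)) dims <- as.integer(ceiling(apply(mesh$vertices, 2, max) / spacing))
  dims <- as.integer(dims)
  bb <- apply(mesh$vertices, 2, range)
  i0 <- pmax(floor(bb[1, ] / spacing - 0.5), 0)
  i1 <- pmin(ceiling(bb[2, ] / spacing), dims - 1L)
  mask <- array(FALSE, dims)
  if (any(i1 < i0)) return(mask)
  ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
  centers_xy <- cbind(rep((ii + 0.5) * spacing[1], times = length(jj)),
                      rep((jj + 0.5) * spacing[2], each = length(ii)))
  zc <- (kk + 0.5) * spacing[3]
  # evaluate parity for all (x, y, z-center) via one call per z-slab batch:
  # reuse the column machinery by testing all points of the sub-grid
  pts <- cbind(centers_xy[rep(seq_len(nrow(centers_xy)), times = length(zc)), ],
               rep(zc, each = nrow(centers_xy)))
  inside <- point_in_mesh(pts, mesh)
  sub <- array(inside, dim = c(length(ii), length(jj), length(kk)))
  mask[ii + 1L, jj + 1L, kk + 1L] <- sub
  mask
}

#' Dice coefficient of two binary masks
#' @param a,b logical arrays of identical dimensions.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# --- overlap resolution and scene assembly ---------------------------------

# minimum signed separation between two watertight meshes: the smallest
# surface-to-surface distance, negative if the meshes interpenetrate
# (vertex-sampled). Distances are capped at `cap` mm, which allows vertices
# far outside the other mesh's bounding box to be pruned.
mesh_separation <- function(m1, m2, cap = 10) {
  sep_dir <- function(p, mesh) {
    bb <- apply(mesh$vertices, 2, range)
    near <- p[, 1] >= bb[1, 1] - cap & p[, 1] <= bb[2, 1] + cap &
            p[, 2] >= bb[1, 2] - cap & p[, 2] <= bb[2, 2] + cap &
            p[, 3] >= bb[1, 3] - cap & p[, 3] <= bb[2, 3] + cap
    p <- p[near, , drop = FALSE]
    if (!nrow(p)) return(cap)
    d <- surface_distance(p, mesh)
    inside <- point_in_mesh(p, mesh)
    min(ifelse(inside, -d, d))
  }
  min(sep_dir(m1$vertices, m2), sep_dir(m2$vertices, m1), cap)
}

#' Translate a mesh until it clears another
#'
#' Translates `movable` along `direction` by the smallest multiple of
#' `step_mm` such that the minimum surface separation from `fixed` reaches
#' `clearance_mm`. Separation is measured at the mesh vertices (negative
#' when interpenetrating).
#'
#' @param fixed,movable watertight `tri_mesh` objects.
#' @param direction length-3 translation direction (normalized internally).
#' @param clearance_mm required minimum separation (default 0.5 mm).
#' @param step_mm translation quantum (default 0.1 mm).
#' @param max_travel_mm give up beyond this distance (default 300 mm).
#' @return List with `mesh` (translated copy of `movable`) and `offset_mm`
#'   (the applied translation distance).
#' @export
resolve_overlap <- function(fixed, movable, direction,
                            clearance_mm = 0.5, step_mm = 0.1,
                            max_travel_mm = 300) {
  stopifnot(inherits(fixed, "tri_mesh"), inherits(movable, "tri_mesh"))
  if (!is_watertight(fixed) || !is_watertight(movable))
    stop("both meshes must be watertight")
  dir <- direction / sqrt(sum(direction^2))
  sep_at <- function(k) {
    m <- movable
    m$vertices <- sweep(m$vertices, 2, k * step_mm * dir, `+`)
    mesh_separation(fixed, m)
  }
  if (sep_at(0) >= clearance_mm)
    return(list(mesh = movable, offset_mm = 0))
  k_hi <- 1L
  k_max <- ceiling(max_travel_mm / step_mm)
  while (sep_at(k_hi) < clearance_mm) {
    k_hi <- k_hi * 2L
    if (k_hi > k_max)
      stop("no separation achievable within ", max_travel_mm,
           " mm along the given direction")
  }
  k_lo <- k_hi %/% 2L
  while (k_hi - k_lo > 1L) {
    mid <- (k_lo + k_hi) %/% 2L
    if (sep_at(mid) >= clearance_mm) k_hi <- mid else k_lo <- mid
  }
  out <- movable
  out$vertices <- sweep(out$vertices, 2, k_hi * step_mm * dir, `+`)
  list(mesh = out, offset_mm = k_hi * step_mm)
}

#' Assemble meshes into a multi-solid scene
#'
#' Verifies that the named parts are pairwise non-overlapping and collects
#' them, preserving order, names and geometry.
#'
#' @param parts named list of watertight `tri_mesh` objects.
#' @return An object of class `mesh_scene`.
#' @export
assemble_scene <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  if (is.null(names(parts)) || any(!nzchar(names(parts))))
    names(parts) <- paste0("part", seq_along(parts))
  for (p in parts) {
    if (!inherits(p, "tri_mesh") || !is_watertight(p))
      stop("all parts must be watertight tri_mesh objects")
  }
  if (length(parts) > 1L) {
    idx <- utils::combn(length(parts), 2)
    for (c_ in seq_len(ncol(idx))) {
      i <- idx[1, c_]; j <- idx[2, c_]
      if (mesh_separation(parts[[i]], parts[[j]]) <= 0)
        stop("assembly error: parts '", names(parts)[i], "' and '",
             names(parts)[j], "' overlap")
    }
  }
  structure(list(parts = parts), class = "mesh_scene")
}

#' @export
print.mesh_scene <- function(x, ...) {
  cat("Mesh scene with", length(x$parts), "solid(s):",
      paste(names(x$parts), collapse = ", "), "\n")
  invisible(x)
}
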