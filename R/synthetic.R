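#' Specification for a synthetic anthropomorphic phantom
#'
#' Describes the synthetic stand-in for a reference voxel anatomy: an
#' elliptical body (a right elliptical cylinder, matching the physical
#' background housing), a liver with an embedded spherical tumour
#' compartment, a spleen, and two kidneys each split into cortex and
#' medulla. Organ shapes are ellipsoids/spheres sized from the target
#' volumes and placed at fixed anatomy-like positions.
#'
#' Default target volumes are the design (STL) volumes of the reference
#' phantom: liver 1306.7, spleen 124.9, tumour 15.9, cortex 90.9/75.7 and
#' medulla 42.9/35.7 mL (left/right). The default body is an elliptical
#' cylinder with internal major/minor axes of 258 and 198 mm and a height
#' of 268 mm.
#'
#' @param volumes_mL named vector of target volumes (mL) for roles
#'   `liver`, `spleen`, `tumour`, `cortex-L`, `cortex-R`, `medulla-L`,
#'   `medulla-R`. The liver target excludes the embedded tumour.
#' @param body_semi_axes_mm ellipse semi-axes (x, y) of the body cylinder.
#' @param body_height_mm body cylinder height.
#' @param spacing_mm isotropic voxel spacing.
#' @param seed integer seed recorded for reproducibility (generation is
#'   fully deterministic).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(volumes_mL = c(liver = 1306.7, spleen = 124.9,
                                          tumour = 15.9,
                                          `cortex-L` = 90.9, `cortex-R` = 75.7,
                                          `medulla-L` = 42.9, `medulla-R` = 35.7),
                           body_semi_axes_mm = c(129, 99),
                           body_height_mm = 268,
                           spacing_mm = 2,
                           seed = 1L) {
  needed <- c("liver", "spleen", "tumour", "cortex-L", "cortex-R",
              "medulla-L", "medulla-R")
  if (!all(needed %in% names(volumes_mL)))
    stop("volumes_mL must name: ", paste(needed, collapse = ", "))
  if (any(volumes_mL <= 0)) stop("all target volumes must be positive")
  if (volumes_mL[["tumour"]] >= volumes_mL[["liver"]])
    stop("tumour volume must be smaller than liver volume")
  if (any(body_semi_axes_mm <= 0) || body_height_mm <= 0 || spacing_mm <= 0)
    stop("body dimensions and spacing must be positive")
  structure(list(volumes_mL = volumes_mL,
                 body_semi_axes_mm = body_semi_axes_mm,
                 body_height_mm = body_height_mm,
                 spacing_mm = spacing_mm,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# semi-axes of an ellipsoid with volume V (mm^3) and axis ratios (1, ry, rz)
ellipsoid_semi_axes <- function(V_mm3, ry, rz) {
  r <- (V_mm3 * 3 / (4 * pi) / (ry * rz))^(1 / 3)
  c(r, ry * r, rz * r)
}

# linear voxel indices whose centers lie inside an axis-aligned ellipsoid
ellipsoid_voxels <- function(dims, s, center, semi) {
  lo <- pmax(floor((center - semi) / s), 0)
  hi <- pmin(ceiling((center + semi) / s), dims - 1L)
  if (any(hi < lo)) return(integer(0))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- (((ii + 0.5) * s - center[1]) / semi[1])^2
  dy2 <- (((jj + 0.5) * s - center[2]) / semi[2])^2
  dz2 <- (((kk + 0.5) * s - center[3]) / semi[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) < 1
  w <- which(inside)
  if (!length(w)) return(integer(0))
  co <- arrayInd(w, dim(inside))
  (co[, 1] + lo[1] - 1L) + dims[1] * ((co[, 2] + lo[2] - 1L) +
    dims[2] * (co[, 3] + lo[3] - 1L)) + 1L
}

#' Generate a synthetic anthropomorphic voxel phantom
#'
#' Rasterizes the organs of a [synthetic_spec()] onto a voxel grid:
#' elliptical-cylinder body, ellipsoidal liver containing a spherical
#' tumour, ellipsoidal spleen, and two kidneys modelled as nested
#' ellipsoids (the inner one the medulla, the shell between them the
#' cortex). Placement is deterministic; organ sizes derive analytically
#' from the target volumes, so voxel-count volumes approach the targets as
#' the spacing shrinks.
#'
#' @param spec a [synthetic_spec()].
#' @return A `voxel_phantom` whose organ table covers one region per
#'   compartment role. Fails with a feasibility error if the requested
#'   organs cannot be placed disjointly inside the body on the given grid.
#' @export
generate_synthetic_phantom <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- spec$spacing_mm
  a <- spec$body_semi_axes_mm[1]; b <- spec$body_semi_axes_mm[2]
  h <- spec$body_height_mm
  V <- spec$volumes_mL * 1000  # mm^3
  m <- 2 * s                   # outside margin
  dims <- as.integer(ceiling(c(2 * a + 2 * m, 2 * b + 2 * m, h + 2 * m) / s))
  cx <- dims[1] * s / 2; cy <- dims[2] * s / 2
  z0 <- (dims[3] * s - h) / 2

  # body: elliptical cylinder
  xc <- ((seq_len(dims[1]) - 0.5) * s - cx) / a
  yc <- ((seq_len(dims[2]) - 0.5) * s - cy) / b
  zc <- (seq_len(dims[3]) - 0.5) * s
  ell2d <- outer(xc^2, yc^2, `+`) < 1
  inz <- zc >= z0 & zc <= z0 + h
  body <- array(FALSE, dims)
  body[, , inz] <- ell2d

  # organ geometry: centers relative to (cx, cy, z0), semi-axes from volumes
  liver_semi <- ellipsoid_semi_axes(V[["liver"]] + V[["tumour"]], 0.76, 0.66)
  tum_r <- (V[["tumour"]] * 3 / (4 * pi))^(1 / 3)
  spleen_semi <- ellipsoid_semi_axes(V[["spleen"]], 0.62, 0.45)
  kidL_semi <- ellipsoid_semi_axes(V[["cortex-L"]] + V[["medulla-L"]], 0.55, 0.50)
  kidR_semi <- ellipsoid_semi_axes(V[["cortex-R"]] + V[["medulla-R"]], 0.55, 0.50)
  medL_semi <- kidL_semi * (V[["medulla-L"]] /
                              (V[["cortex-L"]] + V[["medulla-L"]]))^(1 / 3)
  medR_semi <- kidR_semi * (V[["medulla-R"]] /
                              (V[["cortex-R"]] + V[["medulla-R"]]))^(1 / 3)

  liver_c <- c(cx - 36, cy - 8, z0 + 160)
  tum_c <- liver_c + c(20, 8, 10)
  spleen_c <- c(cx + 72, cy + 18, z0 + 220)
  kidL_c <- c(cx + 48, cy + 46, z0 + 88)
  kidR_c <- c(cx - 48, cy + 46, z0 + 88)

  vox <- list(
    liver = ellipsoid_voxels(dims, s, liver_c, liver_semi),
    tumour = ellipsoid_voxels(dims, s, tum_c, rep(tum_r, 3)),
    spleen = ellipsoid_voxels(dims, s, spleen_c, spleen_semi),
    `kidney-L` = ellipsoid_voxels(dims, s, kidL_c, kidL_semi),
    `medulla-L` = ellipsoid_voxels(dims, s, kidL_c, medL_semi),
    `kidney-R` = ellipsoid_voxels(dims, s, kidR_c, kidR_semi),
    `medulla-R` = ellipsoid_voxels(dims, s, kidR_c, medR_semi)
  )
  if (any(lengths(vox) == 0L))
    stop("feasibility error: an organ rasterized to zero voxels at ",
         s, " mm spacing")

  # feasibility checks
  body_idx <- which(body)
  outside <- setdiff(unique(unlist(vox[c("liver", "spleen", "kidney-L",
                                         "kidney-R")])), body_idx)
  if (length(outside))
    stop("feasibility error: organ voxels fall outside the body ellipse")
  if (length(setdiff(vox$tumour, vox$liver)))
    stop("feasibility error: tumour not fully inside the liver")
  if (length(intersect(vox$`kidney-R`, vox$liver)))
    stop("feasibility error: right kidney overlaps the liver")
  if (length(intersect(vox$`kidney-L`, vox$spleen)))
    stop("feasibility error: left kidney overlaps the spleen")
  if (length(intersect(vox$liver, vox$spleen)))
    stop("feasibility error: liver overlaps the spleen")
  if (length(setdiff(vox$`medulla-L`, vox$`kidney-L`)) ||
      length(setdiff(vox$`medulla-R`, vox$`kidney-R`)))
    stop("feasibility error: medulla not nested inside its kidney")

  labels <- array(0L, dims)
  labels[body_idx] <- 1L
  labels[vox$liver] <- 2L
  labels[vox$tumour] <- 4L
  labels[vox$spleen] <- 3L
  labels[vox$`kidney-L`] <- 5L
  labels[vox$`medulla-L`] <- 6L
  labels[vox$`kidney-R`] <- 7L
  labels[vox$`medulla-R`] <- 8L

  organ_table <- data.frame(
    id = 1:8,
    name = c("body", "liver", "spleen", "tumour",
             "left kidney cortex", "left kidney medulla",
             "right kidney cortex", "right kidney medulla"),
    role = c("body", "liver", "spleen", "tumour",
             "cortex-L", "medulla-L", "cortex-R", "medulla-R"),
    stringsAsFactors = FALSE
  )
  phantom <- load_voxel_phantom(labels, s, organ_table)
  attr(phantom, "spec") <- spec
  phantom
}
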