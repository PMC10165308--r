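test_that("divergence-theorem volume is exact on the cube", {
  cb <- cube_mesh(10)
  expect_true(is_watertight(cb))
  expect_equal(mesh_volume(cb), 1.000, tolerance = 1e-12)
  # reversed winding is flagged, not silently negated
  inv <- cb
  inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_error(mesh_volume(inv), "winding")
  # an open mesh has no defined enclosed volume
  open_mesh <- cb
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_false(is_watertight(open_mesh))
  expect_error(mesh_volume(open_mesh), "watertight")
})

test_that("extracted ellipsoid surface matches the closed-form volume", {
  dims <- c(70, 50, 30)
  lab <- array(0L, dims)
  xc <- ((1:70) - 0.5) - 35; yc <- ((1:50) - 0.5) - 25; zc <- ((1:30) - 0.5) - 15
  inside <- outer(outer((xc / 30)^2, (yc / 20)^2, `+`), (zc / 10)^2, `+`) < 1
  lab[inside] <- 1L
  p <- load_voxel_phantom(lab, 1, data.frame(id = 1L, name = "e", role = "other"))
  m <- extract_surface(p, 1)
  expect_true(is_watertight(m))
  closed_form <- 4 / 3 * pi * 30 * 20 * 10 / 1000
  expect_equal(mesh_volume(m), closed_form, tolerance = 0.02)
  # the boundary surface encloses exactly the voxel volume
  expect_equal(mesh_volume(m), sum(inside) / 1000, tolerance = 1e-12)
  # empty region
  p$organ_table <- rbind(p$organ_table,
                         data.frame(id = 2L, name = "g", role = "other"))
  expect_error(extract_surface(p, 2), "empty")
})

test_that("every organ of the default phantom extracts watertight", {
  p <- default_phantom()
  for (role in c("liver", "spleen", "tumour", "cortex-L", "cortex-R",
                 "medulla-L", "medulla-R")) {
    m <- extract_surface(p, role)
    expect_true(is_watertight(m), label = paste("watertight", role))
    vox_mL <- phantom_volumes(p)
    vv <- vox_mL$volume_mL[vox_mL$role == role]
    expect_equal(mesh_volume(m), vv, tolerance = 0.03,
                 label = paste("volume", role))
  }
})

test_that("Laplacian smoothing shrinks area monotonically, keeps topology", {
  # voxel-stepped sphere, radius 10 mm on a 1 mm grid
  dims <- c(24, 24, 24)
  cc <- ((1:24) - 0.5) - 12
  inside <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`) < 100
  lab <- array(0L, dims); lab[inside] <- 1L
  p <- load_voxel_phantom(lab, 1, data.frame(id = 1L, name = "s", role = "other"))
  m <- extract_surface(p, 1)
  expect_identical(laplacian_smooth(m, 0)$vertices, m$vertices)
  areas <- numeric(10)
  disp <- numeric(10)
  cur <- m
  for (i in 1:10) {
    nxt <- laplacian_smooth(cur, 1, 0.5)
    areas[i] <- mesh_area(nxt)
    disp[i] <- max(sqrt(rowSums((nxt$vertices - cur$vertices)^2)))
    expect_identical(nxt$faces, cur$faces)
    expect_true(is_watertight(nxt))
    cur <- nxt
  }
  expect_true(all(diff(c(mesh_area(m), areas)) < 0))
  # per-iteration displacement settles (smoothing converges)
  expect_true(all(diff(disp) <= 1e-9))
  expect_error(laplacian_smooth(m, 10, lambda = 1.5), "lambda")
  expect_error(laplacian_smooth(m, 10, lambda = 0), "lambda")
})

test_that("default smoothing keeps the liver volume within 5%", {
  sm <- liver_mesh_smoothed()
  expect_true(is_watertight(sm))
  expect_lt(abs(attr(sm, "volume_change")), 0.05)
})

test_that("icosphere at the tumour design radius encloses the design volume", {
  r <- (3 * 15.9e3 / (4 * pi))^(1 / 3)
  expect_equal(r, 15.60, tolerance = 1e-3)
  ic <- icosphere(r, 5)
  expect_equal(nrow(ic$faces), 20480)
  expect_true(is_watertight(ic))
  expect_equal(mesh_volume(ic), 15.9, tolerance = 0.002)
})

test_that("shell extrusion reproduces the offset-sphere closed form", {
  sp <- icosphere(15.58, 4)
  sh <- extrude_shell(sp, 2)
  expect_true(is_watertight(sh$outer))
  closed_form <- 4 / 3 * pi * 17.58^3 / 1000
  expect_equal(mesh_volume(sh$outer), closed_form, tolerance = 0.01)
  expect_gt(mesh_volume(sh$outer), mesh_volume(sh$inner))
  expect_error(extrude_shell(sp, 0), "positive")
  expect_error(extrude_shell(sp, -1), "positive")
})

test_that("medulla shells keep their 1 mm wall within 5%", {
  p <- default_phantom()
  sh <- extrude_shell(laplacian_smooth(extract_surface(p, "medulla-R")), 1)
  expect_equal(mean_wall_distance(sh), 1.0, tolerance = 0.05)
})

test_that("overlap resolution translates by the minimal clearing step", {
  a <- icosphere(10, 3)
  b <- icosphere(10, 3, center = c(15, 0, 0))
  # sphere-pair geometry: 5 mm penetration + 0.5 mm clearance
  r <- resolve_overlap(a, b, c(1, 0, 0))
  expect_gte(r$offset_mm, 5.4)
  expect_lte(r$offset_mm, 5.7)
  expect_gte(mesh_separation(a, r$mesh), 0.5 - 1e-6)
  # already clear: zero translation
  c1 <- icosphere(1, 2); c2 <- icosphere(1, 2, center = c(0, 0, 3.1))
  expect_equal(resolve_overlap(c1, c2, c(0, 0, 1))$offset_mm, 0)
  # pushing into the fixed mesh can never clear
  expect_error(resolve_overlap(a, b, c(-1, 0, 0), max_travel_mm = 20),
               "no separation")
})

test_that("scene assembly verifies pairwise clearance", {
  single <- assemble_scene(list(liver = icosphere(5, 2)))
  expect_s3_class(single, "mesh_scene")
  expect_identical(single$parts$liver$vertices, icosphere(5, 2)$vertices)
  expect_error(assemble_scene(list(a = icosphere(5, 2), b = icosphere(5, 2))),
               "overlap")
})

test_that("liver and right-kidney shells assemble after overlap resolution", {
  p <- default_phantom()
  kid <- merge_labels(p, c("8" = 7))  # whole right kidney
  sh_kid <- extrude_shell(laplacian_smooth(extract_surface(kid, 7)), 2)
  sh_liv <- liver_shell()
  res <- resolve_overlap(sh_liv$outer, sh_kid$outer, c(0, 1, 0))
  sc <- assemble_scene(list(liver = sh_liv$outer, `kidney-R` = res$mesh))
  expect_named(sc$parts, c("liver", "kidney-R"))
})

test_that("binary STL round trip preserves faces and float32 vertices", {
  ic <- icosphere(10, 3)
  path <- tempfile(fileext = ".stl")
  write_stl(ic, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(ic$faces))
  expect_equal(back$vertices[back$faces[1, ], ],
               matrix(ic$vertices[ic$faces[1, ], ], 3), tolerance = 1e-6)
  expect_equal(signed_volume_mL(back), signed_volume_mL(ic), tolerance = 1e-5)
  # write(read(write(x))) is bit-identical to write(x)
  path2 <- tempfile(fileext = ".stl")
  write_stl(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("ASCII and binary dialects agree on geometry", {
  ic <- icosphere(7, 3)
  pb <- tempfile(fileext = ".stl"); pa <- tempfile(fileext = ".stl")
  write_stl(ic, pb, "binary")
  write_stl(ic, pa, "ascii")
  vb <- signed_volume_mL(read_stl(pb))
  va <- signed_volume_mL(read_stl(pa))
  expect_equal(vb, va, tolerance = 1e-5)
  # multi-solid ASCII scenes read back as named meshes
  sc <- assemble_scene(list(a = icosphere(2, 2), b = icosphere(2, 2, center = c(10, 0, 0))))
  ps <- tempfile(fileext = ".stl")
  write_stl(sc, ps, "ascii")
  parts <- read_stl(ps)
  expect_named(parts, c("a", "b"))
})

test_that("corrupt STL files fail with byte diagnostics", {
  ic <- icosphere(5, 2)
  path <- tempfile(fileext = ".stl")
  write_stl(ic, path)
  raw <- readBin(path, "raw", file.size(path))
  # truncate mid-payload
  trunc_path <- tempfile(fileext = ".stl")
  writeBin(raw[1:200], trunc_path)
  expect_error(read_stl(trunc_path), "byte")
  # corrupt the triangle count field
  bad <- raw
  bad[81:84] <- as.raw(c(255, 255, 0, 0))
  bad_path <- tempfile(fileext = ".stl")
  writeBin(bad, bad_path)
  expect_error(read_stl(bad_path), "triangle count")
})

test_that("voxelization marks voxel centers by parity", {
  mask <- voxelize_mesh(cube_mesh(10), 1, dims = c(12, 12, 12))
  expect_equal(sum(mask), 1000)
  # mesh entirely outside the grid
  far <- cube_mesh(10, origin = c(100, 100, 100))
  expect_false(any(voxelize_mesh(far, 1, dims = c(12, 12, 12))))
  # open meshes are rejected
  open_mesh <- cube_mesh(10)
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(voxelize_mesh(open_mesh, 1, dims = c(12, 12, 12)), "watertight")
})

test_that("extract-then-voxelize round trip achieves Dice >= 0.99 per organ", {
  p <- default_phantom()
  for (role in c("liver", "spleen", "tumour", "cortex-L", "cortex-R",
                 "medulla-L", "medulla-R", "body")) {
    m <- extract_surface(p, role)
    mask <- voxelize_mesh(m, p$spacing, dim(p$labels))
    dice <- dice_coefficient(mask, organ_mask(p, role))
    expect_gte(dice, 0.99)
  }
})
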