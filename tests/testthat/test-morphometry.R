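test_that("voxel CoM is the mean of included voxel centres", {
  cube <- labelled_volume(array(1L, c(10, 10, 10)))
  expect_equal(voxel_com(cube, 1), c(4.5, 4.5, 4.5))

  two <- array(0L, c(11, 1, 1)); two[c(1, 11), 1, 1] <- 1L
  expect_equal(voxel_com(labelled_volume(two), 1), c(5, 0, 0))

  # body + legs: excluding leg mass shifts the CoM away from the legs
  g <- array(0L, c(8, 4, 4))
  g[1:4, , ] <- 1L          # body block, x centre 1.5
  g[5:8, 1:2, 1:2] <- 2L    # leg mass on the +x side
  vol <- labelled_volume(g)
  body_only <- voxel_com(vol, 1)
  all_mass <- voxel_com(vol, c(1, 2))
  expect_equal(body_only[1], 1.5)
  expect_gt(all_mass[1], body_only[1])
  # hand-computed: 64 body voxels at 1.5 + 16 leg voxels at 5.5
  expect_equal(all_mass[1], (64 * 1.5 + 16 * 5.5) / 80)
  expect_error(voxel_com(vol, 7), "empty selection")
})

test_that("voxel CoM is translation-equivariant and additive over regions", {
  g <- array(0L, c(6, 5, 4)); g[2:4, 2:3, 1:2] <- 1L; g[6, 5, 4] <- 2L
  v0 <- labelled_volume(g, spacing = c(0.5, 1, 2))
  shift <- c(3, -2, 7)
  v1 <- labelled_volume(g, spacing = c(0.5, 1, 2), origin = shift)
  expect_equal(voxel_com(v1, c(1, 2)), voxel_com(v0, c(1, 2)) + shift)
  # union CoM = volume-weighted mean of per-label CoMs
  n1 <- sum(g == 1); n2 <- sum(g == 2)
  expect_equal(voxel_com(v0, c(1, 2)),
               (n1 * voxel_com(v0, 1) + n2 * voxel_com(v0, 2)) / (n1 + n2),
               tolerance = 1e-12)
})

test_that("mesh CoM matches closed forms and is reference-invariant", {
  cube <- unit_cube_mesh(origin = c(2, 3, 4), side = 2)
  got <- mesh_com(cube)
  expect_equal(got$com, c(3, 4, 5), tolerance = 1e-12)
  expect_equal(got$volume, 8, tolerance = 1e-12)

  sph <- icosphere_mesh(centre = c(3, -1, 7), radius = 2, subdivisions = 3)
  gs <- mesh_com(sph)
  expect_lt(max(abs(gs$com - c(3, -1, 7))), 1e-6)
  expect_rel_equal(gs$volume, 4 / 3 * pi * 8, 0.01)

  # independence of the integration reference point and face order
  g2 <- mesh_com(sph, ref = c(100, -50, 3))
  expect_lt(max(abs(g2$com - gs$com)), 1e-9)
  withr::with_seed(8, {
    perm <- sample(nrow(sph$faces))
  })
  g3 <- mesh_com(tri_mesh(sph$vertices, sph$faces[perm, ]))
  expect_lt(max(abs(g3$com - gs$com)), 1e-9)
})

test_that("defective meshes are rejected with a defect report", {
  cube <- unit_cube_mesh()
  open_mesh <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_com(open_mesh), "mesh integrity")
  flipped <- cube$faces
  flipped[2, ] <- flipped[2, c(1, 3, 2)]
  expect_error(mesh_com(tri_mesh(cube$vertices, flipped)),
               "mesh integrity")
  wt <- check_watertight(open_mesh)
  expect_false(wt$ok)
  expect_match(wt$defects[1], "edge")
})

test_that("mesh and voxel CoM agree within half a voxel", {
  centre <- c(3, -1, 7); radius <- 2; sp <- 0.05
  sph <- icosphere_mesh(centre, radius, subdivisions = 3)
  mc <- mesh_com(sph)$com
  ax <- lapply(1:3, function(d)
    seq(centre[d] - radius - 2 * sp, centre[d] + radius + 2 * sp, by = sp))
  inside <- outer(
    outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
    (ax[[3]] - centre[3])^2, "+") <= radius^2
  vol <- labelled_volume(array(as.integer(inside), dim = lengths(ax)),
                         spacing = rep(sp, 3),
                         origin = vapply(ax, `[`, numeric(1), 1))
  vc <- voxel_com(vol, 1)
  expect_lt(max(abs(mc - vc)), sp / 2)
})

test_that("block-majority binning halves resolution with stable CoM", {
  u <- labelled_volume(array(3L, c(8, 8, 8)), spacing = c(1, 1, 1))
  b <- binning_downsample(u)
  expect_equal(dim(b$grid), c(4, 4, 4))
  expect_true(all(b$grid == 3L))
  expect_equal(b$spacing, c(2, 2, 2))

  # checkerboard: every 2x2x2 block ties 4-4, resolved to the lower label
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  chk <- array(1L + (rowSums(idx) %% 2L), c(4, 4, 4))
  bc <- binning_downsample(labelled_volume(chk))
  expect_true(all(bc$grid == 1L))

  # ellipsoid: CoM moves by less than one coarse voxel under binning
  ax <- lapply(c(50, 40, 30), function(n) seq_len(n))
  e <- outer(outer(((ax[[1]] - 30) / 18)^2, ((ax[[2]] - 18) / 12)^2, "+"),
             ((ax[[3]] - 14) / 9)^2, "+") <= 1
  ev <- labelled_volume(array(as.integer(e), dim = lengths(ax)))
  eb <- binning_downsample(ev)
  expect_lt(max(abs(voxel_com(ev, 1) - voxel_com(eb, 1))), 2)

  odd <- labelled_volume(array(1L, c(5, 4, 4)))
  expect_warning(bo <- binning_downsample(odd), "padding")
  expect_equal(dim(bo$grid), c(3, 2, 2))
})

test_that("ASCII STL round trip preserves geometry", {
  sph <- icosphere_mesh(centre = c(1, 2, 3), radius = 1.5, subdivisions = 2)
  f <- tempfile(fileext = ".stl")
  write_stl(sph, f)
  back <- read_stl(f)
  expect_equal(nrow(back$faces), nrow(sph$faces))
  a <- mesh_com(sph); b <- mesh_com(back)
  expect_lt(max(abs(a$com - b$com)), 1e-6)
  expect_rel_equal(b$volume, a$volume, 1e-6)
})

test_that("NIfTI round trip preserves labels and spacing", {
  g <- array(0L, c(6, 5, 4)); g[2:4, 2:3, 1:2] <- 1L; g[5, 4, 3] <- 2L
  vol <- labelled_volume(g, spacing = c(0.1, 0.1, 0.2))
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, f)
  back <- read_volume_nifti(f)
  expect_equal(back$grid, vol$grid)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})
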