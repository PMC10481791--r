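# Tet mesh generators, face topology, import/export.

test_that("primitive generators produce watertight meshes with the expected volumes", {
  cu <- generate_core("cuboid", list(lx = 1, ly = 1, lz = 1), list(n = c(5L, 5L, 5L)))
  expect_equal(sum(cu$volume), 1, tolerance = 1e-12)
  expect_equal(nrow(cu$tets), 6L * 125L)
  cyl <- generate_core("cylinder", list(radius = 0.5, height = 2),
                       list(nxy = 8L, nz = 2L))  # 64-gon boundary
  expect_lt(abs(sum(cyl$volume) / (pi * 0.25 * 2) - 1), 0.01)
  frame <- generate_core("c_shape",
                         list(width = 0.1, height = 0.08, depth = 0.02,
                              thickness = 0.02, gap = 0),
                         list(h = 5e-3))
  gap0 <- generate_core("c_shape",
                        list(width = 0.1, height = 0.08, depth = 0.02,
                             thickness = 0.02, gap = 1e-9),
                        list(h = 5e-3))
  expect_equal(sum(frame$volume), sum(gap0$volume))  # vanishing gap = closed frame
  gap <- generate_core("c_shape",
                       list(width = 0.1, height = 0.08, depth = 0.02,
                            thickness = 0.02, gap = 0.02),
                       list(h = 5e-3))
  expect_lt(sum(gap$volume), sum(frame$volume))
  expect_error(generate_core("cuboid", list(lx = 0, ly = 1, lz = 1)), "positive")
})

test_that("face topology satisfies counting identities, orientation and closure", {
  one <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(1:4, 1))
  fs1 <- build_faces(one)
  expect_equal(length(fs1$area), 4L)
  expect_true(all(fs1$is_boundary))
  two <- two_tet_mesh()
  fs2 <- build_faces(two)
  expect_equal(length(fs2$area), 7L)
  expect_equal(sum(!fs2$is_boundary), 1L)
  # inner face: plus tet is the lower index, normal points plus -> minus
  inner <- which(!fs2$is_boundary)
  expect_equal(fs2$plus_tet[inner], 1L)
  expect_equal(fs2$minus_tet[inner], 2L)
  dir <- two$centroid[2, ] - two$centroid[1, ]
  expect_gt(sum(fs2$normal[inner, ] * dir), 0)
  # counting identity and closed-boundary sum on a structured mesh
  cu <- generate_core("cuboid", list(lx = 1, ly = 2, lz = 1), list(n = c(4L, 4L, 3L)))
  fs <- build_faces(cu)
  expect_equal(4L * nrow(cu$tets), 2L * sum(!fs$is_boundary) + sum(fs$is_boundary))
  b <- fs$is_boundary
  expect_lt(max(abs(colSums(fs$normal[b, ] * fs$area[b]))), 1e-12 * sum(fs$area[b]))
  # outward boundary normals on a convex body
  expect_true(all(rowSums(fs$normal[b, ] * fs$center[b, ]) -
                    rowSums(fs$normal[b, ] * cu$centroid[fs$plus_tet[b], ]) > 0))
})

test_that("the face set is invariant under tet reordering", {
  cu <- generate_core("cuboid", list(lx = 1, ly = 1, lz = 1), list(n = c(3L, 3L, 3L)))
  perm <- rev(seq_len(nrow(cu$tets)))
  cu2 <- tet_mesh(cu$vertices, cu$tets[perm, ])
  key <- function(fs) sort(paste(fs$faces[, 1], fs$faces[, 2], fs$faces[, 3]))
  expect_identical(key(build_faces(cu)), key(build_faces(cu2)))
})

test_that("non-manifold and degenerate meshes are rejected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1), c(-1, -1, 1))
  three <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5), c(1, 2, 3, 6))
  expect_error(build_faces(tet_mesh(V, three)), "non-manifold")
  expect_error(tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        matrix(1:4, 1)), "degenerate")
})

test_that("STL export/import round-trips a generated surface", {
  cu <- generate_core("cuboid", list(lx = 0.01, ly = 0.01, lz = 0.01),
                      list(n = c(3L, 3L, 3L)))
  surf <- as_surface(cu)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(surf, path)                       # m -> mm on write
  back <- import_stl(path)                    # mm -> m on read
  expect_equal(nrow(back$triangles), nrow(surf$triangles))
  vol_back <- sum(tetrahedralize_surface(back, h = 0.01 / 3)$volume)
  expect_lt(abs(vol_back / 1e-6 - 1), 0.01)
  # a deleted facet produces an open-edge diagnostic, not a mesh
  broken <- surface_mesh(surf$vertices, surf$triangles[-1, ])
  path2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(broken, path2)
  expect_error(import_stl(path2), class = "coremag_open_surface")
})

test_that("external node/ele tet meshes are read with unit scaling", {
  ball <- ball_mesh(1e-2, n = 12L)    # ~10^4 tets
  dir <- withr::local_tempdir()
  npath <- file.path(dir, "s.node"); epath <- file.path(dir, "s.ele")
  writeLines(c(sprintf("%d 3 0 0", nrow(ball$vertices)),
               sprintf("%d %.10g %.10g %.10g", seq_len(nrow(ball$vertices)),
                       ball$vertices[, 1], ball$vertices[, 2], ball$vertices[, 3])),
             npath)
  writeLines(c(sprintf("%d 4 0", nrow(ball$tets)),
               sprintf("%d %d %d %d %d", seq_len(nrow(ball$tets)),
                       ball$tets[, 1], ball$tets[, 2], ball$tets[, 3], ball$tets[, 4])),
             epath)
  mesh <- read_tet_mesh(npath, epath)
  expect_equal(nrow(mesh$tets), nrow(ball$tets))
  expect_lt(abs(sum(mesh$volume) / (4 / 3 * pi * 1e-6) - 1), 0.02)
})

test_that("VTK export writes a parseable unstructured grid", {
  cu <- generate_core("cuboid", list(lx = 1, ly = 1, lz = 1), list(n = c(2L, 2L, 2L)))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(cu, path, cell_data = list(mu_r = rep(2, nrow(cu$tets))))
  txt <- readLines(path)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", txt)))
  expect_true(any(grepl(sprintf("CELLS %d", nrow(cu$tets)), txt)))
  expect_true(any(grepl("SCALARS mu_r", txt)))
})
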