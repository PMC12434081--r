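test_that("triangle area matches closed forms and handles degeneracy", {
  expect_equal(triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(triangle_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
  # equilateral triangle of side 2 has area sqrt(3)
  expect_equal(triangle_area(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)), sqrt(3))
  expect_error(triangle_area(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)), "finite")
})

test_that("mesh surface area: cube, additivity, empty mesh", {
  cube <- make_test_mesh("cube", side = 1)
  expect_equal(mesh_surface_area(cube), 6)
  expect_equal(mesh_surface_area(make_test_mesh("cube", side = 2.5)), 6 * 2.5^2)
  # union of two disjoint cubes is additive
  two <- tri_mesh(rbind(cube$vertices, cube$vertices + 10),
                  rbind(cube$faces, cube$faces + nrow(cube$vertices)))
  expect_equal(mesh_surface_area(two), 12)
  empty <- tri_mesh(cube$vertices, matrix(integer(0), ncol = 3))
  expect_warning(a0 <- mesh_surface_area(empty), "no faces")
  expect_equal(a0, 0)
})

test_that("icosphere area converges monotonically to the sphere area from below", {
  areas <- sapply(0:4, function(s)
    mesh_surface_area(make_test_mesh("icosphere", radius = 1, subdivisions = s)))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas <= 4 * pi))
  expect_lt((4 * pi - areas[5]) / (4 * pi), 0.01)  # within 1% at subdivision 4
})

test_that("capsule mesh converges to the analytic cylinder + caps area", {
  analytic <- 2 * pi * 0.15 * 1.4 + 4 * pi * 0.15^2
  cap <- make_test_mesh("capsule", radius = 0.15, length = 1.4, segments = 96)
  expect_equal(attr(cap, "analytic_area"), analytic)
  a <- mesh_surface_area(cap)
  expect_lt(abs(a - analytic) / analytic, 0.005)
  expect_lt(a, analytic)  # inscribed
  coarse <- mesh_surface_area(make_test_mesh("capsule", radius = 0.15,
                                             length = 1.4, segments = 24))
  expect_lt(abs(a - analytic), abs(coarse - analytic))
})

test_that("area is invariant under rigid motions and relabelling, covariant in scale", {
  set.seed(11)
  for (rep in 1:5) {
    nv <- 12
    v <- matrix(runif(nv * 3), ncol = 3)
    f <- matrix(sample(nv, 30, replace = TRUE), ncol = 3)
    m <- tri_mesh(v, f)
    a <- mesh_surface_area(m)
    R <- rotation_matrix(runif(1, 0, pi), runif(1, 0, pi), runif(1, 0, pi))
    moved <- tri_mesh(v %*% t(R) + 0.7, f)
    expect_equal(mesh_surface_area(moved), a, tolerance = 1e-10)
    k <- runif(1, 0.2, 5)
    expect_equal(mesh_surface_area(tri_mesh(v * k, f)), a * k^2, tolerance = 1e-10)
    # permute faces and relabel vertices consistently
    perm <- sample(nv)
    inv <- order(perm)
    relabelled <- tri_mesh(v[perm, ], matrix(inv[f], ncol = 3)[sample(nrow(f)), ])
    expect_equal(mesh_surface_area(relabelled), a, tolerance = 1e-12)
  }
})

test_that("OBJ round-trip preserves area and fan-triangulates quads", {
  cube <- make_test_mesh("cube", side = 1)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(cube, path)
  back <- read_obj(path)
  expect_equal(mesh_surface_area(back), 6, tolerance = 1e-6)
  # quad face + texture indices + mm scale
  quad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1000 0 0", "v 1000 1000 0", "v 0 1000 0",
               "f 1/1 2/2 3/3 4/4"), quad)
  m <- read_obj(quad, scale = 1e-3)
  expect_equal(nrow(m$faces), 2)
  expect_equal(mesh_surface_area(m), 1)
})

test_that("PLY reader handles ASCII and binary little-endian layouts", {
  ascii <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "3 0 1 2", "3 0 2 3"), ascii)
  m <- read_ply(ascii)
  expect_equal(mesh_surface_area(m), 1)

  bin <- withr::local_tempfile(fileext = ".ply")
  con <- file(bin, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeBin(as.numeric(c(0, 0, 0, 1, 0, 0, 0, 1, 0)), con, size = 4,
           endian = "little")
  writeBin(as.integer(3), con, size = 1)
  writeBin(as.integer(c(0, 1, 2)), con, size = 4, endian = "little")
  close(con)
  m2 <- read_ply(bin)
  expect_equal(mesh_surface_area(m2), 0.5, tolerance = 1e-7)
})

test_that("replicate averaging is the arithmetic mean with single-scan warning", {
  expect_equal(average_replicates(c(1.80, 1.82)), 1.81)
  expect_equal(average_replicates(c(1.77, 1.77)), 1.77)
  expect_warning(one <- average_replicates(1.75), "single scan")
  expect_equal(one, 1.75)
  expect_error(average_replicates(numeric(0)), "no scan")
  expect_error(average_replicates(c(1.8, -0.1)), "> 0")
})

test_that("Grubbs flags a gross outlier against the t-based critical value", {
  x <- c(1, 1.01, 0.99, 1.02, 10)
  res <- grubbs_outliers(x, alpha = 0.05)
  expect_equal(res$outliers, 5L)
  # independent check: published two-sided critical value for n = 5 is 1.715
  expect_equal(res$steps$G_crit[1], 1.715, tolerance = 1e-3)
  expect_gt(res$steps$G[1], res$steps$G_crit[1])
})

test_that("Grubbs leaves tight clusters and degenerate samples unflagged", {
  set.seed(3)
  tight <- 1.8 * (1 + rnorm(50, 0, 0.005))  # CV ~ 0.5%
  expect_length(grubbs_outliers(tight)$outliers, 0)
  expect_warning(res <- grubbs_outliers(rep(2, 10)), "zero-variance")
  expect_length(res$outliers, 0)
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
})

test_that("criterion_from_scans averages replicates and reports QC", {
  scans <- data.frame(id = c("a", "b", "c", "d"),
                      scan1_bsa_m2 = c(1.80, 1.70, 1.90, 1.75),
                      scan2_bsa_m2 = c(1.82, 1.72, 1.88, 1.77))
  res <- criterion_from_scans(scans)
  expect_equal(res$criterion$criterion_bsa_m2, c(1.81, 1.71, 1.89, 1.76))
  expect_length(res$qc$outliers, 0)
  # mesh-path route
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "c1.obj"); p2 <- file.path(dir, "c2.obj")
  write_obj(make_test_mesh("cube", side = 0.5), p1)
  write_obj(make_test_mesh("cube", side = 0.55), p2)
  mtab <- data.frame(id = c("a", "b", "c"),
                     mesh_path_1 = p1, mesh_path_2 = p2)
  suppressWarnings(res2 <- criterion_from_scans(mtab))  # zero-variance QC
  expect_equal(res2$criterion$criterion_bsa_m2,
               rep((6 * 0.25 + 6 * 0.3025) / 2, 3))
})
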